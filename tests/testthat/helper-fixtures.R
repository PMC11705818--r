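# Shared fixture builders; everything is generated in code.

tmp_write <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small two-group study: `n_taxa` taxa with equal baselines, optional
# planted fold changes and one correlation block.
toy_study <- function(n_per_group = c(20L, 20L), n_taxa = 30L,
                      planted = NULL, block = NULL, noise = 0.5,
                      seed = 1L, base_mean = 1) {
  taxa <- data.frame(taxon = sprintf("t%03d", seq_len(n_taxa)),
                     kingdom = rep(c("fungal", "bacterial"),
                                   length.out = n_taxa),
                     base_mean = base_mean)
  simulate_abundance_study(n_per_group, taxa, planted, block, noise,
                           seed = seed)
}

# Random uniform-spectrum correlation-like matrix (diagonal only).
diag_random_matrix <- function(n = 200L, seed = 1L) {
  m <- diag(with_seed_test(seed, runif(n)))
  dimnames(m) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  m
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Scaled GOE matrix (symmetric iid Gaussian off-diagonal).
goe_matrix <- function(n = 200L, seed = 1L) {
  a <- with_seed_test(seed, matrix(rnorm(n * n), n))
  s <- (a + t(a)) / sqrt(2 * n)
  dimnames(s) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  s
}

# Brute-force two-sided rank-sum p-value by full enumeration of group
# assignments (tie-free inputs).
wilcox_enum_p <- function(x, y) {
  nx <- length(x)
  all <- c(x, y)
  r <- rank(all)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(length(all), nx)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# All-pairs AUC oracle with half-credit ties.
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Best-match Jaccard of each truth block against a component list.
block_jaccard <- function(blocks, comps) {
  vapply(blocks, function(b) {
    if (length(comps) == 0L) return(0)
    max(vapply(comps, function(cset)
      length(intersect(b, cset)) / length(union(b, cset)), numeric(1L)))
  }, numeric(1L))
}

unclass_table <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

components_of <- function(net, min_size = 3L) {
  comp <- mycoscan:::components_from_edges(net$nodes, net$edges)
  Filter(function(x) length(x) >= min_size, comp)
}
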