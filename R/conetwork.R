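# Fungal-bacterial co-occurrence networks: prevalence filter, Spearman
# correlation matrix, random-matrix-theory (RMT) threshold selection via
# the nearest-neighbor spacing distribution (NNSD), indirect-edge removal
# by network deconvolution, and the topology-metric panel.

new_co_network <- function(nodes, edges, kingdom = NULL, threshold = NA_real_) {
  deg <- setNames(rep(0L, length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    cnt <- table(c(edges$i, edges$j))
    deg[names(cnt)] <- as.integer(cnt)
  }
  structure(list(nodes = nodes, edges = edges,
                 kingdom = kingdom %||%
                   setNames(rep(NA_character_, length(nodes)), nodes),
                 threshold = threshold, degree = deg),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("<co_network: %d nodes, %d edges, threshold %.2f>\n",
              length(x$nodes), nrow(x$edges),
              if (is.na(x$threshold)) NA else x$threshold))
  invisible(x)
}

#' Prevalence filter
#'
#' Keeps taxa detected (abundance > 0) in strictly more than
#' \code{min_prev} of the samples.
#'
#' @param table Samples x taxa abundance matrix.
#' @param min_prev Prevalence fraction (default 0.10).
#' @return Filtered matrix (kingdom attribute propagated).
#' @export
prevalence_filter <- function(table, min_prev = 0.10) {
  prev <- colMeans(table > 0)
  out <- table[, prev > min_prev, drop = FALSE]
  kd <- attr(table, "kingdom")
  if (!is.null(kd)) attr(out, "kingdom") <- kd[colnames(out)]
  out
}

#' Pairwise correlation matrix across taxa
#'
#' @param table Samples x taxa matrix (>= 10 samples).
#' @param method \code{"spearman"} (default, midranks for ties) or
#'   \code{"pearson"}.
#' @return Symmetric taxa x taxa correlation matrix; zero-variance taxa
#'   get zero correlations (with a warning) and the diagonal is 1.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(table) < 10L) stop("need >= 10 samples")
  zv <- apply(table, 2L, function(v) var(v) == 0)
  m <- suppressWarnings(cor(table, method = method))
  if (any(zv)) {
    warning("zero-variance taxa: ",
            paste(colnames(table)[zv], collapse = ", "))
    m[zv, ] <- 0; m[, zv] <- 0
  }
  m[is.na(m)] <- 0
  diag(m) <- 1
  m
}

#' NNSD goodness-of-fit p-value against the Poisson law
#'
#' Entries below the threshold (in absolute value) are zeroed (diagonal
#' kept), the masked matrix's eigenvalues are unfolded through a
#' monotone cubic spline fitted to the empirical spectral CDF (about
#' n/10 knots), and the normalized nearest-neighbor spacings are tested
#' by Kolmogorov-Smirnov against the exponential law P(s) = exp(-s).
#' Large p: uncorrelated (Poisson) spectrum; small p: GOE-like level
#' repulsion from correlated structure.
#'
#' @param matrix Symmetric correlation matrix.
#' @param threshold Masking threshold.
#' @return KS p-value.
#' @export
nnsd_poisson_pvalue <- function(matrix, threshold) {
  m <- matrix
  m[abs(m) < threshold] <- 0
  diag(m) <- diag(matrix)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(unique(ev))
  if (length(ev) < 20L)
    stop("fewer than 20 distinct eigenvalues; NNSD undefined")
  s <- unfolded_spacings(ev)
  suppressWarnings(ks.test(s, pexp, 1)$p.value)
}

# Spectral unfolding: monotone (Hyman) cubic spline through ceil(n/10)
# knots of the empirical CDF, eigenvalues mapped to unfolded positions,
# spacings normalized to unit mean.
unfolded_spacings <- function(ev) {
  n <- length(ev)
  cdf <- (seq_len(n) - 0.5) / n
  n_knots <- max(4L, ceiling(n / 10))
  ki <- unique(round(seq(1L, n, length.out = n_knots)))
  f <- splinefun(ev[ki], cdf[ki], method = "hyman")
  u <- n * f(ev)
  s <- diff(u)
  s <- s[s > 0]
  s / mean(s)
}

#' RMT threshold scan
#'
#' Scans thresholds ascending and returns the smallest one whose masked
#' matrix has a Poisson-compatible NNSD (p >= \code{p_cut}) and stays
#' Poisson for the next two steps (stability check). If no threshold
#' qualifies, \code{t_max} is returned with a warning.
#'
#' @param matrix Symmetric correlation matrix.
#' @param t_min,t_max,step Scan range and step (defaults 0.30-0.99, 0.01).
#' @param p_cut Poisson-compatibility cutoff (default 0.05).
#' @return Chosen threshold, with attribute \code{scan} (data.frame of
#'   threshold and p).
#' @export
rmt_threshold <- function(matrix, t_min = 0.30, t_max = 0.99, step = 0.01,
                          p_cut = 0.05) {
  ts <- seq(t_min, t_max, by = step)
  ps <- rep(NA_real_, length(ts))
  pval <- function(i) {
    if (i > length(ts)) return(NA_real_)
    if (is.na(ps[i]))
      ps[i] <<- tryCatch(nnsd_poisson_pvalue(matrix, ts[i]),
                         error = function(e) NA_real_)
    ps[i]
  }
  chosen <- NA_real_
  for (i in seq_along(ts)) {
    p0 <- pval(i)
    if (is.na(p0) || p0 < p_cut) next
    p1 <- pval(i + 1L); p2 <- pval(i + 2L)
    ok1 <- is.na(p1) || p1 >= p_cut
    ok2 <- is.na(p2) || p2 >= p_cut
    if (ok1 && ok2) { chosen <- ts[i]; break }
  }
  if (is.na(chosen)) {
    warning("no Poisson-compatible threshold found; returning t_max")
    chosen <- t_max
  }
  structure(chosen, scan = data.frame(threshold = ts, p = ps))
}

#' Mask a correlation matrix into a thresholded network
#'
#' Keeps every off-diagonal pair with |correlation| at or above the
#' threshold as an undirected signed edge.
#'
#' @param matrix Symmetric correlation matrix with taxon dimnames.
#' @param threshold Correlation threshold.
#' @param kingdom Optional named kingdom labels.
#' @return A \code{co_network}.
#' @export
threshold_network <- function(matrix, threshold, kingdom = NULL) {
  nodes <- colnames(matrix)
  idx <- which(abs(matrix) >= threshold & upper.tri(matrix), arr.ind = TRUE)
  edges <- data.frame(i = nodes[idx[, 1L]], j = nodes[idx[, 2L]],
                      weight = matrix[idx],
                      sign = ifelse(matrix[idx] >= 0, "+", "-"),
                      stringsAsFactors = FALSE)
  new_co_network(nodes, edges, kingdom = kingdom, threshold = threshold)
}

#' Remove indirect edges from a thresholded network
#'
#' Three steps: self-loops are dropped; edges at |weight| >= 0.999 are
#' flagged pathological and dropped; then per connected component the
#' weight matrix G is deconvolved as S = G (I + G)^-1, S is rescaled to
#' G's maximum absolute entry, and edges whose deconvolved strength
#' falls below the network threshold are removed (transitive, indirect
#' paths lose support). The output edge set is a subset of the input.
#'
#' @param net A \code{co_network}.
#' @return Pruned \code{co_network}.
#' @export
remove_indirect_edges <- function(net) {
  stopifnot(inherits(net, "co_network"))
  ed <- net$edges
  ed <- ed[ed$i != ed$j, , drop = FALSE]                    # self-loops
  ed <- ed[abs(ed$weight) < 0.999, , drop = FALSE]          # pathological
  if (nrow(ed) == 0L)
    return(new_co_network(net$nodes, ed, net$kingdom, net$threshold))
  comp <- components_from_edges(net$nodes, ed)
  keep <- rep(TRUE, nrow(ed))
  for (cnodes in comp) {
    if (length(cnodes) < 3L) next
    rows <- which(ed$i %in% cnodes & ed$j %in% cnodes)
    G <- matrix(0, length(cnodes), length(cnodes),
                dimnames = list(cnodes, cnodes))
    for (r in rows) {
      G[ed$i[r], ed$j[r]] <- ed$weight[r]
      G[ed$j[r], ed$i[r]] <- ed$weight[r]
    }
    S <- tryCatch(G %*% solve(diag(length(cnodes)) + G),
                  error = function(e) NULL)
    if (is.null(S)) {
      warning("singular (I + G); keeping component unpruned")
      next
    }
    diag(S) <- 0  # only off-diagonal entries are edges
    if (max(abs(S)) > 0) S <- S * (max(abs(G)) / max(abs(S)))
    thr <- if (is.na(net$threshold)) 0 else net$threshold
    for (r in rows) if (abs(S[ed$i[r], ed$j[r]]) < thr) keep[r] <- FALSE
  }
  new_co_network(net$nodes, ed[keep, , drop = FALSE], net$kingdom,
                 net$threshold)
}

# Connected components over an edge list (plus isolated nodes).
components_from_edges <- function(nodes, edges) {
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(match(edges$i[r], nodes)); b <- find(match(edges$j[r], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, numeric(1L))
  unname(split(nodes, roots))
}

#' Whole-network topology metrics
#'
#' Average neighbors 2E/N, density 2E/(N(N-1)), characteristic path
#' length (mean unweighted shortest path over connected pairs),
#' heterogeneity sd(k)/mean(k), Freeman degree centralization
#' (N/(N-2)) (k_max/(N-1) - density), and the ten highest-degree nodes
#' with kingdom labels (ties broken by node id).
#'
#' @param net A \code{co_network}.
#' @return List of class \code{topology_metrics}.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- length(net$nodes); e <- nrow(net$edges)
  deg <- net$degree
  adj <- lapply(setNames(seq_len(n), net$nodes), function(i) integer(0L))
  for (r in seq_len(e)) {
    a <- match(net$edges$i[r], net$nodes); b <- match(net$edges$j[r], net$nodes)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  # BFS characteristic path length over connected pairs
  tot <- 0; npairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); dist[s] <- 0L; queue <- s; qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      for (w in adj[[v]]) if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- dist > 0L
    tot <- tot + sum(dist[reach]); npairs <- npairs + sum(reach)
  }
  cpl <- if (npairs > 0) tot / npairs else NA_real_
  density <- if (n > 1L) 2 * e / (n * (n - 1)) else NA_real_
  het <- if (mean(deg) > 0)
    sd(deg) * sqrt((n - 1) / n) / mean(deg) else 0   # population sd
  centr <- if (n > 2L) (n / (n - 2)) * (max(deg) / (n - 1) - density)
           else NA_real_
  ord <- order(-deg, names(deg))
  hubs <- data.frame(node = names(deg)[ord], degree = unname(deg[ord]),
                     kingdom = unname(net$kingdom[names(deg)[ord]]),
                     stringsAsFactors = FALSE)[seq_len(min(10L, n)), ]
  structure(list(n_nodes = n, n_edges = e, avg_neighbors = 2 * e / n,
                 density = density, char_path_length = cpl,
                 heterogeneity = het, centralization = centr,
                 top_hubs = hubs),
            class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf(paste0("<topology: N=%d E=%d avg_nb=%.2f dens=%.3f ",
                     "cpl=%.2f het=%.3f centr=%.3f>\n"),
              x$n_nodes, x$n_edges, x$avg_neighbors, x$density,
              x$char_path_length, x$heterogeneity, x$centralization))
  invisible(x)
}

#' Build a co-occurrence network from differential taxa
#'
#' Restricts the table to the given taxa, applies the prevalence filter,
#' computes the correlation matrix, picks the RMT threshold, masks,
#' removes indirect edges and attaches topology metrics and the
#' kingdom-annotated hub list.
#'
#' @param table Samples x taxa abundance matrix.
#' @param diff_taxa Taxa to include (e.g. the differential screen's
#'   passing set).
#' @param kingdoms Named kingdom label per taxon (default: the table's
#'   kingdom attribute).
#' @param min_prev Prevalence threshold (default 0.10).
#' @param method Correlation method.
#' @param ... Passed to \code{\link{rmt_threshold}}.
#' @return \code{co_network} with a \code{metrics} element.
#' @export
build_network <- function(table, diff_taxa, kingdoms = NULL,
                          min_prev = 0.10,
                          method = c("spearman", "pearson"), ...) {
  if (length(diff_taxa) == 0L) stop("empty taxon set")
  stopifnot(all(diff_taxa %in% colnames(table)))
  kingdoms <- kingdoms %||% attr(table, "kingdom")
  sub <- table[, diff_taxa, drop = FALSE]
  sub <- prevalence_filter(sub, min_prev)
  if (ncol(sub) < 20L)
    stop("fewer than 20 taxa after filters; RMT needs a spectrum")
  cm <- correlation_matrix(sub, method = match.arg(method))
  thr <- rmt_threshold(cm, ...)
  kd <- if (!is.null(kingdoms)) kingdoms[colnames(sub)] else NULL
  net <- threshold_network(cm, as.numeric(thr), kingdom = kd)
  net <- remove_indirect_edges(net)
  net$metrics <- topology(net)
  net$rmt_scan <- attr(thr, "scan")
  net
}
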