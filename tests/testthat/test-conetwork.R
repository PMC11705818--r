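test_that("prevalence filter keeps taxa above the strict 10% bound", {
  tab <- matrix(0, 100L, 3L,
                dimnames = list(sprintf("s%03d", 1:100), c("a", "b", "c")))
  tab[1:5, "a"] <- 1     # 5% -> dropped
  tab[1:11, "b"] <- 1    # 11% -> kept
  tab[, "c"] <- 1        # all-present -> kept
  out <- prevalence_filter(tab)
  expect_equal(colnames(out), c("b", "c"))
  # exactly 10% does not pass a strict "more than 10%" rule
  tab[1:10, "a"] <- 1
  expect_false("a" %in% colnames(prevalence_filter(tab)))
})

test_that("correlation matrix: monotone invariance, nulls, degeneracies", {
  st <- toy_study(c(10L, 10L), 10L, seed = 100L)
  cm <- correlation_matrix(st$table)
  expect_equal(diag(cm), setNames(rep(1, 10L), colnames(st$table)))
  expect_equal(cm, t(cm))

  x <- st$table
  x[, 2L] <- 2 * x[, 1L]           # monotone copy
  cm2 <- correlation_matrix(x)
  expect_equal(cm2[1L, 2L], 1)

  x[, 3L] <- 5                      # zero variance
  expect_warning(cm3 <- correlation_matrix(x), "zero-variance")
  expect_true(all(cm3[3L, -3L] == 0))
  expect_equal(cm3[3L, 3L], 1)

  expect_error(correlation_matrix(st$table[1:5, ]), ">= 10")

  # independent taxa: most null correlations are small at n = 200
  big <- toy_study(c(100L, 100L), 40L, seed = 101L)
  cmb <- correlation_matrix(big$table)
  off <- abs(cmb[upper.tri(cmb)])
  expect_gt(mean(off < 0.2), 0.95)
})

test_that("NNSD accepts Poisson spectra and rejects GOE spectra", {
  pois <- vapply(1:25, function(s)
    nnsd_poisson_pvalue(diag_random_matrix(200L, seed = s), 0.5),
    numeric(1L))
  expect_gte(mean(pois > 0.05), 0.9)

  goe <- vapply(1:25, function(s)
    nnsd_poisson_pvalue(goe_matrix(150L, seed = s), 0), numeric(1L))
  expect_gte(mean(goe < 0.05), 0.9)

  # evenly spaced eigenvalues have degenerate spacings: Poisson rejected
  arith <- diag(seq(1, 50, length.out = 120L))
  dimnames(arith) <- list(paste0("t", 1:120), paste0("t", 1:120))
  expect_lt(nnsd_poisson_pvalue(arith, 0.5), 0.05)

  tiny <- diag(5L); dimnames(tiny) <- list(letters[1:5], letters[1:5])
  expect_error(nnsd_poisson_pvalue(tiny, 0.5), "20")
})

test_that("rmt_threshold returns t_min on structureless input, t_max when
           nothing is Poisson", {
  idm <- diag_random_matrix(150L, seed = 7L)
  expect_equal(as.numeric(rmt_threshold(idm)), 0.30)

  ones <- matrix(1, 30L, 30L)
  dimnames(ones) <- list(paste0("t", 1:30), paste0("t", 1:30))
  expect_warning(t_all <- rmt_threshold(ones), "t_max")
  expect_equal(as.numeric(t_all), 0.99)
})

test_that("deconvolution removes the transitive edge of a product triangle", {
  cm <- diag(3L)
  dimnames(cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cm["a", "b"] <- cm["b", "a"] <- 0.9
  cm["b", "c"] <- cm["c", "b"] <- 0.9
  cm["a", "c"] <- cm["c", "a"] <- 0.81   # product of the two direct paths
  net <- threshold_network(cm, 0.5)
  pruned <- remove_indirect_edges(net)
  keys <- paste(pruned$edges$i, pruned$edges$j)
  expect_setequal(keys, c("a b", "b c"))
})

test_that("indirect-edge removal never adds edges and strips self-loops", {
  st <- toy_study(c(40L, 40L), 25L, seed = 102L,
                  block = list(list(members = sprintf("t%03d", 1:6),
                                    loading = 0.95)))
  cm <- correlation_matrix(st$table)
  net <- threshold_network(cm, 0.4)
  pruned <- remove_indirect_edges(net)
  key <- function(e) paste(e$i, e$j)
  expect_true(all(key(pruned$edges) %in% key(net$edges)))

  # a hand-built net with a self-loop and a pathological edge
  ed <- data.frame(i = c("a", "a", "b"), j = c("a", "b", "c"),
                   weight = c(1, 0.9995, 0.7), sign = "+")
  bad <- mycoscan:::new_co_network(c("a", "b", "c"), ed, threshold = 0.5)
  cleaned <- remove_indirect_edges(bad)
  expect_equal(nrow(cleaned$edges), 1L)
  expect_equal(cleaned$edges$i, "b")

  # a network with no triangles passes through unchanged
  ed2 <- data.frame(i = c("a", "c"), j = c("b", "d"),
                    weight = c(0.8, 0.7), sign = "+")
  chain <- mycoscan:::new_co_network(letters[1:4], ed2, threshold = 0.5)
  expect_equal(remove_indirect_edges(chain)$edges, ed2)
})

test_that("topology metrics match hand-computed star and clique values", {
  star_edges <- data.frame(i = rep("hub", 4L), j = paste0("leaf", 1:4),
                           weight = 0.9, sign = "+")
  star <- mycoscan:::new_co_network(c("hub", paste0("leaf", 1:4)),
                                    star_edges)
  m <- topology(star)
  expect_equal(m$n_nodes, 5L)
  expect_equal(m$n_edges, 4L)
  expect_equal(m$avg_neighbors, 1.6)
  expect_equal(m$density, 0.4)
  expect_equal(m$char_path_length, 1.6)
  expect_equal(m$heterogeneity, 0.75)
  expect_equal(m$centralization, 1)
  expect_equal(m$top_hubs$node[1L], "hub")

  k4_edges <- do.call(rbind, lapply(combn(4L, 2L, simplify = FALSE),
    function(p) data.frame(i = letters[p[1L]], j = letters[p[2L]],
                           weight = 0.8, sign = "+")))
  k4 <- mycoscan:::new_co_network(letters[1:4], k4_edges)
  mk <- topology(k4)
  expect_equal(mk$density, 1)
  expect_equal(mk$char_path_length, 1)
  expect_equal(mk$heterogeneity, 0)
  expect_equal(mk$centralization, 0)

  two <- mycoscan:::new_co_network(letters[1:4],
    data.frame(i = c("a", "c"), j = c("b", "d"), weight = 0.5, sign = "+"))
  expect_equal(topology(two)$char_path_length, 1)
})

test_that("topology metrics agree with the igraph oracle on random graphs", {
  set.seed(103L)
  for (trial in 1:10) {
    n <- sample(8:25, 1L)
    g <- igraph::sample_gnp(n, runif(1L, 0.15, 0.6))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    el <- igraph::as_edgelist(g)
    net <- mycoscan:::new_co_network(paste0("v", seq_len(n)),
      data.frame(i = el[, 1L], j = el[, 2L],
                 weight = rep(0.5, nrow(el)), sign = "+"))
    m <- topology(net)
    expect_equal(m$n_edges, igraph::gsize(g))
    expect_equal(m$avg_neighbors, mean(igraph::degree(g)),
                 tolerance = 1e-12)
    expect_equal(m$density, igraph::edge_density(g), tolerance = 1e-12)
    if (igraph::gsize(g) > 0)
      expect_equal(m$char_path_length,
                   igraph::mean_distance(g, directed = FALSE,
                                         unconnected = TRUE),
                   tolerance = 1e-12)
    expect_equal(sum(net$degree), 2L * m$n_edges)  # handshake
  }
})

test_that("build_network recovers planted blocks and validates input", {
  taxa <- data.frame(taxon = sprintf("t%03d", 1:60),
                     kingdom = rep(c("fungal", "bacterial"), 30L),
                     base_mean = 1)
  blocks <- list(sprintf("t%03d", 1:8), sprintf("t%03d", 9:16))
  cb <- lapply(blocks, function(b) list(members = b, loading = sqrt(0.9)))
  st <- simulate_abundance_study(c(60L, 60L), taxa, NULL, cb, 0.5,
                                 seed = 104L)
  net <- build_network(st$table, taxa$taxon)
  expect_s3_class(net, "co_network")
  expect_true(all(abs(net$edges$weight) >= net$threshold))
  # the planted blocks surface as the nontrivial components of the
  # thresholded graph (before indirect-edge pruning)
  cm <- correlation_matrix(prevalence_filter(st$table))
  raw <- threshold_network(cm, net$threshold)
  jac <- block_jaccard(blocks, components_of(raw))
  expect_gt(mean(jac), 0.7)
  # hubs of the final pruned network live inside the planted blocks
  hubs <- net$metrics$top_hubs
  expect_gt(mean(hubs$node %in% unlist(blocks)), 0.7)
  expect_true(all(hubs$kingdom %in% c("fungal", "bacterial")))

  expect_error(build_network(st$table, character(0L)), "empty")
  expect_error(build_network(st$table, sprintf("t%03d", 1:10)),
               "fewer than 20")
})

test_that("raising the threshold never adds edges", {
  st <- toy_study(c(30L, 30L), 25L, seed = 105L,
                  block = list(list(members = sprintf("t%03d", 1:6),
                                    loading = 0.9)))
  cm <- correlation_matrix(st$table)
  key <- function(net) paste(net$edges$i, net$edges$j)
  e1 <- key(threshold_network(cm, 0.3))
  e2 <- key(threshold_network(cm, 0.5))
  e3 <- key(threshold_network(cm, 0.7))
  expect_true(all(e2 %in% e1))
  expect_true(all(e3 %in% e2))
})
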