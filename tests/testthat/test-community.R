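test_that("alpha diversity counts positives and computes Shannon", {
  u <- alpha_diversity(rep(1 / 8, 8L))
  expect_equal(u$richness, 8L)
  expect_equal(u$shannon, log(8))

  s <- alpha_diversity(c(5, 0, 0))
  expect_equal(s$richness, 1L)
  expect_equal(s$shannon, 0)

  h <- alpha_diversity(c(0.5, 0.5, 0))
  expect_equal(h$richness, 2L)
  expect_equal(h$shannon, log(2))

  z <- alpha_diversity(c(0, 0))
  expect_equal(z$richness, 0L)
  expect_equal(z$shannon, 0)
  expect_error(alpha_diversity(c(-1, 2)), "negative")
})

test_that("alpha diversity agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  st <- toy_study(c(5L, 5L), 20L, seed = 80L)
  for (i in 1:3) {
    a <- alpha_diversity(st$table[i, ])
    expect_equal(a$shannon,
                 unname(vegan::diversity(st$table[i, , drop = FALSE])),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis on sqrt profiles matches hand and vegan values", {
  tab <- rbind(x = c(1, 0), y = c(0.25, 0.75))
  d <- bray_curtis(tab)
  expect_equal(d["x", "y"],
               (0.5 + sqrt(0.75)) / (1.5 + sqrt(0.75)), tolerance = 1e-12)
  expect_equal(d["x", "y"], 0.5774, tolerance = 1e-4)

  same <- rbind(a = c(2, 3, 5), b = c(2, 3, 5))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(disj)["a", "b"], 1)

  skip_if_not_installed("vegan")
  st <- toy_study(c(6L, 6L), 25L, seed = 81L)
  mine <- bray_curtis(st$table)
  frac <- st$table / rowSums(st$table)
  ref <- as.matrix(vegan::vegdist(sqrt(frac), method = "bray"))
  expect_equal(unclass(mine), ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Bray-Curtis matrices are symmetric with zero diagonal in [0,1]", {
  st <- toy_study(c(8L, 8L), 15L, seed = 82L)
  d <- bray_curtis(st$table)
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA reproduces 1-D Euclidean configurations exactly", {
  pts <- c(0, 1, 2, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  ord <- pcoa_ord(d)
  rec <- as.matrix(dist(ord$coordinates[, 1L]))
  expect_equal(unname(rec), unname(unclass(d)), tolerance = 1e-9)
  expect_lte(sum(ord$explained), 1 + 1e-12)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))  # descending axes

  # a duplicated sample lands on identical coordinates
  d2 <- as.matrix(dist(c(0, 1, 1, 4)))
  ord2 <- pcoa_ord(d2)
  expect_equal(ord2$coordinates[2L, ], ord2$coordinates[3L, ],
               tolerance = 1e-9)
})

test_that("PCoA agrees with the ape oracle on Bray-Curtis input", {
  skip_if_not_installed("ape")
  st <- toy_study(c(10L, 10L), 30L, seed = 83L)
  d <- bray_curtis(st$table)
  mine <- pcoa_ord(d)
  ref <- ape::pcoa(as.dist(unclass(d)))
  npos <- length(mine$eigenvalues)
  expect_equal(mine$eigenvalues[1:3], ref$values$Eigenvalues[1:3],
               tolerance = 1e-8)
  for (ax in 1:2)
    expect_equal(abs(mine$coordinates[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("PERMANOVA separates structure and matches the exact oracle", {
  # two groups collapsed onto two distinct points: R2 = 1
  d <- matrix(1, 4L, 4L) - diag(4L)
  d[1L, 2L] <- d[2L, 1L] <- 0
  d[3L, 4L] <- d[4L, 3L] <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(d, c("a", "a", "b", "b"), n_perm = 99L, seed = 1L)
  expect_equal(res$r2, 1)

  # exact p by full enumeration of the 6-sample label assignments
  st <- toy_study(c(3L, 3L), 10L, seed = 84L)
  dd <- bray_curtis(st$table)
  labs <- c("a", "a", "a", "b", "b", "b")
  res <- permanova(dd, labs, n_perm = 999L, seed = 2L)
  f_of <- function(lab) {
    n <- nrow(dd); d2 <- unclass(dd)^2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (g in unique(lab)) {
      i <- which(lab == g)
      ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  combs <- combn(6L, 3L)
  fs <- apply(combs, 2L, function(idx) {
    lab <- rep("b", 6L); lab[idx] <- "a"; f_of(lab)
  })
  exact_p <- mean(fs >= f_of(labs) - 1e-12)
  # permutation p converges to the enumeration value
  expect_equal(res$pseudo_f, f_of(labs), tolerance = 1e-12)
  expect_lt(abs(res$p - exact_p), 0.08)
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  st <- toy_study(c(10L, 10L), 30L, seed = 85L,
                  planted = data.frame(taxon = sprintf("t%03d", 1:3),
                                       fold_change = 3,
                                       enriched_group = "A"))
  d <- bray_curtis(st$table)
  mine <- permanova(d, st$groups, n_perm = 199L, seed = 3L)
  df <- data.frame(grp = st$groups)
  ref <- vegan::adonis2(as.dist(unclass(d)) ~ grp, data = df,
                        permutations = 199L)
  expect_equal(mine$r2, ref$R2[1L], tolerance = 1e-10)
  expect_equal(mine$pseudo_f, ref$F[1L], tolerance = 1e-10)
})

test_that("PERMANOVA p-values are valid and never zero", {
  st <- toy_study(c(5L, 5L), 10L, seed = 86L)
  d <- bray_curtis(st$table)
  res <- permanova(d, st$groups, n_perm = 99L, seed = 4L)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  expect_error(permanova(d, rep("a", 10L)), "2 groups")
  expect_error(permanova(d, c(rep("a", 9L), "b")), ">= 2 samples")
})
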