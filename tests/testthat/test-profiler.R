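test_that("decoy decontamination removes matching pairs only", {
  g <- simulate_genomes(1L, 10000L, 0.5, seed = 60L)
  decoy <- setNames(simulate_genomes(1L, 10000L, 0.5, seed = 61L), "host")
  fungal <- simulate_reads(g, c(g1 = 1), 50L, seed = 62L)$pairs
  hostish <- simulate_reads(decoy, c(host = 1), 50L, seed = 63L)$pairs
  hostish$id <- paste0("h", hostish$id)
  out <- decontaminate_reads(rbind(fungal, hostish), decoy)
  expect_equal(out$removed, 50L)
  expect_setequal(out$retained$id, fungal$id)

  expect_warning(out0 <- decontaminate_reads(fungal, character(0L)),
                 "empty decoy")
  expect_equal(out0$removed, 0L)
  expect_equal(nrow(out0$retained), 50L)
})

test_that("read assignment picks the unique top genome and drops ties", {
  g <- simulate_genomes(2L, 10000L, 0.5, seed = 64L)
  sim <- simulate_reads(g, c(g1 = 0.5, g2 = 0.5), 100L, seed = 65L)
  hits <- assign_reads(sim$pairs, g)
  expect_equal(nrow(hits), 100L)
  expect_true(all(hits$genome_id ==
                    sim$truth$read_origin[hits$read_id]))

  # identical catalog entries tie every read -> all ambiguous
  twin <- c(g[1L], setNames(g[1L], "g1copy"))
  sim1 <- simulate_reads(g[1L], c(g1 = 1), 20L, seed = 66L)
  hits2 <- assign_reads(sim1$pairs, twin)
  expect_equal(nrow(hits2), 0L)
  expect_equal(unname(attr(hits2, "stats")["n_ambiguous"]), 20L)

  # reads from an unrelated genome score zero and are unassigned
  other <- simulate_genomes(1L, 10000L, 0.5, seed = 67L, prefix = "x")
  simx <- simulate_reads(other, c(x1 = 1), 10L, seed = 68L)
  hits3 <- assign_reads(simx$pairs, g)
  expect_equal(nrow(hits3), 0L)
  expect_equal(unname(attr(hits3, "stats")["n_unassigned"]), 10L)
})

test_that("TPM normalization divides by genome size and closes to 1e6", {
  tpm <- normalize_tpm(c(g1 = 100, g2 = 100), c(g1 = 1e6, g2 = 2e6))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  expect_equal(sum(tpm), 1e6)

  expect_equal(unname(normalize_tpm(c(g = 7), c(g = 123))), 1e6)

  z <- normalize_tpm(c(g1 = 0, g2 = 0), c(g1 = 1e6, g2 = 1e6))
  expect_true(all(z == 0))
  expect_true(attr(z, "empty"))

  expect_error(normalize_tpm(c(g1 = 5), c(g2 = 10)), "no genome size")
  expect_error(normalize_tpm(c(g1 = -1), c(g1 = 10)), "negative")
})

test_that("genome-size invariance: doubling size and count cancels", {
  t1 <- normalize_tpm(c(a = 100, b = 50), c(a = 1e6, b = 3e6))
  t2 <- normalize_tpm(c(a = 200, b = 50), c(a = 2e6, b = 3e6))
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("taxonomic roll-up sums columns and preserves row sums", {
  tx <- data.frame(species_id = c("s1", "s2", "s3"),
                   genus = c("G1", "G1", "G2"),
                   family = c("F1", "F1", "F1"),
                   order = "O1", class = "C1", subphylum = "P1")
  tab <- matrix(c(4e5, 6e5, 0, 2e5, 3e5, 5e5), 2L, 3L, byrow = TRUE,
                dimnames = list(c("sA", "sB"), c("s1", "s2", "s3")))
  gen <- aggregate_taxa(tab, tx, "genus")
  expect_equal(gen["sA", "G1"], 1e6)
  expect_equal(gen["sA", "G2"], 0)
  expect_equal(rowSums(gen), rowSums(tab), tolerance = 1e-6)
  fam <- aggregate_taxa(tab, tx, "family")
  expect_equal(ncol(fam), 1L)

  # species each in their own genus: identity up to renaming
  tx2 <- transform(tx, genus = c("Ga", "Gb", "Gc"))
  ident <- aggregate_taxa(tab, tx2, "genus")
  expect_equal(sort(as.numeric(ident["sB", ])),
               sort(as.numeric(tab["sB", ])))

  expect_error(aggregate_taxa(tab, tx[1:2, ], "genus"), "missing")
})

test_that("aggregation composes: class roll-up equals species->class", {
  st <- toy_study(c(4L, 4L), 12L, seed = 69L)
  tx <- data.frame(species_id = colnames(st$table),
                   genus = rep(c("g1", "g2", "g3"), each = 4L),
                   family = rep(c("f1", "f2"), each = 6L),
                   order = "o1",
                   class = rep(c("c1", "c2"), 6L),
                   subphylum = "p1")
  direct <- aggregate_taxa(st$table, tx, "class")
  expect_equal(rowSums(direct), rowSums(st$table))
  expect_equal(direct[, "c1"],
               rowSums(st$table[, tx$class == "c1"]))
})

test_that("profile_samples recovers a planted composition end to end", {
  g <- simulate_genomes(3L, 10000L, 0.5, seed = 70L)
  comp <- c(g1 = 0.5, g2 = 0.3, g3 = 0.2)
  sim <- simulate_reads(g, comp, 2000L, seed = 71L)
  prof <- profile_samples(list(sample1 = sim$pairs), g, qc = FALSE)
  expect_equal(sum(prof$table["sample1", ]), 1e6, tolerance = 1e-3)
  expect_lt(sum(abs(prof$table["sample1", ] / 1e6 - comp)), 0.05)
  expect_equal(prof$stats$assigned, 2000L)

  # reads only from g1 -> the whole million lands on g1
  sim1 <- simulate_reads(g[1L], c(g1 = 1), 200L, seed = 72L)
  prof1 <- profile_samples(list(s = sim1$pairs), g, qc = FALSE)
  expect_equal(unname(prof1$table["s", "g1"]), 1e6, tolerance = 1e-6)
})

test_that("size normalization recovers fractions, not read fractions", {
  # genomes of size ratio 1:2; reads drawn proportional to size * fraction
  g <- simulate_genomes(1L, 10000L, 0.5, seed = 73L)
  g2 <- setNames(paste0(simulate_genomes(1L, 10000L, 0.5, seed = 74L),
                        simulate_genomes(1L, 10000L, 0.5, seed = 75L)), "g2")
  cat2 <- c(g, g2)
  f <- c(g1 = 0.5, g2 = 0.5)             # true abundance fractions
  sizes <- nchar(cat2)
  read_frac <- f * sizes / sum(f * sizes)  # reads proportional to L * f
  sim <- simulate_reads(cat2, read_frac, 6000L, seed = 76L)
  hits <- assign_reads(sim$pairs, cat2)
  counts <- table(factor(hits$genome_id, levels = names(cat2)))
  tpm <- normalize_tpm(setNames(as.numeric(counts), names(counts)),
                       setNames(sizes, names(cat2)))
  expect_lt(abs(tpm[["g1"]] / 1e6 - 0.5), 0.03)
  expect_lt(abs(tpm[["g2"]] / 1e6 - 0.5), 0.03)
})
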