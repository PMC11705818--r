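# Two-group differential abundance: Wilcoxon rank-sum tests with
# Benjamini-Hochberg adjustment, pseudocounted fold changes, a
# single-feature LDA effect size (LEfSe-style bootstrap of the group-mean
# gap on the per-million scale), and the filter cascade
# FC > 1.2, LDA > 2, abundance > 0.01, q < 0.05.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration (no ties, small samples) or the normal approximation
#' with tie-corrected variance and continuity correction. When every
#' value is identical across both groups the p-value is 1.
#'
#' @param x,y Numeric value vectors (each non-empty).
#' @param mode \code{"auto"} (exact when nx+ny <= 12 and tie-free),
#'   \code{"exact"}, or \code{"normal_approx"}.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(mode,
                  auto = !ties && length(x) + length(y) <= 12L,
                  exact = TRUE,
                  normal_approx = FALSE)
  if (exact && ties)
    stop("exact mode undefined with ties; use normal_approx")
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of raw p-values in [0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Fold change between two group means
#'
#' Ratio of the larger to the smaller mean with a pseudocount on both, so
#' zero means stay finite; the enriched group is the one with the larger
#' mean (\code{"none"} on exact equality).
#'
#' @param mean_a,mean_b Non-negative group means (fraction scale).
#' @param pseudo Pseudocount (default 1e-6, one TPM on fraction scale).
#' @return List with \code{fc} (>= 1) and \code{enriched_group}.
#' @export
fold_change <- function(mean_a, mean_b, pseudo = 1e-6) {
  stopifnot(mean_a >= 0, mean_b >= 0)
  if (mean_a == mean_b) return(list(fc = 1, enriched_group = "none"))
  hi <- max(mean_a, mean_b); lo <- min(mean_a, mean_b)
  list(fc = (hi + pseudo) / (lo + pseudo),
       enriched_group = if (mean_a > mean_b) "A" else "B")
}

#' Single-feature LDA effect size
#'
#' LEfSe-style bootstrap: each round subsamples both groups without
#' replacement at \code{subsample}, measures the absolute group-mean
#' difference of the taxon on the per-million (TPM) scale, and the score
#' is log10(1 + mean over rounds). Scores above 2 correspond to a
#' consistent gap of about 100 TPM.
#'
#' @param table Samples x taxa TPM matrix.
#' @param labels Group label per sample (two groups, each >= 5 samples).
#' @param taxon Taxon (column) id.
#' @param n_boot Bootstrap rounds (default 30).
#' @param subsample Per-group subsampling fraction (default 2/3).
#' @param seed Integer seed.
#' @return LDA score (log10 scale).
#' @export
lda_effect_size <- function(table, labels, taxon, n_boot = 30L,
                            subsample = 2 / 3, seed = 1L) {
  labels <- as.character(labels)
  gs <- unique(labels)
  stopifnot(length(gs) == 2L)
  ia <- which(labels == gs[1L]); ib <- which(labels == gs[2L])
  if (length(ia) < 5L || length(ib) < 5L)
    stop("both groups need >= 5 samples")
  v <- table[, taxon]
  with_seed(seed, {
    effects <- vapply(seq_len(n_boot), function(b) {
      sa <- sample(ia, max(1L, floor(length(ia) * subsample)))
      sb <- sample(ib, max(1L, floor(length(ib) * subsample)))
      if (length(sa) == 0L || length(sb) == 0L) return(NA_real_)
      abs(mean(v[sa]) - mean(v[sb]))
    }, numeric(1L))
    log10(1 + mean(effects, na.rm = TRUE))
  })
}

#' Differential-abundance screen with the FC/LDA/abundance filter cascade
#'
#' Per taxon: group means, pseudocounted fold change, Wilcoxon p with BH
#' adjustment across taxa, and the LDA effect size. A taxon passes when
#' FC > \code{fc_min}, LDA > \code{lda_min}, the larger group mean (on
#' the fraction scale) exceeds \code{ab_min}, and q < \code{alpha}; all
#' strict.
#'
#' @param table Samples x taxa TPM matrix.
#' @param labels Group label per sample ("A"/"B" or any two labels; the
#'   first level encountered is reported as group A).
#' @param fc_min Fold-change threshold (default 1.2).
#' @param lda_min LDA-score threshold (default 2).
#' @param ab_min Relative-abundance threshold on the fraction scale
#'   (default 0.01, i.e. 1%).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param n_boot,subsample,seed Passed to \code{\link{lda_effect_size}}.
#' @return data.frame of class \code{diff_table}, one row per taxon,
#'   sorted by LDA score descending: taxon, mean_a, mean_b (fraction
#'   scale), fc, enriched_group, lda, p, q, passes.
#' @export
differential_screen <- function(table, labels, fc_min = 1.2, lda_min = 2,
                                ab_min = 0.01, alpha = 0.05, n_boot = 30L,
                                subsample = 2 / 3, seed = 1L) {
  if (ncol(table) == 0L) {
    out <- data.frame(taxon = character(0L), mean_a = numeric(0L),
                      mean_b = numeric(0L), fc = numeric(0L),
                      enriched_group = character(0L), lda = numeric(0L),
                      p = numeric(0L), q = numeric(0L),
                      passes = logical(0L))
    class(out) <- c("diff_table", "data.frame")
    return(out)
  }
  labels <- as.character(labels)
  gs <- unique(labels)
  stopifnot(length(gs) == 2L, nrow(table) == length(labels))
  ia <- labels == gs[1L]; ib <- labels == gs[2L]
  frac <- table / 1e6
  taxa <- colnames(table)
  mean_a <- colMeans(frac[ia, , drop = FALSE])
  mean_b <- colMeans(frac[ib, , drop = FALSE])
  fcs <- Map(fold_change, mean_a, mean_b)
  p <- vapply(taxa, function(t)
    wilcoxon_rank_sum(table[ia, t], table[ib, t], mode = "normal_approx"),
    numeric(1L))
  q <- bh_adjust(p)
  lda <- vapply(seq_along(taxa), function(i)
    lda_effect_size(table, labels, taxa[i], n_boot, subsample,
                    seed = seed + i - 1L), numeric(1L))
  out <- data.frame(
    taxon = taxa,
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    fc = vapply(fcs, `[[`, numeric(1L), "fc"),
    enriched_group = unname(
      c(A = gs[1L], B = gs[2L], none = "none")[
        vapply(fcs, `[[`, character(1L), "enriched_group")]),
    lda = lda, p = unname(p), q = unname(q),
    stringsAsFactors = FALSE)
  out$passes <- out$fc > fc_min & out$lda > lda_min &
    pmax(out$mean_a, out$mean_b) > ab_min & out$q < alpha
  out <- out[order(-out$lda, out$taxon), ]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}

#' @export
print.diff_table <- function(x, n = 10L, ...) {
  cat(sprintf("<diff_table: %d taxa, %d passing>\n", nrow(x),
              sum(x$passes)))
  print.data.frame(head(x, n), digits = 4L)
  invisible(x)
}
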