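# Read-level quality control for paired FASTQ input. A pair is dropped
# when either mate fails a rule; rules are checked in a fixed order
# (length, mean quality, low-quality-base fraction, complexity) and a
# pair is tallied once, under the first rule it fails. PolyG tails are
# trimmed before any rule is evaluated.

#' Mean Phred quality of a quality string
#'
#' @param qual Phred+33 quality string.
#' @return Arithmetic mean of the per-base Phred scores.
#' @export
mean_quality <- function(qual) {
  if (nchar(qual) == 0L) stop("empty quality string")
  mean(utf8ToInt(qual) - 33L)
}

#' Fraction of bases below a quality cutoff
#'
#' @param qual Phred+33 quality string.
#' @param q_cut Phred cutoff; bases strictly below it count (default 20).
#' @return Fraction in [0, 1].
#' @export
low_quality_fraction <- function(qual, q_cut = 20L) {
  if (nchar(qual) == 0L) stop("empty quality string")
  mean((utf8ToInt(qual) - 33L) < q_cut)
}

#' Sequence complexity as distinct k-mer fraction
#'
#' Complexity is the number of distinct k-mers divided by the number of
#' k-mer positions. Homopolymers score 1/(L-k+1) and dinucleotide repeats
#' 2/(L-k+1), so both fall below a 30% cutoff, while random sequence
#' scores near 1. Sequences shorter than k have complexity 0.
#'
#' @param seq Sequence string.
#' @param k K-mer size (default 3).
#' @return Fraction in [0, 1].
#' @export
complexity <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(0)
  km <- kmers(seq, k)
  length(unique(km)) / length(km)
}

# Trim a trailing run of >= min_run G from a read (two-color chemistry
# artifact); the quality string is cut to match.
trim_polyg <- function(seq, qual, min_run = 10L) {
  m <- regexpr(sprintf("G{%d,}$", min_run), seq)
  keep <- ifelse(m > 0L, m - 1L, nchar(seq))
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

#' Quality-filter a table of read pairs
#'
#' Applies, after polyG-tail trimming, the removal rules: (1) either mate
#' shorter than \code{min_len}; (2) mean Phred below \code{min_mean_q};
#' (3) more than \code{max_lowq_frac} of bases below Phred 20; (4)
#' complexity under \code{min_complexity}. All thresholds are strict.
#'
#' @param pairs Pair table (columns id, seq1, qual1, seq2, qual2).
#' @param min_len Minimum mate length in bp (default 90).
#' @param min_mean_q Minimum mean Phred (default 20).
#' @param max_lowq_frac Maximum fraction of sub-Q20 bases (default 0.30).
#' @param min_complexity Minimum distinct-3-mer fraction (default 0.30).
#' @param n_unpaired Count of unpaired input records to report (default 0).
#' @return List with \code{passed} (pair table, polyG-trimmed) and
#'   \code{report} (class \code{qc_report}: input_pairs, passed_pairs and
#'   a removed-by-reason table).
#' @export
filter_pairs <- function(pairs, min_len = 90L, min_mean_q = 20,
                         max_lowq_frac = 0.30, min_complexity = 0.30,
                         n_unpaired = 0L) {
  n <- nrow(pairs)
  if (n > 0L) {
    t1 <- trim_polyg(pairs$seq1, pairs$qual1)
    t2 <- trim_polyg(pairs$seq2, pairs$qual2)
    pairs$seq1 <- t1$seq; pairs$qual1 <- t1$qual
    pairs$seq2 <- t2$seq; pairs$qual2 <- t2$qual
  }
  reason <- rep(NA_character_, n)
  fail <- function(f) {
    v1 <- vapply(seq_len(n), function(i) f(pairs$seq1[i], pairs$qual1[i]),
                 logical(1L))
    v2 <- vapply(seq_len(n), function(i) f(pairs$seq2[i], pairs$qual2[i]),
                 logical(1L))
    v1 | v2
  }
  if (n > 0L) {
    rules <- list(
      short = function(s, q) nchar(s) < min_len,
      mean_q = function(s, q) nchar(q) > 0L && mean_quality(q) < min_mean_q,
      frac_lowq = function(s, q) nchar(q) > 0L &&
        low_quality_fraction(q) > max_lowq_frac,
      low_complexity = function(s, q) complexity(s) < min_complexity)
    for (rn in names(rules)) {
      bad <- is.na(reason) & fail(rules[[rn]])
      reason[bad] <- rn
    }
  }
  removed <- c(short = sum(reason == "short", na.rm = TRUE),
               mean_q = sum(reason == "mean_q", na.rm = TRUE),
               frac_lowq = sum(reason == "frac_lowq", na.rm = TRUE),
               low_complexity = sum(reason == "low_complexity", na.rm = TRUE),
               unpaired = as.integer(n_unpaired))
  passed <- pairs[is.na(reason), , drop = FALSE]
  rownames(passed) <- NULL
  report <- structure(
    list(input_pairs = n + as.integer(n_unpaired),
         passed_pairs = nrow(passed), removed = removed),
    class = "qc_report")
  list(passed = passed, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %d in, %d passed>\n", x$input_pairs,
              x$passed_pairs))
  rm <- x$removed[x$removed > 0]
  if (length(rm))
    cat("  removed:", paste(sprintf("%s=%d", names(rm), rm),
                            collapse = ", "), "\n")
  invisible(x)
}
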