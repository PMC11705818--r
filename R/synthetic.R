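# Synthetic data generators: genomes at controlled pairwise identity,
# error-bearing paired reads from a known composition (with optional
# contaminants), and two-group abundance studies with planted fold
# changes and correlation blocks. Every generator is deterministic given
# its seed and returns its ground truth alongside the data.

#' Simulate random genomes at a fixed GC content
#'
#' @param n Number of genomes.
#' @param length Genome length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param prefix Id prefix, default \code{"g"}.
#' @return Named character vector of sequences (a sequence set).
#' @export
simulate_genomes <- function(n, length = 50000L, gc = 0.5, seed = 1L,
                             prefix = "g") {
  stopifnot(n >= 1L, length >= 1000L)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, length, replace = TRUE, prob = prob),
            collapse = ""), character(1L))
    setNames(seqs, paste0(prefix, seq_len(n)))
  })
}

#' Mutate a genome to a target average nucleotide identity
#'
#' Applies point substitutions independently at rate \code{1 - target_ani},
#' each to a uniformly chosen different base, so the realized identity of
#' output versus input concentrates tightly around the target.
#'
#' @param genome A single sequence string.
#' @param target_ani Target identity in [0.80, 1).
#' @param seed Integer seed.
#' @return Mutated sequence of the same length.
#' @export
mutate_to_ani <- function(genome, target_ani, seed = 1L) {
  stopifnot(length(genome) == 1L)
  if (target_ani < 0.80 || target_ani >= 1)
    stop("target_ani must be in [0.80, 1)")
  rate <- 1 - target_ani
  with_seed(seed, {
    chars <- strsplit(genome, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(chars)) < rate)
    if (length(hit)) {
      # substitute with one of the three other bases, uniformly
      cur <- match(chars[hit], DNA_BASES)
      shift <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate error-bearing paired-end reads from a genome composition
#'
#' Fragments start uniformly along the source genome; the fragment strand
#' is chosen with probability 0.5; mate 1 is the fragment's first
#' \code{read_len} bases and mate 2 the reverse complement of its last
#' \code{read_len} bases. Substitution errors occur per base at
#' \code{error_rate}; qualities are a constant Q30 string. A fraction of
#' pairs can be drawn from contaminant sequences instead.
#'
#' @param genomes Sequence set of source genomes.
#' @param composition Named fractions over \code{names(genomes)}, sum 1.
#' @param n_pairs Number of read pairs.
#' @param read_len Read length (must not exceed half the shortest genome).
#' @param error_rate Per-base substitution error rate.
#' @param contaminants Optional sequence set of contaminant sources.
#' @param contaminant_frac Fraction of pairs drawn from contaminants.
#' @param seed Integer seed.
#' @return List with \code{pairs} (pair table as in
#'   \code{\link{read_fastq_pairs}}) and \code{truth} (list with
#'   \code{composition}, \code{read_origin}, \code{seed}).
#' @export
simulate_reads <- function(genomes, composition, n_pairs, read_len = 100L,
                           error_rate = 0, contaminants = NULL,
                           contaminant_frac = 0, seed = 1L) {
  if (length(composition) == 0L) stop("empty composition")
  stopifnot(all(names(composition) %in% names(genomes)),
            abs(sum(composition) - 1) < 1e-9, n_pairs >= 1L)
  if (2L * read_len > min(nchar(genomes[names(composition)])))
    stop("fragment (2 x read_len) longer than shortest genome")
  q30 <- strrep(rawToChar(as.raw(30L + 33L)), read_len)
  with_seed(seed, {
    is_contam <- if (!is.null(contaminants) && contaminant_frac > 0)
      runif(n_pairs) < contaminant_frac else rep(FALSE, n_pairs)
    origin <- character(n_pairs)
    origin[!is_contam] <- sample(names(composition), sum(!is_contam),
                                 replace = TRUE, prob = composition)
    if (any(is_contam))
      origin[is_contam] <- sample(names(contaminants), sum(is_contam),
                                  replace = TRUE)
    src <- ifelse(is_contam, contaminants[origin], genomes[origin])
    frag_len <- 2L * read_len
    start <- floor(runif(n_pairs) * (nchar(src) - frag_len + 1L)) + 1L
    frag <- substr(src, start, start + frag_len - 1L)
    minus <- runif(n_pairs) < 0.5
    frag[minus] <- revcomp(frag[minus])
    r1 <- substr(frag, 1L, read_len)
    r2 <- revcomp(substr(frag, read_len + 1L, frag_len))
    if (error_rate > 0) {
      r1 <- vapply(r1, add_read_errors, character(1L), error_rate,
                   USE.NAMES = FALSE)
      r2 <- vapply(r2, add_read_errors, character(1L), error_rate,
                   USE.NAMES = FALSE)
    }
    ids <- sprintf("read%06d", seq_len(n_pairs))
    list(pairs = data.frame(id = ids, seq1 = r1, qual1 = q30, seq2 = r2,
                            qual2 = q30, stringsAsFactors = FALSE),
         truth = list(composition = composition,
                      read_origin = setNames(origin, ids),
                      contaminant = setNames(is_contam, ids),
                      seed = seed))
  })
}

add_read_errors <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    cur <- match(chars[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

#' Simulate a two-group abundance study with planted structure
#'
#' Per-taxon abundances are log-normal: on the log scale each sample gets
#' a taxon baseline plus noise of sd \code{noise_sd_log}; taxa in a
#' correlation block share a per-sample latent factor with the given
#' loading (correlation on the log scale is loading^2 between members,
#' and ranks survive exponentiation); planted taxa have their mean in the
#' enriched group multiplied by the fold change. Rows are renormalized to
#' the TPM scale (each sample sums to one million).
#'
#' @param n_per_group Length-2 counts (nA, nB), each >= 3.
#' @param taxa data.frame with columns \code{taxon}, \code{kingdom}
#'   (\code{"fungal"}/\code{"bacterial"}) and optional \code{base_mean}
#'   (relative weight; default drawn log-normal).
#' @param planted_diff data.frame with columns \code{taxon},
#'   \code{fold_change} (> 0), \code{enriched_group} (\code{"A"}/\code{"B"});
#'   or NULL.
#' @param corr_blocks List of lists with \code{members} (taxon ids) and
#'   \code{loading} (latent-factor loading in (0, 1)); or NULL.
#' @param noise_sd_log Log-scale noise sd (natural log), default 0.5.
#' @param seed Integer seed.
#' @return List with \code{table} (samples x taxa TPM matrix, kingdom in
#'   \code{attr(,"kingdom")}), \code{groups} (named "A"/"B" labels) and
#'   \code{truth} (planted effects, blocks, seed).
#' @export
simulate_abundance_study <- function(n_per_group = c(50L, 50L), taxa,
                                     planted_diff = NULL, corr_blocks = NULL,
                                     noise_sd_log = 0.5, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 3L),
            is.data.frame(taxa), all(c("taxon", "kingdom") %in% names(taxa)))
  if (!is.null(planted_diff)) {
    if (any(planted_diff$fold_change <= 0)) stop("fold_change must be > 0")
    if (!all(planted_diff$enriched_group %in% c("A", "B")))
      stop("enriched_group must be \"A\" or \"B\"")
    if (!all(planted_diff$taxon %in% taxa$taxon))
      stop("planted taxon not in taxa")
  }
  nA <- n_per_group[1L]; nB <- n_per_group[2L]; n <- nA + nB
  p <- nrow(taxa)
  groups <- setNames(rep(c("A", "B"), c(nA, nB)),
                     sprintf("s%03d", seq_len(n)))
  with_seed(seed, {
    base <- if ("base_mean" %in% names(taxa)) taxa$base_mean
            else exp(rnorm(p, mean = 0, sd = 1.5))
    logmu <- matrix(rep(log(base), each = n), n, p,
                    dimnames = list(names(groups), taxa$taxon))
    if (!is.null(planted_diff)) {
      for (r in seq_len(nrow(planted_diff))) {
        t <- planted_diff$taxon[r]
        g <- planted_diff$enriched_group[r]
        logmu[groups == g, t] <- logmu[groups == g, t] +
          log(planted_diff$fold_change[r])
      }
    }
    eps <- matrix(rnorm(n * p), n, p)
    if (!is.null(corr_blocks)) {
      for (b in corr_blocks) {
        a <- b$loading
        stopifnot(a > 0, a < 1, all(b$members %in% taxa$taxon))
        f <- rnorm(n)
        cols <- match(b$members, taxa$taxon)
        eps[, cols] <- a * f + sqrt(1 - a^2) * eps[, cols]
      }
    }
    x <- exp(logmu + noise_sd_log * eps)
    tab <- x / rowSums(x) * 1e6
    attr(tab, "kingdom") <- setNames(taxa$kingdom, taxa$taxon)
    truth <- list(planted_diff = planted_diff, corr_blocks = corr_blocks,
                  base_mean = setNames(base, taxa$taxon),
                  noise_sd_log = noise_sd_log, seed = seed)
    list(table = tab, groups = groups, truth = truth)
  })
}
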