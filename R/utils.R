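#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor eigen ks.test p.adjust pexp quantile rbinom rnorm
#'   runif sd setNames splinefun var wilcox.test
#' @importFrom utils head read.table write.table combn
NULL

# Run `expr` under a locally seeded RNG without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                   collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# All k-mers of one sequence as a character vector (empty if too short).
kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0L))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Strand-canonical k-mers: lexicographic min of a k-mer and its reverse
# complement, so both strands of a read index identically.
canonical_kmers <- function(seq, k) {
  fwd <- kmers(seq, k)
  if (length(fwd) == 0L) return(fwd)
  rev <- rev(kmers(revcomp(seq), k))
  pmin(fwd, rev)
}

# 31-bit integer hash of k-mers via base-4 Horner evaluation mod the
# Mersenne prime 2^31-1, followed by two Lehmer mixing steps. All
# arithmetic stays below 2^53 so doubles are exact.
KMER_HASH_P <- 2147483647

hash_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0L))
  code <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1L
  if (anyNA(code)) {
    # N (or other) bases poison every k-mer window they touch -- drop those
    bad <- which(is.na(code))
    code[bad] <- 0L
  } else bad <- integer(0L)
  m <- n - k + 1L
  h <- numeric(m)
  idx <- seq_len(m)
  for (j in 0L:(k - 1L)) h <- (h * 4 + code[idx + j]) %% KMER_HASH_P
  if (length(bad)) {
    poisoned <- unique(unlist(lapply(bad, function(b)
      max(1L, b - k + 1L):min(m, b))))
    h <- h[-poisoned]
  }
  h <- (h * 48271) %% KMER_HASH_P
  (h * 48271) %% KMER_HASH_P
}

# Canonical k-mer hashes: elementwise min of forward and reverse-complement
# strand hashes, aligned by position.
hash_canonical_kmers <- function(seq, k) {
  f <- hash_kmers(seq, k)
  if (length(f) == 0L) return(f)
  r <- rev(hash_kmers(revcomp(seq), k))
  if (length(r) != length(f)) return(f)  # N-poisoned windows already dropped
  pmin(f, r)
}

# Hashed-set membership index over canonical k-mers of a sequence set.
# Environment keyed by the canonical k-mer string (exact, no collisions).
kmer_set_index <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs) {
    for (km in unique(canonical_kmers(s, k))) assign(km, TRUE, envir = env)
  }
  attr(env, "k") <- k
  attr(env, "n_kmers") <- length(ls(env))
  env
}

# Fraction of a sequence's canonical k-mers found in a set index.
kmer_hit_fraction <- function(seq, index) {
  k <- attr(index, "k")
  km <- canonical_kmers(seq, k)
  if (length(km) == 0L) return(0)
  hits <- vapply(km, function(x) exists(x, envir = index, inherits = FALSE),
                 logical(1L), USE.NAMES = FALSE)
  mean(hits)
}

# Multi-genome index: canonical k-mer -> integer vector of genome indices.
kmer_genome_index <- function(seqs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (km in unique(canonical_kmers(seqs[[i]], k))) {
      cur <- if (exists(km, envir = env, inherits = FALSE))
        get(km, envir = env) else integer(0L)
      assign(km, c(cur, i), envir = env)
    }
  }
  attr(env, "k") <- k
  attr(env, "genomes") <- names(seqs)
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a
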