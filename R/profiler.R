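# Abundance profiling: decoy-based read decontamination, k-mer
# pseudo-assignment of read pairs to catalog genomes (an external SAM/TSV
# best-hit table is accepted as a drop-in), genome-size-normalized TPM,
# and taxonomic roll-up.

#' Remove read pairs matching a decoy reference
#'
#' A pair is removed when either mate has at least \code{hit_frac} of its
#' canonical k-mers in the decoy index (host genome, prokaryotic catalog,
#' rRNA/tRNA database -- any FASTA set works as decoy).
#'
#' @param pairs Pair table.
#' @param decoys Sequence set of decoy sequences (may be empty), or a
#'   prebuilt \code{kmer_set_index}.
#' @param k K-mer size (default 31).
#' @param hit_frac Matching fraction at which a mate is called decoy
#'   (default 0.5).
#' @return List with \code{retained} (pair table) and \code{removed}
#'   (count).
#' @export
decontaminate_reads <- function(pairs, decoys, k = 31L, hit_frac = 0.5) {
  if (!is.environment(decoys) && length(decoys) == 0L) {
    warning("empty decoy set; passing all reads through")
    return(list(retained = pairs, removed = 0L))
  }
  idx <- if (is.environment(decoys)) decoys else kmer_set_index(decoys, k)
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    kmer_hit_fraction(pairs$seq1[i], idx) >= hit_frac ||
      kmer_hit_fraction(pairs$seq2[i], idx) >= hit_frac
  }, logical(1L))
  list(retained = pairs[!hit, , drop = FALSE], removed = sum(hit))
}

#' Assign read pairs to catalog genomes by shared k-mers
#'
#' Each genome is scored by the canonical k-mers it shares with the two
#' mates jointly; the pair is assigned to the unique top-scoring genome.
#' Ties and zero-score pairs are discarded and tallied, mirroring the
#' conservative best-hit rule used for external alignments.
#'
#' @param pairs Pair table.
#' @param catalog Sequence set of catalog representatives, or a prebuilt
#'   \code{kmer_genome_index}.
#' @param k K-mer size (default 31).
#' @return data.frame (read_id, genome_id, score) with attribute
#'   \code{stats} (n_ambiguous, n_unassigned).
#' @export
assign_reads <- function(pairs, catalog, k = 31L) {
  idx <- if (is.environment(catalog)) catalog
         else kmer_genome_index(catalog, k)
  genomes <- attr(idx, "genomes")
  k <- attr(idx, "k")
  n <- nrow(pairs)
  out_read <- character(n); out_gen <- character(n); out_sc <- numeric(n)
  kept <- 0L; n_amb <- 0L; n_un <- 0L
  for (i in seq_len(n)) {
    km <- c(canonical_kmers(pairs$seq1[i], k),
            canonical_kmers(pairs$seq2[i], k))
    hits <- unlist(mget(km, envir = idx, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (is.null(hits) || length(hits) == 0L) { n_un <- n_un + 1L; next }
    sc <- tabulate(hits, nbins = length(genomes))
    top <- which(sc == max(sc))
    if (length(top) > 1L) { n_amb <- n_amb + 1L; next }
    kept <- kept + 1L
    out_read[kept] <- pairs$id[i]
    out_gen[kept] <- genomes[top]
    out_sc[kept] <- sc[top]
  }
  out <- data.frame(read_id = out_read[seq_len(kept)],
                    genome_id = out_gen[seq_len(kept)],
                    score = out_sc[seq_len(kept)],
                    stringsAsFactors = FALSE)
  attr(out, "stats") <- c(n_ambiguous = n_amb, n_unassigned = n_un)
  out
}

#' Genome-size-normalized TPM
#'
#' Each genome's read count is divided by its genome size; the normalized
#' counts are rescaled to sum to one million per sample, so profiles are
#' comparable across samples and unbiased by genome length.
#'
#' @param counts Named non-negative read counts per genome.
#' @param genome_sizes Named genome lengths in bp (> 0); must cover every
#'   counted genome.
#' @return Named TPM vector over the counted genomes (sums to 1e6), or an
#'   all-zero vector with attribute \code{empty = TRUE} when no reads
#'   were assigned.
#' @export
normalize_tpm <- function(counts, genome_sizes) {
  if (any(counts < 0)) stop("negative counts")
  miss <- setdiff(names(counts), names(genome_sizes))
  if (length(miss))
    stop("no genome size for: ", paste(miss, collapse = ", "))
  sizes <- genome_sizes[names(counts)]
  if (any(sizes <= 0)) stop("non-positive genome size")
  r <- counts / sizes
  tot <- sum(r)
  if (tot == 0) {
    out <- setNames(rep(0, length(counts)), names(counts))
    attr(out, "empty") <- TRUE
    return(out)
  }
  1e6 * r / tot
}

#' Roll an abundance table up to a higher taxonomic rank
#'
#' Column-sums species columns by their lineage at the requested rank;
#' row sums are preserved exactly (the roll-up is a linear, sum-
#' preserving projection).
#'
#' @param table Samples x species TPM matrix.
#' @param taxonomy Lineage data.frame as from
#'   \code{\link{read_taxonomy_tsv}}.
#' @param rank One of genus, family, order, class, subphylum.
#' @return Samples x taxa matrix at the requested rank.
#' @export
aggregate_taxa <- function(table, taxonomy,
                           rank = c("genus", "family", "order", "class",
                                    "subphylum")) {
  rank <- match.arg(rank)
  sp <- colnames(table)
  m <- match(sp, taxonomy$species_id)
  if (anyNA(m))
    stop("species missing from taxonomy: ",
         paste(sp[is.na(m)], collapse = ", "))
  lin <- taxonomy[[rank]][m]
  out <- t(rowsum(t(table), group = lin))
  kd <- attr(table, "kingdom")
  if (!is.null(kd))
    attr(out, "kingdom") <- tapply(kd[sp], lin, function(x) x[1L])[colnames(out)]
  out
}

#' Profile a set of samples end to end
#'
#' Per sample: read QC, decoy decontamination, k-mer assignment to the
#' catalog, then genome-size-normalized TPM. Samples that fail a stage
#' are reported and skipped; the rest continue.
#'
#' @param samples Named list of pair tables (one per sample), or a
#'   data.frame with columns sample_id, r1, r2 naming FASTQ files.
#' @param catalog Sequence set of catalog representatives.
#' @param decoys Optional decoy sequence set.
#' @param k K-mer size for decontamination/assignment.
#' @param qc Logical: apply \code{\link{filter_pairs}} first.
#' @return List with \code{table} (samples x genomes TPM matrix) and
#'   \code{stats} (per-sample data.frame of read counts at each stage).
#' @export
profile_samples <- function(samples, catalog, decoys = NULL, k = 31L,
                            qc = TRUE) {
  if (is.data.frame(samples)) {
    nm <- samples$sample_id
    samples <- Map(function(r1, r2) read_fastq_pairs(r1, r2),
                   samples$r1, samples$r2)
    names(samples) <- nm
  }
  idx <- kmer_genome_index(catalog, k)
  didx <- if (!is.null(decoys) && length(decoys) > 0L)
    kmer_set_index(decoys, k) else NULL
  sizes <- setNames(nchar(catalog), names(catalog))
  tab <- matrix(0, length(samples), length(catalog),
                dimnames = list(names(samples), names(catalog)))
  stats <- data.frame(sample_id = names(samples), input = NA_integer_,
                      qc_passed = NA_integer_, decontaminated = NA_integer_,
                      assigned = NA_integer_, error = NA_character_,
                      stringsAsFactors = FALSE)
  for (si in seq_along(samples)) {
    res <- tryCatch({
      pr <- samples[[si]]
      stats$input[si] <- nrow(pr)
      if (qc) pr <- filter_pairs(pr)$passed
      stats$qc_passed[si] <- nrow(pr)
      if (!is.null(didx)) pr <- decontaminate_reads(pr, didx)$retained
      stats$decontaminated[si] <- nrow(pr)
      hits <- assign_reads(pr, idx)
      stats$assigned[si] <- nrow(hits)
      counts <- table(factor(hits$genome_id, levels = names(catalog)))
      tpm <- normalize_tpm(setNames(as.numeric(counts), names(counts)),
                           sizes)
      tab[si, names(tpm)] <- tpm
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) stats$error[si] <- res
  }
  list(table = tab, stats = stats)
}
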