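# Genome catalog curation: assembly QC (N50 / scaffold-count filters),
# scaffold-level bacterial decontamination by k-mer content, MinHash ANI
# estimation, and greedy representative-linkage clustering at the 95%
# species boundary.

#' Construct a genome record from scaffold sequences
#'
#' @param id Genome id.
#' @param scaffolds Named or unnamed character vector of scaffold
#'   sequences.
#' @return A \code{genome_record}: list with \code{id}, \code{scaffolds},
#'   \code{total_len}, \code{n_scaffolds}, \code{n50}.
#' @export
genome_record <- function(id, scaffolds) {
  stopifnot(length(scaffolds) >= 1L, all(nchar(scaffolds) > 0L))
  st <- assembly_stats_lengths(nchar(scaffolds))
  structure(list(id = id, scaffolds = scaffolds, total_len = st$total_len,
                 n_scaffolds = st$n_scaffolds, n50 = st$n50),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record %s: %d scaffold(s), %d bp, N50 %d>\n",
              x$id, x$n_scaffolds, x$total_len, x$n50))
  invisible(x)
}

#' Assembly summary statistics
#'
#' N50 is the length of the scaffold at which the descending cumulative
#' length first reaches half of the total assembly length.
#'
#' @param g A \code{genome_record}.
#' @return List with \code{total_len}, \code{n_scaffolds}, \code{n50}.
#' @export
assembly_stats <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  assembly_stats_lengths(nchar(g$scaffolds))
}

assembly_stats_lengths <- function(lens) {
  stopifnot(length(lens) >= 1L)
  lens <- sort(as.integer(lens), decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1L]]
  list(total_len = total, n_scaffolds = length(lens), n50 = n50)
}

#' Assembly quality filter
#'
#' Removes genomes of extremely low assembly quality: N50 below
#' \code{min_n50} or more than \code{max_scaffolds} scaffolds. Both
#' inequalities are strict, so the boundary values are retained.
#'
#' @param genomes List of \code{genome_record}s.
#' @param min_n50 Minimum N50 in bp (default 2000).
#' @param max_scaffolds Maximum scaffold count (default 10000).
#' @return List with \code{retained} (genome_records) and \code{removed}
#'   (data.frame id, reasons).
#' @export
qc_filter <- function(genomes, min_n50 = 2000L, max_scaffolds = 10000L) {
  retained <- list(); rem_id <- character(0L); rem_why <- character(0L)
  for (g in genomes) {
    reasons <- c(if (g$n50 < min_n50) "n50",
                 if (g$n_scaffolds > max_scaffolds) "scaffolds")
    if (length(reasons)) {
      rem_id <- c(rem_id, g$id)
      rem_why <- c(rem_why, paste(reasons, collapse = ","))
    } else retained[[length(retained) + 1L]] <- g
  }
  list(retained = retained,
       removed = data.frame(id = rem_id, reasons = rem_why,
                            stringsAsFactors = FALSE))
}

#' Drop scaffolds matching a bacterial reference
#'
#' A scaffold is removed when at least \code{frac_threshold} of its
#' canonical k-mers occur in the bacterial reference index; the genome is
#' dropped entirely (NULL returned) if no scaffold survives.
#'
#' @param g A \code{genome_record}.
#' @param bacterial_ref Sequence set of bacterial sequences, or a
#'   prebuilt index from \code{kmer_set_index}.
#' @param k K-mer size (default 31).
#' @param frac_threshold Matching k-mer fraction at which a scaffold is
#'   called bacterial (default 0.5).
#' @return Cleaned \code{genome_record} with stats recomputed, or NULL.
#' @export
decontaminate_scaffolds <- function(g, bacterial_ref, k = 31L,
                                    frac_threshold = 0.5) {
  stopifnot(inherits(g, "genome_record"))
  idx <- if (is.environment(bacterial_ref)) bacterial_ref
         else kmer_set_index(bacterial_ref, k)
  frac <- vapply(g$scaffolds, kmer_hit_fraction, numeric(1L), idx,
                 USE.NAMES = FALSE)
  keep <- frac < frac_threshold
  if (!any(keep)) return(NULL)
  genome_record(g$id, g$scaffolds[keep])
}

#' MinHash bottom sketch of a genome
#'
#' @param g A \code{genome_record} or a single sequence string.
#' @param k K-mer size (default 21).
#' @param sketch Sketch size (default 2000).
#' @return Sorted numeric vector of the smallest \code{sketch} distinct
#'   canonical k-mer hashes, with attributes \code{k} and \code{sketch}.
#' @export
genome_sketch <- function(g, k = 21L, sketch = 2000L) {
  seqs <- if (inherits(g, "genome_record")) g$scaffolds else g
  h <- sort(unique(unlist(lapply(seqs, hash_canonical_kmers, k))))
  structure(head(h, sketch), k = k, sketch = sketch)
}

#' Estimate average nucleotide identity from MinHash sketches
#'
#' The bottom-sketch Jaccard estimate j is mapped through the Mash
#' distance d = -(1/k) log(2j / (1 + j)); the returned ANI is 1 - d
#' clamped to [0, 1] (j = 0 reports ANI 0). Symmetric in its arguments.
#'
#' @param a,b \code{genome_record}s, sequences, or precomputed sketches
#'   from \code{\link{genome_sketch}}.
#' @param k K-mer size (default 21; ignored for precomputed sketches).
#' @param sketch Sketch size (default 2000).
#' @return ANI estimate in [0, 1].
#' @export
estimate_ani <- function(a, b, k = 21L, sketch = 2000L) {
  sa <- if (!is.null(attr(a, "sketch"))) a else genome_sketch(a, k, sketch)
  sb <- if (!is.null(attr(b, "sketch"))) b else genome_sketch(b, k, sketch)
  stopifnot(attr(sa, "k") == attr(sb, "k"))
  k <- attr(sa, "k")
  s <- min(attr(sa, "sketch"), attr(sb, "sketch"))
  merged <- head(sort(unique(c(sa, sb))), s)
  j <- sum(merged %in% sa & merged %in% sb) / length(merged)
  if (j == 0) return(0)
  d <- -(1 / k) * log(2 * j / (1 + j))
  min(1, max(0, 1 - d))
}

#' Greedy species clustering at an ANI threshold
#'
#' Genomes are sorted by (N50 desc, total length desc, id asc); each joins
#' the first existing cluster whose representative it matches at
#' \code{ani_threshold} or better, else founds a new cluster. The result
#' partitions the input and is invariant to input order.
#'
#' @param genomes List of \code{genome_record}s (QC-passed,
#'   decontaminated).
#' @param ani_threshold ANI at or above which two genomes are conspecific
#'   (default 0.95).
#' @param k,sketch Sketch parameters passed to \code{\link{genome_sketch}}.
#' @return List of clusters, each a list with \code{representative},
#'   \code{members}, \code{rep_rule}.
#' @export
cluster_species <- function(genomes, ani_threshold = 0.95, k = 21L,
                            sketch = 2000L) {
  if (length(genomes) == 0L) return(list())
  ids <- vapply(genomes, `[[`, character(1L), "id")
  n50 <- vapply(genomes, `[[`, integer(1L), "n50")
  tot <- vapply(genomes, `[[`, integer(1L), "total_len")
  ord <- order(-n50, -tot, ids)
  sketches <- lapply(genomes, genome_sketch, k = k, sketch = sketch)
  clusters <- list()
  reps <- integer(0L)  # genome indices of representatives
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (estimate_ani(sketches[[i]], sketches[[reps[ci]]]) >= ani_threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(representative = ids[i], members = ids[i],
             rep_rule = "max_n50_then_len_then_id")
      reps <- c(reps, i)
    }
  }
  clusters
}

#' Run the full catalog curation
#'
#' QC filter, optional decontamination, then species clustering; returns
#' the catalog table and the representative sequence set.
#'
#' @param genomes List of \code{genome_record}s.
#' @param bacterial_ref Optional sequence set for decontamination.
#' @param min_n50,max_scaffolds QC thresholds.
#' @param ani_threshold Species ANI threshold.
#' @param k,sketch Sketch parameters.
#' @return List with \code{catalog} (data.frame genome_id, cluster_id,
#'   representative_flag, n50, n_scaffolds, total_len), \code{clusters},
#'   \code{representatives} (sequence set, scaffolds concatenated) and
#'   \code{removed}.
#' @export
build_catalog <- function(genomes, bacterial_ref = NULL, min_n50 = 2000L,
                          max_scaffolds = 10000L, ani_threshold = 0.95,
                          k = 21L, sketch = 2000L) {
  qc <- qc_filter(genomes, min_n50, max_scaffolds)
  kept <- qc$retained
  if (!is.null(bacterial_ref)) {
    idx <- kmer_set_index(bacterial_ref, 31L)
    kept <- Filter(Negate(is.null),
                   lapply(kept, decontaminate_scaffolds, idx))
  }
  clusters <- cluster_species(kept, ani_threshold, k, sketch)
  ids <- vapply(kept, `[[`, character(1L), "id")
  rows <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    data.frame(genome_id = cl$members,
               cluster_id = sprintf("c%03d", ci),
               representative_flag = cl$members == cl$representative,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(genome_id = character(0L), cluster_id = character(0L),
                       representative_flag = logical(0L))
  m <- match(rows$genome_id, ids)
  rows$n50 <- vapply(kept[m], `[[`, integer(1L), "n50")
  rows$n_scaffolds <- vapply(kept[m], `[[`, integer(1L), "n_scaffolds")
  rows$total_len <- vapply(kept[m], `[[`, integer(1L), "total_len")
  reps <- vapply(clusters, `[[`, character(1L), "representative")
  rep_seqs <- setNames(vapply(kept[match(reps, ids)], function(g)
    paste(g$scaffolds, collapse = ""), character(1L)), reps)
  list(catalog = rows, clusters = clusters, representatives = rep_seqs,
       removed = qc$removed)
}
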