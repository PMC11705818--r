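# Readers and writers for every on-disk artifact the pipeline touches:
# FASTA / FASTQ (Phred+33), SAM or TSV best-hit tables, abundance and
# lineage TSVs, and network edge-list + GraphML exports.

#' Read a FASTA file into a sequence set
#'
#' A sequence set is a named character vector (names are record ids,
#' values are upper-case DNA strings over A, C, G, T, N). Multi-line
#' records are concatenated; case is folded to upper.
#'
#' @param path Path to a FASTA file (gzip accepted by extension).
#' @param on_alpha What to do with characters outside \code{ACGTN}:
#'   \code{"error"} (default) or \code{"mask"} (replace with N).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, on_alpha = c("error", "mask")) {
  on_alpha <- match.arg(on_alpha)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- nchar(seqs) == 0L
  if (any(empty)) stop("empty sequence: ", paste(ids[empty], collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_alpha == "error")
      stop("non-ACGTN characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  setNames(seqs, ids)
}

#' Write a sequence set to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read paired FASTQ files into a pair table
#'
#' Pairs are matched by record order; mate ids must agree after stripping
#' a trailing \code{/1} or \code{/2} (or \code{.1}/\code{.2}) suffix.
#' Unequal record counts are an error that reports the unpaired ids.
#'
#' @param path_r1,path_r2 FASTQ paths (gzip accepted by extension).
#' @return A data.frame with columns \code{id}, \code{seq1}, \code{qual1},
#'   \code{seq2}, \code{qual2}; qualities are Phred+33 strings.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  id1 <- strip_mate_suffix(r1$id)
  id2 <- strip_mate_suffix(r2$id)
  if (nrow(r1) != nrow(r2)) {
    n <- min(nrow(r1), nrow(r2))
    extra <- if (nrow(r1) > n) id1[(n + 1L):nrow(r1)] else id2[(n + 1L):nrow(r2)]
    stop(length(extra), " unpaired read(s): ",
         paste(head(extra, 10L), collapse = ", "))
  }
  mism <- id1 != id2
  if (any(mism))
    stop("mate id mismatch at record(s) ",
         paste(head(which(mism), 10L), collapse = ", "), ": e.g. '",
         id1[which(mism)[1L]], "' vs '", id2[which(mism)[1L]], "'")
  data.frame(id = id1, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    # the reader warns that FASTQ metadata columns are dropped; we only
    # need ids, bases and qualities
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) stop("FASTQ parse error in '", path, "': ",
                             conditionMessage(e)))
  seqs <- toupper(as.character(set))
  quals <- as.character(Biostrings::quality(set))
  if (any(nchar(seqs) != nchar(quals)))
    stop("sequence/quality length mismatch in '", path, "'")
  data.frame(id = sub("\\s.*$", "", names(set)), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

strip_mate_suffix <- function(ids) sub("[/.][12]$", "", ids)

#' Write a pair table to two FASTQ files
#'
#' @param pairs Pair table as from \code{\link{read_fastq_pairs}}.
#' @param path_r1,path_r2 Output paths; \code{.gz} extension compresses.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_one <- function(ids, seqs, quals, path, mate) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", quals), con)
  }
  write_one(pairs$id, pairs$seq1, pairs$qual1, path_r1, 1L)
  write_one(pairs$id, pairs$seq2, pairs$qual2, path_r2, 2L)
  invisible(c(path_r1, path_r2))
}

#' Read best read-to-genome hits from SAM or TSV
#'
#' For SAM input, unmapped (flag 0x4) and secondary/supplementary
#' (0x100/0x800) records are dropped; among the remaining records of a
#' read the highest alignment score (AS tag) wins, and reads whose top
#' score is tied across genomes are discarded as ambiguous. TSV input has
#' columns \code{read_id}, \code{genome_id}, \code{score} and receives the
#' same best-hit reduction.
#'
#' @param path Input path.
#' @param format \code{"sam"} or \code{"tsv"} (default: by extension).
#' @return data.frame (\code{read_id}, \code{genome_id}, \code{score}),
#'   one row per retained read, with attribute \code{n_ambiguous}.
#' @export
read_best_hits <- function(path, format = c("auto", "sam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  tab <- if (format == "sam") read_sam_hits(path) else {
    x <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    if (!all(c("read_id", "genome_id", "score") %in% names(x)))
      stop("TSV must have columns read_id, genome_id, score")
    if (any(x$score < 0)) stop("negative alignment score")
    x[, c("read_id", "genome_id", "score")]
  }
  best_hit_reduce(tab)
}

read_sam_hits <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM input requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "rname"), tag = "AS",
                               flag = flags)
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  score <- x$tag$AS
  if (is.null(score)) score <- rep(0, length(x$qname))
  score[is.na(score)] <- 0
  data.frame(read_id = x$qname, genome_id = as.character(x$rname),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

# One best-hit row per read; top-score ties across genomes are ambiguous
# and dropped (tallied in attr n_ambiguous). Idempotent.
best_hit_reduce <- function(tab) {
  if (nrow(tab) == 0L) {
    attr(tab, "n_ambiguous") <- 0L
    return(tab)
  }
  keep <- integer(0L)
  n_amb <- 0L
  for (rows in split(seq_len(nrow(tab)), tab$read_id)) {
    sc <- tab$score[rows]
    top <- rows[sc == max(sc)]
    if (length(unique(tab$genome_id[top])) > 1L) n_amb <- n_amb + 1L
    else keep <- c(keep, top[1L])
  }
  out <- tab[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Write / read an abundance table as TSV
#'
#' Samples are rows, taxa columns; the first column is \code{sample_id}.
#' Values are serialized with 6 significant digits.
#'
#' @param table Numeric matrix, samples x taxa, with dimnames.
#' @param path Output path.
#' @export
write_abundance_tsv <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   signif(as.data.frame(table), 6L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a taxonomy lineage table
#'
#' TSV with columns \code{species_id}, \code{genus}, \code{family},
#' \code{order}, \code{class}, \code{subphylum}; empty ranks become
#' \code{"unclassified"}.
#'
#' @param path Input path.
#' @return data.frame keyed by \code{species_id}.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("species_id", "genus", "family", "order", "class", "subphylum")
  if (!all(need %in% names(df)))
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  for (r in need[-1L]) {
    blank <- is.na(df[[r]]) | df[[r]] == ""
    df[[r]][blank] <- "unclassified"
  }
  if (anyDuplicated(df$species_id)) stop("duplicate species_id in taxonomy")
  df[, need]
}

#' Write a co-occurrence network to edge-list TSV and GraphML
#'
#' The TSV has columns source, target, weight, sign; the GraphML carries
#' node attributes \code{kingdom} and \code{degree}. A round-trip through
#' \code{\link{read_network}} reproduces the adjacency exactly.
#'
#' @param net A \code{co_network} (see \code{\link{build_network}}).
#' @param path_edges,path_graphml Output paths.
#' @export
write_network <- function(net, path_edges, path_graphml) {
  stopifnot(inherits(net, "co_network"))
  ed <- net$edges
  write.table(
    data.frame(source = ed$i, target = ed$j,
               weight = signif(ed$weight, 6L), sign = ed$sign),
    path_edges, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes,
                            kingdom = unname(net$kingdom[net$nodes]),
                            degree = unname(net$degree[net$nodes]))
  if (nrow(ed) > 0L)
    g <- igraph::add_edges(g, rbind(match(ed$i, net$nodes),
                                    match(ed$j, net$nodes)),
                           weight = ed$weight, sign = ed$sign)
  igraph::write_graph(g, path_graphml, format = "graphml")
  invisible(net)
}

#' @rdname write_network
#' @param threshold Correlation threshold recorded on the rebuilt network.
#' @export
read_network <- function(path_edges, path_graphml, threshold = NA_real_) {
  g <- igraph::read_graph(path_graphml, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  kingdom <- setNames(igraph::vertex_attr(g, "kingdom") %||%
                        rep(NA_character_, length(nodes)), nodes)
  ed <- read.table(path_edges, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "character"))
  names(ed) <- c("i", "j", "weight", "sign")
  new_co_network(nodes, ed, kingdom = kingdom, threshold = threshold)
}
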