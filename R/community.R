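# Community-level statistics: alpha diversity, Bray-Curtis dissimilarity
# on square-root transformed profiles, principal coordinate analysis via
# Gower double-centering, and permutation PERMANOVA.

#' Alpha diversity of one sample
#'
#' Richness is the number of taxa with abundance greater than zero;
#' Shannon's index is -sum p log p (natural log) over the positive
#' fractions. Computed on untransformed profiles.
#'
#' @param profile Non-negative abundance vector (any scale).
#' @return List with \code{richness} and \code{shannon}.
#' @export
alpha_diversity <- function(profile) {
  if (any(profile < 0)) stop("negative abundances")
  pos <- profile[profile > 0]
  if (length(pos) == 0L) return(list(richness = 0L, shannon = 0))
  p <- pos / sum(pos)
  list(richness = length(pos), shannon = -sum(p * log(p)))
}

#' Bray-Curtis distance matrix
#'
#' Profiles are brought to the fraction scale (TPM / 1e6 when rows sum to
#' one million), square-root transformed by default, and compared as
#' d(i,j) = sum |x_i - x_j| / sum (x_i + x_j).
#'
#' @param table Samples x taxa abundance matrix (TPM or fraction scale).
#' @param transform \code{"sqrt"} (default) or \code{"none"}.
#' @return Symmetric distance matrix with zero diagonal, entries in
#'   [0, 1], class \code{dist_matrix}.
#' @export
bray_curtis <- function(table, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (nrow(table) < 2L) stop("need at least 2 samples")
  rs <- rowSums(table)
  x <- table / ifelse(rs > 0, rs, 1)  # fraction scale
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(x[i, ] + x[j, ])
      if (denom == 0) {
        warning("two all-zero samples; distance set to 0")
        d[i, j] <- d[j, i] <- 0
      } else d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Principal coordinate analysis
#'
#' Gower double-centering of the squared distances, eigendecomposition,
#' and coordinates scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues are dropped from both the
#' coordinates and the explained-variance denominator.
#'
#' @param d Symmetric distance matrix.
#' @return List of class \code{pcoa_result} with \code{coordinates}
#'   (samples x axes), \code{eigenvalues} and \code{explained}.
#' @export
pcoa_ord <- function(d) {
  d <- unclass(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = lam,
                 explained = lam / sum(lam)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result: %d samples, %d positive axes>\n",
              nrow(x$coordinates), length(x$eigenvalues)))
  cat("  explained:", paste(sprintf("%.1f%%", 100 * head(x$explained, 5L)),
                            collapse = ", "), "...\n")
  invisible(x)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared-distance sums into between- and within-group
#' components, forms the pseudo-F statistic, and obtains its p-value by
#' label permutation with the +1 correction (p is never zero).
#'
#' @param d Symmetric distance matrix.
#' @param labels Group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class \code{permanova_result} with \code{r2},
#'   \code{pseudo_f}, \code{p}, \code{n_perm}.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- unclass(d)
  n <- nrow(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  tabn <- table(labels)
  if (length(tabn) < 2L) stop("need at least 2 groups")
  if (any(tabn < 2L)) stop("every group needs >= 2 samples")
  d2 <- d^2
  f_stat <- function(lab) {
    ss_total <- sum(d2[upper.tri(d2)]) / n
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    g <- length(unique(lab))
    c(f = (ss_between / (g - 1)) / (ss_within / (n - g)),
      r2 = ss_between / ss_total)
  }
  obs <- f_stat(labels)
  perm_f <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    f_stat(sample(labels))[["f"]], numeric(1L)))
  p <- (1 + sum(perm_f >= obs[["f"]])) / (1 + n_perm)
  structure(list(r2 = obs[["r2"]], pseudo_f = obs[["f"]], p = p,
                 n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d perms)>\n",
              x$r2, x$pseudo_f, x$p, x$n_perm))
  invisible(x)
}
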