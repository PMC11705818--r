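# Disease-state classification from abundance profiles: stratified
# repeated k-fold cross-validation, out-of-fold AUC with bootstrap CI,
# random-forest and LASSO models, and importance rankings.

#' Define a cross-validation scheme
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Repeats (default 5).
#' @param stratified Keep per-fold class proportions within one sample of
#'   the global proportions (default TRUE).
#' @param seed Integer seed; repeats use sub-seeds derived from it.
#' @return List of class \code{cv_scheme}.
#' @export
cv_scheme <- function(n_folds = 10L, n_repeats = 5L, stratified = TRUE,
                      seed = 1L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Stratified fold assignment
#'
#' Every sample appears in exactly one test fold per repeat; with
#' stratification each class is dealt round-robin over a shuffled order,
#' so per-fold class counts differ by at most one sample.
#'
#' @param labels Class label per sample.
#' @param scheme A \code{\link{cv_scheme}}.
#' @return Integer matrix samples x repeats of fold ids in
#'   1..\code{n_folds}.
#' @export
make_folds <- function(labels, scheme) {
  labels <- as.character(labels)
  n <- length(labels)
  if (min(table(labels)) < scheme$n_folds)
    stop("a class has fewer samples than folds")
  out <- matrix(NA_integer_, n, scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    out[, r] <- with_seed(scheme$seed * 1000L + r, {
      fold <- integer(n)
      if (scheme$stratified) {
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          fold[sample(idx)] <- rep_len(seq_len(scheme$n_folds), length(idx))
        }
      } else fold[sample.int(n)] <- rep_len(seq_len(scheme$n_folds), n)
      fold
    })
  }
  out
}

#' Rank-statistic AUC from scores
#'
#' Mann-Whitney formulation with midranks for tied scores; equals the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Predicted score per sample (higher = more positive).
#' @param labels Class label per sample.
#' @param positive The positive class (default: the lexicographically
#'   larger label).
#' @return AUC in [0, 1].
#' @export
auc_from_scores <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("need exactly 2 classes")
  positive <- positive %||% cls[2L]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples within each class with replacement and takes the 2.5/97.5
#' percentiles of the resampled AUCs.
#'
#' @param scores,labels,positive As \code{\link{auc_from_scores}}.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return Length-2 vector (lo, hi).
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L,
                   positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2L)
  i1 <- which(labels == cls[1L]); i2 <- which(labels == cls[2L])
  with_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i2, replace = TRUE))
      auc_from_scores(scores[idx], labels[idx], positive)
    }, numeric(1L))
    unname(quantile(aucs, c(0.025, 0.975)))
  })
}

#' Cross-validated classification of a two-group study
#'
#' Per repeat and fold the model is fitted on the training part only
#' (LASSO: features standardized on the training fold, penalty picked by
#' inner 5-fold CV minimizing deviance; random forest: fixed forest
#' size) and scores the held-out fold. The AUC is computed on the pooled
#' out-of-fold scores of each repeat and averaged over repeats; the CI is
#' a stratified bootstrap on the per-sample scores averaged across
#' repeats. Importance: RF mean Gini-decrease rank across folds, LASSO
#' mean absolute standardized coefficient.
#'
#' @param table Samples x taxa abundance matrix (TPM or fraction scale;
#'   converted to fractions internally).
#' @param labels Class label per sample (two classes).
#' @param model \code{"rf"} or \code{"lasso"}.
#' @param scheme A \code{\link{cv_scheme}}; default 10-fold x 5 repeats
#'   for RF and 5-fold x 5 repeats for LASSO.
#' @param hyper List of hyperparameters (\code{ntree} for RF, default
#'   500).
#' @return List of class \code{classifier_report}: model, auc, auc_ci,
#'   per_repeat_auc, per_sample_scores, oof_scores (samples x repeats
#'   out-of-fold score matrix), importance, scheme, positive.
#' @export
crossval_model <- function(table, labels, model = c("rf", "lasso"),
                           scheme = NULL, hyper = list()) {
  model <- match.arg(model)
  scheme <- scheme %||%
    cv_scheme(n_folds = if (model == "rf") 10L else 5L, n_repeats = 5L)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  stopifnot(length(cls) == 2L, nrow(table) == length(labels))
  x <- as.matrix(table)
  if (max(x) > 1) x <- x / 1e6  # fraction scale
  y <- factor(labels, levels = cls)
  folds <- make_folds(labels, scheme)
  n <- nrow(x); p <- ncol(x)
  scores <- matrix(NA_real_, n, scheme$n_repeats)
  imp <- matrix(0, p, 0)
  for (r in seq_len(scheme$n_repeats)) {
    for (f in seq_len(scheme$n_folds)) {
      test <- folds[, r] == f
      fit_seed <- scheme$seed * 100000L + r * 100L + f
      if (model == "rf") {
        ntree <- hyper$ntree %||% 500L
        fit <- with_seed(fit_seed,
          randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                     ntree = ntree))
        scores[test, r] <- stats::predict(fit, x[test, , drop = FALSE],
                                          type = "prob")[, cls[2L]]
        imp <- cbind(imp, fit$importance[, "MeanDecreaseGini"])
      } else {
        xtr <- x[!test, , drop = FALSE]
        mu <- colMeans(xtr); sg <- apply(xtr, 2L, sd)
        use <- sg > 0
        xs <- scale(xtr[, use, drop = FALSE], mu[use], sg[use])
        cvfit <- with_seed(fit_seed,
          glmnet::cv.glmnet(xs, y[!test], family = "binomial",
                            nfolds = 5L, type.measure = "deviance",
                            standardize = FALSE))
        xte <- scale(x[test, use, drop = FALSE], mu[use], sg[use])
        scores[test, r] <- as.numeric(
          stats::predict(cvfit, xte, s = "lambda.min", type = "response"))
        co <- rep(0, p)
        co[use] <- abs(as.numeric(
          stats::coef(cvfit, s = "lambda.min"))[-1L])
        imp <- cbind(imp, co)
      }
    }
  }
  per_repeat <- vapply(seq_len(scheme$n_repeats), function(r)
    auc_from_scores(scores[, r], labels, positive = cls[2L]), numeric(1L))
  mean_scores <- rowMeans(scores)
  importance <- if (model == "rf") {
    # mean rank (high importance = low rank number) aggregated over folds
    rk <- apply(-imp, 2L, rank)
    v <- rowMeans(rk)
    data.frame(taxon = colnames(table), value = p + 1 - v,
               stringsAsFactors = FALSE)[order(v), ]
  } else {
    v <- rowMeans(imp)
    data.frame(taxon = colnames(table), value = v,
               stringsAsFactors = FALSE)[order(-v), ]
  }
  rownames(importance) <- NULL
  structure(list(model = model, auc = mean(per_repeat),
                 auc_ci = auc_ci(mean_scores, labels,
                                 seed = scheme$seed + 7L,
                                 positive = cls[2L]),
                 per_repeat_auc = per_repeat,
                 per_sample_scores = setNames(mean_scores, rownames(table)),
                 oof_scores = scores,
                 importance = importance, scheme = scheme,
                 positive = cls[2L]),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report %s: AUC %.3f (95%% CI %.3f-%.3f), %dx%d CV>\n",
              x$model, x$auc, x$auc_ci[1L], x$auc_ci[2L],
              x$scheme$n_folds, x$scheme$n_repeats))
  invisible(x)
}

#' Joint fungal + bacterial classification
#'
#' Concatenates the two kingdom tables on shared samples (features
#' prefixed \code{F__}/\code{B__}) and runs \code{\link{crossval_model}};
#' the importance table gains a kingdom column.
#'
#' @param fungal,bacterial Samples x taxa matrices over identical
#'   samples.
#' @param labels Class label per sample.
#' @param model,scheme,hyper As \code{\link{crossval_model}}.
#' @return \code{classifier_report} with per-kingdom importance.
#' @export
combined_model <- function(fungal, bacterial, labels,
                           model = c("rf", "lasso"), scheme = NULL,
                           hyper = list()) {
  if (!identical(rownames(fungal), rownames(bacterial)))
    stop("sample ids differ between the fungal and bacterial tables")
  f <- fungal; b <- bacterial
  if (max(f) > 1) f <- f / 1e6
  if (max(b) > 1) b <- b / 1e6
  colnames(f) <- paste0("F__", colnames(fungal))
  colnames(b) <- paste0("B__", colnames(bacterial))
  rep <- crossval_model(cbind(f, b), labels, model = model, scheme = scheme,
                        hyper = hyper)
  rep$importance$kingdom <- ifelse(grepl("^F__", rep$importance$taxon),
                                   "fungal", "bacterial")
  rep
}
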