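#' Hard confusion matrix
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param positive Positive class label (default \code{"EARLY"}).
#' @return Object of class \code{hard_cm}: integer counts \code{tp},
#'   \code{fn}, \code{fp}, \code{tn}.
#' @export
hard_confusion_matrix <- function(truth, predicted, positive = "EARLY") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  pos <- truth == positive
  pred_pos <- predicted == positive
  hard_cm(tp = sum(pos & pred_pos), fn = sum(pos & !pred_pos),
          fp = sum(!pos & pred_pos), tn = sum(!pos & !pred_pos))
}

#' @param tp,fn,fp,tn Nonnegative integer cell counts.
#' @rdname hard_confusion_matrix
#' @export
hard_cm <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0)) stop("confusion-matrix cells must be nonnegative")
  structure(as.list(cells), class = "hard_cm")
}

#' @export
print.hard_cm <- function(x, ...) {
  cat("confusion matrix (rows = truth, cols = prediction):\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("EARLY", "LATE"), c("EARLY", "LATE")))
  print(m)
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Computes accuracy \eqn{CA = (tp+tn)/n}, precision \eqn{PR = tp/(tp+fp)},
#' recall \eqn{RE = tp/(tp+fn)} and the F-beta measure
#' \eqn{F_\beta = (1+\beta^2) PR \cdot RE / (\beta^2 PR + RE)}, reported as
#' percentages. Undefined ratios (zero denominators) are defined as 0 with a
#' warning. Values are returned unrounded; round to one decimal for
#' presentation.
#'
#' @param cm A \code{hard_cm} (or list with fields tp, fn, fp, tn).
#' @param beta Beta of the F-measure (default 1).
#' @return Named numeric vector \code{c(CA, PR, RE, F)} in percent.
#' @examples
#' round(cm_metrics(hard_cm(348, 134, 891, 1893)), 1)
#' @export
cm_metrics <- function(cm, beta = 1) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      0
    } else num / den
  }
  ca <- (tp + tn) / n
  pr <- safe_div(tp, tp + fp, "precision")
  re <- safe_div(tp, tp + fn, "recall")
  f <- if (pr == 0 && re == 0) 0 else
    (1 + beta^2) * pr * re / (beta^2 * pr + re)
  100 * c(CA = ca, PR = pr, RE = re, F = f)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped into one step), records the true/false positive rates and
#' integrates the curve with the trapezoid rule. The area equals the
#' pairwise concordance probability (concordant pairs plus half the tied
#' pairs over all positive-negative pairs).
#'
#' @param scores Numeric vector; larger means more positive.
#' @param labels Class labels.
#' @param positive Positive class label.
#' @return List of class \code{roc_result}: \code{curve} (data frame with
#'   \code{threshold}, \code{fpr}, \code{tpr}) and \code{auc} in [0, 1].
#' @export
roc_auroc <- function(scores, labels, positive = "EARLY") {
  labels <- as.character(labels)
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into a single threshold step
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_group]
  fp <- cumsum(!p)[last_of_group]
  curve <- data.frame(threshold = c(Inf, s[last_of_group]),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d threshold steps, auROC = %.3f\n",
              nrow(x$curve) - 1L, x$auc))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Assigns every row to exactly one of \code{k} folds so that the per-fold
#' count of each class differs by at most one across folds (shuffled within
#' class, then dealt round-robin). Deterministic for a fixed seed.
#'
#' @param labels Class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 42L) {
  labels <- as.character(labels)
  if (any(table(labels) < k))
    stop("every class needs at least k = ", k, " members")
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a GMLVQ configuration
#'
#' For each fold the standardization is fitted on the training split only
#' (no leakage), a model is trained with \code{\link{gmlvq_train}} and the
#' held-out rows are predicted. Hard confusion matrices and scores are
#' accumulated; headline metrics are computed on the pooled predictions,
#' per-fold metrics (mean and sd) secondarily, and the auROC on the pooled
#' scores.
#'
#' @param table Labeled feature table (must contain a \code{label} column).
#' @param config A \code{\link{train_config}}; per-fold training seeds are
#'   derived from \code{config$seed}.
#' @param spec A \code{\link{cost_spec}}.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment (defaults to the config seed).
#' @param positive Positive class label.
#' @return Object of class \code{cv_report}: pooled confusion matrix and
#'   metrics, auROC, per-fold metric table, fold assignment, pooled
#'   predictions and the per-fold standardization parameters.
#' @export
cross_validate <- function(table, config = train_config(),
                           spec = cost_spec("CA"), k = 10L,
                           seed = config$seed, positive = "EARLY") {
  sp <- .split_table(table)
  fold <- stratified_kfold(sp$labels, k = k, seed = seed)
  pred_label <- character(nrow(table))
  pred_score <- numeric(nrow(table))
  fold_rows <- list()
  fold_standardization <- list()
  for (f in seq_len(k)) {
    test <- fold == f
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- tryCatch(
      gmlvq_train(sp$x[!test, , drop = FALSE], sp$labels[!test],
                  config = cfg_f, spec = spec, positive = positive),
      error = function(e) stop("training failed in fold ", f, ": ",
                               conditionMessage(e)))
    fold_standardization[[f]] <- list(center = model$center,
                                      scale = model$scale)
    pr <- predict(model, sp$x[test, , drop = FALSE])
    pred_label[test] <- pr$label
    pred_score[test] <- pr$score
    cm_f <- hard_confusion_matrix(sp$labels[test], pr$label, positive)
    met_f <- suppressWarnings(cm_metrics(cm_f, beta = spec$beta))
    fold_rows[[f]] <- data.frame(fold = f, tp = cm_f$tp, fn = cm_f$fn,
                                 fp = cm_f$fp, tn = cm_f$tn,
                                 CA = met_f["CA"], PR = met_f["PR"],
                                 RE = met_f["RE"], F = met_f["F"],
                                 row.names = NULL)
  }
  pooled_cm <- hard_confusion_matrix(sp$labels, pred_label, positive)
  pooled <- suppressWarnings(cm_metrics(pooled_cm, beta = spec$beta))
  roc <- roc_auroc(pred_score, sp$labels, positive)
  folds <- do.call(rbind, fold_rows)
  structure(list(pooled_cm = pooled_cm, pooled_metrics = pooled,
                 auroc = roc$auc, roc = roc, folds = folds,
                 fold_assignment = fold,
                 predictions = data.frame(label = pred_label,
                                          score = pred_score,
                                          truth = sp$labels,
                                          fold = fold),
                 fold_standardization = fold_standardization,
                 config = config, spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s cost)\n",
              max(x$fold_assignment), x$spec$kind))
  cat(sprintf("  pooled CM: TP %d  FP %d / FN %d  TN %d\n",
              x$pooled_cm$tp, x$pooled_cm$fp, x$pooled_cm$fn,
              x$pooled_cm$tn))
  m <- x$pooled_metrics
  cat(sprintf("  CA %.1f  PR %.1f  RE %.1f  F1 %.1f  auROC %.1f (%%)\n",
              m["CA"], m["PR"], m["RE"], m["F"], 100 * x$auroc))
  invisible(x)
}

#' Write a cross-validation report as CSV files
#'
#' Emits \code{cv_summary.csv} (pooled confusion matrix and metrics plus
#' auROC, one row, percentages unrounded) and \code{cv_folds.csv} (per-fold
#' confusion matrices and metrics).
#'
#' @param report A \code{cv_report}.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- report$pooled_metrics
  summary_df <- data.frame(
    tp = report$pooled_cm$tp, fn = report$pooled_cm$fn,
    fp = report$pooled_cm$fp, tn = report$pooled_cm$tn,
    CA = m["CA"], PR = m["PR"], RE = m["RE"], F = m["F"],
    auROC = 100 * report$auroc, row.names = NULL)
  f1 <- file.path(dir, "cv_summary.csv")
  write.csv(summary_df, f1, row.names = FALSE)
  f2 <- file.path(dir, "cv_folds.csv")
  write.csv(report$folds, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
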