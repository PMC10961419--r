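# Multiclass evaluation: confusion matrix, one-vs-rest precision/recall/F1,
# macro aggregation, overall accuracy, and per-crop-group summaries.

#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in `1..K` (equal length, non-empty).
#' @param K class count.
#' @return `K x K` integer matrix; entry `(i, j)` counts samples of true
#'   class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  if (length(y_true) == 0L) stop("empty label vector")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (any(y_true < 1L | y_true > K) || any(y_pred < 1L | y_pred > K))
    stop("label out of range")
  M <- matrix(0L, K, K)
  tab <- table(factor(y_true, levels = seq_len(K)),
               factor(y_pred, levels = seq_len(K)))
  M[] <- as.integer(tab)
  M
}

#' Metrics from a confusion matrix
#'
#' One-vs-rest per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, with the `0/0` convention of 0 (a warning is emitted).
#' Macro metrics are unweighted class means (support-weighted means are also
#' returned).  Overall accuracy is `trace/total`; the one-vs-rest accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` is additionally reported per class but is not the
#' headline accuracy, since summing it over classes inflates the value.
#'
#' @param M non-negative `K x K` count matrix with a positive total.
#' @param groups optional integer/character vector of length `K` mapping each
#'   class to a group (crop); when given, per-group macro metrics are added.
#' @return object of class `metrics_report`: `confusion`, `per_class` (data
#'   frame with P, R, F1, support, ovr_accuracy), `precision`, `recall`,
#'   `f1` (macro), `weighted_precision`/`recall`/`f1`, `accuracy`, and
#'   optionally `per_group`.
#' @export
metrics_from_confusion <- function(M, groups = NULL) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  if (any(M < 0)) stop("negative counts")
  total <- sum(M)
  if (total == 0) stop("all-zero confusion matrix")
  K <- nrow(M)
  tp <- diag(M)
  fp <- colSums(M) - tp
  fn <- rowSums(M) - tp
  tn <- total - tp - fp - fn
  any_00 <- FALSE
  safe_div <- function(num, den) {
    if (any(den == 0)) any_00 <<- TRUE
    ifelse(den == 0, 0, num / den)
  }
  P <- safe_div(tp, tp + fp)
  R <- safe_div(tp, tp + fn)
  F1 <- safe_div(2 * P * R, P + R)
  if (any_00) warning("0/0 metric encountered; reported as 0")
  support <- rowSums(M)
  per_class <- data.frame(class = seq_len(K), precision = P, recall = R,
                          f1 = F1, support = support,
                          ovr_accuracy = (tp + tn) / total)
  w <- support / total
  rep <- list(confusion = M, per_class = per_class,
              precision = mean(P), recall = mean(R), f1 = mean(F1),
              weighted_precision = sum(w * P), weighted_recall = sum(w * R),
              weighted_f1 = sum(w * F1),
              accuracy = sum(tp) / total)
  if (!is.null(groups)) {
    if (length(groups) != K) stop("groups must map every class")
    if (any(is.na(groups))) stop("unmapped class in groups")
    rep$per_group <- per_group_metrics(M, groups)
  }
  structure(rep, class = "metrics_report")
}

#' Per-group (per-crop) macro metrics
#'
#' Averages the one-vs-rest per-class metrics over the member classes of
#' each group — macro within group.
#'
#' @param M `K x K` confusion matrix.
#' @param groups vector of length `K` assigning each class to a group.
#' @return data frame with one row per group: n_classes, precision, recall,
#'   f1, accuracy (macro one-vs-rest within the group).
#' @export
per_group_metrics <- function(M, groups) {
  K <- nrow(M)
  if (length(groups) != K || any(is.na(groups))) stop("groups must map every class")
  base <- suppressWarnings(metrics_from_confusion(M))
  pc <- base$per_class
  out <- do.call(rbind, lapply(split(seq_len(K), groups), function(cls) {
    data.frame(n_classes = length(cls),
               precision = mean(pc$precision[cls]),
               recall = mean(pc$recall[cls]),
               f1 = mean(pc$f1[cls]),
               accuracy = mean(pc$ovr_accuracy[cls]))
  }))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[, c("group", "n_classes", "precision", "recall", "f1", "accuracy")]
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f (%d classes, n = %d)\n",
              x$accuracy, x$precision, x$recall, x$f1,
              nrow(x$confusion), sum(x$confusion)))
  invisible(x)
}
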