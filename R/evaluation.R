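#' One-vs-rest confusion counts
#'
#' Counts TP/FP/TN/FN for one grade treated as positive against all others.
#'
#' @param y_true,y_pred Equal-length grade vectors (labels 0-4).
#' @param positive_class The grade treated as positive.
#' @return A `confusion_counts` list (TP, FP, TN, FN, n).
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 n = length(y_true), positive_class = positive_class),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Classification metrics from confusion counts
#'
#' Sensitivity SE = TP/(TP+FN); specificity SP = TN/(TN+FP); precision
#' PR = TP/(TP+FP); F1 = 2TP/(2TP+FP+FN); accuracy ACC =
#' (TP+TN)/(TP+FP+TN+FN); Matthews correlation coefficient MCC =
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric with a
#' zero denominator is reported as 0 with its `undefined` flag set, so
#' cross-validation aggregation never aborts.
#'
#' @param counts A [confusion_counts()] object.
#' @return A one-row tibble: SE, SP, PR, F1, ACC, MCC plus an `undefined`
#'   character column naming flagged metrics ("" if none).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  se <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  pr <- safe_div(tp, tp + fp)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  acc <- safe_div(tp + tn, tp + fp + tn + fn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  vals <- c(SE = se, SP = sp, PR = pr, F1 = f1, ACC = acc, MCC = mcc)
  undef <- names(vals)[is.na(vals)]
  vals[is.na(vals)] <- 0
  tibble::tibble(SE = vals[["SE"]], SP = vals[["SP"]], PR = vals[["PR"]],
                 F1 = vals[["F1"]], ACC = vals[["ACC"]], MCC = vals[["MCC"]],
                 undefined = paste(undef, collapse = ","))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC traced over the distinct score
#' thresholds; with ties this equals the rank-based (Mann-Whitney)
#' statistic (concordant pairs + half ties) / (n_pos * n_neg).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  tpr <- c(0, tp[keep] / npos)
  fpr <- c(0, fp[keep] / nneg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Per-class and macro-averaged metric report
#'
#' One-vs-rest metrics for every grade plus the unweighted (macro) average
#' row, with per-class AUC when a score matrix is supplied.
#'
#' @param y_true,y_pred Grade vectors.
#' @param scores Optional n x K probability/score matrix (columns = grades
#'   0..K-1) for AUC.
#' @param classes Class labels (default 0-4).
#' @return Tibble with one row per class and a final "macro" row.
#' @export
metric_report <- function(y_true, y_pred, scores = NULL, classes = 0:4) {
  rows <- lapply(classes, function(cl) {
    m <- classification_metrics(confusion_counts(y_true, y_pred, cl))
    m$class <- as.character(cl)
    m$AUC <- if (!is.null(scores) && length(unique(y_true == cl)) == 2)
      roc_auc(scores[, which(classes == cl)], y_true == cl) else NA_real_
    m
  })
  per <- dplyr::bind_rows(rows)
  macro <- dplyr::summarise(per, dplyr::across(c("SE", "SP", "PR", "F1",
                                                 "ACC", "MCC", "AUC"),
                                               ~ mean(.x, na.rm = TRUE)))
  macro$class <- "macro"
  macro$undefined <- ""
  dplyr::bind_rows(per, macro)[, c("class", "SE", "SP", "PR", "F1", "ACC",
                                   "MCC", "AUC", "undefined")]
}

#' Stratified cross-validation folds
#'
#' Seeded stratified fold assignment: folds are pairwise disjoint, cover the
#' data, and per-class sizes differ by at most one item.
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) per item.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (min(table(labels)) < k)
    stop("k exceeds the size of the smallest class", call. = FALSE)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  folds
}

#' k-fold cross-validation of a grading pipeline
#'
#' Stratified seeded folds; for each fold the pipeline factory is called on
#' the training rows and must return a predictor `function(manifest)` giving
#' a tibble/list with `grade` (and optionally `scores`, an n x 5 matrix).
#' Per-fold macro metrics are collected and averaged (unweighted).
#'
#' @param manifest Dataset manifest tibble with a `grade` column.
#' @param k Number of folds (10 in the study design).
#' @param pipeline_factory `function(train_manifest)` returning a predictor.
#' @param seed Integer seed.
#' @return A `fundushr_cv` object: `folds` (per-fold macro metric tibble),
#'   `average` (unweighted mean row), `fold_ids`.
#' @export
kfold_cv <- function(manifest, k = 10L, pipeline_factory, seed = 1L) {
  fold_ids <- make_folds(manifest$grade, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train <- manifest[fold_ids != f, , drop = FALSE]
    test <- manifest[fold_ids == f, , drop = FALSE]
    predictor <- pipeline_factory(train)
    out <- predictor(test)
    scores <- if (is.list(out) && !is.data.frame(out)) out$scores else NULL
    pred <- if (is.list(out) && !is.data.frame(out)) out$grade else out$grade
    rep <- metric_report(test$grade, pred, scores)
    rep$fold <- f
    reports[[f]] <- rep
  }
  per_fold <- dplyr::bind_rows(reports)
  macro <- dplyr::filter(per_fold, .data$class == "macro")
  avg <- dplyr::summarise(macro, dplyr::across(c("SE", "SP", "PR", "F1",
                                                 "ACC", "MCC", "AUC"),
                                               ~ mean(.x, na.rm = TRUE)))
  structure(list(folds = per_fold, average = avg, fold_ids = fold_ids, k = k),
            class = "fundushr_cv")
}

#' @export
print.fundushr_cv <- function(x, ...) {
  cat(sprintf("<fundushr_cv> %d folds; macro-average:\n", x$k))
  print(x$average)
  invisible(x)
}
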