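# independent brute-force implementations used as oracles
brute_metrics <- function(tp, fp, tn, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(SE = div(tp, tp + fn), SP = div(tn, tn + fp), PR = div(tp, tp + fp),
    F1 = div(2 * tp, 2 * tp + fp + fn), ACC = div(tp + tn, tp + fp + tn + fn),
    MCC = {
      d <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (d == 0) NA_real_ else (tp * tn - fp * fn) / d
    })
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

test_that("confusion counts partition the sample", {
  y <- c(0, 0, 1, 2, 3, 4, 4, 1, 2, 0)
  p <- c(0, 1, 1, 2, 4, 4, 4, 0, 2, 0)
  for (cl in 0:4) {
    cc <- confusion_counts(y, p, cl)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, length(y))
  }
  cc <- confusion_counts(y, y, 2)
  expect_equal(cc$FP, 0); expect_equal(cc$FN, 0)
  # all predicted positive, half the truths positive
  y2 <- rep(c(1, 0), each = 5)
  cc2 <- confusion_counts(y2, rep(1, 10), 1)
  expect_equal(cc2$TN, 0); expect_equal(cc2$FP, 5)
  expect_equal(cc2$TP, 5); expect_equal(cc2$FN, 0)
  expect_error(confusion_counts(1:3, 1:4, 1), "equal length")
})

test_that("metrics reproduce the hand-worked confusion case", {
  m <- classification_metrics(
    structure(list(TP = 9, FP = 2, TN = 8, FN = 1, n = 20,
                   positive_class = 1), class = "confusion_counts"))
  expect_equal(m$SE, 0.9)
  expect_equal(m$SP, 0.8)
  expect_equal(m$PR, 9 / 11, tolerance = 1e-12)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$F1, 18 / 21, tolerance = 1e-12)
  expect_equal(m$MCC, 70 / sqrt(9900), tolerance = 1e-12)
  perfect <- classification_metrics(
    structure(list(TP = 10, FP = 0, TN = 10, FN = 0, n = 20,
                   positive_class = 1), class = "confusion_counts"))
  expect_equal(unlist(perfect[, c("SE", "SP", "PR", "F1", "ACC", "MCC")]),
               c(SE = 1, SP = 1, PR = 1, F1 = 1, ACC = 1, MCC = 1))
})

test_that("metrics agree with the brute-force oracle on random count tuples", {
  set.seed(31)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    tn <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp + tn + fn == 0) next
    m <- classification_metrics(
      structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                     n = tp + fp + tn + fn, positive_class = 1),
                class = "confusion_counts"))
    o <- brute_metrics(tp, fp, tn, fn)
    flagged <- strsplit(m$undefined, ",")[[1]]
    for (nm in names(o)) {
      if (nm %in% flagged) {
        expect_true(is.na(o[[nm]]))
        expect_equal(m[[nm]], 0)
      } else {
        expect_equal(m[[nm]], o[[nm]], tolerance = 1e-12)
      }
    }
  }
})

test_that("metric identities hold where defined", {
  set.seed(32)
  for (i in 1:200) {
    tp <- sample(1:40, 1); fp <- sample(0:40, 1)
    tn <- sample(1:40, 1); fn <- sample(0:40, 1)
    m <- classification_metrics(
      structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                     n = tp + fp + tn + fn, positive_class = 1),
                class = "confusion_counts"))
    # F1 = harmonic mean of PR and SE
    expect_equal(m$F1, 2 * m$PR * m$SE / (m$PR + m$SE), tolerance = 1e-12)
    expect_true(m$MCC >= -1 && m$MCC <= 1)
    if (fp == 0 && fn == 0) expect_equal(m$MCC, 1)
  }
})

test_that("ROC AUC handles separation, ties and random scores", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  set.seed(33)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    sc <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), brute_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("macro report averages per-class rows", {
  set.seed(34)
  y <- sample(0:4, 60, replace = TRUE)
  p <- ifelse(runif(60) < 0.7, y, sample(0:4, 60, replace = TRUE))
  sc <- matrix(runif(300), 60, 5)
  sc <- sc / rowSums(sc)
  rep <- metric_report(y, p, sc)
  expect_equal(nrow(rep), 6)
  per <- rep[rep$class != "macro", ]
  macro <- rep[rep$class == "macro", ]
  expect_equal(macro$SE, mean(per$SE), tolerance = 1e-12)
  expect_equal(macro$MCC, mean(per$MCC), tolerance = 1e-12)
})

test_that("stratified folds are disjoint, covering and balanced", {
  labels <- rep(0:4, times = c(40, 20, 20, 20, 40))
  folds <- make_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), length(labels))
  sizes <- table(folds)
  expect_true(all(sizes == 14))
  for (cl in 0:4) {
    per_class <- table(folds[labels == cl])
    expect_lte(max(per_class) - min(per_class), 1)
  }
  expect_error(make_folds(labels, k = 1), "at least 2")
  expect_error(make_folds(rep(0:4, 2), k = 10), "smallest class")
})

test_that("cross-validation aggregates per-fold reports", {
  set.seed(35)
  manifest <- tibble::tibble(grade = rep(0:4, times = 8),
                             feature = rnorm(40) + rep(0:4, times = 8))
  factory <- function(train) {
    centers <- tapply(train$feature, train$grade, mean)
    function(test) {
      g <- as.integer(names(centers))[
        apply(abs(outer(test$feature, centers, `-`)), 1, which.min)]
      list(grade = g, scores = NULL)
    }
  }
  cv <- kfold_cv(manifest, k = 4, factory, seed = 9)
  expect_s3_class(cv, "fundushr_cv")
  macro <- cv$folds[cv$folds$class == "macro", ]
  expect_equal(nrow(macro), 4)
  for (nm in c("SE", "SP", "ACC", "MCC")) {
    expect_gte(cv$average[[nm]], min(macro[[nm]]))
    expect_lte(cv$average[[nm]], max(macro[[nm]]))
  }
  expect_equal(cv$average$SE, mean(macro$SE), tolerance = 1e-12)
})
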