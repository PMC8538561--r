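#' Tidy a trained grading classifier
#'
#' Returns the per-epoch training curves (epoch, train_loss, val_loss,
#' train_acc, val_acc) as a tibble.
#'
#' @param x An `hr_classifier` from [train_classifier()].
#' @param ... Unused.
#' @return A tibble with one row per epoch.
#' @export
tidy.hr_classifier <- function(x, ...) x$curves

#' @rdname tidy.hr_classifier
#' @export
glance.hr_classifier <- function(x, ...) {
  last <- x$curves[nrow(x$curves), ]
  tibble::tibble(epochs = nrow(x$curves),
                 best_val_acc = x$best_val_acc,
                 final_train_loss = last$train_loss,
                 final_val_loss = last$val_loss,
                 final_val_acc = last$val_acc,
                 n_train = length(x$train_indices),
                 n_val = length(x$val_indices))
}

#' Tidy cross-validation results
#'
#' @param x A `fundushr_cv` from [kfold_cv()].
#' @param ... Unused.
#' @return `tidy()`: per-fold, per-class metric tibble; `glance()`: one row
#'   with the macro-averaged metrics over folds.
#' @export
tidy.fundushr_cv <- function(x, ...) x$folds

#' @rdname tidy.fundushr_cv
#' @export
glance.fundushr_cv <- function(x, ...) {
  dplyr::mutate(x$average, k = x$k, .before = 1)
}

#' Plot training curves
#'
#' Loss and accuracy of the training and validation splits over epochs.
#'
#' @param model An `hr_classifier`.
#' @return A ggplot object.
#' @export
plot_training_curves <- function(model) {
  stopifnot(inherits(model, "hr_classifier"))
  cv <- model$curves
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = cv$epoch, value = cv$train_loss,
                   metric = "loss", split = "train"),
    tibble::tibble(epoch = cv$epoch, value = cv$val_loss,
                   metric = "loss", split = "validation"),
    tibble::tibble(epoch = cv$epoch, value = cv$train_acc,
                   metric = "accuracy", split = "train"),
    tibble::tibble(epoch = cv$epoch, value = cv$val_acc,
                   metric = "accuracy", split = "validation"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param y_true Grade vector.
#' @param scores n x K score matrix (columns = grades 0..K-1).
#' @param classes Class labels.
#' @return A ggplot object.
#' @export
plot_roc <- function(y_true, scores, classes = 0:4) {
  pts <- lapply(classes, function(cl) {
    lab <- as.integer(y_true == cl)
    if (length(unique(lab)) < 2) return(NULL)
    sc <- scores[, which(classes == cl)]
    ord <- order(sc, decreasing = TRUE)
    tp <- cumsum(lab[ord]); fp <- cumsum(1 - lab[ord])
    tibble::tibble(fpr = c(0, fp / max(fp)), tpr = c(0, tp / max(tp)),
                   class = paste0("grade ", cl))
  })
  df <- dplyr::bind_rows(pts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a phantom, mask or label map
#'
#' Renders an image array or an integer label matrix (colour-coded) with
#' ggplot2; handy in the vignette and for eyeballing phantoms.
#'
#' @param x H x W x 3 array in [0, 1] or an integer H x W matrix.
#' @return A ggplot object.
#' @export
plot_image <- function(x) {
  if (is.matrix(x)) {
    df <- tibble::tibble(row = rep(seq_len(nrow(x)), ncol(x)),
                         col = rep(seq_len(ncol(x)), each = nrow(x)),
                         value = factor(as.vector(x)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::theme_void()
  } else {
    assert_rgb_image(x)
    df <- tibble::tibble(row = rep(seq_len(dim(x)[1]), dim(x)[2]),
                         col = rep(seq_len(dim(x)[2]), each = dim(x)[1]),
                         fill = grDevices::rgb(as.vector(x[, , 1]),
                                               as.vector(x[, , 2]),
                                               as.vector(x[, , 3])))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::theme_void()
  }
}
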