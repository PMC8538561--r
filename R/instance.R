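#' Otsu threshold of a gray-level image
#'
#' Exhaustive maximisation of the between-class variance over the 256-bin
#' histogram of the [0, 1]-scaled image. Returns the threshold (bin boundary
#' on the [0, 1] scale) and the binary map `gray > threshold`.
#'
#' @param gray Numeric matrix with values in [0, 1].
#' @return List with `threshold` (scalar, `NA` for a constant image) and
#'   `binary` (logical matrix).
#' @export
otsu_threshold <- function(gray) {
  if (!is.matrix(gray) || length(gray) == 0)
    stop("`gray` must be a non-empty numeric matrix", call. = FALSE)
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 1)
    stop("gray values must lie in [0, 1]", call. = FALSE)
  lev <- as.integer(round(gray * 255))
  counts <- tabulate(lev + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    warning("constant image: no Otsu threshold exists, returning empty mask")
    return(list(threshold = NA_real_,
                binary = matrix(FALSE, nrow(gray), ncol(gray))))
  }
  n <- length(lev)
  p <- counts / n
  omega <- cumsum(p)                     # class-0 mass for cut after bin t
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  # between-class variance for cuts t = 0..254 (class 0: levels <= t)
  w0 <- omega[1:255]
  sb <- (mu_t * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  t_star <- which.max(sb) - 1L           # first argmax
  thr <- (t_star + 0.5) / 255
  list(threshold = thr, binary = gray > thr)
}

#' Watershed post-processing configuration
#'
#' @param open_iterations Binary-opening iterations (3 x 3 box) that remove
#'   speckle noise before anything else.
#' @param dilate_iterations Dilation iterations defining the sure-background
#'   envelope.
#' @param fg_fraction Sure-foreground cut: distance > fg_fraction x
#'   max(distance).
#' @param marker_peak_fraction Watershed markers are seeded at
#'   distance-transform peaks, i.e. pixels within this fraction of their
#'   foreground component's peak height. Must exceed `fg_fraction`.
#' @return A `watershed_config` list.
#' @export
watershed_config <- function(open_iterations = 2L, dilate_iterations = 3L,
                             fg_fraction = 0.2, marker_peak_fraction = 0.9) {
  stopifnot(fg_fraction > 0, fg_fraction < 1,
            marker_peak_fraction > fg_fraction, marker_peak_fraction <= 1)
  structure(list(open_iterations = as.integer(open_iterations),
                 dilate_iterations = as.integer(dilate_iterations),
                 fg_fraction = fg_fraction,
                 marker_peak_fraction = marker_peak_fraction),
            class = "watershed_config")
}

#' Split a binary lesion mask into instances by marker-controlled watershed
#'
#' The classic chain: (1) binary opening removes noise; (2) dilation of the
#' opened mask gives the sure-background envelope; (3) the Euclidean distance
#' transform with the 0.2 x max cut gives the sure foreground; (4) their
#' difference is the unknown region; (5) markers are seeded at the distance
#' peaks of each sure-foreground component (within `marker_peak_fraction` of
#' the component's peak height — seeding at peaks rather than at whole
#' sure-foreground components is what lets deeply overlapping lesions split);
#' (6) Meyer's flooding over the negated distance transform grows the
#' markers, ridge pixels where two floods meet go to background, and labels
#' are intersected with the opened mask and relabelled 1..n (4-connected).
#'
#' @param binary Logical/0-1 matrix (foreground = lesion).
#' @param cfg A [watershed_config()].
#' @return An `instance_labels` object: `labels` (H x W integer matrix,
#'   0 = background, 1..n = instances) and `n_instances`.
#' @export
watershed_postprocess <- function(binary, cfg = watershed_config()) {
  if (!is.matrix(binary)) stop("`binary` must be a matrix", call. = FALSE)
  b <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  empty <- function() structure(list(labels = matrix(0L, nrow(b), ncol(b)),
                                     n_instances = 0L),
                                class = "instance_labels")
  if (sum(b) == 0) return(empty())
  kern <- EBImage::makeBrush(3L, shape = "box")
  opened <- b
  for (i in seq_len(cfg$open_iterations)) opened <- EBImage::erode(opened, kern)
  for (i in seq_len(cfg$open_iterations)) opened <- EBImage::dilate(opened, kern)
  if (sum(opened) == 0) return(empty())
  sure_bg_env <- opened
  for (i in seq_len(cfg$dilate_iterations))
    sure_bg_env <- EBImage::dilate(sure_bg_env, kern)
  dist <- EBImage::distmap(opened)
  sure_fg <- dist > cfg$fg_fraction * max(dist)
  unknown <- sure_bg_env > 0 & !sure_fg

  # markers: distance peaks within each sure-foreground component
  fg_comp <- label_components_4(matrix(as.integer(sure_fg), nrow(b)))
  peak <- matrix(FALSE, nrow(b), ncol(b))
  for (lab in seq_len(max(fg_comp))) {
    sel <- fg_comp == lab
    peak[sel] <- dist[sel] >= cfg$marker_peak_fraction * max(dist[sel])
  }
  markers <- label_components_4(matrix(as.integer(peak), nrow(b)))
  n_mark <- max(markers)
  if (n_mark == 0) return(empty())
  # background seed outside the sure-background envelope, shifted labels
  markers[markers > 0] <- markers[markers > 0] + 1L
  markers[sure_bg_env == 0] <- 1L
  markers[unknown] <- 0L

  ws <- marker_watershed(-dist, markers)
  inst <- ws
  inst[inst <= 1L] <- 0L
  inst[opened == 0] <- 0L
  labels <- label_components_4(matrix(as.integer(inst > 0), nrow(b)))
  structure(list(labels = labels, n_instances = max(labels)),
            class = "instance_labels")
}

#' @export
print.instance_labels <- function(x, ...) {
  cat(sprintf("<instance_labels> %d x %d, %d instance(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_instances))
  invisible(x)
}

#' Instance segmentation of a fundus image
#'
#' Resizes the image to the mask network's working resolution, predicts the
#' lesion probability mask, binarises it with Otsu's threshold, splits
#' touching lesions with the marker-controlled watershed chain, and maps the
#' labels back to the source resolution (nearest neighbour).
#'
#' @param image H x W x C array in [0, 1].
#' @param net A trained [build_unet()].
#' @param cfg A [watershed_config()].
#' @return An `instance_labels` object at the source resolution.
#' @export
segment_instances <- function(image, net, cfg = watershed_config()) {
  stopifnot(inherits(net, "unet"))
  d0 <- dim(image)[1:2]
  sz <- net$input_size
  im <- if (!all(d0 == sz)) resize_image(image, sz, sz) else image
  prob <- predict_prob_mask(net, im)  # working resolution
  ot <- withCallingHandlers(
    otsu_threshold(clip01(prob)),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(ot$threshold) || !any(ot$binary)) {
    return(structure(list(labels = matrix(0L, d0[1], d0[2]),
                          n_instances = 0L), class = "instance_labels"))
  }
  res <- watershed_postprocess(ot$binary, cfg)
  if (!all(dim(res$labels) == d0)) {
    lab <- resize_image(res$labels, d0[1], d0[2], "nearest")
    res$labels <- matrix(as.integer(lab), d0[1], d0[2])
    res$n_instances <- length(setdiff(unique(as.vector(res$labels)), 0L))
  }
  res
}
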