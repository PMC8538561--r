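#' Image array helpers
#'
#' Images are plain numeric arrays of shape height x width x 3 with channel
#' values in [0, 1] (sRGB companded); label masks are integer matrices of the
#' same height x width. PNG is the on-disk format: 8-bit inputs are divided by
#' 255 on read and rounded half-up on write.
#'
#' @name image-io
NULL

assert_rgb_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be a height x width x 3 array", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop(sprintf("`%s` must have all channel values in [0, 1]", arg),
         call. = FALSE)
  invisible(img)
}

#' Read an image or label mask from PNG
#'
#' @param path Path to a PNG file.
#' @return `read_image()` returns an H x W x 3 array in [0, 1]; grayscale
#'   files are replicated across the three channels. `read_mask()` returns an
#'   integer label matrix (8-bit gray level = label index).
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (!is.matrix(px)) px <- px[, , 1L]
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

#' Write an image or label mask to PNG
#'
#' @param img H x W x 3 array in [0, 1], or an integer label matrix for
#'   `write_mask()` (stored as 8-bit gray levels).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  png::writePNG(floor(img * 255 + 0.5) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(img, path) {
  if (max(img) > 255) stop("mask labels must fit in 8 bits", call. = FALSE)
  png::writePNG(matrix(as.integer(img), nrow(img), ncol(img)) / 255, path)
  invisible(path)
}

#' Resize an image or mask
#'
#' Bilinear interpolation for continuous images, nearest neighbour for label
#' masks (labels must stay categorical).
#'
#' @param img H x W x C array or H x W matrix.
#' @param height,width Target size.
#' @param method "bilinear" or "nearest".
#' @return Resized array/matrix.
#' @export
resize_image <- function(img, height, width, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (method == "nearest") return(resize_nearest(img, height, width))
  if (is.matrix(img))
    return(EBImage::resize(img, w = height, h = width))
  out <- array(0, c(height, width, dim(img)[3]))
  for (c in seq_len(dim(img)[3]))
    out[, , c] <- EBImage::resize(img[, , c], w = height, h = width)
  out
}

resize_nearest <- function(img, height, width) {
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  ri <- pmin(h, pmax(1L, as.integer(ceiling((seq_len(height) - 0.5) * h / height))))
  ci <- pmin(w, pmax(1L, as.integer(ceiling((seq_len(width) - 0.5) * w / width))))
  if (is.matrix(img)) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

#' Flip or rotate an image or mask
#'
#' `flip_image()` reverses rows ("vertical") or columns ("horizontal").
#' `rotate_image()` rotates counter-clockwise about the image centre; 90, 180
#' and 270 degrees are exact array permutations, other angles are resampled
#' (bilinear for images, nearest for masks) with out-of-frame pixels set to
#' `fill`.
#'
#' @param img H x W x C array or H x W matrix.
#' @param direction "horizontal" or "vertical".
#' @param degrees Rotation angle, counter-clockwise.
#' @param interp "bilinear" or "nearest".
#' @param fill Fill value for pixels sampled outside the frame.
#' @return Transformed array/matrix of the same shape.
#' @export
flip_image <- function(img, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  if (is.matrix(img)) {
    if (direction == "horizontal") img[, rev(seq_len(ncol(img))), drop = FALSE]
    else img[rev(seq_len(nrow(img))), , drop = FALSE]
  } else {
    if (direction == "horizontal") img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    else img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  }
}

#' @rdname flip_image
#' @export
rotate_image <- function(img, degrees, interp = c("bilinear", "nearest"),
                         fill = 0) {
  interp <- match.arg(interp)
  deg <- degrees %% 360
  rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  apply_planes <- function(f) {
    if (is.matrix(img)) return(f(img))
    planes <- lapply(seq_len(dim(img)[3]), function(c) f(img[, , c]))
    array(unlist(planes), c(dim(planes[[1]]), dim(img)[3]))
  }
  if (deg == 0) return(img)
  if (deg %in% c(90, 180, 270)) {
    f <- switch(as.character(deg),
                "90" = rot90,
                "180" = function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
                "270" = function(m) rot90(rot90(rot90(m))))
    return(apply_planes(f))
  }
  h <- if (is.matrix(img)) nrow(img) else dim(img)[1]
  w <- if (is.matrix(img)) ncol(img) else dim(img)[2]
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # inverse map: target (y, x) -> source coordinates (rotate by -theta)
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  sy <- cy - sin(th) * xx + cos(th) * yy
  sx <- cx + cos(th) * xx + sin(th) * yy
  sample_plane <- function(m) {
    if (interp == "nearest") {
      ry <- round(sy); rx <- round(sx)
      ok <- ry >= 1 & ry <= h & rx >= 1 & rx <= w
      out <- matrix(fill, h, w)
      out[ok] <- m[cbind(ry[ok], rx[ok])]
      out
    } else {
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      get <- function(yi, xi) {
        ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
        v <- matrix(fill, h, w)
        v[ok] <- m[cbind(yi[ok], xi[ok])]
        v
      }
      get(y0, x0) * (1 - fy) * (1 - fx) + get(y0 + 1, x0) * fy * (1 - fx) +
        get(y0, x0 + 1) * (1 - fy) * fx + get(y0 + 1, x0 + 1) * fy * fx
    }
  }
  apply_planes(sample_plane)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)  # x first: pmin/pmax keep attributes of arg 1

#' Gaussian blur of a single plane
#'
#' Replicated-boundary Gaussian filtering (used by the contrast-boost step).
#'
#' @param m Numeric matrix.
#' @param sigma Blur scale in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma > 0)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  limit <- min(dim(m))
  if (size > limit) size <- limit - (1L - limit %% 2L)  # largest odd <= dims
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  EBImage::filter2(m, brush, boundary = "replicate")
}

# deterministic local RNG: run fn under a seed without touching global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
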