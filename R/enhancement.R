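#' Fundus enhancement configuration
#'
#' Controls the perceptual enhancement pipeline: sRGB -> JCh, adaptive gamma
#' correction of the lightness plane, luminance-gain relighting (which
#' preserves chromaticity by scaling r, g, b by a common per-pixel gain), and
#' a final blur-subtraction contrast boost.
#'
#' @param agc_enabled Apply CDF-weighted adaptive gamma correction to J?
#' @param gain_enabled Apply the enhancement through a per-pixel luminance
#'   gain map (ratio of enhanced to original luminance)? When `FALSE` the
#'   recombined JCh image is returned directly.
#' @param graham_enabled Apply the blur-subtraction contrast boost?
#' @param graham_alpha,graham_beta,graham_gamma Contrast-boost coefficients
#'   of `alpha * I + beta * blur(I, sigma) + gamma` on the [0, 1] scale.
#' @param graham_sigma Blur scale in pixels; `NULL` means image_width / 30.
#' @param luminance_norm "euclidean" for sqrt(r^2 + g^2 + b^2), "sumsq" for
#'   the plain sum of squares.
#' @param viewing_conditions A [viewing_conditions()] object.
#' @return An `enhancement_config` list.
#' @export
enhancement_config <- function(agc_enabled = TRUE,
                               gain_enabled = TRUE,
                               graham_enabled = TRUE,
                               graham_alpha = 4,
                               graham_beta = -4,
                               graham_gamma = 0.5,
                               graham_sigma = NULL,
                               luminance_norm = c("euclidean", "sumsq"),
                               viewing_conditions = fundushr::viewing_conditions()) {
  if (!is.null(graham_sigma) && graham_sigma <= 0)
    stop("graham_sigma must be positive", call. = FALSE)
  structure(list(agc_enabled = isTRUE(agc_enabled),
                 gain_enabled = isTRUE(gain_enabled),
                 graham_enabled = isTRUE(graham_enabled),
                 graham_alpha = graham_alpha, graham_beta = graham_beta,
                 graham_gamma = graham_gamma, graham_sigma = graham_sigma,
                 luminance_norm = match.arg(luminance_norm),
                 viewing_conditions = viewing_conditions),
            class = "enhancement_config")
}

#' Per-pixel luminance intensity
#'
#' The Euclidean norm of the (r, g, b) vector (or, optionally, the plain sum
#' of squared channels) used as the denominator of the luminance gain map.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param norm "euclidean" (default) or "sumsq".
#' @return H x W matrix of non-negative luminance values.
#' @export
pixel_luminance <- function(img, norm = c("euclidean", "sumsq")) {
  norm <- match.arg(norm)
  assert_rgb_image(img)
  ss <- img[, , 1]^2 + img[, , 2]^2 + img[, , 3]^2
  if (norm == "euclidean") sqrt(ss) else ss
}

#' Apply a per-pixel luminance gain map
#'
#' Each channel is multiplied by the same per-pixel gain, so channel ratios
#' (chromaticity) are preserved wherever the result is not clipped to [0, 1].
#'
#' @param img H x W x 3 array in [0, 1].
#' @param lg H x W matrix of non-negative finite gains.
#' @return Relit H x W x 3 array, clipped to [0, 1].
#' @export
apply_luminance_gain <- function(img, lg) {
  assert_rgb_image(img)
  if (!is.matrix(lg) || !all(dim(lg) == dim(img)[1:2]))
    stop("`lg` must be an H x W matrix matching the image", call. = FALSE)
  if (anyNA(lg) || any(!is.finite(lg)) || min(lg) < 0)
    stop("luminance gains must be finite and non-negative", call. = FALSE)
  out <- img * as.vector(lg)  # recycles the gain over the 3 channels
  clip01(out)
}

#' Adaptive gamma correction of an intensity plane
#'
#' CDF-weighted gamma mapping on a 256-level quantisation of the plane:
#' `T(l) = l_max * (l / l_max)^(1 - cdf(l))`, where `cdf` is the cumulative
#' distribution function of the normalised intensity histogram. Dim levels
#' (low CDF) get a strong brightness boost, the brightest occupied level maps
#' to itself, and the mapping is monotone non-decreasing, so intensity order
#' is preserved.
#'
#' @param plane H x W matrix (or vector) with values in [0, 1].
#' @return Corrected plane of the same shape, in [0, 1].
#' @export
adaptive_gamma_correct <- function(plane) {
  if (length(plane) == 0) stop("empty intensity plane", call. = FALSE)
  if (anyNA(plane) || min(plane) < 0 || max(plane) > 1)
    stop("plane values must lie in [0, 1]", call. = FALSE)
  lev <- as.integer(round(plane * 255))
  counts <- tabulate(lev + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(lev)
  lmax <- max(lev)
  if (lmax == 0L) return(plane)
  lut <- numeric(256)
  l <- 0:255
  lut <- lmax * (l / lmax)^(1 - cdf)
  lut[1] <- ifelse(cdf[1] >= 1, lmax, 0)  # 0^0 convention at level 0
  out <- lut[lev + 1L] / 255
  out <- clip01(out)
  if (is.matrix(plane)) matrix(out, nrow(plane), ncol(plane)) else out
}

#' Blur-subtraction contrast boost
#'
#' `clip(alpha * I + beta * blur(I, sigma) + gamma)` applied per channel: the
#' local mean is subtracted and the residual amplified around mid-grey,
#' flattening smooth illumination while amplifying lesion-scale detail.
#'
#' @param img H x W x 3 array in [0, 1].
#' @param cfg An [enhancement_config()].
#' @return Contrast-boosted image in [0, 1].
#' @export
graham_contrast <- function(img, cfg = enhancement_config()) {
  assert_rgb_image(img)
  sigma <- cfg$graham_sigma
  if (is.null(sigma)) sigma <- dim(img)[2] / 30
  stopifnot(sigma > 0)
  out <- img
  for (c in 1:3) {
    out[, , c] <- cfg$graham_alpha * img[, , c] +
      cfg$graham_beta * gaussian_blur(img[, , c], sigma) +
      cfg$graham_gamma
  }
  clip01(out)
}

#' Enhance a fundus image in the JCh appearance space
#'
#' The full preprocessing pipeline: the image is taken to CIECAM02 JCh; the
#' lightness plane J is normalised to [0, 1] and adaptive-gamma corrected;
#' the corrected J* is recombined with the original chroma and hue and
#' inverted back to sRGB; the ratio of the relit to the original luminance
#' forms a per-pixel gain map applied to the original image (preserving
#' chromaticity); finally the blur-subtraction contrast boost is applied.
#' Each step can be disabled in the configuration; with every step disabled
#' the image passes only through the forward/inverse colour transform
#' (identity to round-trip tolerance).
#'
#' @param img H x W x 3 sRGB array in [0, 1].
#' @param cfg An [enhancement_config()].
#' @return Enhanced image of identical shape, values in [0, 1], with
#'   attribute `"clipped"` (gain-stage clip count).
#' @export
enhance_fundus <- function(img, cfg = enhancement_config()) {
  assert_rgb_image(img)
  vc <- cfg$viewing_conditions
  jch <- srgb_to_jch(img, vc)
  d <- dim(img)
  J <- jch[, , 1]
  if (cfg$agc_enabled) {
    Jn <- clip01(J / 100)
    J_star <- adaptive_gamma_correct(Jn) * 100
  } else {
    J_star <- J
  }
  jch2 <- jch
  jch2[, , 1] <- J_star
  relit <- jch_to_srgb(jch2, vc)
  n_clip <- attr(relit, "clipped")
  relit <- clip01(relit)
  if (cfg$gain_enabled) {
    lum0 <- pixel_luminance(img, cfg$luminance_norm)
    lum1 <- pixel_luminance(relit, cfg$luminance_norm)
    lg <- ifelse(lum0 > 1e-9, lum1 / lum0, 0)
    out <- apply_luminance_gain(img, lg)
  } else {
    out <- relit
  }
  if (cfg$graham_enabled) out <- graham_contrast(out, cfg)
  attr(out, "clipped") <- n_clip
  out
}
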