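#' CIECAM02 colour appearance transforms
#'
#' Forward and inverse transforms between sRGB and the CIECAM02 lightness,
#' chroma and hue correlates (J, C, h) used by the fundus enhancement stage.
#' The appearance model follows CIE 159:2004: CAT02 chromatic adaptation,
#' Hunt-Pointer-Estevez cone space, post-adaptation compression, and the
#' J/C/h correlates under stated viewing conditions.
#'
#' @name ciecam02
NULL

# sRGB (IEC 61966-2-1) <-> XYZ, D65, 2-degree observer
.M_RGB2XYZ <- matrix(c(0.41239080, 0.35758434, 0.18048079,
                       0.21263901, 0.71516868, 0.07219232,
                       0.01933082, 0.11919478, 0.95053215),
                     3, 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)

.M_CAT02 <- matrix(c(0.7328, 0.4296, -0.1624,
                     -0.7036, 1.6975, 0.0061,
                     0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
.M_HPE <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0, 0, 1), 3, 3, byrow = TRUE)
.M_HPE_CAT02INV <- .M_HPE %*% solve(.M_CAT02)
.M_CAT02_HPEINV <- .M_CAT02 %*% solve(.M_HPE)

.SURROUNDS <- list(average = c(F = 1.0, c = 0.69, Nc = 1.0),
                   dim = c(F = 0.9, c = 0.59, Nc = 0.9),
                   dark = c(F = 0.8, c = 0.525, Nc = 0.8))

#' Viewing conditions for the CIECAM02 model
#'
#' The defaults are the customary "average surround over a 20%
#' grey background" conditions: D65 white (as realised by the sRGB conversion
#' matrix, on the 0-100 scale), adapting luminance 63.66 cd/m2 (20% of
#' 318.31), background luminance factor Yb = 20.
#'
#' With `discount_illuminant = TRUE` (the default, appropriate when the
#' "illuminant" is the camera's own white) the degree of adaptation D is
#' forced to 1, so the reference white is exactly achromatic in JCh and
#' within-image processing of the J plane leaves grey axes grey. Set it to
#' `FALSE` to compute D from the adapting luminance as the model prescribes
#' (required to reproduce the published CIECAM02 test stimuli).
#'
#' @param white_point XYZ triple of the reference white, Y = 100 scale.
#' @param adapting_luminance Adapting field luminance LA in cd/m2 (> 0).
#' @param background_luminance_factor Yb, percent of white (0, 100].
#' @param surround One of "average", "dim", "dark".
#' @param discount_illuminant Force complete chromatic adaptation (D = 1)?
#' @return A `fundushr_vc` object.
#' @export
viewing_conditions <- function(white_point = as.numeric(.M_RGB2XYZ %*% rep(1, 3)) * 100,
                               adapting_luminance = 63.66,
                               background_luminance_factor = 20,
                               surround = c("average", "dim", "dark"),
                               discount_illuminant = TRUE) {
  surround <- match.arg(surround)
  if (adapting_luminance <= 0)
    stop("adapting_luminance must be positive", call. = FALSE)
  if (background_luminance_factor <= 0 || background_luminance_factor > 100)
    stop("background_luminance_factor must lie in (0, 100]", call. = FALSE)
  vc <- list(white_point = white_point,
             adapting_luminance = adapting_luminance,
             background_luminance_factor = background_luminance_factor,
             surround = surround,
             discount_illuminant = isTRUE(discount_illuminant))
  class(vc) <- "fundushr_vc"
  vc
}

# derived model constants for a set of viewing conditions
vc_params <- function(vc) {
  s <- .SURROUNDS[[vc$surround]]
  XYZw <- vc$white_point
  LA <- vc$adapting_luminance
  RGBw <- as.numeric(.M_CAT02 %*% XYZw)
  D <- if (isTRUE(vc$discount_illuminant)) 1 else
    min(1, max(0, s[["F"]] * (1 - (1 / 3.6) * exp((-LA - 42) / 92))))
  Dr <- D * XYZw[2] / RGBw + 1 - D
  k <- 1 / (5 * LA + 1)
  FL <- 0.2 * k^4 * (5 * LA) + 0.1 * (1 - k^4)^2 * (5 * LA)^(1 / 3)
  n <- vc$background_luminance_factor / XYZw[2]
  Nbb <- 0.725 * (1 / n)^0.2
  z <- 1.48 + sqrt(n)
  RGBwp <- as.numeric(.M_HPE_CAT02INV %*% (Dr * RGBw))
  tw <- (FL * RGBwp / 100)^0.42
  RGBwa <- 400 * tw / (tw + 27.13) + 0.1
  Aw <- (2 * RGBwa[1] + RGBwa[2] + RGBwa[3] / 20 - 0.305) * Nbb
  list(c = s[["c"]], Nc = s[["Nc"]], Dr = Dr, FL = FL, n = n,
       Nbb = Nbb, Ncb = Nbb, z = z, Aw = Aw)
}

as_pixel_matrix <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) {
    d <- dim(img)
    list(m = matrix(img, d[1] * d[2], d[3]), dim = d[1:2])
  } else if (is.matrix(img) && ncol(img) == 3L) {
    list(m = img, dim = NULL)
  } else stop("expected an H x W x 3 array or an N x 3 matrix", call. = FALSE)
}

restore_shape <- function(m, dim2) {
  if (is.null(dim2)) m else array(m, c(dim2, ncol(m)))
}

#' sRGB to XYZ tristimulus values
#'
#' Standard sRGB decompanding followed by the D65 linear-RGB to XYZ matrix.
#' The Y of sRGB white is 1; multiply by 100 before feeding CIECAM02 (done
#' internally by [srgb_to_jch()]).
#'
#' @param img H x W x 3 array (or N x 3 matrix) of sRGB values in [0, 1].
#' @return Array/matrix of the same shape holding X, Y, Z.
#' @export
srgb_to_xyz <- function(img) {
  px <- as_pixel_matrix(img)
  if (anyNA(px$m) || min(px$m) < 0 || max(px$m) > 1)
    stop("sRGB channel values must lie in [0, 1]", call. = FALSE)
  lin <- ifelse(px$m <= 0.04045, px$m / 12.92, ((px$m + 0.055) / 1.055)^2.4)
  restore_shape(lin %*% t(.M_RGB2XYZ), px$dim)
}

#' @rdname srgb_to_xyz
#' @param xyz XYZ values on the Y-of-white = 1 scale.
#' @param clip Clip out-of-gamut channels into [0, 1]? The number of clipped
#'   values is attached as attribute `"clipped"`.
#' @export
xyz_to_srgb <- function(xyz, clip = TRUE) {
  px <- as_pixel_matrix(xyz)
  lin <- px$m %*% t(.M_XYZ2RGB)
  srgb <- ifelse(lin <= 0.0031308, 12.92 * lin,
                 1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
  n_clip <- sum(srgb < 0 | srgb > 1)
  if (clip) srgb <- clip01(srgb)
  out <- restore_shape(srgb, px$dim)
  attr(out, "clipped") <- n_clip
  out
}

#' XYZ to CIECAM02 J, C, h correlates
#'
#' @param xyz H x W x 3 array or N x 3 matrix of XYZ values scaled so the
#'   white's Y is 100.
#' @param vc A [viewing_conditions()] object.
#' @return Same-shaped container with planes/columns J (lightness, 0-100),
#'   C (chroma, >= 0) and h (hue angle, [0, 360) degrees). Degenerate black
#'   pixels map to J = 0, C = 0, h = 0.
#' @export
xyz_to_jch <- function(xyz, vc = viewing_conditions()) {
  stopifnot(inherits(vc, "fundushr_vc"))
  p <- vc_params(vc)
  px <- as_pixel_matrix(xyz)
  RGBc <- sweep(px$m %*% t(.M_CAT02), 2, p$Dr, `*`)
  RGBp <- RGBc %*% t(.M_HPE_CAT02INV)
  sg <- sign(RGBp)
  tt <- (p$FL * abs(RGBp) / 100)^0.42
  RGBa <- sg * 400 * tt / (tt + 27.13) + 0.1
  a <- RGBa[, 1] - 12 * RGBa[, 2] / 11 + RGBa[, 3] / 11
  b <- (RGBa[, 1] + RGBa[, 2] - 2 * RGBa[, 3]) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  e <- (12500 / 13) * p$Nc * p$Ncb * (cos(h * pi / 180 + 2) + 3.8)
  A <- (2 * RGBa[, 1] + RGBa[, 2] + RGBa[, 3] / 20 - 0.305) * p$Nbb
  J <- ifelse(A > 1e-9, 100 * (pmax(A, 0) / p$Aw)^(p$c * p$z), 0)
  denom <- RGBa[, 1] + RGBa[, 2] + 21 * RGBa[, 3] / 20
  tmag <- e * sqrt(a^2 + b^2) / denom
  C <- ifelse(J > 0, tmag^0.9 * sqrt(J / 100) * (1.64 - 0.29^p$n)^0.73, 0)
  h[J <= 0] <- 0
  out <- cbind(J = J, C = C, h = h)
  restore_shape(out, px$dim)
}

#' @rdname xyz_to_jch
#' @param jch J, C, h container as returned by [xyz_to_jch()].
#' @export
jch_to_xyz <- function(jch, vc = viewing_conditions()) {
  stopifnot(inherits(vc, "fundushr_vc"))
  p <- vc_params(vc)
  px <- as_pixel_matrix(jch)
  J <- px$m[, 1]; C <- px$m[, 2]; h <- px$m[, 3]
  pos <- J > 0
  t <- rep(0, length(J))
  t[pos] <- (C[pos] / (sqrt(J[pos] / 100) * (1.64 - 0.29^p$n)^0.73))^(1 / 0.9)
  e <- (12500 / 13) * p$Nc * p$Ncb * (cos(h * pi / 180 + 2) + 3.8)
  A <- p$Aw * (pmax(J, 0) / 100)^(1 / (p$c * p$z))
  p2 <- A / p$Nbb + 0.305
  hr <- h * pi / 180
  sin_h <- sin(hr); cos_h <- cos(hr)
  a <- b <- rep(0, length(J))
  nz <- t > 1e-12
  if (any(nz)) {
    p1 <- e[nz] / t[nz]
    sh <- sin_h[nz]; ch <- cos_h[nz]
    use_sin <- abs(sh) >= abs(ch)
    aa <- bb <- numeric(sum(nz))
    k1 <- (2 + 21 / 20) * (460 / 1403)
    k2 <- (2 + 21 / 20) * (220 / 1403)
    k3 <- 27 / 1403 - (21 / 20) * (6300 / 1403)
    if (any(use_sin)) {
      p4 <- p1[use_sin] / sh[use_sin]
      bb[use_sin] <- p2[nz][use_sin] * k1 /
        (p4 + k2 * (ch[use_sin] / sh[use_sin]) - k3)
      aa[use_sin] <- bb[use_sin] * ch[use_sin] / sh[use_sin]
    }
    if (any(!use_sin)) {
      p5 <- p1[!use_sin] / ch[!use_sin]
      aa[!use_sin] <- p2[nz][!use_sin] * k1 /
        (p5 + k2 - k3 * (sh[!use_sin] / ch[!use_sin]))
      bb[!use_sin] <- aa[!use_sin] * sh[!use_sin] / ch[!use_sin]
    }
    a[nz] <- aa; b[nz] <- bb
  }
  Ra <- (460 * p2 + 451 * a + 288 * b) / 1403
  Ga <- (460 * p2 - 891 * a - 261 * b) / 1403
  Ba <- (460 * p2 - 220 * a - 6300 * b) / 1403
  RGBa <- cbind(Ra, Ga, Ba)
  x <- RGBa - 0.1
  sg <- sign(x)
  ax <- pmin(abs(x), 399.99)
  RGBp <- sg * (100 / p$FL) * (27.13 * ax / (400 - ax))^(1 / 0.42)
  RGBc <- RGBp %*% t(.M_CAT02_HPEINV)
  RGB <- sweep(RGBc, 2, p$Dr, `/`)
  xyz <- RGB %*% t(solve(.M_CAT02))
  xyz[!pos, ] <- 0
  restore_shape(xyz, px$dim)
}

#' sRGB to/from the JCh appearance space
#'
#' Convenience composition used by the enhancement pipeline. `srgb_to_jch()`
#' scales XYZ to the 0-100 range expected by CIECAM02; `jch_to_srgb()`
#' applies the inverse model, converts back to sRGB and clips out-of-gamut
#' values (count attached as attribute `"clipped"`).
#'
#' @inheritParams xyz_to_jch
#' @param img H x W x 3 sRGB array in [0, 1].
#' @export
srgb_to_jch <- function(img, vc = viewing_conditions()) {
  xyz_to_jch(srgb_to_xyz(img) * 100, vc)
}

#' @rdname srgb_to_jch
#' @param jch J, C, h container.
#' @export
jch_to_srgb <- function(jch, vc = viewing_conditions()) {
  xyz_to_srgb(jch_to_xyz(jch, vc) / 100)
}
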