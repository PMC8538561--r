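#' Mask labels used by the phantom generator
#'
#' Integer palette of the single-channel label masks: 0 background (outside
#' the field of view), 1 field of view, 2 vessel, 3 optic disc, 4 bright
#' lesion (exudates / cotton wool spots), 5 dark lesion (hemorrhages /
#' microaneurysms).
#'
#' @return Named integer vector.
#' @export
mask_labels <- function() {
  c(background = 0L, field_of_view = 1L, vessel = 2L, optic_disc = 3L,
    bright_lesion = 4L, dark_lesion = 5L)
}

#' Grade recipe for synthetic fundus phantoms
#'
#' Encodes how hypertensive-retinopathy severity shows up in the phantoms:
#' grade 0 is a clean fundus; grade 1 narrows the vessels; grade 2 adds
#' bright (exudate / cotton-wool) and dark (hemorrhage / microaneurysm)
#' blobs; grade 3 additionally swells and brightens the optic disc; grade 4
#' adds a papilledema-like halo around the swollen disc and more lesions.
#' Lesion counts are non-decreasing with grade. All sizes are fractions of
#' the shorter image side, so phantoms scale from 700 x 600 down to quick
#' test sizes. The numeric defaults are this package's own synthetic
#' conventions, chosen so that the five grades are visually and statistically
#' distinct.
#'
#' @param n_bright,n_dark Per-grade lesion counts (length 5, grades 0-4).
#' @param vessel_width_frac Base vessel half-width (fraction of short side).
#' @param narrow_factor Vessel-width multiplier for grades >= 1 (< 1).
#' @param disc_radius_frac Optic-disc radius (fraction of short side).
#' @param disc_swell_factor Disc radius multiplier for grades >= 3.
#' @param halo_width_frac Width of the grade-4 disc halo.
#' @param bright_radius_frac,dark_radius_frac Lesion radius ranges.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return A `grade_spec` list.
#' @export
grade_spec <- function(n_bright = c(0L, 0L, 6L, 9L, 12L),
                       n_dark = c(0L, 0L, 6L, 9L, 12L),
                       vessel_width_frac = 0.010,
                       narrow_factor = 0.5,
                       disc_radius_frac = 0.075,
                       disc_swell_factor = 1.45,
                       halo_width_frac = 0.045,
                       bright_radius_frac = c(0.018, 0.038),
                       dark_radius_frac = c(0.014, 0.030),
                       noise_sd = 0.02) {
  stopifnot(length(n_bright) == 5, length(n_dark) == 5)
  if (is.unsorted(n_bright) || is.unsorted(n_dark))
    stop("lesion counts must be non-decreasing with grade", call. = FALSE)
  structure(list(n_bright = as.integer(n_bright), n_dark = as.integer(n_dark),
                 vessel_width_frac = vessel_width_frac,
                 narrow_factor = narrow_factor,
                 disc_radius_frac = disc_radius_frac,
                 disc_swell_factor = disc_swell_factor,
                 halo_width_frac = halo_width_frac,
                 bright_radius_frac = bright_radius_frac,
                 dark_radius_frac = dark_radius_frac,
                 noise_sd = noise_sd),
            class = "grade_spec")
}

blend <- function(img, weight, colour) {
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - weight) + colour[c] * weight
  img
}

#' Generate one synthetic fundus phantom
#'
#' Deterministic for fixed (grade, spec, seed): a dark canvas with a circular
#' reddish field of view, radial shading and a seeded illumination gradient,
#' branching vessels radiating from the optic disc, the disc itself, and
#' grade-dependent lesions per the [grade_spec()] recipe, together with a
#' pixel-aligned label mask.
#'
#' @param grade Integer 0-4.
#' @param spec A [grade_spec()].
#' @param seed Integer seed.
#' @param height,width Canvas size in pixels (default 600 x 700, the
#'   pipeline's standard fundus raster).
#' @return A `fundus_phantom` list: `image` (H x W x 3 array in [0, 1]),
#'   `mask` (H x W integer matrix, see [mask_labels()]), `grade`, `seed`.
#' @export
generate_phantom <- function(grade, spec = grade_spec(), seed = 1L,
                             height = 600L, width = 700L) {
  if (!is.numeric(grade) || length(grade) != 1 || is.na(grade) ||
      grade != round(grade) || grade < 0 || grade > 4)
    stop("`grade` must be an integer in 0..4", call. = FALSE)
  grade <- as.integer(grade)
  with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    S <- min(h, w)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    R <- 0.95 * S / 2
    yy <- matrix(seq_len(h), h, w) - cy
    xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
    dist <- sqrt(yy^2 + xx^2)
    fov <- dist <= R
    mask <- matrix(0L, h, w)
    mask[fov] <- 1L

    # base fundus colouring: radial falloff + seeded illumination gradient
    shade <- 1 - 0.35 * (dist / R)^2
    angle <- runif(1, 0, 2 * pi)
    gradient <- 1 + 0.15 * (cos(angle) * xx + sin(angle) * yy) / R
    img <- array(0, c(h, w, 3))
    base <- c(0.72, 0.33, 0.18)
    for (c in 1:3) img[, , c] <- base[c] * shade * gradient

    # optic disc, offset horizontally from centre
    side <- sample(c(-1, 1), 1)
    dcy <- cy + runif(1, -0.08, 0.08) * S
    dcx <- cx + side * 0.55 * R
    rd <- spec$disc_radius_frac * S
    if (grade >= 3) rd <- rd * spec$disc_swell_factor
    ddisc <- sqrt((yy - (dcy - cy))^2 + (xx - (dcx - cx))^2)
    disc_col <- c(0.97, 0.85, 0.55)
    if (grade >= 3) disc_col <- pmin(disc_col + 0.08, 1)
    wdisc <- clip01((1.08 - ddisc / rd) / 0.16)
    img <- blend(img, wdisc * fov, disc_col)
    if (grade == 4) {
      halo <- spec$halo_width_frac * S
      whalo <- clip01(1 - abs(ddisc - (rd + halo / 2)) / (halo / 2))
      img <- blend(img, 0.55 * whalo * fov, c(0.95, 0.88, 0.70))
      mask[whalo > 0.25 & fov] <- 3L
    }

    # branching vessels radiating from the disc
    vw <- spec$vessel_width_frac * S
    if (grade >= 1) vw <- vw * spec$narrow_factor
    vessel <- matrix(FALSE, h, w)
    n_branch <- 6L
    for (b in seq_len(n_branch)) {
      theta <- 2 * pi * (b - 0.5) / n_branch + runif(1, -0.25, 0.25)
      py <- dcy; px <- dcx
      step <- S / 60
      n_steps <- as.integer(3.2 * R / step)
      for (s in seq_len(n_steps)) {
        theta <- theta + runif(1, -0.22, 0.22)
        py <- py + step * sin(theta); px <- px + step * cos(theta)
        if (sqrt((py - cy)^2 + (px - cx)^2) > 0.93 * R) break
        hw <- max(1, ceiling(vw * (1 - 0.5 * s / n_steps)))
        y0 <- max(1L, floor(py - hw)); y1 <- min(h, ceiling(py + hw))
        x0 <- max(1L, floor(px - hw)); x1 <- min(w, ceiling(px + hw))
        if (y0 > y1 || x0 > x1) next
        ly <- y0:y1; lx <- x0:x1
        d2 <- outer((ly - py)^2, (lx - px)^2, `+`)
        vessel[ly, lx] <- vessel[ly, lx] | (d2 <= hw^2)
      }
    }
    vessel <- vessel & fov & ddisc > 0.6 * rd
    img <- blend(img, 0.85 * vessel, c(0.45, 0.12, 0.08))
    mask[vessel] <- 2L
    mask[ddisc <= rd & fov] <- 3L

    lesion_centres <- list()
    place_lesions <- function(n, rfrac, colour, strength, label) {
      placed <- 0L; tries <- 0L
      while (placed < n && tries < 200L * n) {
        tries <- tries + 1L
        ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 0.82 * R
        ly <- cy + rad * sin(ang); lx <- cx + rad * cos(ang)
        if (sqrt((ly - dcy)^2 + (lx - dcx)^2) < rd + rfrac[2] * S + 2) next
        r <- runif(1, rfrac[1], rfrac[2]) * S
        clash <- any(vapply(lesion_centres, function(p)
          sqrt((p[1] - ly)^2 + (p[2] - lx)^2) < p[3] + r + 2, logical(1)))
        if (clash) next
        lesion_centres[[length(lesion_centres) + 1L]] <<- c(ly, lx, r)
        y0 <- max(1L, floor(ly - 1.5 * r)); y1 <- min(h, ceiling(ly + 1.5 * r))
        x0 <- max(1L, floor(lx - 1.5 * r)); x1 <- min(w, ceiling(lx + 1.5 * r))
        iy <- y0:y1; ix <- x0:x1
        d2 <- outer((iy - ly)^2, (ix - lx)^2, `+`)
        prof <- exp(-d2 / (2 * (r / 1.6)^2))
        wloc <- strength * prof * fov[iy, ix]
        for (c in 1:3)
          img[iy, ix, c] <<- img[iy, ix, c] * (1 - wloc) + colour[c] * wloc
        mm <- mask[iy, ix]
        mm[prof > 0.4 & fov[iy, ix]] <- label
        mask[iy, ix] <<- mm
        placed <- placed + 1L
      }
      invisible(placed)
    }
    place_lesions(spec$n_bright[grade + 1L], spec$bright_radius_frac,
                  c(0.97, 0.93, 0.62), 0.95, mask_labels()[["bright_lesion"]])
    place_lesions(spec$n_dark[grade + 1L], spec$dark_radius_frac,
                  c(0.12, 0.03, 0.03), 0.9, mask_labels()[["dark_lesion"]])

    noise <- array(rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3))
    img <- img + noise
    for (c in 1:3) {
      plane <- img[, , c]
      plane[!fov] <- 0.02
      img[, , c] <- plane
    }
    img <- clip01(img)
    structure(list(image = img, mask = mask, grade = grade, seed = seed),
              class = "fundus_phantom")
  })
}

#' Generate a synthetic fundus dataset on disk
#'
#' Emits `counts[g]` phantoms per grade (default canvas 700 x 600) as PNG
#' image/mask pairs plus a `manifest.csv`, mirroring the five-grade class
#' distribution 400/200/200/200/400 of the study design when called with the
#' default counts.
#'
#' @param counts Integer vector of length 5: phantoms per grade 0-4.
#' @param spec A [grade_spec()].
#' @param seed Integer seed; per-record seeds are drawn from it.
#' @param out_dir Output directory (created if missing).
#' @param height,width Canvas size.
#' @return A tibble manifest: image, mask, grade, augmented, seed.
#' @export
generate_dataset <- function(counts = c(400L, 200L, 200L, 200L, 400L),
                             spec = grade_spec(), seed = 1L, out_dir,
                             height = 600L, width = 700L) {
  stopifnot(length(counts) == 5, all(counts >= 0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir", call. = FALSE)
  n <- sum(counts)
  grades <- rep(0:4, times = counts)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(grades[i], spec, seeds[i], height, width)
    img_path <- file.path(out_dir, sprintf("image_%05d.png", i))
    msk_path <- file.path(out_dir, sprintf("mask_%05d.png", i))
    write_image(ph$image, img_path)
    write_mask(ph$mask, msk_path)
    rows[[i]] <- tibble::tibble(image = img_path, mask = msk_path,
                                grade = grades[i], augmented = FALSE,
                                seed = seeds[i], transform = NA_character_,
                                angle = NA_real_)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Double a dataset by offline augmentation
#'
#' Adds exactly one augmented copy per original record. The transform is
#' drawn uniformly from horizontal flip, vertical flip, and rotation by an
#' angle uniform in [90, 180] degrees (no scaling); the mask receives the
#' identical transform with nearest-neighbour resampling so labels stay
#' categorical.
#'
#' @param manifest Manifest tibble from [generate_dataset()].
#' @param seed Integer seed for the transform draws.
#' @param out_dir Directory for augmented files (default: alongside the
#'   originals).
#' @return Manifest with 2x the rows; augmented rows carry the transform
#'   type and rotation angle.
#' @export
augment_dataset <- function(manifest, seed = 1L, out_dir = NULL) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (is.null(out_dir)) out_dir <- dirname(manifest$image[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(manifest)
  draws <- with_seed(seed, {
    type <- sample(c("hflip", "vflip", "rotate"), n, replace = TRUE)
    angle <- runif(n, 90, 180)
    list(type = type, angle = ifelse(type == "rotate", angle, NA_real_))
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- read_image(manifest$image[i])
    msk <- read_mask(manifest$mask[i])
    tr <- draws$type[i]
    if (tr == "hflip") {
      img2 <- flip_image(img, "horizontal")
      msk2 <- flip_image(msk, "horizontal")
    } else if (tr == "vflip") {
      img2 <- flip_image(img, "vertical")
      msk2 <- flip_image(msk, "vertical")
    } else {
      img2 <- clip01(rotate_image(img, draws$angle[i], "bilinear", fill = 0.02))
      msk2 <- rotate_image(msk, draws$angle[i], "nearest", fill = 0)
    }
    stem <- sub("\\.png$", "", basename(manifest$image[i]))
    img_path <- file.path(out_dir, paste0(stem, "_aug.png"))
    msk_path <- file.path(out_dir, paste0(sub("image", "mask", stem), "_aug.png"))
    write_image(img2, img_path)
    write_mask(msk2, msk_path)
    rows[[i]] <- tibble::tibble(image = img_path, mask = msk_path,
                                grade = manifest$grade[i], augmented = TRUE,
                                seed = manifest$seed[i], transform = tr,
                                angle = draws$angle[i])
  }
  out <- dplyr::bind_rows(manifest, dplyr::bind_rows(rows))
  utils::write.csv(out, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  out
}
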