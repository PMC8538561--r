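test_that("phantom generation is deterministic and grade-consistent", {
  p1 <- generate_phantom(2, seed = 5, height = 96, width = 96)
  p2 <- generate_phantom(2, seed = 5, height = 96, width = 96)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  p3 <- generate_phantom(2, seed = 6, height = 96, width = 96)
  expect_false(identical(p1$image, p3$image))
  expect_error(generate_phantom(5), "0..4")
  expect_error(generate_phantom(-1), "0..4")
})

test_that("grade 0 phantoms carry no lesion pixels; lesions grow with grade", {
  lab <- mask_labels()
  for (seed in 1:3) {
    m0 <- generate_phantom(0, seed = seed, height = 96, width = 96)$mask
    expect_equal(sum(m0 %in% lab[c("bright_lesion", "dark_lesion")]), 0)
  }
  n_lesion <- sapply(c(0, 2, 4), function(g)
    sum(generate_phantom(g, seed = 9, height = 128,
                         width = 128)$mask %in% 4:5))
  expect_true(all(diff(n_lesion) > 0))
})

test_that("optic disc swells with severity at equal seed", {
  a1 <- sum(generate_phantom(1, seed = 12)$mask == 3)
  a4 <- sum(generate_phantom(4, seed = 12)$mask == 3)
  expect_gt(a4, a1)
})

test_that("lesion pixels lie inside the field of view", {
  m <- generate_phantom(4, seed = 13, height = 96, width = 96)$mask
  yy <- matrix(seq_len(96), 96, 96) - 48.5
  xx <- t(yy)
  outside <- sqrt(yy^2 + xx^2) > 0.95 * 48
  expect_equal(sum(m[outside] %in% 2:5), 0)
})

test_that("default phantoms use the standard 700 x 600 raster", {
  ph <- generate_phantom(0, seed = 1)
  expect_equal(dim(ph$image), c(600L, 700L, 3L))
  expect_equal(dim(ph$mask), c(600L, 700L))
})

test_that("dataset generation writes counts, masks and a faithful manifest", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(c(3L, 1L, 1L, 1L, 2L), seed = 2, out_dir = dir,
                        height = 48L, width = 48L)
  expect_equal(nrow(m), 8)
  expect_equal(as.integer(table(factor(m$grade, levels = 0:4))),
               c(3L, 1L, 1L, 1L, 2L))
  expect_true(all(file.exists(m$image)))
  expect_true(all(file.exists(m$mask)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # masks survive the PNG round trip exactly
  ph_mask <- read_mask(m$mask[1])
  expect_true(all(ph_mask %in% 0:5))
  # single-record edge case
  dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(c(1L, 0L, 0L, 0L, 0L), seed = 3, out_dir = dir2,
                         height = 48L, width = 48L)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$grade, 0L)
})

test_that("dataset generation is reproducible for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(c(2L, 0L, 1L, 0L, 0L), seed = 4, out_dir = d1,
                         height = 48L, width = 48L)
  m2 <- generate_dataset(c(2L, 0L, 1L, 0L, 0L), seed = 4, out_dir = d2,
                         height = 48L, width = 48L)
  expect_identical(m1$seed, m2$seed)
  for (i in seq_len(nrow(m1)))
    expect_identical(png::readPNG(m1$image[i]), png::readPNG(m2$image[i]))
})

test_that("augmentation doubles the set and keeps masks aligned", {
  dir <- withr::local_tempdir()
  m <- generate_dataset(c(2L, 1L, 1L, 1L, 1L), seed = 6, out_dir = dir,
                        height = 64L, width = 64L)
  aug <- augment_dataset(m, seed = 7)
  expect_equal(nrow(aug), 2 * nrow(m))
  expect_equal(table(aug$grade[aug$augmented]), table(m$grade))
  for (i in which(aug$augmented)) {
    rec <- aug[i, ]
    orig_i <- match(sub("_aug", "", basename(rec$image)),
                    basename(aug$image[!aug$augmented]))
    orig <- aug[!aug$augmented, ][orig_i, ]
    img_a <- read_image(rec$image)
    msk_a <- read_mask(rec$mask)
    img_o <- read_image(orig$image)
    msk_o <- read_mask(orig$mask)
    expect_false(identical(img_a, img_o))
    if (rec$transform == "hflip") {
      expect_equal(flip_image(img_a, "horizontal"), img_o, tolerance = 1 / 255)
      expect_identical(flip_image(msk_a, "horizontal"), msk_o)
    } else if (rec$transform == "vflip") {
      expect_equal(flip_image(img_a, "vertical"), img_o, tolerance = 1 / 255)
      expect_identical(flip_image(msk_a, "vertical"), msk_o)
    } else {
      expect_true(rec$angle >= 90 && rec$angle <= 180)
      # inverse rotation recovers the original mask away from the border
      back <- rotate_image(msk_a, -rec$angle, "nearest")
      fov <- msk_o > 0 & back > 0
      iou <- sum(back[fov] == msk_o[fov]) / max(1, sum(fov))
      expect_gte(iou, 0.95)
    }
  }
})

test_that("exact flips and right-angle rotations are self-inverse", {
  ph <- generate_phantom(3, seed = 8, height = 48, width = 48)
  expect_identical(flip_image(flip_image(ph$image, "horizontal"),
                              "horizontal"), ph$image)
  expect_identical(rotate_image(rotate_image(ph$mask, 90), 270), ph$mask)
  expect_identical(rotate_image(rotate_image(ph$mask, 180), 180), ph$mask)
})

test_that("lesion count recipes must be non-decreasing in grade", {
  expect_error(grade_spec(n_bright = c(2, 1, 3, 4, 5)), "non-decreasing")
})
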