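# Shared fixtures, all built in code at test time.

# binary canvas with one or more filled discs
disc_mask <- function(centers, r, n = 256L) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(rep(seq_len(n), each = n), n, n)
  out <- matrix(FALSE, n, n)
  for (c in centers) out <- out | ((yy - c[1])^2 + (xx - c[2])^2 <= r^2)
  out
}

# tiny deterministic phantom set for segmentation tests
phantom_set <- function(grades, size = 64L, seed0 = 100L) {
  lapply(seq_along(grades), function(i)
    generate_phantom(grades[i], seed = seed0 + i,
                     height = size, width = size))
}

lesion_binary <- function(mask) {
  lab <- mask_labels()
  matrix(as.numeric(mask %in% lab[c("bright_lesion", "dark_lesion")]),
         nrow(mask), ncol(mask))
}

# reference CIECAM02 appearance correlates for the published test stimuli
# (viewing conditions: Yb = 20, average surround, D from LA)
ciecam02_cases <- function() {
  list(
    list(XYZ = c(19.01, 20.00, 21.78), white = c(95.05, 100, 108.88),
         LA = 318.31, J = 41.7311, C = 0.1047, h = 219.0484),
    list(XYZ = c(57.06, 43.06, 31.96), white = c(95.05, 100, 108.88),
         LA = 31.83, J = 65.9552, C = 48.5705, h = 19.5574),
    list(XYZ = c(3.53, 6.56, 2.14), white = c(109.85, 100, 35.58),
         LA = 318.31, J = 21.7854, C = 46.9441, h = 177.1403),
    list(XYZ = c(19.01, 20.00, 21.78), white = c(109.85, 100, 35.58),
         LA = 31.83, J = 42.5319, C = 51.9150, h = 248.9042))
}
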