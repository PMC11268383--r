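test_that("plans have three steps, are seeded, and sample uniformly", {
  rg <- transform_ranges()
  p1 <- sample_plan(rg, seed = 11)
  p2 <- sample_plan(rg, seed = 11)
  expect_length(p1$steps, 3L)
  expect_identical(p1$steps, p2$steps)
  for (s in p1$steps) {
    lim <- hsipath:::range_for(rg, s$name)
    expect_gte(s$strength, lim[1]); expect_lte(s$strength, lim[2])
  }
  # frequency: ~10k draws, each of the 13 transforms within 4 sigma of 1/13
  set.seed(202)
  nm <- unlist(lapply(seq_len(3334), function(i)
    vapply(sample_plan(rg)$steps, `[[`, "", "name")))
  n <- length(nm)
  p <- 1 / 13
  tol <- 4 * sqrt(n * p * (1 - p))
  counts <- table(factor(nm, levels = hsipath:::AUGMENT_TRANSFORMS))
  expect_true(all(abs(counts - n * p) < tol))
  expect_length(counts, 13L)
})

test_that("invalid ranges are rejected", {
  expect_error(transform_ranges(rotate = c(2, 1)), "lo <= hi")
  expect_error(transform_ranges(zeroing = c(0, 2.5)), "integers")
  expect_error(transform_ranges(bogus = c(0, 1)), "unknown")
})

test_that("quarter-turn rotation matches the index-permutation oracle", {
  set.seed(3)
  m <- array(runif(6 * 6 * 2), c(6, 6, 2))
  cb <- hypercube(m, c(500, 600), "transmittance")
  rot <- apply_geometric(cb, "rotate", pi / 2, fill = 0)
  oracle <- m * 0
  for (r in 1:6) for (cc in 1:6) oracle[r, cc, ] <- m[6 + 1 - cc, r, ]
  expect_equal(rot$data, oracle, tolerance = 1e-12)
})

test_that("translation shifts content and fills vacated rows", {
  expect_equal(apply_geometric(rand_cube(seed = 4), "translateX", 0)$data,
               rand_cube(seed = 4)$data, tolerance = 1e-12)
  set.seed(5)
  m <- array(runif(100 * 100 * 2), c(100, 100, 2))
  cb <- hypercube(m, c(500, 600), "transmittance")
  tr <- apply_geometric(cb, "translateY", 0.5, fill = 1)
  expect_equal(tr$data[51:100, , ], m[1:50, , ], tolerance = 1e-12)
  expect_true(all(tr$data[1:50, , ] == 1))
  expect_error(apply_geometric(cb, "swirl", 0.1), "unknown")
})

test_that("shear at the origin row is exact and fills elsewhere", {
  cb <- rand_cube(9, 9, 2, seed = 6)
  sh <- apply_geometric(cb, "shearX", 0.25)
  # center row (y = 0) is unchanged by a horizontal shear
  expect_equal(sh$data[5, , ], cb$data[5, , ], tolerance = 1e-12)
  expect_equal(apply_geometric(cb, "shearY", 0)$data, cb$data,
               tolerance = 1e-12)
})

test_that("brightness is an additive lift by a fraction of the maximum", {
  cb <- const_cube(0.2)
  cb$data[1, 1, 1] <- 0.4   # max
  out <- adjust_brightness(cb, 0.5)
  expect_equal(out$data[2, 2, 2], 0.2 + 0.5 * 0.4, tolerance = 1e-12)
  expect_equal(adjust_brightness(cb, 0)$data, cb$data)
  expect_true(all(adjust_brightness(rand_cube(seed = 8), 1)$data <= 1))
})

test_that("the contrast curve has its stated identity and fixed point", {
  cb <- rand_cube(seed = 9)
  expect_equal(adjust_contrast(cb, 0)$data, cb$data, tolerance = 1e-8)
  for (C in c(0.3, 0.9, 1.5, 2)) {
    half <- adjust_contrast(const_cube(0.5), C)
    expect_equal(max(abs(half$data - 0.5)), 0, tolerance = 1e-12)
  }
  # direct evaluation of the published formula at I = 0.75, C = 0.5
  v <- adjust_contrast(const_cube(0.75), 0.5, clip = FALSE)$data[1, 1, 1]
  expect_equal(v, 1.0157 * 1.5 * 0.25 / (1.0157 - 0.5) + 0.5,
               tolerance = 1e-12)
  expect_equal(round(v, 4), 1.2386)
  expect_equal(adjust_contrast(const_cube(0.75), 0.5)$data[1, 1, 1], 1)
  # the clamped denominator keeps the map finite beyond the singularity
  expect_true(all(is.finite(adjust_contrast(cb, 2)$data)))
})

test_that("unsharp masking sharpens edges and preserves flats", {
  cb <- rand_cube(seed = 10)
  expect_identical(sharpen_bands(cb, 0)$data, cb$data)
  expect_equal(sharpen_bands(const_cube(0.37), 4)$data,
               const_cube(0.37)$data, tolerance = 1e-12)
  # step edge: hand-convolved 3x3 binomial blur predicts the overshoot
  m <- matrix(rep(c(0.2, 0.8), each = 4 * 8), 8, 8)
  cb2 <- hypercube(array(m, c(8, 8, 1)), 550, "transmittance")
  out <- sharpen_bands(cb2, 1)$data[, , 1]
  blur <- hsipath:::blur3_band(m)
  expect_equal(out, pmin(pmax(m + 1 * (m - blur), 0), 1), tolerance = 1e-12)
  # overshoot on the bright side of the edge, undershoot on the dark side
  expect_gt(out[4, 5], 0.8)
  expect_lt(out[4, 4], 0.2)
})

test_that("spectral noise adds one recorded offset per band", {
  cb <- rand_cube(6, 6, 5, seed = 12)
  expect_identical(add_spectral_noise(cb, 0, seed = 1)$data, cb$data)
  a <- add_spectral_noise(cb, 0.3, seed = 7)
  b <- add_spectral_noise(cb, 0.3, seed = 7)
  expect_identical(a$data, b$data)
  deltas <- attr(a, "deltas")
  expect_length(deltas, 5L)
  expect_true(all(deltas >= 0 & deltas <= 0.3 * max(cb$data)))
  pre <- apply(cb$data, 3, mean)
  post <- apply(pmin(cb$data + rep(deltas, each = 36), 1), 3, mean)
  expect_equal(apply(a$data, 3, mean), post, tolerance = 1e-12)
})

test_that("the spectral ramp anchors at 600 nm with unit gain", {
  wl <- seq(467, 721, length.out = 8)
  cb <- rand_cube(4, 4, 8, seed = 13)
  expect_equal(apply_spectral_ramp(cb, 0)$data, cb$data, tolerance = 1e-12)
  # a band exactly at 600 nm never changes
  cb600 <- hypercube(array(0.4, c(3, 3, 3)), c(500, 600, 700), "transmittance")
  out <- apply_spectral_ramp(cb600, 1.7)
  expect_equal(out$data[, , 2], cb600$data[, , 2], tolerance = 1e-12)
  # ramp factor at the red end, A = 2 over the 467-721 nm support
  fac <- 1 + 2 * (721 - 600) / (721 - 467)
  small <- hypercube(array(0.2, c(2, 2, 8)), wl, "transmittance")
  expect_equal(apply_spectral_ramp(small, 2)$data[1, 1, 8],
               min(1, 0.2 * fac), tolerance = 1e-12)
  expect_equal(fac, 1.9527559, tolerance = 1e-6)
})

test_that("zeroing blacks out exactly k bands and no others", {
  cb <- rand_cube(5, 5, 84, seed = 14)
  expect_identical(zero_bands(cb, 0)$data, cb$data)
  z <- zero_bands(cb, 3, seed = 21)
  sel <- attr(z, "zeroed")
  expect_length(sel, 3L)
  expect_true(all(z$data[, , sel] == 0))
  expect_identical(z$data[, , -sel], cb$data[, , -sel])
  expect_identical(zero_bands(cb, 3, seed = 21)$data, z$data)
})

test_that("every transform at the low end of its range is the identity", {
  cb <- rand_cube(10, 10, 6, seed = 15)
  low <- list(rotate = 0, shearX = 0, shearY = 0, translateX = 0,
              translateY = 0, brightness = 0, contrast = 0, sharpen = 0,
              spectral_noise = 0, shifting = 0, zeroing = 0)
  for (nm in names(low)) {
    out <- hsipath:::apply_transform(cb, nm, low[[nm]], seed = 3)
    expect_lt(max(abs(out$data - cb$data)), 1e-8, label = nm)
    expect_identical(out$wavelengths, cb$wavelengths)
    expect_identical(dim(out), dim(cb))
  }
})

test_that("RandAugment composes three transforms reproducibly in [0,1]", {
  cb <- rand_cube(16, 16, 6, seed = 16)
  out1 <- rand_augment(cb, seed = 77)
  out2 <- rand_augment(cb, seed = 77)
  expect_identical(out1$data, out2$data)
  expect_length(attr(out1, "plan")$steps, 3L)
  expect_identical(dim(out1), dim(cb))
  expect_true(min(out1$data) >= 0 && max(out1$data) <= 1)
  # an all-identity plan returns the input untouched
  idplan <- structure(list(steps = rep(list(list(name = "identity",
                                                 strength = 0)), 3)),
                      class = "augment_plan")
  expect_identical(rand_augment(cb, plan = idplan)$data, cb$data)
  # seeded runs across many seeds keep the contract
  for (s in 1:20) {
    o <- rand_augment(cb, seed = s, nmf_cfg = list(max_iter = 40))
    expect_identical(dim(o), dim(cb))
    expect_true(min(o$data) >= 0 && max(o$data) <= 1)
  }
})
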