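#' Strength ranges for the hyperspectral RandAugment transforms
#'
#' One `[lo, hi]` strength interval per transform. Geometric strengths are
#' in radians (rotate) or fractions of the image length (shear, translate);
#' photometric strengths are on the 0-1 intensity scale except contrast
#' (multiples of original contrast) and the NMF gamma exponent. Zeroing
#' counts whole spectral channels and is integer-valued.
#'
#' @param ... named overrides, each a length-2 numeric `c(lo, hi)`.
#' @return named list of ranges, class `transform_ranges`.
#' @export
transform_ranges <- function(...) {
  r <- list(
    rotate = c(0, pi / 2),
    translate = c(0, 0.5),
    shear = c(0, 0.5),
    contrast = c(0, 2.0),
    sharpen = c(0, 5),
    spectral_noise = c(0, 0.5),
    shifting = c(0, 2.0),
    zeroing = c(0, 3),
    brightness = c(0, 1.0),
    nmf = c(0.5, 1.5))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(r)) stop("unknown transform range: ", nm)
    r[[nm]] <- as.numeric(ov[[nm]])
  }
  for (nm in names(r)) {
    if (length(r[[nm]]) != 2 || r[[nm]][1] > r[[nm]][2])
      stop("range for '", nm, "' must be c(lo, hi) with lo <= hi")
  }
  if (any(r$zeroing != round(r$zeroing)))
    stop("zeroing bounds must be integers")
  structure(r, class = "transform_ranges")
}

# the 13-entry transform list (translate/shear split by axis, identity listed)
AUGMENT_TRANSFORMS <- c("identity", "rotate", "shearX", "shearY",
                        "translateX", "translateY", "brightness", "contrast",
                        "sharpen", "spectral_noise", "shifting", "zeroing",
                        "nmf")

range_for <- function(ranges, name) {
  key <- switch(name,
                shearX = , shearY = "shear",
                translateX = , translateY = "translate",
                identity = NULL,
                name)
  if (is.null(key)) c(0, 0) else ranges[[key]]
}

#' Sample a RandAugment plan
#'
#' Draws exactly 3 transforms uniformly with replacement from the 13-entry
#' transform list and a uniform strength within each transform's range
#' (zeroing strength is a uniform integer count).
#'
#' @param ranges a [transform_ranges] object.
#' @param seed RNG seed (NULL = current stream).
#' @return object of class `augment_plan`: list of 3 steps, each
#'   `list(name, strength)`.
#' @export
sample_plan <- function(ranges = transform_ranges(), seed = NULL) {
  stopifnot(inherits(ranges, "transform_ranges"))
  with_seed(seed, {
    steps <- lapply(seq_len(3), function(i) {
      nm <- AUGMENT_TRANSFORMS[sample.int(length(AUGMENT_TRANSFORMS), 1)]
      rg <- range_for(ranges, nm)
      s <- if (nm == "zeroing") {
        sample(seq.int(rg[1], rg[2]), 1)
      } else stats::runif(1, rg[1], rg[2])
      list(name = nm, strength = s)
    })
    structure(list(steps = steps, seed = seed), class = "augment_plan")
  })
}

#' @export
print.augment_plan <- function(x, ...) {
  for (s in x$steps) cat(sprintf("%-14s strength=%.4g\n", s$name, s$strength))
  invisible(x)
}

# inverse-map bilinear warp shared by all geometric transforms; `inv` maps
# output-centered (x, y) to source-centered coordinates.
warp_cube <- function(cube, inv, fill) {
  d <- dim(cube$data)
  h <- d[1]; w <- d[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r_o <- rep(seq_len(h), times = w) - cy     # y, row-down
  c_o <- rep(seq_len(w), each = h) - cx      # x
  src <- inv(c_o, r_o)
  sr <- src$y + cy; sc <- src$x + cx
  valid <- sr >= 1 & sr <= h & sc >= 1 & sc <= w
  sr <- pmin(pmax(sr, 1), h); sc <- pmin(pmax(sc, 1), w)
  i0 <- pmin(as.integer(floor(sr)), h - 1L); wi <- sr - i0
  j0 <- pmin(as.integer(floor(sc)), w - 1L); wj <- sc - j0
  m <- matrix(cube$data, h * w, d[3])
  g <- function(i, j) m[i + (j - 1L) * h, , drop = FALSE]
  out <- g(i0, j0) * ((1 - wi) * (1 - wj)) +
    g(i0 + 1L, j0) * (wi * (1 - wj)) +
    g(i0, j0 + 1L) * ((1 - wi) * wj) +
    g(i0 + 1L, j0 + 1L) * (wi * wj)
  out[!valid, ] <- fill
  hypercube(array(out, d), cube$wavelengths, cube$kind)
}

#' Apply a geometric transform identically to every band
#'
#' Rotation is clockwise about the image center; shear and translation act
#' horizontally (`X`) or vertically (`Y`) with strength measured as a
#' fraction of the image length. Out-of-frame regions are set to `fill`
#' (default 1: bright slide background in transmittance). Bilinear
#' interpolation per band; integer-pixel maps (e.g. quarter turns on square
#' images) are exact index permutations.
#'
#' @param cube a `hypercube`.
#' @param kind one of `"rotate"`, `"shearX"`, `"shearY"`, `"translateX"`,
#'   `"translateY"`.
#' @param strength radians for rotate, fraction of image length otherwise.
#' @param fill fill value for vacated pixels.
#' @return transformed `hypercube` of identical shape.
#' @export
apply_geometric <- function(cube, kind, strength, fill = 1.0) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  inv <- switch(kind,
    rotate = function(x, y) list(x = x * cos(strength) + y * sin(strength),
                                 y = -x * sin(strength) + y * cos(strength)),
    shearX = function(x, y) list(x = x - strength * y, y = y),
    shearY = function(x, y) list(x = x, y = y - strength * x),
    translateX = function(x, y) list(x = x - strength * d[2], y = y),
    translateY = function(x, y) list(x = x, y = y - strength * d[1]),
    stop("unknown geometric transform: ", kind))
  warp_cube(cube, inv, fill)
}

#' Brightness adjustment
#'
#' Adds `s * max(I)` to every value (an additive lift by a fraction of the
#' image's maximum intensity) and clips to `[0, 1]`.
#'
#' @param cube a `hypercube`.
#' @param s strength in `[0, 1]`.
#' @return adjusted `hypercube`.
#' @export
adjust_brightness <- function(cube, s) {
  stopifnot(inherits(cube, "hypercube"), s >= 0)
  hypercube(clip01(cube$data + s * max(cube$data)), cube$wavelengths, cube$kind)
}

#' Contrast adjustment
#'
#' Applies `I' = 1.0157 (C + 1) (I - 0.5) / (1.0157 - C) + 0.5` elementwise.
#' The denominator is clamped below at 0.01 so the map stays finite over the
#' full strength range `[0, 2]` (it changes sign at C = 1.0157). `C = 0` is
#' the identity and `I = 0.5` is a fixed point for every admissible `C`.
#'
#' @param cube a `hypercube`.
#' @param C contrast strength in `[0, 2]`.
#' @param clip clip the result to `[0, 1]` (default). `clip = FALSE` exposes
#'   the raw formula value.
#' @return adjusted `hypercube`.
#' @export
adjust_contrast <- function(cube, C, clip = TRUE) {
  stopifnot(inherits(cube, "hypercube"), C >= 0)
  denom <- max(1.0157 - C, 0.01)
  out <- 1.0157 * (C + 1) * (cube$data - 0.5) / denom + 0.5
  if (clip) out <- clip01(out) else out[out < 0] <- 0
  hypercube(out, cube$wavelengths, cube$kind)
}

# 3x3 binomial blur with replicate padding, the fixed unsharp-mask smoother
blur3_band <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(1L, seq_len(h), h); ci <- c(1L, seq_len(w), w)
  p <- m[ri, ci]
  k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + k[dy + 1, dx + 1] * p[dy + seq_len(h), dx + seq_len(w)]
  out
}

#' Unsharp-mask sharpening
#'
#' Per band, `I' = I + s (I - blur(I))` with a fixed 3x3 binomial smoothing
#' kernel (replicate-padded), clipped to `[0, 1]`. Constant bands are
#' unchanged for any strength.
#'
#' @param cube a `hypercube`.
#' @param s sharpening multiplier in `[0, 5]`.
#' @return sharpened `hypercube`.
#' @export
sharpen_bands <- function(cube, s) {
  stopifnot(inherits(cube, "hypercube"), s >= 0)
  if (s == 0) return(cube)
  d <- dim(cube$data)
  out <- cube$data
  for (b in seq_len(d[3])) {
    m <- cube$data[, , b]
    out[, , b] <- m + s * (m - blur3_band(m))
  }
  hypercube(clip01(out), cube$wavelengths, cube$kind)
}

#' Band-wise spectral offset noise
#'
#' Draws one offset per band, `delta_b ~ Uniform[0, s * max(I)]`, adds it to
#' all pixels of that band and clips to `[0, 1]`. The drawn offsets are
#' attached as attribute `"deltas"`.
#'
#' @param cube a `hypercube`.
#' @param s strength in `[0, 0.5]`.
#' @param seed RNG seed (NULL = current stream).
#' @return noisy `hypercube` with attribute `deltas`.
#' @export
add_spectral_noise <- function(cube, s, seed = NULL) {
  stopifnot(inherits(cube, "hypercube"), s >= 0)
  b <- n_bands(cube)
  with_seed(seed, {
    deltas <- stats::runif(b, 0, s * max(cube$data))
    out <- cube$data + rep(deltas, each = prod(dim(cube$data)[1:2]))
    res <- hypercube(clip01(out), cube$wavelengths, cube$kind)
    attr(res, "deltas") <- deltas
    res
  })
}

#' Spectral shifting: a linear ramp across the spectrum
#'
#' Multiplies each band by `max(0, 1 + A (lambda - 600) / (lambda_max -
#' lambda_min))`: a wavelength-linear gain with unit gain anchored at
#' 600 nm, then clips to `[0, 1]`. `A = 0` is the identity and a band at
#' exactly 600 nm is never changed.
#'
#' @param cube a `hypercube`.
#' @param A ramp strength in `[0, 2]`.
#' @return adjusted `hypercube`.
#' @export
apply_spectral_ramp <- function(cube, A) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$wavelengths
  span <- max(wl) - min(wl)
  fac <- pmax(0, 1 + A * (wl - 600) / span)
  out <- cube$data * rep(fac, each = prod(dim(cube$data)[1:2]))
  hypercube(clip01(out), cube$wavelengths, cube$kind)
}

#' Zero out randomly chosen spectral channels
#'
#' Sets `k` distinct bands to exactly 0 (black), mimicking channel
#' occlusion; every other band is untouched. Chosen band indices are
#' attached as attribute `"zeroed"`.
#'
#' @param cube a `hypercube`.
#' @param k integer number of bands to zero, `0 <= k <= min(3, B)`.
#' @param seed RNG seed (NULL = current stream).
#' @return `hypercube` with `k` zeroed bands.
#' @export
zero_bands <- function(cube, k, seed = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  k <- as.integer(round(k))
  b <- n_bands(cube)
  stopifnot(k >= 0, k <= b)
  if (k == 0) return(cube)
  with_seed(seed, {
    sel <- sample.int(b, k)
    out <- cube$data
    out[, , sel] <- 0
    res <- hypercube(out, cube$wavelengths, cube$kind)
    attr(res, "zeroed") <- sort(sel)
    res
  })
}

apply_transform <- function(cube, name, strength, fill = 1.0, seed = NULL,
                            nmf_cfg = list()) {
  switch(name,
    identity = cube,
    rotate = , shearX = , shearY = , translateX = , translateY =
      apply_geometric(cube, name, strength, fill),
    brightness = adjust_brightness(cube, strength),
    contrast = adjust_contrast(cube, strength),
    sharpen = sharpen_bands(cube, strength),
    spectral_noise = add_spectral_noise(cube, strength, seed),
    shifting = apply_spectral_ramp(cube, strength),
    zeroing = zero_bands(cube, strength, seed),
    nmf = do.call(nmf_stain_augment,
                  c(list(cube = cube, gamma = strength, seed = seed), nmf_cfg)),
    stop("unknown transform: ", name))
}

#' Hyperspectral RandAugment
#'
#' Samples a 3-step [sample_plan] (or uses a supplied one) and applies the
#' transforms in order. All stochastic choices (transform selection,
#' strengths, band picks, NMF initialization) are drawn from one seeded RNG
#' stream, so identical `(seed, input)` gives bit-identical output.
#'
#' @param cube a `hypercube` (values on the 0-1 scale).
#' @param ranges a [transform_ranges] object.
#' @param seed RNG seed (NULL = current stream).
#' @param plan optional pre-sampled `augment_plan` overriding the draw.
#' @param nmf_cfg named list of overrides for [nmf_stain_augment] (e.g.
#'   `max_iter`, `fit_px`).
#' @return augmented `hypercube`, same shape and wavelengths, values in
#'   `[0, 1]`; the applied plan is attached as attribute `"plan"`.
#' @export
rand_augment <- function(cube, ranges = transform_ranges(), seed = NULL,
                         plan = NULL, nmf_cfg = list()) {
  stopifnot(inherits(cube, "hypercube"))
  with_seed(seed, {
    if (is.null(plan)) plan <- sample_plan(ranges)
    out <- cube
    for (s in plan$steps)
      out <- apply_transform(out, s$name, s$strength, nmf_cfg = nmf_cfg)
    out$data <- clip01(out$data)
    attr(out, "plan") <- plan
    out
  })
}
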