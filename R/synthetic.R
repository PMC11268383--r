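#' Build a three-stain absorbance basis
#'
#' Returns unit-peak Gaussian-bump absorbance curves for a hematoxylin-like,
#' an eosin-like and a hemoglobin-like chromophore sampled at the given
#' wavelengths. These are idealized endmembers for simulation and for
#' testing NMF stain recovery, not measured stain spectra.
#'
#' @param wavelengths increasing wavelength grid (nm).
#' @param peaks named numeric vector of peak wavelengths (nm).
#' @param widths named numeric vector of Gaussian sigmas (nm).
#' @return An object of class `stain_basis`: list with `spectra` (3 x B
#'   matrix, rows hematoxylin/eosin/hemoglobin), `wavelengths`, `peaks`.
#' @export
make_stain_basis <- function(wavelengths,
                             peaks = c(hematoxylin = 560, eosin = 527,
                                       hemoglobin = 576),
                             widths = c(hematoxylin = 22, eosin = 16,
                                        hemoglobin = 13)) {
  stopifnot(length(wavelengths) >= 2, all(diff(wavelengths) > 0))
  spectra <- t(vapply(names(peaks), function(nm) {
    s <- exp(-0.5 * ((wavelengths - peaks[[nm]]) / widths[[nm]])^2)
    s / max(s)  # unit peak on the sampled grid
  }, numeric(length(wavelengths))))
  structure(list(spectra = spectra, wavelengths = wavelengths, peaks = peaks,
                 widths = widths), class = "stain_basis")
}

#' Scene configuration for the synthetic patch generator
#'
#' Describes one synthetic H&E-like patch: geometry of the nucleus field
#' (cancer-like) or of the follicle ring around a colloid lumen
#' (normal-like), plus sensor noise. Defaults target the small fast grid
#' used throughout the test-suite; set `n_bands = 84` and
#' `patch_px = 224` for full-scale cubes.
#'
#' @param patch_px patch side (pixels).
#' @param n_bands number of spectral bands.
#' @param wl_range wavelength range in nm (band centers are equally spaced).
#' @param class `"normal"` or `"cancer"`.
#' @param n_nuclei number of nucleus disks for a cancer patch.
#' @param nucleus_radius inclusive integer range of nucleus radii (pixels).
#' @param follicle_radius range of follicle ring radii (pixels).
#' @param ring_width follicle wall thickness (pixels).
#' @param noise_sd additive Gaussian noise on transmittance.
#' @param seed RNG seed (NULL = current stream).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(patch_px = 56, n_bands = 8, wl_range = c(467, 721),
                         class = c("cancer", "normal"), n_nuclei = 40,
                         nucleus_radius = c(2, 4), follicle_radius = c(10, 18),
                         ring_width = 3, noise_sd = 0.01, seed = NULL) {
  class <- match.arg(class)
  stopifnot(patch_px >= 8, n_bands >= 2, ring_width > 0, noise_sd >= 0)
  structure(list(patch_px = patch_px, n_bands = n_bands, wl_range = wl_range,
                 class = class, n_nuclei = n_nuclei,
                 nucleus_radius = nucleus_radius,
                 follicle_radius = follicle_radius, ring_width = ring_width,
                 noise_sd = noise_sd, seed = seed), class = "scene_config")
}

scene_wavelengths <- function(cfg) {
  seq(cfg$wl_range[1], cfg$wl_range[2], length.out = cfg$n_bands)
}

# paint a filled disk into matrix m (additively, capped at `cap`)
paint_disk <- function(m, r0, c0, radius, value, cap = Inf) {
  n <- nrow(m)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  sel <- (rr - r0)^2 + (cc - c0)^2 <= radius^2
  m[sel] <- pmin(m[sel] + value, cap)
  m
}

#' Render one synthetic H&E-like hyperspectral patch
#'
#' Draws per-stain abundance maps for the requested class and converts them
#' to transmittance with the Beer-Lambert law, `T(lambda) =
#' 10^(-sum_i c_i(x,y) eps_i(lambda))`. Cancer-like patches are dense fields
#' of small high-hematoxylin disks (nuclei) over an eosin-stained stroma;
#' normal-like patches are a follicle: a stained epithelial ring around a
#' nearly unstained colloid lumen. Both receive sparse hemoglobin blobs and
#' seeded additive Gaussian sensor noise.
#'
#' @param cfg a [scene_config].
#' @param basis a [make_stain_basis] result on the matching wavelength grid.
#' @return list with `cube` (transmittance `hypercube`) and `abundance`
#'   (`patch_px x patch_px x 3` ground-truth stain abundances).
#' @export
render_patch <- function(cfg, basis = make_stain_basis(scene_wavelengths(cfg))) {
  stopifnot(inherits(cfg, "scene_config"), inherits(basis, "stain_basis"))
  wl <- scene_wavelengths(cfg)
  if (!isTRUE(all.equal(wl, basis$wavelengths)))
    stop("basis wavelengths do not match the scene configuration")
  n <- cfg$patch_px
  with_seed(cfg$seed, {
    hema <- matrix(0, n, n)
    eos <- matrix(0.18 + 0.08 * stats::runif(1), n, n)
    # gentle smooth stroma variation
    gx <- outer(seq_len(n) / n, rep(1, n)); gy <- t(gx)
    eos <- eos * (1 + 0.2 * sin(2 * pi * (gx * stats::runif(1, 0.5, 1.5) +
                                            gy * stats::runif(1, 0.5, 1.5))))
    hemo <- matrix(0, n, n)
    if (cfg$class == "cancer") {
      for (i in seq_len(cfg$n_nuclei)) {
        r <- stats::runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
        hema <- paint_disk(hema, stats::runif(1, 1, n), stats::runif(1, 1, n),
                           r, stats::runif(1, 0.8, 1.2), cap = 1.4)
      }
      eos <- eos * stats::runif(1, 1.0, 1.3)  # denser stroma
    } else {
      r0 <- stats::runif(1, n * 0.35, n * 0.6)
      c0 <- stats::runif(1, n * 0.35, n * 0.6)
      rad <- stats::runif(1, cfg$follicle_radius[1], cfg$follicle_radius[2])
      ring_o <- paint_disk(matrix(0, n, n), r0, c0, rad + cfg$ring_width, 1)
      lumen <- paint_disk(matrix(0, n, n), r0, c0, rad, 1)
      ring <- ring_o - lumen
      hema <- hema + ring * stats::runif(1, 0.4, 0.6)
      # colloid lumen: nearly unstained
      eos[lumen == 1] <- 0.05
      eos <- eos + ring * 0.2
      # a few epithelial nuclei on the ring
      border <- which(ring == 1, arr.ind = TRUE)
      if (nrow(border) > 0) {
        for (i in seq_len(5)) {
          p <- border[sample.int(nrow(border), 1), ]
          hema <- paint_disk(hema, p[1], p[2], 1.5, 0.6, cap = 1.0)
        }
      }
    }
    for (i in seq_len(sample.int(3, 1))) {
      hemo <- paint_disk(hemo, stats::runif(1, 1, n), stats::runif(1, 1, n),
                         stats::runif(1, 2, 4), stats::runif(1, 0.4, 0.7))
    }
    ab <- array(c(hema, eos, hemo), c(n, n, 3))
    od <- matrix(ab, n * n, 3) %*% basis$spectra
    tr <- 10^(-od)
    if (cfg$noise_sd > 0)
      tr <- tr + stats::rnorm(length(tr), sd = cfg$noise_sd)
    list(cube = hypercube(array(clip01(tr), c(n, n, cfg$n_bands)), wl,
                          "transmittance"),
         abundance = ab)
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' Renders `n_per_class` patches per class and assigns synthetic patient IDs
#' in contiguous blocks (each patient contributes `patients_block` patches of
#' a single class) so that patient-stratified splitting is exercised
#' realistically. Cubes are kept in memory; pass `out_dir` to also write each
#' cube (HDF5) and reference the file in the manifest.
#'
#' @param n_per_class patches per class.
#' @param cfg_template a [scene_config] used for both classes (class and seed
#'   fields are overridden per patch).
#' @param seed master seed; every patch gets a derived sub-seed.
#' @param patients_block patches per synthetic patient.
#' @param out_dir optional directory for HDF5 cube files.
#' @return list with `manifest` (data.frame: slide_id, patient_id, grid_row,
#'   grid_col, label, path), `cubes` (list of `hypercube`), `abundances`.
#' @export
make_dataset <- function(n_per_class, cfg_template = scene_config(),
                         seed = 1, patients_block = 10, out_dir = NULL) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c("cancer", "normal"), each = n_per_class)
  n <- length(labels)
  # patients are numbered within each class so no block straddles classes
  per_class <- ceiling(seq_len(n_per_class) / patients_block)
  pid_num <- c(per_class, max(per_class) + per_class)
  manifest <- data.frame(
    slide_id = sprintf("S%03d", pid_num),
    patient_id = sprintf("P%03d", pid_num),
    grid_row = 0L, grid_col = ((seq_len(n) - 1L) %% patients_block),
    label = labels, path = NA_character_,
    stringsAsFactors = FALSE)
  basis <- make_stain_basis(scene_wavelengths(cfg_template))
  cubes <- vector("list", n)
  abund <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- cfg_template
    cfg$class <- labels[i]
    cfg$seed <- (as.integer(seed) * 7919L + i * 13L) %% 2147483647L
    r <- render_patch(cfg, basis)
    cubes[[i]] <- r$cube
    abund[[i]] <- r$abundance
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      p <- file.path(out_dir, sprintf("patch_%04d.h5", i))
      write_cube(r$cube, p, "hdf5")
      manifest$path[i] <- p
    }
  }
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, cubes = cubes, abundances = abund)
}

#' Synthesize a raw/white/dark calibration triplet
#'
#' Builds sensor-count frames consistent with a rendered scene: the white
#' reference is a bright smooth band profile, the dark current a small
#' near-constant offset, and the raw frame is `dark + (white - dark) * T`
#' for the scene's true transmittance `T`, plus seeded sensor noise on the
#' raw counts. [calibrate_transmittance] applied to the result recovers `T`
#' up to that noise.
#'
#' @param cfg a [scene_config]; its `noise_sd` scales the raw-count noise.
#' @return list with `frames` ([calibration_frames]), `truth` (noise-free
#'   transmittance `hypercube`) and `abundance`.
#' @export
make_reference_frames <- function(cfg = scene_config()) {
  cfg_noiseless <- cfg
  cfg_noiseless$noise_sd <- 0
  scene <- render_patch(cfg_noiseless)
  wl <- scene_wavelengths(cfg)
  d <- dim(scene$cube$data)
  with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    # smooth illumination profile peaking mid-spectrum, ~4000 counts
    prof <- 4000 * (0.7 + 0.3 * exp(-0.5 * ((wl - 590) / 120)^2))
    white <- array(rep(prof, each = d[1] * d[2]), d)
    dark <- array(100 + stats::rnorm(prod(d), sd = 1), d)
    raw <- dark + (white - dark) * scene$cube$data
    if (cfg$noise_sd > 0)  # per-band scaling so transmittance error sd == noise_sd
      raw <- raw + stats::rnorm(prod(d)) * (white - dark) * cfg$noise_sd
    raw[raw < 0] <- 0
    list(frames = calibration_frames(
           raw = hypercube(raw, wl, "raw_counts"),
           white = hypercube(white, wl, "raw_counts"),
           dark = hypercube(dark, wl, "raw_counts")),
         truth = scene$cube, abundance = scene$abundance)
  })
}
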