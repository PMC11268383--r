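#' Construct a hypercube
#'
#' A hypercube is the universal image object of the toolkit: an `H x W x B`
#' array of nonnegative intensities together with the `B` band-center
#' wavelengths in nanometres. Cubes are either raw sensor counts
#' (`kind = "raw_counts"`) or calibrated transmittance (`kind =
#' "transmittance"`, nominally on a 0-1 scale although values slightly above
#' 1 can occur where tissue outshines the blank-area white reference).
#'
#' @param data numeric `H x W x B` array (a matrix is promoted to `H x W x 1`).
#' @param wavelengths strictly increasing numeric vector of length `B`, in nm.
#' @param kind `"raw_counts"` or `"transmittance"`.
#' @return An object of class `hypercube` with elements `data`, `wavelengths`
#'   and `kind`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw_counts", "transmittance")) {
  kind <- match.arg(kind)
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be an H x W x B array")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("number of bands (", dim(data)[3], ") != length(wavelengths) (",
         length(wavelengths), ")")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("'wavelengths' must be strictly increasing")
  if (anyNA(data)) stop("'data' contains NA")
  if (kind == "transmittance" && min(data) < 0)
    stop("transmittance cube has negative values")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%.0f-%.0f nm), kind=%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

n_bands <- function(cube) dim(cube$data)[3]

#' Bundle raw, white-reference and dark-current frames
#'
#' The calibration triplet acquired for each slide: the raw scene cube, a
#' white reference taken at a blank slide area, and a dark-current frame
#' taken with the shutter closed. All three must share shape and wavelengths.
#'
#' @param raw,white,dark `hypercube` objects with `kind = "raw_counts"`.
#' @return An object of class `calibration_frames`.
#' @export
calibration_frames <- function(raw, white, dark) {
  frames <- list(raw = raw, white = white, dark = dark)
  for (nm in names(frames)) {
    f <- frames[[nm]]
    if (!inherits(f, "hypercube")) stop("'", nm, "' is not a hypercube")
    if (!identical(dim(f$data), dim(raw$data)))
      stop("shape mismatch between 'raw' and '", nm, "'")
    if (!isTRUE(all.equal(f$wavelengths, raw$wavelengths)))
      stop("wavelength mismatch between 'raw' and '", nm, "'")
  }
  structure(frames, class = "calibration_frames")
}

#' Calibrate raw counts to transmittance
#'
#' Per pixel and band, transmittance is `(raw - dark) / (white - dark)`.
#' The denominator is clamped below at `denom_floor` to keep dead sensor
#' pixels finite, and negative results (raw below dark, i.e. noise) are
#' clamped to 0. Values above 1 are kept: tissue can transmit more than the
#' blank reference area locally.
#'
#' @param frames a [calibration_frames] triplet.
#' @param denom_floor small positive clamp for `white - dark`.
#' @return A `hypercube` with `kind = "transmittance"`.
#' @export
calibrate_transmittance <- function(frames, denom_floor = 1e-6) {
  stopifnot(inherits(frames, "calibration_frames"), denom_floor > 0)
  denom <- pmax(frames$white$data - frames$dark$data, denom_floor)
  tr <- (frames$raw$data - frames$dark$data) / denom
  tr[tr < 0] <- 0
  hypercube(tr, frames$raw$wavelengths, kind = "transmittance")
}

#' Tile a whole frame into non-overlapping square patches
#'
#' Splits the frame into a row-major grid of `patch_px`-sized tiles; partial
#' tiles at the right/bottom edges are dropped, so the patch count is
#' `floor(H/patch_px) * floor(W/patch_px)`.
#'
#' @param frame a `hypercube`.
#' @param patch_px tile side in pixels.
#' @param slide_id,patient_id,label metadata copied onto every patch record.
#' @return List of patch records, each a list with elements `cube`,
#'   `grid_row`, `grid_col` (0-based), `slide_id`, `patient_id`, `label`.
#' @export
tile_patches <- function(frame, patch_px, slide_id = NA_character_,
                         patient_id = NA_character_, label = "unknown") {
  stopifnot(inherits(frame, "hypercube"), patch_px >= 1)
  patch_px <- as.integer(patch_px)
  d <- dim(frame$data)
  nr <- d[1] %/% patch_px
  nc <- d[2] %/% patch_px
  if (nr == 0L || nc == 0L) {
    warning("patch_px (", patch_px, ") exceeds frame size; no tiles produced")
    return(list())
  }
  out <- vector("list", nr * nc)
  k <- 1L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rows <- ((i - 1L) * patch_px + 1L):(i * patch_px)
      cols <- ((j - 1L) * patch_px + 1L):(j * patch_px)
      out[[k]] <- list(
        cube = hypercube(frame$data[rows, cols, , drop = FALSE],
                         frame$wavelengths, frame$kind),
        grid_row = i - 1L, grid_col = j - 1L,
        slide_id = slide_id, patient_id = patient_id, label = label)
      k <- k + 1L
    }
  }
  out
}

# Reassemble tiles into a frame; inverse of tile_patches on the cropped frame.
assemble_tiles <- function(patches, patch_px) {
  stopifnot(length(patches) > 0L)
  nr <- max(vapply(patches, `[[`, 0L, "grid_row")) + 1L
  nc <- max(vapply(patches, `[[`, 0L, "grid_col")) + 1L
  b <- n_bands(patches[[1]]$cube)
  out <- array(NA_real_, c(nr * patch_px, nc * patch_px, b))
  for (p in patches) {
    rows <- (p$grid_row * patch_px + 1L):((p$grid_row + 1L) * patch_px)
    cols <- (p$grid_col * patch_px + 1L):((p$grid_col + 1L) * patch_px)
    out[rows, cols, ] <- p$cube$data
  }
  hypercube(out, patches[[1]]$cube$wavelengths, patches[[1]]$cube$kind)
}

# Separable bilinear resample of one band (matrix), pixel-center aligned.
# Constant inputs stay constant; identity size is an exact copy.
resample_band <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  map1 <- function(n_out, n_in) {
    if (n_in == 1L) return(list(i0 = rep(1L, n_out), w = rep(0, n_out)))
    # output pixel centers -> fractional 1-based input pixel-center index
    f <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    f <- pmin(pmax(f, 1), n_in)
    i0 <- pmin(as.integer(floor(f)), n_in - 1L)
    list(i0 = i0, w = f - i0)
  }
  ry <- map1(out_h, in_h); rx <- map1(out_w, in_w)
  i1 <- pmin(ry$i0 + 1L, in_h); j1 <- pmin(rx$i0 + 1L, in_w)
  # rows first
  a <- m[ry$i0, , drop = FALSE] * (1 - ry$w) + m[i1, , drop = FALSE] * ry$w
  a[, rx$i0, drop = FALSE] * rep(1 - rx$w, each = out_h) +
    a[, j1, drop = FALSE] * rep(rx$w, each = out_h)
}

# 1-D gaussian kernel, sd in pixels
gauss_kernel <- function(sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-(seq(-r, r))^2 / (2 * sd^2))
  k / sum(k)
}

# separable gaussian blur with replicate padding
blur_band <- function(m, sd) {
  k <- gauss_kernel(sd)
  r <- (length(k) - 1L) / 2L
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  conv1 <- function(x) { # along rows of a matrix
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- 0
    for (t in seq_along(k)) out <- out + k[t] * xp[t:(t + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Resize a square patch with anti-aliased bilinear interpolation
#'
#' Each band is resampled independently with the same pixel-center-aligned
#' bilinear map. When downscaling, a Gaussian pre-filter with
#' `sd = max(0, (in/out - 1)/2)` pixels suppresses aliasing. Output values
#' are clipped to `[0, max(input)]`.
#'
#' @param patch a `hypercube` with equal spatial dimensions.
#' @param out_px output side length in pixels.
#' @return resized `hypercube`, band count and wavelengths unchanged.
#' @export
resize_patch <- function(patch, out_px) {
  stopifnot(inherits(patch, "hypercube"))
  if (out_px <= 0) stop("'out_px' must be positive")
  d <- dim(patch$data)
  if (d[1] != d[2]) stop("patch must be square")
  out_px <- as.integer(out_px)
  if (out_px == d[1]) return(patch)
  sd <- max(0, (d[1] / out_px - 1) / 2)
  hi <- max(patch$data)
  out <- array(0, c(out_px, out_px, d[3]))
  for (b in seq_len(d[3])) {
    m <- patch$data[, , b]
    if (sd > 1e-3) m <- blur_band(m, sd)
    out[, , b] <- resample_band(m, out_px, out_px)
  }
  out[out < 0] <- 0
  out[out > hi] <- hi
  hypercube(out, patch$wavelengths, patch$kind)
}

# Gaussian-lobe fits to the CIE 1931 2-degree color matching functions
# (Wyman-style multi-lobe approximation); adequate for display synthesis.
cmf_1931 <- function(wl) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-0.5 * ((x - mu) / s)^2)
  }
  xbar <- 1.056 * g(wl, 599.8, 37.9, 31.0) + 0.362 * g(wl, 442.0, 16.0, 26.7) -
    0.065 * g(wl, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(wl, 568.8, 46.9, 40.5) + 0.286 * g(wl, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(wl, 437.0, 11.8, 36.0) + 0.681 * g(wl, 459.0, 26.0, 13.8)
  cbind(x = xbar, y = ybar, z = zbar)
}

#' Synthesize a display RGB image from a transmittance cube
#'
#' Projects each pixel's transmittance spectrum onto CIE-1931-style
#' color-matching weights sampled at the cube's wavelengths, normalizes by
#' the white point (a flat unit-transmittance spectrum), converts XYZ to
#' linear sRGB and applies the sRGB transfer curve. This is a display
#' projection, not a colorimetric reproduction of any specific scanner.
#'
#' @param cube a transmittance `hypercube` whose wavelength support overlaps
#'   400-720 nm.
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
hsi_to_rgb <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "transmittance") stop("'cube' must be a transmittance cube")
  wl <- cube$wavelengths
  if (max(wl) < 400 || min(wl) > 720)
    stop("wavelength support (", min(wl), "-", max(wl),
         " nm) entirely outside 400-720 nm")
  cmf <- cmf_1931(wl)
  d <- dim(cube$data)
  # trapezoid weights over (possibly irregular) wavelength grid
  B <- length(wl)
  dw <- if (B == 1L) 1 else if (B == 2L) rep(diff(wl) / 2, 2) else
    c(diff(wl)[1] / 2, (wl[3:B] - wl[1:(B - 2)]) / 2, diff(wl)[B - 1] / 2)
  W <- cmf * dw
  px <- matrix(cube$data, d[1] * d[2], d[3])
  xyz <- px %*% W
  white <- colSums(W)                         # XYZ of a flat unit spectrum
  m <- matrix(c(3.2406, -1.5372, -0.4986,
                -0.9689, 1.8758, 0.0415,
                0.0557, -0.2040, 1.0570), 3, 3, byrow = TRUE)
  rgb_lin <- xyz %*% t(m)
  # white balance: a flat unit-transmittance spectrum maps to (1, 1, 1)
  w_rgb <- as.numeric(m %*% white)
  rgb_lin <- sweep(rgb_lin, 2, pmax(w_rgb, 1e-12), "/")
  rgb_lin[rgb_lin < 0] <- 0
  rgb_lin[rgb_lin > 1] <- 1
  srgb <- ifelse(rgb_lin <= 0.0031308, 12.92 * rgb_lin,
                 1.055 * rgb_lin^(1 / 2.4) - 0.055)
  array(srgb, c(d[1], d[2], 3))
}

#' Read a hypercube from disk
#'
#' Two on-disk formats are supported: HDF5 (datasets `data`, `wavelengths`
#' and a scalar string attribute-free dataset `kind`) and ENVI (a `.hdr`
#' text header next to a BSQ binary file, `wavelength` field required).
#'
#' @param path file path. For ENVI, either the header or the binary path.
#' @param format `"hdf5"` or `"envi"`; guessed from the extension by default.
#' @return a `hypercube`.
#' @export
read_cube <- function(path, format = c("auto", "hdf5", "envi")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "envi"
  }
  if (format == "hdf5") read_cube_hdf5(path) else read_cube_envi(path)
}

#' Write a hypercube to disk
#'
#' @param cube a `hypercube`.
#' @param path output path (`.h5` for HDF5; for ENVI the binary path, the
#'   header is written alongside as `<path>.hdr`).
#' @param format `"hdf5"` or `"envi"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, format = c("auto", "hdf5", "envi")) {
  stopifnot(inherits(cube, "hypercube"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5" else "envi"
  }
  if (format == "hdf5") write_cube_hdf5(cube, path) else write_cube_envi(cube, path)
  invisible(path)
}

read_cube_hdf5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  contents <- rhdf5::h5ls(path)$name
  if (!"wavelengths" %in% contents)
    stop("HDF5 file missing required 'wavelengths' dataset: ", path)
  if (!"data" %in% contents)
    stop("HDF5 file missing required 'data' dataset: ", path)
  data <- rhdf5::h5read(path, "data")
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths"))
  kind <- if ("kind" %in% contents) as.character(rhdf5::h5read(path, "kind")) else "transmittance"
  hypercube(data, wl, kind)
}

write_cube_hdf5 <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$data, path, "data")
  rhdf5::h5write(cube$wavelengths, path, "wavelengths")
  rhdf5::h5write(cube$kind, path, "kind")
  rhdf5::h5closeAll()
}

envi_paths <- function(path) {
  if (grepl("\\.hdr$", path)) list(hdr = path, bin = sub("\\.hdr$", "", path))
  else list(hdr = paste0(path, ".hdr"), bin = path)
}

read_cube_envi <- function(path) {
  p <- envi_paths(path)
  if (!file.exists(p$hdr)) stop("ENVI header not found: ", p$hdr)
  if (!file.exists(p$bin)) stop("ENVI binary not found: ", p$bin)
  txt <- paste(readLines(p$hdr, warn = FALSE), collapse = "\n")
  fld <- function(name) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", name, "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  blk <- function(name) {
    m <- regmatches(txt, regexec(paste0("(?si)", name, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(gsub("\\s", "", m[2]), ",")[[1]])
  }
  lines_ <- as.integer(fld("lines")); samples <- as.integer(fld("samples"))
  bands <- as.integer(fld("bands")); dtype <- as.integer(fld("data type"))
  interleave <- tolower(fld("interleave"))
  wl <- blk("wavelength")
  if (is.null(wl)) stop("ENVI header missing required 'wavelength' field: ", p$hdr)
  if (anyNA(c(lines_, samples, bands))) stop("ENVI header missing dimensions: ", p$hdr)
  if (!identical(interleave, "bsq")) stop("only BSQ interleave supported, got: ", interleave)
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype))
  n <- lines_ * samples * bands
  raw_vals <- readBin(p$bin, "double", n = n, size = size, endian = "little")
  if (length(raw_vals) != n)
    stop("ENVI binary size mismatch: expected ", n, " values, got ", length(raw_vals))
  kind <- fld("description")
  kind <- if (!is.na(kind) && grepl("raw_counts", kind)) "raw_counts" else "transmittance"
  # BSQ: band-sequential, each band stored row-major (samples fastest)
  arr <- aperm(array(raw_vals, c(samples, lines_, bands)), c(2, 1, 3))
  hypercube(arr, wl, kind)
}

write_cube_envi <- function(cube, path) {
  p <- envi_paths(path)
  d <- dim(cube$data)
  hdr <- c("ENVI",
           sprintf("description = {hsipath cube, kind=%s}", cube$kind),
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = Nanometers",
           sprintf("wavelength = {%s}", paste(sprintf("%.17g", cube$wavelengths),
                                              collapse = ", ")))
  writeLines(hdr, p$hdr)
  con <- file(p$bin, "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(cube$data, c(2, 1, 3))), con, size = 8L,
           endian = "little")
}
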