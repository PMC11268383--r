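#' Head-average and identity-mix one layer's attention maps
#'
#' Averages the per-head attention matrices, then forms the convex
#' combination `0.5 * mean + 0.5 * I` and renormalizes rows, yielding a
#' row-stochastic layer matrix that accounts for the residual path.
#'
#' @param heads per-head attention: a `seq x seq x n_heads` array or a list
#'   of `seq x seq` matrices, each row-stochastic.
#' @return row-stochastic `seq x seq` matrix.
#' @export
layer_mix <- function(heads) {
  if (is.list(heads)) heads <- simplify2array(heads)
  if (length(dim(heads)) == 2) heads <- array(heads, c(dim(heads), 1))
  m <- apply(heads, c(1, 2), mean)
  m <- 0.5 * m + 0.5 * diag(nrow(m))
  m / rowSums(m)
}

#' Attention rollout: chain layer matrices into token relevance
#'
#' Multiplies the identity-mixed layer matrices in order, layer 1 through
#' depth. Each factor is row-stochastic, so the product is too: row `i` of
#' the result distributes token `i`'s final-layer attention over input
#' tokens.
#'
#' @param mats list of square row-stochastic matrices, equal sizes.
#' @return the rollout matrix.
#' @export
rollout <- function(mats) {
  stopifnot(length(mats) >= 1)
  n <- nrow(mats[[1]])
  for (m in mats) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("all rollout layers must be square matrices of the same size")
  }
  Reduce(`%*%`, mats)
}

#' Build a spatial heatmap from a rollout matrix
#'
#' Takes the class-token row of the rollout, drops the class-token column,
#' reshapes the remaining weights onto the token grid (row-major) and
#' min-max scales to `[0, 1]`. A constant map carries no contrast and is
#' returned as zeros with a warning. When per-band weights are supplied the
#' grid map is replicated across bands and modulated by them before
#' scaling.
#'
#' @param R rollout matrix.
#' @param grid_shape `c(rows, cols)` of the token grid.
#' @param cls_index row/column index of the class token (default 1).
#' @param band_weights optional per-band nonnegative weights.
#' @return `rows x cols` matrix, or `rows x cols x B` array when
#'   `band_weights` is given, values in `[0, 1]`.
#' @export
heatmap_from_rollout <- function(R, grid_shape, cls_index = 1,
                                 band_weights = NULL) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  w <- R[cls_index, -cls_index]
  if (length(w) != prod(grid_shape))
    stop("rollout size does not match the grid shape")
  map <- matrix(w, grid_shape[1], grid_shape[2], byrow = TRUE)
  scale01 <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) {
      warning("constant attention map; returning zeros")
      return(x * 0)
    }
    (x - rng[1]) / diff(rng)
  }
  if (is.null(band_weights)) return(scale01(map))
  stopifnot(all(band_weights >= 0))
  out <- array(0, c(grid_shape, length(band_weights)))
  for (b in seq_along(band_weights)) out[, , b] <- map * band_weights[b]
  scale01(out)
}

#' Per-band attention-rollout heatmaps for one cube
#'
#' Runs the model with attention capture and rolls out the spatial
#' attention stream separately for every band: per layer and band, the
#' per-head spatial maps are head-averaged and identity-mixed
#' ([layer_mix]), then chained across layers ([rollout]); the class-token
#' row gives that band's spatial map. The factorized architecture has a
#' second, spectral stream that the class token never joins; its rollout
#' cannot be read out at the class token directly, so each band's map is
#' weighted by the mean spectral-attention mass that band receives
#' (head-averaged, over all positions and layers). The stack is min-max
#' scaled to `[0, 1]` jointly.
#'
#' @param model an `hsi_model`.
#' @param cube a `hypercube` matching the model configuration.
#' @return list with `heatmap` (`grid x grid x B`, in `[0, 1]`),
#'   `per_band_maps` (unscaled class-token maps), `band_weights` and
#'   `probs` (the classifier output for the same forward pass).
#' @export
attention_rollout <- function(model, cube) {
  fw <- model_forward(model, cube, capture = TRUE)
  lay <- model$layout
  depth <- model$cfg$depth
  g <- lay$grid
  maps <- array(0, c(g, g, lay$B))
  for (b in seq_len(lay$B)) {
    chain <- lapply(seq_len(depth), function(l)
      layer_mix(fw$attn$spatial[[l]][[b]]))
    R <- rollout(chain)
    w <- R[1, -1]                       # class token is group element 1
    maps[, , b] <- matrix(w, g, g, byrow = TRUE)
  }
  # spectral mass received by each band: head-averaged column mass of the
  # spectral attention maps, averaged over positions and layers
  wband <- numeric(lay$B)
  for (l in seq_len(depth)) {
    for (n in seq_len(lay$N)) {
      A <- apply(fw$attn$spectral[[l]][[n]], c(1, 2), mean)
      wband <- wband + colSums(A)
    }
  }
  wband <- wband / (depth * lay$N)      # mean incoming mass per band
  wband <- wband / max(wband)
  heat <- maps
  for (b in seq_len(lay$B)) heat[, , b] <- maps[, , b] * wband[b]
  rng <- range(heat)
  heat <- if (diff(rng) < 1e-12) heat * 0 else (heat - rng[1]) / diff(rng)
  list(heatmap = heat, per_band_maps = maps, band_weights = wband,
       probs = fw$probs)
}
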