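#' Configuration of the spectral-spatial transformer
#'
#' The classifier factorizes self-attention over a hypercube into a
#' spectral stream (tokens at the same spatial position attend across
#' bands) and a spatial stream (tokens in the same band attend across
#' positions), alternating inside every block. The default configuration
#' is the full-size network (224 px, 84 bands, 12 blocks);
#' [tiny_model_config] is small enough to train on a CPU in minutes.
#'
#' @param image_px input side length; must be divisible by `patch_px`.
#' @param patch_px square patch side for tokenization.
#' @param n_bands number of spectral bands.
#' @param embed_dim token embedding width; divisible by `n_heads`.
#' @param n_heads attention heads per stream.
#' @param depth number of divided-attention blocks.
#' @param n_classes output classes.
#' @param dropout residual dropout probability (training mode only).
#' @param band_pos use a learnable band ("temporal") positional embedding.
#' @param input_center,input_scale input standardization applied before the
#'   patch embedding, `(x - center) / scale`. The defaults approximate the
#'   mean and spread of H&E transmittance (bright background near 1, stained
#'   tissue below); standardized inputs carry the tissue contrast at unit
#'   order, which is what lets the network train from random initialization.
#'   Set `center = 0, scale = 1` to embed raw values.
#' @param init_seed seed for parameter initialization.
#' @return list of class `model_config`.
#' @export
model_config <- function(image_px = 224, patch_px = 16, n_bands = 84,
                         embed_dim = 768, n_heads = 12, depth = 12,
                         n_classes = 2, dropout = 0, band_pos = TRUE,
                         input_center = 0.9, input_scale = 0.15,
                         init_seed = 0) {
  if (image_px %% patch_px != 0) stop("image_px must be divisible by patch_px")
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  stopifnot(depth >= 1, n_classes >= 2, dropout >= 0, dropout < 1,
            input_scale > 0)
  structure(list(image_px = image_px, patch_px = patch_px, n_bands = n_bands,
                 embed_dim = embed_dim, n_heads = n_heads, depth = depth,
                 n_classes = n_classes, dropout = dropout,
                 band_pos = band_pos, input_center = input_center,
                 input_scale = input_scale, init_seed = init_seed),
            class = "model_config")
}

#' @rdname model_config
#' @param ... further arguments passed to [model_config].
#' @export
tiny_model_config <- function(image_px = 56, patch_px = 8, n_bands = 8,
                              embed_dim = 64, n_heads = 4, depth = 2, ...) {
  model_config(image_px = image_px, patch_px = patch_px, n_bands = n_bands,
               embed_dim = embed_dim, n_heads = n_heads, depth = depth, ...)
}

# static token layout: band-major token rows (position fastest), class
# token last.
model_layout <- function(cfg) {
  g <- cfg$image_px %/% cfg$patch_px
  N <- g * g
  B <- cfg$n_bands
  p <- cfg$patch_px
  # linear indices (into an image_px x image_px matrix) of each token's pixels
  patch_idx <- matrix(0L, N, p * p)
  for (r in seq_len(g)) for (cc in seq_len(g)) {
    n <- (r - 1L) * g + cc
    rows <- (r - 1L) * p + seq_len(p)
    cols <- (cc - 1L) * p + seq_len(p)
    patch_idx[n, ] <- as.integer(outer(rows, (cols - 1L) * cfg$image_px, "+"))
  }
  list(grid = g, N = N, B = B, T = B * N + 1L, patch_idx = patch_idx)
}

model_dims <- function(model, S) {
  cfg <- model$cfg
  lay <- model$layout
  list(S = as.integer(S), N = lay$N, B = lay$B, D = cfg$embed_dim,
       heads = cfg$n_heads, depth = cfg$depth, p2 = cfg$patch_px^2,
       n_classes = cfg$n_classes, band_pos = isTRUE(cfg$band_pos))
}

init_block_params <- function(D) {
  lin <- function(din, dout) list(W = matrix(trunc_norm(din * dout), din, dout),
                                  b = numeric(dout))
  list(ln1_g = rep(1, D), ln1_b = numeric(D),
       spe_q = lin(D, D), spe_k = lin(D, D), spe_v = lin(D, D), spe_o = lin(D, D),
       ln2_g = rep(1, D), ln2_b = numeric(D),
       spa_q = lin(D, D), spa_k = lin(D, D), spa_v = lin(D, D), spa_o = lin(D, D),
       ln3_g = rep(1, D), ln3_b = numeric(D),
       mlp1 = lin(D, 4 * D), mlp2 = lin(4 * D, D))
}

#' Build a model with freshly initialized parameters
#'
#' Weights are truncated-normal (sd 0.02), biases zero, layer-norm gains
#' one; the draw is governed by `cfg$init_seed`. An optional nested list of
#' arrays (`weights`) overrides matching parameters, which serves as the
#' import hook for externally trained checkpoints.
#'
#' @param cfg a [model_config].
#' @param weights optional named list of parameter overrides (names as in
#'   `model$params`, nested lists allowed).
#' @return list of class `hsi_model` with `cfg`, `params`, `layout`.
#' @export
make_model <- function(cfg, weights = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  lay <- model_layout(cfg)
  D <- cfg$embed_dim
  params <- with_seed(cfg$init_seed, {
    p <- list(
      embed_W = matrix(trunc_norm(cfg$patch_px^2 * D), cfg$patch_px^2, D),
      embed_b = numeric(D),
      pos_spatial = matrix(trunc_norm(lay$N * D), lay$N, D),
      cls = trunc_norm(D),
      blocks = lapply(seq_len(cfg$depth), function(i) init_block_params(D)),
      lnf_g = rep(1, D), lnf_b = numeric(D),
      head_W = matrix(trunc_norm(D * cfg$n_classes), D, cfg$n_classes),
      head_b = numeric(cfg$n_classes))
    if (cfg$band_pos) p$pos_band <- matrix(trunc_norm(lay$B * D), lay$B, D)
    p
  })
  if (!is.null(weights)) params <- utils::modifyList(params, weights)
  structure(list(cfg = cfg, params = params, layout = lay),
            class = "hsi_model")
}

#' @export
print.hsi_model <- function(x, ...) {
  cat(sprintf(
    "<hsi_model> %d blocks, embed %d, %d heads, %d bands, %d px (%d tokens), %s parameters\n",
    x$cfg$depth, x$cfg$embed_dim, x$cfg$n_heads, x$cfg$n_bands,
    x$cfg$image_px, x$layout$N, format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an `hsi_model`.
#' @return integer count.
#' @export
n_params <- function(model) {
  s <- 0L
  walk <- function(x) for (el in x) {
    if (is.list(el)) walk(el) else s <<- s + length(el)
  }
  walk(model$params)
  s
}

addb <- function(M, b) M + rep(b, each = nrow(M))

# stacked patch matrix for a batch: rows ordered (sample, band, position),
# position fastest; columns are the patch pixels.
build_patch_matrix <- function(model, cubes) {
  cfg <- model$cfg
  lay <- model$layout
  S <- length(cubes)
  P <- matrix(0, S * lay$B * lay$N, cfg$patch_px^2)
  for (s in seq_len(S)) {
    d <- dim(cubes[[s]]$data)
    if (d[1] != cfg$image_px || d[2] != cfg$image_px || d[3] != cfg$n_bands)
      stop(sprintf("cube %dx%dx%d does not match config %dx%dx%d",
                   d[1], d[2], d[3], cfg$image_px, cfg$image_px, cfg$n_bands))
    for (b in seq_len(lay$B)) {
      rr <- ((s - 1L) * lay$B + (b - 1L)) * lay$N + seq_len(lay$N)
      P[rr, ] <- cubes[[s]]$data[, , b][lay$patch_idx]
    }
  }
  (P - cfg$input_center) / cfg$input_scale
}

# residual-dropout masks for one batch (train mode with dropout > 0)
make_drop_masks <- function(model, n_rows) {
  p <- model$cfg$dropout
  D <- model$cfg$embed_dim
  one <- function() matrix(stats::rbinom(n_rows * D, 1, 1 - p) / (1 - p),
                           n_rows, D)
  lapply(seq_len(model$cfg$depth), function(l)
    list(m1 = one(), m2 = one(), m3 = one()))
}

# Batched forward pass over a list of cubes (compiled core).
forward_batch <- function(model, cubes, train = FALSE, capture = FALSE) {
  S <- length(cubes)
  P <- build_patch_matrix(model, cubes)
  masks <- if (train && model$cfg$dropout > 0)
    make_drop_masks(model, S * model$layout$B * model$layout$N + S)
  .cpp_forward(P, model$params, model_dims(model, S), masks, capture)
}

# Batched loss + batch-averaged gradients for one minibatch.
backward_batch <- function(model, cubes, ys, train = FALSE) {
  S <- length(cubes)
  stopifnot(length(ys) == S)
  P <- build_patch_matrix(model, cubes)
  masks <- if (train && model$cfg$dropout > 0)
    make_drop_masks(model, S * model$layout$B * model$layout$N + S)
  out <- .cpp_backward(P, model$params, model_dims(model, S),
                       as.integer(ys), masks)
  out$grads <- match_shapes(out$grads, model$params)
  out
}

# the compiled core returns vector gradients as n x 1 matrices; restore the
# shapes of the corresponding parameters so updates preserve them
match_shapes <- function(g, p) {
  for (nm in names(p)) {
    if (is.list(p[[nm]])) g[[nm]] <- match_shapes(g[[nm]], p[[nm]])
    else if (is.null(dim(p[[nm]]))) g[[nm]] <- as.numeric(g[[nm]])
  }
  g
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d)) V` with `d = ncol(Q)`,
#' the head dimension. The row-stochastic attention matrix is returned
#' alongside the output so it can be captured for rollout.
#'
#' @param Q,K,V conformable numeric matrices (rows = tokens).
#' @return list with `output` and `attention`.
#' @export
scaled_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  A <- row_softmax(tcrossprod(Q, K) / sqrt(ncol(Q)))
  list(output = A %*% V, attention = A)
}

#' Tokenize a hypercube into embedded patch tokens
#'
#' Each band is cut into the same non-overlapping patch grid; one shared
#' linear projection (the "convolutional kernel") embeds every patch, the
#' spatial positional embedding is shared across bands, the optional band
#' positional embedding is shared across positions, and a learnable class
#' token is appended as the last row.
#'
#' @param model an `hsi_model`.
#' @param cube a `hypercube` matching the configuration.
#' @return `(B*N + 1) x embed_dim` token matrix (band-major rows, class
#'   token last).
#' @export
embed_patches <- function(model, cube) {
  lay <- model$layout
  p <- model$params
  P <- build_patch_matrix(model, list(cube))
  X <- matrix(0, lay$T, model$cfg$embed_dim)
  X[seq_len(lay$B * lay$N), ] <- addb(P %*% p$embed_W, p$embed_b) +
    p$pos_spatial[rep(seq_len(lay$N), lay$B), , drop = FALSE]
  if (model$cfg$band_pos)
    X[seq_len(lay$B * lay$N), ] <- X[seq_len(lay$B * lay$N), ] +
      p$pos_band[rep(seq_len(lay$B), each = lay$N), , drop = FALSE]
  X[lay$T, ] <- p$cls
  X
}

#' Run one divided-attention block
#'
#' Applies, with pre-norm residuals: spectral attention (tokens at the same
#' spatial position attend across bands; the class token bypasses this
#' stream), then spatial attention (tokens in the same band attend across
#' positions, class token included and its head outputs averaged over
#' bands), then the 4x GELU feed-forward sub-layer.
#'
#' @param model an `hsi_model`.
#' @param tokens token matrix from [embed_patches].
#' @param layer block index in `1:depth`.
#' @return updated token matrix.
#' @export
divided_attention_block <- function(model, tokens, layer = 1L) {
  stopifnot(layer >= 1, layer <= model$cfg$depth)
  .cpp_block_forward(tokens, model$params$blocks[[layer]],
                     model_dims(model, 1L))
}

#' Forward pass of the classifier
#'
#' Embeds the cube, runs all divided-attention blocks, layer-normalizes the
#' class token and applies the linear head. Deterministic in evaluation
#' mode (`train = FALSE`, the default).
#'
#' @param model an `hsi_model`.
#' @param cube a `hypercube` matching the configuration.
#' @param capture also return per-layer attention matrices (head-resolved:
#'   `attn$spatial[[layer]][[band]]` is `(N+1) x (N+1) x heads` with the
#'   class token first; `attn$spectral[[layer]][[position]]` is
#'   `B x B x heads`).
#' @param train training mode: applies residual dropout when
#'   `cfg$dropout > 0`.
#' @return list with `logits`, `probs`, and optionally `attn`.
#' @export
model_forward <- function(model, cube, capture = FALSE, train = FALSE) {
  fw <- forward_batch(model, list(cube), train = train, capture = capture)
  out <- list(logits = as.numeric(fw$logits), probs = as.numeric(fw$probs))
  if (capture) out$attn <- fw$attn
  out
}

#' Class probabilities for one cube
#'
#' @param model an `hsi_model`.
#' @param cube a `hypercube`.
#' @return numeric vector of length `n_classes`, summing to 1
#'   (`c(normal, cancer)` for the default two-class setup).
#' @export
forward_classify <- function(model, cube) {
  model_forward(model, cube)$probs
}

# Single-sample convenience wrapper; `y` is the 1-based true class.
model_backward <- function(model, cube, y, train = FALSE) {
  bw <- backward_batch(model, list(cube), y, train = train)
  bw$probs <- as.numeric(bw$probs)
  bw
}
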