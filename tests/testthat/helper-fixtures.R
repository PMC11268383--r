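# small deterministic fixtures shared across the suite

wl8 <- seq(467, 721, length.out = 8)

rand_cube <- function(h = 6, w = 6, b = 4, seed = 1,
                      kind = "transmittance") {
  set.seed(seed)
  hypercube(array(runif(h * w * b), c(h, w, b)),
            seq(467, 721, length.out = b), kind)
}

const_cube <- function(value, h = 6, w = 6, b = 4) {
  hypercube(array(value, c(h, w, b)), seq(467, 721, length.out = b),
            "transmittance")
}

micro_model <- function(depth = 2, band_pos = TRUE, init_seed = 4) {
  make_model(model_config(image_px = 8, patch_px = 4, n_bands = 3,
                          embed_dim = 8, n_heads = 2, depth = depth,
                          band_pos = band_pos, init_seed = init_seed))
}

micro_cube <- function(seed = 1) {
  set.seed(seed)
  hypercube(array(runif(8 * 8 * 3), c(8, 8, 3)), c(500, 600, 700),
            "transmittance")
}
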