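test_that("token grids follow the configuration arithmetic", {
  expect_equal(hsipath:::model_layout(model_config())$N, 196L)
  expect_equal(hsipath:::model_layout(
    model_config(image_px = 56, patch_px = 8, n_bands = 8))$N, 49L)
  expect_error(model_config(image_px = 224, patch_px = 15), "divisible")
  expect_error(model_config(embed_dim = 65, n_heads = 4), "divisible")
})

test_that("scaled attention equals a per-pair brute-force oracle", {
  oracle <- function(Q, K, V) {
    n <- nrow(Q); m <- nrow(K); d <- ncol(Q)
    A <- matrix(0, n, m)
    for (i in seq_len(n)) {
      sc <- numeric(m)
      for (j in seq_len(m)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
      e <- exp(sc - max(sc))
      A[i, ] <- e / sum(e)
    }
    list(output = A %*% V, attention = A)
  }
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(2:8, 1); d <- sample(c(2, 4, 8), 1)
    Q <- matrix(rnorm(n * d), n); K <- matrix(rnorm(n * d), n)
    V <- matrix(rnorm(n * d), n)
    got <- scaled_attention(Q, K, V)
    want <- oracle(Q, K, V)
    expect_equal(got$output, want$output, tolerance = 1e-5)
    expect_equal(got$attention, want$attention, tolerance = 1e-5)
    expect_equal(rowSums(got$attention), rep(1, n), tolerance = 1e-6)
    expect_true(all(got$attention >= 0))
  }
  # single token: attention is [[1]] and the value passes through
  one <- scaled_attention(matrix(1, 1, 4), matrix(2, 1, 4), matrix(3, 1, 4))
  expect_equal(one$attention, matrix(1, 1, 1))
  expect_equal(one$output, matrix(3, 1, 4))
  # equal scores average the value rows
  eq <- scaled_attention(matrix(0, 2, 3), matrix(rnorm(6), 2, 3),
                         rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(eq$output, rbind(c(.5, .5, 0), c(.5, .5, 0)), tolerance = 1e-12)
})

test_that("the parameter count matches the closed-form expression", {
  cfg <- tiny_model_config()
  m <- make_model(cfg)
  D <- cfg$embed_dim
  N <- (cfg$image_px / cfg$patch_px)^2
  closed <- cfg$patch_px^2 * D + D +          # patch embedding
    N * D + cfg$n_bands * D + D +             # positional + class
    cfg$depth * (3 * 2 * D +                  # three layer norms
                 2 * 4 * (D^2 + D) +          # two attention streams (QKVO)
                 D * 4 * D + 4 * D + 4 * D * D + D) +  # feed-forward
    2 * D + D * cfg$n_classes + cfg$n_classes # final norm + head
  expect_equal(n_params(m), as.integer(closed))
})

test_that("probabilities normalize and eval mode is deterministic", {
  m <- micro_model()
  cb <- micro_cube()
  p1 <- forward_classify(m, cb)
  p2 <- forward_classify(m, cb)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, p2)
  expect_error(model_forward(m, rand_cube(6, 6, 3)), "does not match")
})

test_that("a zero cube embeds to the standardized-zero projection plus bias and position", {
  m <- micro_model()
  z <- hypercube(array(0, c(8, 8, 3)), c(500, 600, 700), "transmittance")
  X <- embed_patches(m, z)
  p <- m$params
  pz <- rep((0 - m$cfg$input_center) / m$cfg$input_scale, 16)
  want <- as.numeric(pz %*% p$embed_W) + p$embed_b + p$pos_spatial[1, ] +
    p$pos_band[1, ]
  expect_equal(X[1, ], want, tolerance = 1e-12)
  expect_equal(X[nrow(X), ], p$cls)
  # without standardization the tokens are exactly bias + positional terms
  m0 <- make_model(model_config(image_px = 8, patch_px = 4, n_bands = 3,
                                embed_dim = 8, n_heads = 2, depth = 2,
                                input_center = 0, input_scale = 1,
                                init_seed = 4))
  X0 <- embed_patches(m0, z)
  expect_equal(X0[1, ], m0$params$embed_b + m0$params$pos_spatial[1, ] +
                 m0$params$pos_band[1, ], tolerance = 1e-12)
})

test_that("spectral attention is uniform when bands are identical", {
  # band positional encoding off: identical bands give identical tokens
  m <- micro_model(band_pos = FALSE)
  set.seed(4)
  one <- matrix(runif(64), 8, 8)
  cb <- hypercube(array(one, c(8, 8, 3)), c(500, 600, 700), "transmittance")
  fw <- model_forward(m, cb, capture = TRUE)
  A <- fw$attn$spectral[[1]][[2]]      # position 2, layer 1: B x B x heads
  expect_equal(max(abs(A - 1 / 3)), 0, tolerance = 1e-6)
  # spatial attention rows always sum to one
  S <- fw$attn$spatial[[2]][[1]]
  for (h in seq_len(dim(S)[3]))
    expect_equal(rowSums(S[, , h]), rep(1, nrow(S)), tolerance = 1e-6)
})

test_that("band permutation leaves the output invariant without band encoding", {
  m <- micro_model(band_pos = FALSE)
  cb <- micro_cube(seed = 8)
  perm <- c(3, 1, 2)
  cb_p <- hypercube(cb$data[, , perm], sort(cb$wavelengths), "transmittance")
  out <- model_forward(m, cb)$logits
  out_p <- model_forward(m, cb_p)$logits
  expect_equal(out, out_p, tolerance = 1e-8)
  # with the band encoding on, permutation does change the output
  m2 <- micro_model(band_pos = TRUE)
  expect_gt(max(abs(model_forward(m2, cb)$logits -
                    model_forward(m2, cb_p)$logits)), 1e-6)
})

test_that("analytic gradients match central finite differences", {
  m <- micro_model()
  cb1 <- micro_cube(seed = 1)
  cb2 <- micro_cube(seed = 2)
  ys <- c(2L, 1L)
  bw <- hsipath:::backward_batch(m, list(cb1, cb2), ys)
  get_par <- function(p, path) { for (k in path) p <- p[[k]]; p }
  set_par <- function(p, path, v) {
    if (length(path) == 1) { p[[path[[1]]]] <- v; return(p) }
    p[[path[[1]]]] <- set_par(p[[path[[1]]]], path[-1], v)
    p
  }
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    fw <- hsipath:::forward_batch(m2, list(cb1, cb2))
    -mean(log(fw$probs[cbind(1:2, ys)]))
  }
  paths <- list(list("embed_W"), list("pos_spatial"), list("pos_band"),
                list("cls"), list("blocks", 1L, "spe_q", "W"),
                list("blocks", 1L, "spa_o", "W"),
                list("blocks", 2L, "mlp1", "W"), list("blocks", 2L, "ln3_b"),
                list("lnf_g"), list("head_W"))
  eps <- 1e-5
  set.seed(9)
  for (pa in paths) {
    P <- get_par(m$params, pa)
    G <- get_par(bw$grads, pa)
    for (i in sample(length(P), min(3, length(P)))) {
      Pp <- P; Pp[i] <- P[i] + eps
      Pm <- P; Pm[i] <- P[i] - eps
      num <- (loss_at(set_par(m$params, pa, Pp)) -
                loss_at(set_par(m$params, pa, Pm))) / (2 * eps)
      expect_equal(as.numeric(G[i]), num, tolerance = 1e-4,
                   label = paste(unlist(pa), collapse = "/"))
    }
  }
})

test_that("batched and per-sample forwards agree exactly", {
  m <- micro_model()
  cubes <- lapply(1:3, micro_cube)
  fb <- hsipath:::forward_batch(m, cubes)
  for (i in 1:3)
    expect_equal(as.numeric(fb$logits[i, ]), model_forward(m, cubes[[i]])$logits,
                 tolerance = 1e-12)
})

test_that("divided_attention_block transforms tokens shape-preservingly", {
  m <- micro_model()
  X <- embed_patches(m, micro_cube())
  Y <- divided_attention_block(m, X, 1L)
  expect_identical(dim(Y), dim(X))
  expect_gt(max(abs(Y - X)), 0)
  # a checkpoint import hook round-trip: weights override is honored
  m2 <- make_model(m$cfg, weights = list(cls = rep(0.5, 8)))
  expect_equal(m2$params$cls, rep(0.5, 8))
})

test_that("non-finite activations are reported with the failing block", {
  m <- micro_model()
  m$params$blocks[[2]]$mlp1$W[1, 1] <- Inf
  expect_error(model_forward(m, micro_cube()), "block 2")
})
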