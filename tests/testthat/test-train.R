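test_that("the step schedule halves the learning rate every five epochs", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(cfg, 0), 1e-3)
  expect_identical(lr_at_epoch(cfg, 4), 1e-3)
  expect_identical(lr_at_epoch(cfg, 5), 5e-4)
  expect_identical(lr_at_epoch(cfg, 14), 2.5e-4)
  expect_equal(vapply(0:14, function(e) lr_at_epoch(cfg, e), 0),
               1e-3 * 0.5^(0:14 %/% 5))
  expect_error(lr_at_epoch(cfg, 15))
})

make_manifest <- function(n_patients = 12, per_patient = 6) {
  data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)),
                     each = per_patient),
    label = rep(rep(c("cancer", "normal"), each = per_patient),
                n_patients / 2),
    stringsAsFactors = FALSE)
}

test_that("patient splits are disjoint, deterministic and stratified", {
  man <- make_manifest()
  sp <- split_by_patient(man, c(.5, .25, .25), seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(man))
  pats <- lapply(sp, function(d) unique(d$patient_id))
  expect_length(intersect(pats$train, pats$val), 0L)
  expect_length(intersect(pats$train, pats$test), 0L)
  expect_length(intersect(pats$val, pats$test), 0L)
  sp2 <- split_by_patient(man, c(.5, .25, .25), seed = 3)
  expect_identical(sp, sp2)
  # class proportions near the global 50/50 in every split
  for (d in sp)
    expect_lt(abs(mean(d$label == "cancer") - 0.5), 0.21)
  expect_error(split_by_patient(man[man$patient_id %in% c("P01", "P02"), ]),
               "fewer patients")
})

# a very small but real training problem: distinguishable classes on a
# micro model so the optimization tests stay fast
micro_problem <- function(n_per_class = 8, seed = 5) {
  cfg <- scene_config(patch_px = 28, n_bands = 4, n_nuclei = 12,
                      nucleus_radius = c(2, 3), follicle_radius = c(6, 9),
                      ring_width = 2, seed = seed)
  ds <- make_dataset(n_per_class, cfg, seed = seed, patients_block = 4)
  dataset_from(ds$cubes, ds$manifest$label)
}

micro_train_model <- function(init_seed = 2) {
  make_model(model_config(image_px = 28, patch_px = 7, n_bands = 4,
                          embed_dim = 32, n_heads = 4, depth = 2,
                          init_seed = init_seed))
}

test_that("a 16-sample overfit run drives the loss below 0.1", {
  data <- micro_problem(8)
  m <- micro_train_model()
  state <- NULL
  cfg <- train_config(optimizer = "adam")
  losses <- numeric(0)
  for (step in seq_len(200)) {
    bw <- hsipath:::backward_batch(m, data$x, data$y, train = TRUE)
    st <- hsipath:::optim_step(cfg, m$params, bw$grads, state, 1e-3)
    m$params <- st$p
    state <- st$state
    losses[step] <- bw$loss
    if (bw$loss < 0.1) break
  }
  expect_lt(min(losses), 0.1)
})

test_that("training logs the schedule, selects the best-F1 checkpoint and is reproducible", {
  tr <- micro_problem(8, seed = 11)
  va <- micro_problem(4, seed = 12)
  cfg <- train_config(epochs = 6, batch_size = 8, optimizer = "adam",
                      lr0 = 1e-3, seed = 4)
  m <- micro_train_model()
  fit <- train_model(m, tr, va, cfg)
  expect_equal(nrow(fit$log), 6L)
  expect_equal(fit$log$lr, vapply(0:5, function(e) lr_at_epoch(cfg, e), 0))
  # checkpoint-selection invariant (ties -> earliest epoch)
  expect_equal(fit$best_epoch,
               fit$log$epoch[which.max(fit$log$val_f1)])
  expect_false(fit$diverged)
  # end-to-end seeded determinism
  fit2 <- train_model(micro_train_model(), tr, va, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$model$params$head_W, fit2$model$params$head_W)
})

test_that("training runs with augmentation enabled and logs every epoch", {
  tr <- micro_problem(6, seed = 21)
  va <- micro_problem(3, seed = 22)
  cfg <- train_config(epochs = 2, batch_size = 6, optimizer = "adam",
                      augment = TRUE, seed = 9)
  fit <- train_model(micro_train_model(), tr, va, cfg,
                     ranges = transform_ranges())
  expect_equal(nrow(fit$log), 2L)
  expect_true(all(is.finite(fit$log$train_loss)))
  # the same augmented run is bit-reproducible
  fit2 <- train_model(micro_train_model(), tr, va, cfg)
  expect_identical(fit$log, fit2$log)
})

test_that("label coding maps cancer to the positive class", {
  expect_identical(hsipath:::label_index(c("normal", "cancer")), c(1L, 2L))
  expect_identical(hsipath:::label_index(c(0, 1, 1)), c(1L, 2L, 2L))
  d <- dataset_from(list(micro_cube()), "cancer")
  expect_identical(d$y, 2L)
})
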