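# Memoized scaled-down training experiment shared by the learnability and
# schedule acceptance checks: 400 synthetic patches, patient-stratified
# 200/100/100 split, tiny spectral-spatial transformer trained 20 epochs
# with the SGD + Nesterov protocol.
learn_cache <- new.env(parent = emptyenv())

get_learn_fit <- function() {
  if (!is.null(learn_cache$fit)) return(learn_cache$fit)
  ds <- make_dataset(200, scene_config(), seed = 101)
  sp <- split_by_patient(ds$manifest, c(.5, .25, .25), seed = 7)
  key <- function(man) paste(man$patient_id, man$grid_col, man$label)
  pick <- function(man) match(key(man), key(ds$manifest))
  tr <- dataset_from(ds$cubes[pick(sp$train)], sp$train$label)
  va <- dataset_from(ds$cubes[pick(sp$val)], sp$val$label)
  te <- dataset_from(ds$cubes[pick(sp$test)], sp$test$label)
  model <- make_model(tiny_model_config(init_seed = 1))
  cfg <- train_config(epochs = 20, optimizer = "sgd", augment = FALSE,
                      seed = 1)
  fit <- train_model(model, tr, va, cfg)
  fit$test_eval <- hsipath:::eval_model(fit$model, te)
  fit$sizes <- vapply(list(tr$x, va$x, te$x), length, 0L)
  learn_cache$fit <- fit
  fit
}
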