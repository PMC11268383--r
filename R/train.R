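#' Training configuration
#'
#' Mirrors the study protocol: SGD with Nesterov momentum 0.9, batch size
#' 16, initial learning rate 1e-3 halved every five epochs, 15 epochs, with
#' the checkpoint chosen at the epoch of maximum validation weighted F1.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr0 initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param augment apply [rand_augment] to training inputs.
#' @param optimizer `"sgd"` (stochastic gradient descent with Nesterov
#'   momentum, the study protocol for fine-tuning pretrained weights) or
#'   `"adam"` (adaptive moments; recommended when training from random
#'   initialization, where plain SGD is known to stall on transformers).
#' @param seed master seed for shuffling and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 15, batch_size = 16, lr0 = 1e-3,
                         momentum = 0.9, lr_decay = 0.5, decay_every = 5,
                         augment = FALSE, optimizer = c("sgd", "adam"),
                         seed = 0) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0, lr_decay > 0,
            lr_decay <= 1, decay_every >= 1)
  optimizer <- match.arg(optimizer)
  structure(list(epochs = epochs, batch_size = batch_size, lr0 = lr0,
                 momentum = momentum, lr_decay = lr_decay,
                 decay_every = decay_every, augment = augment,
                 optimizer = optimizer, seed = seed),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' `lr0 * lr_decay^floor(epoch / decay_every)` — a step schedule that halves
#' the rate every five epochs at the defaults.
#'
#' @param cfg a [train_config].
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  stopifnot(epoch >= 0, epoch < cfg$epochs)
  cfg$lr0 * cfg$lr_decay^(epoch %/% cfg$decay_every)
}

#' Patient-stratified dataset split
#'
#' Partitions records into train/validation/test with no patient appearing
#' in two splits. Patients are stratified by their majority label and
#' assigned, in seeded random order, to the split with the largest
#' remaining record deficit within their stratum, which keeps per-split
#' class proportions close to the global ones.
#'
#' @param manifest data.frame with columns `patient_id` and `label`.
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed RNG seed.
#' @return list of three manifests `train`, `val`, `test` (row subsets).
#' @export
split_by_patient <- function(manifest, fractions = c(0.5, 0.25, 0.25),
                             seed = 0) {
  stopifnot(all(c("patient_id", "label") %in% names(manifest)),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  patients <- unique(manifest$patient_id)
  if (length(patients) < 3) stop("fewer patients than splits")
  pat_label <- vapply(patients, function(p) {
    tab <- table(manifest$label[manifest$patient_id == p])
    names(tab)[which.max(tab)]
  }, character(1))
  pat_n <- vapply(patients, function(p) sum(manifest$patient_id == p),
                  numeric(1))
  assign <- setNames(integer(length(patients)), patients)
  with_seed(seed, {
    for (lab in sort(unique(pat_label))) {
      sel <- which(pat_label == lab)
      sel <- sel[sample.int(length(sel))]
      target <- fractions * sum(pat_n[sel])
      got <- numeric(3)
      for (i in sel) {
        k <- which.max(target - got)
        assign[i] <- k
        got[k] <- got[k] + pat_n[i]
      }
    }
  })
  split_of <- assign[match(manifest$patient_id, patients)]
  out <- list(train = manifest[split_of == 1, , drop = FALSE],
              val = manifest[split_of == 2, , drop = FALSE],
              test = manifest[split_of == 3, , drop = FALSE])
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

# label vector ("cancer"/"normal" or 0/1) -> 1-based class index (normal=1)
label_index <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels) + 1L)
  ifelse(labels == "cancer", 2L, 1L)
}

# SGD with Nesterov momentum (PyTorch semantics):
#   v <- mu * v + g ; theta <- theta - lr * (g + mu * v)
sgd_step <- function(params, grads, state, lr, mu) {
  step <- function(p, g, v) {
    if (is.list(p)) {
      if (is.null(v)) v <- vector("list", length(p))
      names(v) <- names(p)
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], v[[nm]])
        p[[nm]] <- r$p
        v[[nm]] <- r$v
      }
      return(list(p = p, v = v))
    }
    if (is.null(v)) v <- 0 * p
    v <- mu * v + g
    list(p = p - lr * (g + mu * v), v = v)
  }
  step(params, grads, state)
}

# Adam with bias correction (Kingma-Ba defaults for beta1/beta2)
adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) state <- list(t = 0, m = NULL, v = NULL)
  state$t <- state$t + 1
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  step <- function(p, g, mm, vv) {
    if (is.list(p)) {
      if (is.null(mm)) { mm <- vector("list", length(p)); names(mm) <- names(p) }
      if (is.null(vv)) { vv <- vector("list", length(p)); names(vv) <- names(p) }
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], mm[[nm]], vv[[nm]])
        p[[nm]] <- r$p; mm[[nm]] <- r$m; vv[[nm]] <- r$v
      }
      return(list(p = p, m = mm, v = vv))
    }
    if (is.null(mm)) mm <- 0 * p
    if (is.null(vv)) vv <- 0 * p
    mm <- b1 * mm + (1 - b1) * g
    vv <- b2 * vv + (1 - b2) * g^2
    list(p = p - lr * (mm / c1) / (sqrt(vv / c2) + eps), m = mm, v = vv)
  }
  r <- step(params, grads, state$m, state$v)
  list(p = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

optim_step <- function(cfg, params, grads, state, lr) {
  if (cfg$optimizer == "adam") {
    r <- adam_step(params, grads, state, lr)
    list(p = r$p, state = r$state)
  } else {
    r <- sgd_step(params, grads, state, lr, cfg$momentum)
    list(p = r$p, state = r$v)
  }
}

#' Bundle cubes and labels into a training dataset
#'
#' @param cubes list of `hypercube`s.
#' @param labels vector of `"cancer"`/`"normal"` strings or 0/1 integers
#'   (1 = cancer).
#' @return list with `x` (the cubes) and `y` (1-based class indices).
#' @export
dataset_from <- function(cubes, labels) {
  stopifnot(length(cubes) == length(labels))
  list(x = cubes, y = label_index(labels))
}

eval_model <- function(model, data, chunk = 32L) {
  n <- length(data$x)
  probs <- matrix(0, n, model$cfg$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    probs[idx, ] <- forward_batch(model, data$x[idx])$probs
  }
  pred <- max.col(probs) - 1L
  truth <- data$y - 1L
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), data$y)], 1e-12)))
  m <- classification_metrics(truth, pred, probs[, 2])
  list(loss = loss, metrics = m, pred = pred, scores = probs[, 2])
}

#' Train the classifier
#'
#' Minimizes unweighted cross-entropy with SGD + Nesterov momentum under
#' the step learning-rate schedule of [lr_at_epoch]. When `cfg$augment` is
#' on, each training cube is passed through [rand_augment] with a
#' per-sample child seed, so runs are reproducible end to end. After every
#' epoch the model is evaluated on the validation set; the returned
#' checkpoint is the epoch with the maximum validation weighted F1 (ties
#' resolved to the earliest epoch). A non-finite training loss aborts with
#' a warning, returning the log up to the last finite epoch.
#'
#' @param model an `hsi_model` (initial parameters).
#' @param train_data,val_data lists from [dataset_from]: `x` a list of
#'   `hypercube`s, `y` 1-based class indices.
#' @param cfg a [train_config].
#' @param ranges [transform_ranges] used when augmenting.
#' @param verbose print one line per epoch.
#' @return list with `model` (best checkpoint), `log` (one row per epoch:
#'   epoch, lr, train_loss, val_loss, val_accuracy, val_f1), `best_epoch`
#'   (0-based) and `diverged`.
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config(),
                        ranges = transform_ranges(), verbose = FALSE) {
  stopifnot(length(train_data$x) > 0, length(val_data$x) > 0,
            !anyNA(train_data$y), !anyNA(val_data$y))
  n <- length(train_data$x)
  state <- NULL
  log_rows <- list()
  best_f1 <- -Inf
  best_params <- model$params
  best_epoch <- NA_integer_
  diverged <- FALSE
  global_step <- 0L
  for (epoch in 0:(cfg$epochs - 1L)) {
    lr <- lr_at_epoch(cfg, epoch)
    ord <- with_seed((cfg$seed * 131L + epoch) %% 2147483647L, sample.int(n))
    epoch_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xs <- train_data$x[idx]
      if (cfg$augment) {
        for (j in seq_along(idx)) {
          child <- (cfg$seed * 1000003L + (global_step + j) * 7L + idx[j]) %%
            2147483647L
          xs[[j]] <- rand_augment(xs[[j]], ranges, seed = child)
        }
      }
      global_step <- global_step + length(idx)
      bw <- backward_batch(model, xs, train_data$y[idx], train = TRUE)
      bl <- bw$loss
      if (!is.finite(bl)) {
        warning("training diverged (non-finite loss) at epoch ", epoch)
        diverged <- TRUE
        break
      }
      st <- optim_step(cfg, model$params, bw$grads, state, lr)
      model$params <- st$p
      state <- st$state
      epoch_loss <- epoch_loss + bl
      nb <- nb + 1L
    }
    if (diverged) break
    ev <- eval_model(model, val_data)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = epoch_loss / max(nb, 1L),
      val_loss = ev$loss, val_accuracy = ev$metrics$accuracy,
      val_f1 = ev$metrics$weighted_f1)
    if (verbose)
      message(sprintf("epoch %2d lr %.2e train %.4f val %.4f acc %.3f f1 %.3f",
                      epoch, lr, epoch_loss / max(nb, 1L), ev$loss,
                      ev$metrics$accuracy, ev$metrics$weighted_f1))
    if (ev$metrics$weighted_f1 > best_f1) {
      best_f1 <- ev$metrics$weighted_f1
      best_params <- model$params
      best_epoch <- epoch
    }
  }
  model$params <- best_params
  list(model = model,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                    val_loss = numeric(), val_accuracy = numeric(),
                    val_f1 = numeric()),
       best_epoch = best_epoch, diverged = diverged)
}
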