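#' Training configuration
#'
#' The network is trained with mean-squared error on the density maps using
#' the Adam optimizer. The learning rate starts at `lr0` and is multiplied
#' by `lr_decay_factor` every `lr_decay_every` epochs (a step schedule).
#'
#' @param lr0 Initial learning rate (> 0); default 1e-4.
#' @param lr_decay_factor Multiplicative decay; default 0.1.
#' @param lr_decay_every Epochs between decays; default 10.
#' @param batch_size Minibatch size; default 8.
#' @param epochs Number of epochs (>= 0); default 100.
#' @param seed Integer seed for shuffling (and any weight init done by the
#'   caller under the same seed).
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 1e-4, lr_decay_factor = 0.1,
                         lr_decay_every = 10L, batch_size = 8L,
                         epochs = 100L, seed = 1L) {
  if (lr0 <= 0) abort("`lr0` must be > 0")
  if (epochs < 0) abort("`epochs` must be >= 0")
  structure(list(lr0 = lr0, lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Step learning-rate schedule
#'
#' `lr = lr0 * decay^floor(epoch / decay_every)` with 0-based epochs.
#'
#' @param epoch Epoch index (>= 0).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @examples
#' lr_schedule(0, train_config())   # 1e-4
#' lr_schedule(10, train_config())  # 1e-5
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 0)
  cfg$lr0 * cfg$lr_decay_factor^(floor(epoch / cfg$lr_decay_every))
}

#' Split tiles into training and test sets by patient
#'
#' Selects a seeded random `train_fraction` of each patient's tiles for
#' training and the rest for testing, so both sets contain every patient but
#' no tile appears twice.
#'
#' @param image_ids Character vector of tile ids.
#' @param patient_ids Parallel vector of patient ids.
#' @param train_fraction Fraction per patient used for training; default 0.7.
#' @param seed Integer seed.
#' @return Tibble with columns `image_id`, `patient_id`, `split`
#'   (`"train"`/`"test"`).
#' @export
split_by_patient <- function(image_ids, patient_ids, train_fraction = 0.7,
                             seed = 1L) {
  stopifnot(length(image_ids) == length(patient_ids))
  with_private_seed(seed, {
    tibble(image_id = image_ids, patient_id = patient_ids) %>%
      group_by(.data$patient_id) %>%
      mutate(split = {
        k <- max(1L, round(train_fraction * n()))
        s <- rep("test", n())
        s[sample.int(n(), min(k, n()))] <- "train"
        s
      }) %>%
      ungroup()
  })
}

mse_loss <- function(pred, target) mean((pred - target)^2)

#' Train the density-regression network
#'
#' Minibatch Adam on the mean-squared error between predicted and target
#' density maps. Gradients are averaged over the batch; one optimizer step
#' is taken per batch; the learning rate follows [lr_schedule()]. Runs are
#' reproducible for a fixed `cfg$seed` and initial model.
#'
#' @param model A `density_net` from [build_density_net()].
#' @param samples Non-empty list of `list(x = image, y = density_map)`
#'   pairs, all with the model's spatial size.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return `list(model, history)`: the trained model and a tibble with one
#'   mean-loss row per epoch.
#' @export
train_network <- function(model, samples, cfg = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(model, "density_net"), inherits(cfg, "train_config"))
  if (length(samples) == 0L) abort("`samples` must be non-empty")
  if (cfg$epochs == 0L)
    return(list(model = model,
                history = tibble(epoch = integer(), loss = numeric())))
  with_private_seed(cfg$seed, {
    params <- param_flatten(model$layers)
    m1 <- lapply(params, function(p) p * 0)
    m2 <- m1
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- numeric(cfg$epochs)
    n <- length(samples)
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_schedule(ep - 1L, cfg)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        acc <- NULL
        bl <- 0
        for (i in idx) {
          fw <- net_forward(model, samples[[i]]$x, train = TRUE)
          resid <- fw$y - unclass(samples[[i]]$y)
          bl <- bl + mean(resid^2)
          gout <- (2 / length(resid)) * resid
          g <- param_flatten(net_backward(model, fw, gout))
          acc <- if (is.null(acc)) g
                 else purrr::map2(acc, g[names(acc)], `+`)
        }
        acc <- lapply(acc, function(g) g / length(idx))
        losses <- c(losses, bl / length(idx))
        step <- step + 1L
        for (k in names(params)) {
          m1[[k]] <- beta1 * m1[[k]] + (1 - beta1) * acc[[k]]
          m2[[k]] <- beta2 * m2[[k]] + (1 - beta2) * acc[[k]]^2
          mhat <- m1[[k]] / (1 - beta1^step)
          vhat <- m2[[k]] / (1 - beta2^step)
          params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
        }
        model$layers <- param_assign(model$layers, params)
      }
      history[ep] <- mean(losses)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.6f", ep, lr, history[ep]))
    }
    list(model = model,
         history = tibble(epoch = seq_len(cfg$epochs), loss = history))
  })
}

#' Mean squared error of a frozen model over samples
#'
#' @param model A `density_net`.
#' @param samples List of `list(x, y)` pairs.
#' @return Mean over samples of the per-sample MSE.
#' @export
evaluate_loss <- function(model, samples) {
  mean(vapply(samples, function(s)
    mse_loss(net_forward(model, s$x), unclass(s$y)), numeric(1)))
}
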