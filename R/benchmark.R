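#' High-contrast preset for the synthetic generator
#'
#' A deliberately easy configuration of [synth_params()]: 64-px tiles,
#' five non-overlapping cells (2 immunopositive, 2 immunonegative,
#' 1 lymphocyte) with strong chromatic contrast and low noise. Used by the
#' small-scale training benchmark, where the pipeline is expected to recover
#' nearly all cells.
#'
#' @param seed Integer seed.
#' @param width,height Tile size in pixels.
#' @return A [synth_params()] object.
#' @export
easy_synth_params <- function(seed, width = 64, height = 64) {
  synth_params(width = width, height = height, n_per_class = c(2L, 2L, 2L),
               radius_range = list(c(4, 6), c(4, 6), c(2.5, 3.5)),
               color_mean = rbind(c(150, 95, 45),    # DAB brown
                                  c(70, 100, 170),   # hematoxylin blue
                                  c(25, 20, 70)),    # dense dark lymphocyte
               color_sd = c(5, 5, 3), overlap_fraction = 0, noise_std = 2,
               min_center_separation = 4, seed = seed)
}

#' Small-scale end-to-end training benchmark
#'
#' Generates an easy synthetic training and test set ([easy_synth_params()]),
#' trains a reduced density-regression network (64x64 input, stem 8, stage
#' widths 8/16/32) with Adam on MSE, runs the full detection pipeline on the
#' held-out tiles and evaluates it with radius matching. This is the
#' package's self-contained substitute for full-dataset training: it
#' demonstrates that every stage composes correctly and that the pipeline
#' recovers nearly all cells when the imaging problem is easy.
#'
#' @param n_train,n_test Number of training / held-out tiles.
#' @param epochs Training epochs.
#' @param lr0 Initial Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Master seed: tile generation, weight init and shuffling all
#'   derive from it.
#' @param verbose Print per-epoch losses.
#' @return List with `report` (a `cell_eval_report`), `history` (loss
#'   tibble), `model`, and `self_report` (the truth evaluated against
#'   itself, as a sanity floor).
#' @export
run_synthetic_benchmark <- function(n_train = 300, n_test = 50, epochs = 25,
                                    lr0 = 1e-4, batch_size = 4L, seed = 1L,
                                    verbose = FALSE) {
  gen <- function(n, offset) lapply(seq_len(n), function(i) {
    s <- generate_image(easy_synth_params(derive_seed(seed, offset + i)),
                        image_id = sprintf("tile_%05d", offset + i),
                        patient_id = sprintf("P%02d", (i - 1L) %% 5L + 1L))
    list(x = s$image, y = encode_density(s$truth), truth = s$truth)
  })
  train <- gen(n_train, 0L)
  test <- gen(n_test, 100000L)

  cfg <- network_config(input_size = c(64L, 64L), stem_channels = 8L,
                        stage_widths = c(8L, 16L, 32L))
  model <- with_private_seed(seed, build_density_net(cfg))
  tc <- train_config(lr0 = lr0, lr_decay_every = max(2L, epochs - 5L),
                     batch_size = batch_size, epochs = epochs, seed = seed)
  fit <- train_network(model, train, tc, verbose = verbose)

  post <- postprocess_config(threshold = 0.4)
  truths <- lapply(test, `[[`, "truth")
  preds <- lapply(test, function(s) {
    det <- extract_centers(predict_density(fit$model, s$x), post,
                           image_id = s$truth$image_id)
    det$patient_id <- s$truth$patient_id
    det
  })
  report <- evaluate_detections(preds, truths, match_config(10))
  self_report <- evaluate_detections(truths, truths, match_config(10))
  list(report = report, history = fit$history, model = fit$model,
       self_report = self_report)
}
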