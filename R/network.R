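#' Network architecture configuration
#'
#' The density-regression backend is a U-Net-like encoder-decoder in which
#' every convolutional stage except the stem is a residual dilated inception
#' module (RDIM, [build_rdim()]): a two-layer stem, three encoder stages
#' (2x2 max-pool then an encoder RDIM that doubles the channel width), four
#' decoder RDIMs — one at the bottleneck, then three interleaved with 2x
#' nearest-neighbour upsampling and skip connections — and a head of three
#' 1x1 convolutions with a linear output producing one density channel per
#' cell class.
#'
#' @param input_size `(H, W)`; both must be divisible by `2^n_encoder_rdim`.
#' @param stem_channels Width of the two stem convolutions.
#' @param stage_widths Input width of each encoder RDIM (one per encoder
#'   stage); the doubling contract forces
#'   `stage_widths[i+1] == 2 * stage_widths[i]` and
#'   `stage_widths[1] == stem_channels`.
#' @param skip_mode `"concat"` (default) or `"add"` for the encoder-decoder
#'   skip connections.
#' @param n_encoder_rdim,n_decoder_rdim Module counts (3 and 4; the extra
#'   decoder RDIM sits at the bottleneck).
#' @param dilation_rate Dilation of the RDIM dilated path.
#' @return A `network_config` list.
#' @export
network_config <- function(input_size = c(256L, 256L),
                           stem_channels = 16L,
                           stage_widths = c(16L, 32L, 64L),
                           skip_mode = c("concat", "add"),
                           n_encoder_rdim = 3L,
                           n_decoder_rdim = 4L,
                           dilation_rate = 4L) {
  skip_mode <- match.arg(skip_mode)
  n_encoder_rdim <- as.integer(n_encoder_rdim)
  if (length(stage_widths) != n_encoder_rdim)
    abort("`stage_widths` needs one entry per encoder stage")
  if (stage_widths[1] != stem_channels)
    abort("`stage_widths[1]` must equal `stem_channels`")
  if (n_encoder_rdim > 1 &&
      !all(stage_widths[-1] == 2L * stage_widths[-n_encoder_rdim]))
    abort("encoder RDIMs double the width: stage_widths[i+1] == 2*stage_widths[i]")
  if (as.integer(n_decoder_rdim) != n_encoder_rdim + 1L)
    abort("decoder has one RDIM per encoder stage plus one at the bottleneck")
  div <- 2L^n_encoder_rdim
  if (any(input_size %% div != 0L))
    abort(sprintf("input size must be divisible by %d", div))
  structure(list(input_size = as.integer(input_size),
                 stem_channels = as.integer(stem_channels),
                 stage_widths = as.integer(stage_widths),
                 skip_mode = skip_mode,
                 n_encoder_rdim = n_encoder_rdim,
                 n_decoder_rdim = as.integer(n_decoder_rdim),
                 output_channels = 3L,
                 dilation_rate = as.integer(dilation_rate)),
            class = "network_config")
}

#' Build the density-regression network
#'
#' Instantiates the architecture of [network_config()] with He-initialized
#' weights drawn from the current RNG state (seed it for reproducible
#' models).
#'
#' @param cfg A [network_config()].
#' @return A `density_net` model object.
#' @examples
#' set.seed(1)
#' net <- build_density_net(network_config(input_size = c(64, 64),
#'                                         stem_channels = 8,
#'                                         stage_widths = c(8, 16, 32)))
#' count_parameters(net)
#' @export
build_density_net <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  w <- cfg$stage_widths
  n <- cfg$n_encoder_rdim
  layers <- list(
    stem1 = new_conv_layer(3L, cfg$stem_channels, 3L, 1L, "relu"),
    stem2 = new_conv_layer(cfg$stem_channels, cfg$stem_channels, 3L, 1L, "relu"))
  for (i in seq_len(n))
    layers[[paste0("enc", i)]] <-
      build_rdim(rdim_config("encoder", w[i], 2L * w[i], cfg$dilation_rate))
  bott_in <- 2L * w[n]
  if (cfg$skip_mode == "concat") {
    dec_out <- c(bott_in, rev(c(cfg$stem_channels, 2L * w[-n])))
    layers$dec1 <- build_rdim(rdim_config("decoder", bott_in, dec_out[1],
                                          cfg$dilation_rate))
    up_in <- dec_out[1]
    skips <- rev(c(cfg$stem_channels, 2L * w[-n]))  # e.g. 2*w2, 2*w1, stem
    for (i in seq_len(n)) {
      cin <- up_in + skips[i]
      layers[[paste0("dec", i + 1L)]] <-
        build_rdim(rdim_config("decoder", cin, dec_out[i + 1L],
                               cfg$dilation_rate))
      up_in <- dec_out[i + 1L]
    }
  } else {  # add: decoder widths must equal the skip widths
    skips <- rev(c(cfg$stem_channels, 2L * w[-n]))
    layers$dec1 <- build_rdim(rdim_config("decoder", bott_in, skips[1],
                                          cfg$dilation_rate))
    for (i in seq_len(n)) {
      cout <- if (i < n) skips[i + 1L] else cfg$stem_channels
      layers[[paste0("dec", i + 1L)]] <-
        build_rdim(rdim_config("decoder", skips[i], cout, cfg$dilation_rate))
    }
  }
  head_in <- if (cfg$skip_mode == "concat") cfg$stem_channels else cfg$stem_channels
  layers$head1 <- new_conv_layer(head_in, head_in, 1L, 1L, "relu")
  layers$head2 <- new_conv_layer(head_in, head_in, 1L, 1L, "relu")
  layers$head3 <- new_conv_layer(head_in, 3L, 1L, 1L, "linear")
  # near-zero init of the linear readout: the untrained network predicts an
  # almost-empty density map, so early optimization grows the signal
  # instead of crushing feature amplitudes (which kills ReLUs on sparse
  # targets); kept slightly non-zero so gradients reach every layer from
  # the first step
  layers$head3$W[] <- rnorm(length(layers$head3$W), 0, 1e-3)
  structure(list(cfg = cfg, layers = layers), class = "density_net")
}

#' @export
print.density_net <- function(x, ...) {
  cat(sprintf("<density_net> input %dx%d, stem %d, stages (%s), skip %s\n",
              x$cfg$input_size[1], x$cfg$input_size[2], x$cfg$stem_channels,
              paste(x$cfg$stage_widths, collapse = ", "), x$cfg$skip_mode))
  cat(sprintf("  %d trainable parameters in %d layers/modules\n",
              count_parameters(x), length(x$layers)))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `density_net`.
#' @return Integer: total number of weights and biases.
#' @export
count_parameters <- function(model) {
  sum(vapply(param_flatten(model$layers), length, integer(1)))
}

# full forward pass; returns output plus per-layer caches when train = TRUE
net_forward <- function(model, x, train = FALSE) {
  L <- model$layers
  n <- model$cfg$n_encoder_rdim
  caches <- list()
  f <- conv_fw(L$stem1, x); caches$stem1 <- f$cache
  f <- conv_fw(L$stem2, f$y); caches$stem2 <- f$cache
  skips <- list(f$y)          # full-resolution skip
  cur <- f$y
  pools <- list()
  for (i in seq_len(n)) {
    p <- maxpool2_fw(cur)
    pools[[i]] <- list(idx = p$idx, H = dim(cur)[1], W = dim(cur)[2])
    r <- rdim_fw(L[[paste0("enc", i)]], p$y)
    caches[[paste0("enc", i)]] <- r$cache
    cur <- r$y
    if (i < n) skips[[i + 1L]] <- cur
  }
  r <- rdim_fw(L$dec1, cur); caches$dec1 <- r$cache; cur <- r$y
  concat_splits <- integer(n)
  for (i in seq_len(n)) {
    cur <- upsample2_fw(cur)
    sk <- skips[[n + 1L - i]]
    if (model$cfg$skip_mode == "concat") {
      concat_splits[i] <- dim(cur)[3]
      cur <- channel_concat(cur, sk)
    } else {
      cur <- cur + sk
    }
    r <- rdim_fw(L[[paste0("dec", i + 1L)]], cur)
    caches[[paste0("dec", i + 1L)]] <- r$cache
    cur <- r$y
  }
  f <- conv_fw(L$head1, cur); caches$head1 <- f$cache
  f <- conv_fw(L$head2, f$y); caches$head2 <- f$cache
  f <- conv_fw(L$head3, f$y); caches$head3 <- f$cache
  out <- f$y
  if (!train) return(out)
  list(y = out, caches = caches, pools = pools, splits = concat_splits)
}

# gradient of every parameter given the upstream gradient at the output
net_backward <- function(model, fw, gout) {
  L <- model$layers
  n <- model$cfg$n_encoder_rdim
  caches <- fw$caches
  grads <- list()
  g <- conv_bw(L$head3, caches$head3, gout); grads$head3 <- g$grads
  g <- conv_bw(L$head2, caches$head2, g$gx); grads$head2 <- g$grads
  g <- conv_bw(L$head1, caches$head1, g$gx); grads$head1 <- g$grads
  gcur <- g$gx
  gskips <- vector("list", n)   # gradient flowing into each stored skip
  for (i in rev(seq_len(n))) {
    r <- rdim_bw(L[[paste0("dec", i + 1L)]], caches[[paste0("dec", i + 1L)]],
                 gcur)
    grads[[paste0("dec", i + 1L)]] <- r$grads
    gin <- r$gx
    if (model$cfg$skip_mode == "concat") {
      k <- fw$splits[i]
      gup <- gin[, , seq_len(k), drop = FALSE]
      gsk <- gin[, , k + seq_len(dim(gin)[3] - k), drop = FALSE]
    } else {
      gup <- gin; gsk <- gin
    }
    gskips[[n + 1L - i]] <- gsk
    gcur <- upsample2_bw(gup)
  }
  r <- rdim_bw(L$dec1, caches$dec1, gcur); grads$dec1 <- r$grads
  gcur <- r$gx
  for (i in rev(seq_len(n))) {
    if (i < n) gcur <- gcur + gskips[[i + 1L]]
    r <- rdim_bw(L[[paste0("enc", i)]], caches[[paste0("enc", i)]], gcur)
    grads[[paste0("enc", i)]] <- r$grads
    gcur <- maxpool2_bw(r$gx, fw$pools[[i]]$idx, fw$pools[[i]]$H,
                        fw$pools[[i]]$W)
  }
  gcur <- gcur + gskips[[1L]]
  g <- conv_bw(L$stem2, caches$stem2, gcur); grads$stem2 <- g$grads
  g <- conv_bw(L$stem1, caches$stem1, g$gx); grads$stem1 <- g$grads
  grads
}

#' Predict a density map for one tile
#'
#' Runs the network forward on an RGB tile. The head is linear, so small
#' negative values can occur; clipping is the post-processing stage's job.
#'
#' @param model A trained (or freshly built) `density_net`.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return A `density_map` (`H x W x 3`).
#' @export
predict_density <- function(model, image) {
  stopifnot(inherits(model, "density_net"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    abort("`image` must be an H x W x 3 array")
  div <- 2L^model$cfg$n_encoder_rdim
  if (any(d[1:2] %% div != 0L))
    abort(sprintf("image dimensions must be divisible by %d", div))
  structure(net_forward(model, image, train = FALSE), class = "density_map")
}

#' Save / load a model
#'
#' Weights are serialized as flat JSON (text, framework-free) next to the
#' architecture configuration, so a checkpoint fully rebuilds the model.
#'
#' @param model A `density_net`.
#' @param path Output `.json` file.
#' @return `path` invisibly; `load_model()` returns the rebuilt model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "density_net"))
  flat <- param_flatten(model$layers)
  obj <- list(config = unclass(model$cfg),
              params = lapply(flat, function(p)
                list(dim = if (is.matrix(p)) dim(p) else length(p),
                     data = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- do.call(network_config,
                 obj$config[c("input_size", "stem_channels", "stage_widths",
                              "skip_mode", "n_encoder_rdim", "n_decoder_rdim",
                              "dilation_rate")])
  model <- build_density_net(cfg)
  flat <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  model$layers <- param_assign(model$layers, flat)
  model
}
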