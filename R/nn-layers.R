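# Minimal layer toolkit for the density-regression network.
#
# A layer is a plain list with a `type`; parameters live in fields named `W`
# and `b` so they can be walked generically (see param_map / param_flatten).
# Forward passes return list(y, cache); backward passes take the upstream
# gradient plus the cache and return list(gx, grads) where grads mirrors the
# layer's parameter structure.

new_conv_layer <- function(cin, cout, k = 3L, dilation = 1L,
                           act = c("relu", "linear")) {
  act <- match.arg(act)
  fan_in <- k * k * cin
  # small positive bias keeps ReLU units alive at narrow widths
  list(type = "conv", k = as.integer(k), dilation = as.integer(dilation),
       cin = cin, cout = cout, act = act,
       W = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
       b = rep(if (act == "relu") 0.01 else 0, cout))
}

conv_fw <- function(layer, x) {
  pre <- conv2d_fw(x, layer$W, layer$b, layer$k, layer$k, layer$dilation)
  y <- if (layer$act == "relu") relu(pre) else pre
  list(y = y, cache = list(x = x, pre = pre))
}

conv_bw <- function(layer, cache, gy) {
  if (layer$act == "relu") gy <- gy * (cache$pre > 0)
  g <- conv2d_bw(cache$x, layer$W, gy, layer$k, layer$k, layer$dilation)
  list(gx = g$x, grads = list(W = g$W, b = g$b))
}

#' Residual dilated inception module configuration
#'
#' An RDIM sums three parallel paths: (a) two plain 3x3 convolutions, (b) two
#' 3x3 dilated convolutions (dilation 4 by default), and (c) a residual of
#' the module input. In the encoder variant the output width is twice the
#' input width and the residual is the input duplicated along channels; in
#' the decoder variant a 1x1 convolution projects the input to the output
#' width. Spatial size is always preserved.
#'
#' @param variant `"encoder"` or `"decoder"`.
#' @param channels_in,channels_out Channel widths; the encoder variant
#'   requires `channels_out == 2 * channels_in`.
#' @param dilation_rate Dilation of path (b); default 4.
#' @return An `rdim_config` list.
#' @export
rdim_config <- function(variant = c("encoder", "decoder"),
                        channels_in, channels_out,
                        dilation_rate = 4L) {
  variant <- match.arg(variant)
  if (variant == "encoder" && channels_out != 2L * channels_in)
    abort("encoder RDIM requires channels_out == 2 * channels_in")
  structure(list(variant = variant, channels_in = channels_in,
                 channels_out = channels_out, kernel_size = 3L,
                 dilation_rate = as.integer(dilation_rate)),
            class = "rdim_config")
}

#' Build a residual dilated inception module
#'
#' @param cfg An [rdim_config()].
#' @return A composable block usable inside the network; weights are
#'   He-initialized from the current RNG state.
#' @export
build_rdim <- function(cfg) {
  stopifnot(inherits(cfg, "rdim_config"))
  blk <- list(type = "rdim", variant = cfg$variant,
              cin = cfg$channels_in, cout = cfg$channels_out,
              a1 = new_conv_layer(cfg$channels_in, cfg$channels_out, 3L, 1L, "relu"),
              a2 = new_conv_layer(cfg$channels_out, cfg$channels_out, 3L, 1L, "linear"),
              b1 = new_conv_layer(cfg$channels_in, cfg$channels_out, 3L,
                                  cfg$dilation_rate, "relu"),
              b2 = new_conv_layer(cfg$channels_out, cfg$channels_out, 3L,
                                  cfg$dilation_rate, "linear"))
  # residual-friendly init: the branch-closing convolutions start near zero
  # so a fresh module is (approximately) its residual mapping; the branches
  # grow in during training. Greatly shortens the escape from the trivial
  # all-zero regression solution on sparse density targets, while the small
  # non-zero values keep gradient flowing through every path from the first
  # optimizer step.
  eps_w <- 1e-3
  blk$a2$W[] <- rnorm(length(blk$a2$W), 0, eps_w)
  blk$b2$W[] <- rnorm(length(blk$b2$W), 0, eps_w)
  if (cfg$variant == "decoder") {
    blk$res <- new_conv_layer(cfg$channels_in, cfg$channels_out, 1L, 1L, "linear")
    # partial-identity init of the residual projection: pass the trailing
    # input channels (the skip connection, when one is concatenated)
    # straight through, so an untrained decoder forwards encoder features
    # instead of randomly mixing them
    if (cfg$channels_out <= cfg$channels_in) {
      blk$res$W[] <- rnorm(length(blk$res$W), 0, eps_w)
      for (j in seq_len(cfg$channels_out))
        blk$res$W[cfg$channels_in - cfg$channels_out + j, j] <- 1
    }
  }
  blk
}

rdim_fw <- function(blk, x) {
  fa1 <- conv_fw(blk$a1, x);       fa2 <- conv_fw(blk$a2, fa1$y)
  fb1 <- conv_fw(blk$b1, x);       fb2 <- conv_fw(blk$b2, fb1$y)
  if (blk$variant == "encoder") {
    res <- channel_concat(x, x)
    rcache <- NULL
  } else {
    fr <- conv_fw(blk$res, x)
    res <- fr$y; rcache <- fr$cache
  }
  s <- fa2$y + fb2$y + res
  list(y = relu(s),
       cache = list(a1 = fa1$cache, a2 = fa2$cache, b1 = fb1$cache,
                    b2 = fb2$cache, res = rcache, s = s))
}

rdim_bw <- function(blk, cache, gy) {
  gs <- gy * (cache$s > 0)
  ga2 <- conv_bw(blk$a2, cache$a2, gs); ga1 <- conv_bw(blk$a1, cache$a1, ga2$gx)
  gb2 <- conv_bw(blk$b2, cache$b2, gs); gb1 <- conv_bw(blk$b1, cache$b1, gb2$gx)
  grads <- list(a1 = ga1$grads, a2 = ga2$grads,
                b1 = gb1$grads, b2 = gb2$grads)
  if (blk$variant == "encoder") {
    cin <- blk$cin
    gres <- gs[, , seq_len(cin), drop = FALSE] +
            gs[, , cin + seq_len(cin), drop = FALSE]
  } else {
    gr <- conv_bw(blk$res, cache$res, gs)
    grads$res <- gr$grads
    gres <- gr$gx
  }
  list(gx = ga1$gx + gb1$gx + gres, grads = grads)
}

channel_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# recursively collect every W/b array of a nested layer structure
param_flatten <- function(x, path = character()) {
  out <- list()
  for (nm in names(x)) {
    el <- x[[nm]]
    if (nm %in% c("W", "b") && is.numeric(el)) {
      out[[paste(c(path, nm), collapse = ".")]] <- el
    } else if (is.list(el)) {
      out <- c(out, param_flatten(el, c(path, nm)))
    }
  }
  out
}

param_assign <- function(x, flat, path = character()) {
  for (nm in names(x)) {
    el <- x[[nm]]
    key <- paste(c(path, nm), collapse = ".")
    if (nm %in% c("W", "b") && is.numeric(el)) {
      if (!is.null(flat[[key]])) x[[nm]] <- flat[[key]]
    } else if (is.list(el)) {
      x[[nm]] <- param_assign(el, flat, c(path, nm))
    }
  }
  x
}
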