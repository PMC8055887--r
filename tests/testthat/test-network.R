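test_that("dilated convolution matches hand-evaluated cases", {
  # identity kernel leaves any signal unchanged
  withr::with_seed(1, sig <- matrix(runif(49), 7, 7))
  expect_equal(apply_dilated_conv(sig, matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3)),
               sig)
  # 1-D impulse through [1,1,1] at dilation 2: taps at i-2, i, i+2
  expect_equal(apply_dilated_conv(c(0, 0, 1, 0, 0), c(1, 1, 1), d = 2),
               c(1, 0, 1, 0, 1))
  expect_error(apply_dilated_conv(c(1, 2, 3), numeric(0)), "non-empty")
  expect_error(apply_dilated_conv(c(1, 2, 3), c(1, 1)), "odd")
})

test_that("dilated convolution equals ordinary convolution of the
           zero-inflated kernel", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      sig <- matrix(rnorm(81), 9, 9)
      k <- matrix(rnorm(9), 3, 3)
      inflated <- matrix(0, 5, 5)
      inflated[c(1, 3, 5), c(1, 3, 5)] <- k
      expect_equal(apply_dilated_conv(sig, k, d = 2),
                   apply_dilated_conv(sig, inflated, d = 1))
    }
  })
})

test_that("RDIM channel contract: encoder doubles, decoder is free", {
  withr::with_seed(5, {
    enc <- build_rdim(rdim_config("encoder", 8, 16))
    x <- array(runif(12 * 12 * 8), c(12, 12, 8))
    y <- ki67cells:::rdim_fw(enc, x)$y
    expect_equal(dim(y), c(12, 12, 16))

    dec <- build_rdim(rdim_config("decoder", 16, 16))
    x2 <- array(runif(12 * 12 * 16), c(12, 12, 16))
    expect_equal(dim(ki67cells:::rdim_fw(dec, x2)$y), c(12, 12, 16))

    expect_error(rdim_config("encoder", 8, 12), "2 \\* channels_in")
  })
})

test_that("zero-weight encoder RDIM reduces to channel duplication", {
  withr::with_seed(6, {
    enc <- build_rdim(rdim_config("encoder", 4, 8))
    for (nm in c("a1", "a2", "b1", "b2")) {
      enc[[nm]]$W[] <- 0
      enc[[nm]]$b[] <- 0
    }
    x <- array(runif(10 * 10 * 4), c(10, 10, 4))  # non-negative input
    y <- ki67cells:::rdim_fw(enc, x)$y
    expect_equal(y[, , 1:4], x)
    expect_equal(y[, , 5:8], x)
  })
})

test_that("the network maps H x W x 3 to H x W x 3 at several sizes", {
  set.seed(11)
  net64 <- build_density_net(network_config(input_size = c(64, 64),
                                            stem_channels = 8,
                                            stage_widths = c(8, 16, 32)))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(dim(predict_density(net64, x)), c(64, 64, 3))

  net256 <- build_density_net(network_config())  # 256 x 256 default
  x256 <- array(runif(256 * 256 * 3), c(256, 256, 3))
  expect_equal(dim(predict_density(net256, x256)), c(256, 256, 3))

  expect_error(predict_density(net64, array(0, c(60, 60, 3))), "divisible")
  expect_error(predict_density(net64, array(0, c(64, 64, 4))), "H x W x 3")
  expect_error(network_config(input_size = c(100, 100)), "divisible")
})

test_that("parameter count matches the closed-form layer-spec sum", {
  # conv params = (k^2 cin + 1) cout; RDIM = a1 + a2 + b1 + b2 (+ res)
  conv_p <- function(k, cin, cout) (k * k * cin + 1) * cout
  rdim_p <- function(cin, cout, dec) {
    conv_p(3, cin, cout) + conv_p(3, cout, cout) +   # plain path
    conv_p(3, cin, cout) + conv_p(3, cout, cout) +   # dilated path
    if (dec) conv_p(1, cin, cout) else 0
  }
  stem <- 8; w <- c(8, 16, 32)
  expected <- conv_p(3, 3, stem) + conv_p(3, stem, stem) +
    sum(mapply(function(ci) rdim_p(ci, 2 * ci, FALSE), w)) +
    rdim_p(64, 64, TRUE) +            # bottleneck
    rdim_p(64 + 32, 32, TRUE) +       # up + skip(enc2)
    rdim_p(32 + 16, 16, TRUE) +       # up + skip(enc1)
    rdim_p(16 + 8, 8, TRUE) +         # up + skip(stem)
    conv_p(1, 8, 8) + conv_p(1, 8, 8) + conv_p(1, 8, 3)
  set.seed(2)
  net <- build_density_net(network_config(input_size = c(64, 64),
                                          stem_channels = 8,
                                          stage_widths = c(8, 16, 32)))
  expect_identical(count_parameters(net), as.integer(expected))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(99)
  cfg <- network_config(input_size = c(16, 16), stem_channels = 2,
                        stage_widths = c(2, 4, 8))
  net <- build_density_net(cfg)
  # draw every parameter from a continuous distribution so no pre-activation
  # sits exactly on a ReLU kink (where the loss is not differentiable)
  jitter <- lapply(ki67cells:::param_flatten(net$layers), function(p)
    p + rnorm(length(p), 0, 0.05))
  net$layers <- ki67cells:::param_assign(net$layers, jitter)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- array(runif(16 * 16 * 3, 0, 0.2), c(16, 16, 3))
  fw <- ki67cells:::net_forward(net, x, train = TRUE)
  gout <- (2 / length(fw$y)) * (fw$y - y)
  ana <- ki67cells:::param_flatten(ki67cells:::net_backward(net, fw, gout))
  flat <- ki67cells:::param_flatten(net$layers)
  loss_at <- function(f) {
    n2 <- net; n2$layers <- ki67cells:::param_assign(net$layers, f)
    mean((ki67cells:::net_forward(n2, x) - y)^2)
  }
  eps <- 1e-5
  withr::with_seed(3, {
    for (k in sample(names(flat), 10)) {
      i <- sample(length(flat[[k]]), 1)
      up <- flat; up[[k]][i] <- up[[k]][i] + eps
      dn <- flat; dn[[k]][i] <- dn[[k]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(ana[[k]][i], num, tolerance = 1e-3,
                   label = sprintf("gradient of %s[%d]", k, i))
    }
  })
})

test_that("learning-rate schedule follows the closed form", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(9, cfg), 1e-4)
  expect_equal(lr_schedule(10, cfg), 1e-5)
  expect_equal(lr_schedule(25, cfg), 1e-6)
  for (ep in c(0:12, 50, 99))
    expect_equal(lr_schedule(ep, cfg),
                 cfg$lr0 * cfg$lr_decay_factor^(ep %/% cfg$lr_decay_every))
})

test_that("zero epochs leaves the model unchanged with empty history", {
  set.seed(4)
  net <- build_density_net(network_config(input_size = c(16, 16),
                                          stem_channels = 2,
                                          stage_widths = c(2, 4, 8)))
  s <- list(x = array(runif(768), c(16, 16, 3)),
            y = array(0, c(16, 16, 3)))
  fit <- train_network(net, list(s), train_config(epochs = 0))
  expect_identical(fit$model, net)
  expect_identical(nrow(fit$history), 0L)
  expect_error(train_network(net, list(), train_config()), "non-empty")
})

test_that("one optimizer step changes every trainable layer", {
  set.seed(8)
  net <- build_density_net(network_config(input_size = c(16, 16),
                                          stem_channels = 2,
                                          stage_widths = c(2, 4, 8)))
  s <- withr::with_seed(1, list(x = array(runif(768), c(16, 16, 3)),
                                y = array(runif(768, 0, 0.3), c(16, 16, 3))))
  fit <- train_network(net, list(s),
                       train_config(lr0 = 1e-4, batch_size = 1, epochs = 1))
  before <- ki67cells:::param_flatten(net$layers)
  after <- ki67cells:::param_flatten(fit$model$layers)
  layer_of <- sub("\\..*$", "", names(before))
  for (ly in unique(layer_of)) {
    moved <- any(vapply(which(layer_of == ly), function(i)
      any(before[[i]] != after[[i]]), logical(1)))
    expect_true(moved, label = sprintf("layer %s moved", ly))
  }
})

test_that("training loss history matches an independent MSE computation", {
  set.seed(14)
  net <- build_density_net(network_config(input_size = c(16, 16),
                                          stem_channels = 2,
                                          stage_widths = c(2, 4, 8)))
  samples <- withr::with_seed(2, lapply(1:3, function(i)
    list(x = array(runif(768), c(16, 16, 3)),
         y = array(runif(768, 0, 0.2), c(16, 16, 3)))))
  # frozen model: lr 0 keeps weights fixed, so the recorded epoch loss must
  # equal the mean per-sample squared error computed directly
  fit <- train_network(net, samples,
                       train_config(lr0 = 1e-30, batch_size = 3, epochs = 1))
  manual <- mean(vapply(samples, function(s)
    mean((ki67cells:::net_forward(net, s$x) - s$y)^2), numeric(1)))
  expect_equal(fit$history$loss[1], manual, tolerance = 1e-10)
  expect_equal(evaluate_loss(net, samples), manual, tolerance = 1e-12)
})

test_that("a small network overfits a handful of easy tiles", {
  # five easy tiles, many epochs: the final loss must fall well below a
  # tenth of the initial loss
  samples <- lapply(1:5, function(i) {
    p <- synth_params(width = 32, height = 32, n_per_class = c(1L, 1L, 1L),
                      radius_range = list(c(3, 4), c(3, 4), c(2, 3)),
                      color_sd = c(5, 5, 4), overlap_fraction = 0,
                      noise_std = 2, min_center_separation = 3,
                      seed = 400 + i)
    s <- generate_image(p)
    list(x = s$image, y = encode_density(s$truth))
  })
  set.seed(12)
  net <- build_density_net(network_config(input_size = c(32, 32),
                                          stem_channels = 8,
                                          stage_widths = c(8, 16, 32)))
  fit <- train_network(net, samples,
                       train_config(lr0 = 3e-4, batch_size = 1L,
                                    epochs = 150L, lr_decay_every = 1000L,
                                    seed = 12))
  expect_identical(nrow(fit$history), 150L)
  expect_lt(fit$history$loss[150], 0.1 * fit$history$loss[1])
})

test_that("prediction is pure and zero-weight heads give zero maps", {
  set.seed(21)
  net <- build_density_net(network_config(input_size = c(32, 32),
                                          stem_channels = 4,
                                          stage_widths = c(4, 8, 16)))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_density(net, x), predict_density(net, x))
  net$layers$head3$W[] <- 0
  net$layers$head3$b[] <- 0
  expect_true(all(predict_density(net, x) == 0))
})

test_that("models round-trip through the JSON checkpoint", {
  set.seed(33)
  net <- build_density_net(network_config(input_size = c(32, 32),
                                          stem_channels = 4,
                                          stage_widths = c(4, 8, 16)))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "model.json")
  save_model(net, f)
  back <- load_model(f)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(predict_density(back, x), predict_density(net, x),
               tolerance = 1e-12)
})

test_that("patient-wise split keeps every patient in both sets", {
  ids <- sprintf("img%03d", 1:40)
  pats <- rep(sprintf("P%d", 1:4), each = 10)
  sp <- split_by_patient(ids, pats, train_fraction = 0.7, seed = 2)
  expect_identical(nrow(sp), 40L)
  by_pat <- table(sp$patient_id, sp$split)
  expect_true(all(by_pat[, "train"] == 7))
  expect_true(all(by_pat[, "test"] == 3))
  # seeded: reproducible
  expect_identical(sp, split_by_patient(ids, pats, 0.7, seed = 2))
})
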