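test_that("zero-weight cell halves every gate and zeroes the state", {
  H <- 3
  z <- matrix(0, H, H)
  w <- lstm_weights(z, z, z, z, z, z, z, z,
                    numeric(H), numeric(H), numeric(H), numeric(H))
  s <- lstm_cell_step(rnorm(H), list(h = numeric(H), c = numeric(H)), w)
  g <- attr(s, "gates")
  expect_equal(g$f, rep(0.5, H))
  expect_equal(g$i, rep(0.5, H))
  expect_equal(g$o, rep(0.5, H))
  expect_equal(g$a, rep(0, H))
  expect_equal(s$c, rep(0, H))
  expect_equal(s$h, rep(0, H))
})

test_that("the scalar cell matches exact evaluation of the gate equations", {
  w <- lstm_weights(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0)
  s <- lstm_cell_step(0.5, list(h = 0, c = 0), w)
  g <- attr(s, "gates")
  sig05 <- 1 / (1 + exp(-0.5))
  expect_equal(g$f, sig05, tolerance = 1e-12)
  expect_equal(round(g$f, 5), 0.62246)
  expect_equal(round(g$a, 5), 0.46212)
  # exact: c = sigma(0.5) * tanh(0.5), h = sigma(0.5) * tanh(c)
  expect_equal(s$c, sig05 * tanh(0.5), tolerance = 1e-12)
  expect_equal(s$c, 0.2876490, tolerance = 1e-5)
  expect_equal(s$h, sig05 * tanh(sig05 * tanh(0.5)), tolerance = 1e-12)
  expect_equal(s$h, 0.1742697, tolerance = 1e-5)
})

test_that("vectorized cell, scalar reference and batched layer all agree over 20 steps", {
  set.seed(11)
  H <- 4; Fi <- 3; Tn <- 20
  w <- random_lstm_weights(H, Fi)
  xs <- matrix(rnorm(Tn * Fi), Tn, Fi)

  st_pkg <- list(h = numeric(H), c = numeric(H))
  st_ref <- list(h = numeric(H), c = numeric(H))
  hs_pkg <- matrix(0, Tn, H)
  for (t in seq_len(Tn)) {
    st_pkg <- lstm_cell_step(xs[t, ], st_pkg, w)
    st_ref <- scalar_lstm_step(xs[t, ], st_ref$h, st_ref$c, w)
    expect_lt(max(abs(st_pkg$h - st_ref$h)), 1e-10)
    expect_lt(max(abs(st_pkg$c - st_ref$c)), 1e-10)
    hs_pkg[t, ] <- st_pkg$h
  }

  # bridge: the batched training layer carries the same recurrence
  layer <- alcoeeg:::layer_lstm(Fi, H, return_seq = TRUE)
  layer$W_x <- cbind(t(w$U_f), t(w$U_i), t(w$U_a), t(w$U_o))
  layer$W_h <- cbind(t(w$W_f), t(w$W_i), t(w$W_a), t(w$W_o))
  layer$b <- c(w$b_f, w$b_i, w$b_a, w$b_o)
  X <- array(0, c(1, Tn, Fi))
  X[1, , ] <- xs
  out <- alcoeeg:::lstm_layer_forward(layer, X)
  expect_lt(max(abs(out[1, , ] - hs_pkg)), 1e-10)
})

test_that("gate activations and hidden states respect their ranges", {
  set.seed(12)
  for (rep in 1:5) {
    w <- random_lstm_weights(6, 4, scale = 0.6)
    st <- list(h = numeric(6), c = numeric(6))
    for (t in 1:10) {
      st <- lstm_cell_step(rnorm(4), st, w)
      g <- attr(st, "gates")
      expect_true(all(g$f > 0 & g$f < 1))
      expect_true(all(g$i > 0 & g$i < 1))
      expect_true(all(g$o > 0 & g$o < 1))
      expect_true(all(abs(g$a) < 1))
      expect_true(all(abs(st$h) < 1))
    }
  }
})

test_that("bidirectional forward pass concatenates two independent directions", {
  set.seed(13)
  H <- 3; Fi <- 2
  fw <- random_lstm_weights(H, Fi)
  bw <- random_lstm_weights(H, Fi)

  x1 <- matrix(rnorm(Fi), 1, Fi)
  out1 <- bilstm_forward(x1, fw, bw)
  sf <- lstm_cell_step(x1[1, ], list(h = numeric(H), c = numeric(H)), fw)
  sb <- lstm_cell_step(x1[1, ], list(h = numeric(H), c = numeric(H)), bw)
  expect_equal(as.numeric(out1), c(sf$h, sb$h), tolerance = 1e-12)

  seqx <- matrix(rnorm(5 * Fi), 5, Fi)
  out <- bilstm_forward(seqx, fw, bw)
  expect_equal(dim(out), c(5L, 2L * H))
  # reversing the sequence with swapped direction weights mirrors the output
  out_rev <- bilstm_forward(seqx[5:1, ], bw, fw)
  expect_equal(out_rev[5:1, (H + 1):(2 * H)], out[, 1:H], tolerance = 1e-12)
  expect_equal(out_rev[5:1, 1:H], out[, (H + 1):(2 * H)], tolerance = 1e-12)

  z <- matrix(0, H, H)
  wz <- lstm_weights(z, z, z, z, matrix(0, H, Fi), matrix(0, H, Fi),
                     matrix(0, H, Fi), matrix(0, H, Fi),
                     numeric(H), numeric(H), numeric(H), numeric(H))
  expect_true(all(bilstm_forward(seqx, wz, wz) == 0))
})

test_that("layer shapes follow the closed-form recurrences in both padding modes", {
  cfg_valid <- model_config(input_length = 76, padding_mode = "valid", seed = 1)
  tab <- describe_model(build_model(cfg_valid, "proposed"))
  conv_pool <- tab$output_shape[tab$layer %in% c("conv1d", "maxpool")]
  expect_equal(conv_pool,
               c("74x64", "37x64", "35x64", "33x128", "31x128", "15x128"))

  cfg_same <- model_config(input_length = 76, padding_mode = "same", seed = 1)
  tab2 <- describe_model(build_model(cfg_same, "proposed"))
  conv_pool2 <- tab2$output_shape[tab2$layer %in% c("conv1d", "maxpool")]
  expect_equal(conv_pool2,
               c("76x64", "38x64", "38x64", "38x128", "38x128", "19x128"))

  # Bi-LSTM output width is 2 x units
  expect_equal(tab2$output_shape[tab2$layer == "bilstm"], c("4x128", "128"))
})

test_that("parameter counts match the closed forms", {
  # LSTM(64) over 64-feature input: 4 (H^2 + H F + H)
  l <- alcoeeg:::layer_lstm(64, 64)
  n_lstm <- length(l$W_x) + length(l$W_h) + length(l$b)
  expect_equal(n_lstm, 4 * (64^2 + 64 * 64 + 64))
  expect_equal(n_lstm, 33024)

  cfg <- model_config(input_length = 69, seed = 2)
  tab <- describe_model(build_model(cfg, "proposed"))
  conv1 <- tab$params[tab$layer == "conv1d"][1]
  expect_equal(conv1, 3 * 1 * 64 + 64)
  bil <- tab$params[tab$layer == "bilstm"]
  expect_equal(bil[1], 2 * 4 * (64^2 + 64 * 64 + 64))
  expect_equal(sum(tab$params), sum(glance(build_model(cfg, "proposed"))$n_params))
})

test_that("model building is deterministic under a fixed seed", {
  cfg <- model_config(input_length = 40, seed = 99)
  m1 <- build_model(cfg, "proposed")
  m2 <- build_model(cfg, "proposed")
  w1 <- alcoeeg:::trainable_layers(m1$layers)
  w2 <- alcoeeg:::trainable_layers(m2$layers)
  for (i in seq_along(w1)) {
    for (nm in w1[[i]]$param_names) {
      expect_identical(w1[[i]][[nm]], w2[[i]][[nm]])
    }
  }
})

test_that("sigmoid head outputs probabilities for arbitrary inputs", {
  cfg <- model_config(input_length = 30, seed = 5)
  for (arch in c("proposed", "cnn", "lstm", "bilstm")) {
    m <- build_model(cfg, arch)
    p <- predict(m, matrix(rnorm(4 * 30, sd = 10), 4))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("backpropagation matches numerical differentiation on a small network", {
  cfg <- model_config(
    input_length = 20,
    conv_stack = list(c(4, 3, 1), c(4, 3, 1), c(6, 3, 1), c(6, 3, 1)),
    pre_rnn_dense = 8, bilstm_units = c(3, 3), head_dense = c(8, 5, 4),
    dropout_rate = 0, rnn_timesteps = 2, seed = 3
  )
  m <- build_model(cfg, "proposed")
  set.seed(9)
  x <- matrix(rnorm(5 * 20), 5)
  y <- c(1, 0, 1, 1, 0)
  loss_fn <- function() {
    p <- as.numeric(alcoeeg:::nn_forward(m$layers, x, train = FALSE))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  p <- as.numeric(alcoeeg:::nn_forward(m$layers, x, train = FALSE))
  alcoeeg:::nn_backward_from_logits(m$layers, matrix((p - y) / 5, ncol = 1))
  eps <- 1e-6
  for (layer in alcoeeg:::trainable_layers(m$layers)) {
    for (nm in layer$param_names) {
      i <- sample(length(layer[[nm]]), 1)
      analytic <- layer[[paste0("g", nm)]][i]
      old <- layer[[nm]]
      v <- old; v[i] <- v[i] + eps
      assign(nm, v, envir = layer); lp <- loss_fn()
      v[i] <- v[i] - 2 * eps
      assign(nm, v, envir = layer); lm <- loss_fn()
      assign(nm, old, envir = layer)
      numeric_g <- (lp - lm) / (2 * eps)
      expect_lt(abs(analytic - numeric_g), 1e-5 * max(1, abs(numeric_g)))
    }
  }
})
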