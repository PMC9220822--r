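# Minimal batched neural-network kernels: 1-D convolution, max pooling,
# dense, dropout, LSTM / bidirectional LSTM, trained with Adam. Layers are
# environments so backward passes can stash gradients in place; data flows
# as (batch, length, channels) arrays between spatial layers and
# (batch, features) matrices between dense layers. Everything runs on BLAS
# matrix products (im2col for convolutions).

sigmoid <- function(z) 1 / (1 + exp(-z))

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dim = dims)
}

orthogonal_init <- function(rows, cols) {
  # per-block orthogonal matrix via QR of a Gaussian draw
  a <- matrix(rnorm(rows * max(rows, cols)), nrow = max(rows, cols))
  q <- qr.Q(qr(a))
  q[seq_len(rows), seq_len(cols), drop = FALSE]
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

layer_conv1d <- function(in_channels, filters, kernel, padding = "same") {
  W <- glorot_uniform(kernel * in_channels, filters,
                      c(kernel, in_channels, filters))
  new_layer("conv1d",
            W = W, b = numeric(filters),
            kernel = kernel, padding = padding,
            param_names = c("W", "b"))
}

layer_dense <- function(fan_in, fan_out) {
  new_layer("dense",
            W = glorot_uniform(fan_in, fan_out, c(fan_in, fan_out)),
            b = numeric(fan_out),
            param_names = c("W", "b"))
}

layer_lstm <- function(input_size, hidden, return_seq = TRUE,
                       go_backward = FALSE) {
  # gate order in the concatenated matrices: f, i, a, o
  W_x <- glorot_uniform(input_size, 4 * hidden, c(input_size, 4 * hidden))
  W_h <- do.call(cbind, lapply(1:4, function(g) orthogonal_init(hidden, hidden)))
  b <- numeric(4 * hidden)
  b[seq_len(hidden)] <- 1  # forget-gate bias 1: standard recurrent init
  new_layer("lstm",
            W_x = W_x, W_h = W_h, b = b,
            hidden = hidden, input_size = input_size,
            return_seq = return_seq, go_backward = go_backward,
            param_names = c("W_x", "W_h", "b"))
}

layer_bilstm <- function(input_size, hidden, return_seq = TRUE) {
  new_layer("bilstm",
            fw = layer_lstm(input_size, hidden, return_seq, FALSE),
            bw = layer_lstm(input_size, hidden, return_seq, TRUE),
            hidden = hidden, input_size = input_size,
            return_seq = return_seq,
            param_names = character(0))
}

layer_simple <- function(type, ...) new_layer(type, ..., param_names = character(0))

# ---------------------------------------------------------------- forward --

conv1d_forward <- function(layer, X) {
  d <- dim(X)
  B <- d[1]; L <- d[2]; Cin <- d[3]
  K <- layer$kernel
  if (layer$padding == "same") {
    pl <- (K - 1L) %/% 2L
    Lp <- L + K - 1L
    Xp <- array(0, c(B, Lp, Cin))
    Xp[, pl + seq_len(L), ] <- X
    Lout <- L
  } else {
    Xp <- X
    Lp <- L
    Lout <- L - K + 1L
  }
  Cout <- dim(layer$W)[3]
  M <- matrix(0, B * Lout, K * Cin)
  for (k in seq_len(K)) {
    M[, (k - 1L) * Cin + seq_len(Cin)] <-
      matrix(Xp[, k + seq_len(Lout) - 1L, , drop = FALSE], B * Lout, Cin)
  }
  Wmat <- matrix(aperm(layer$W, c(2, 1, 3)), K * Cin, Cout)
  Y <- M %*% Wmat
  Y <- Y + rep(layer$b, each = B * Lout)
  layer$cache <- list(M = M, B = B, L = L, Lout = Lout, Lp = Lp,
                      Cin = Cin, Wmat = Wmat)
  array(Y, c(B, Lout, Cout))
}

conv1d_backward <- function(layer, dY) {
  cc <- layer$cache
  K <- layer$kernel
  Cout <- dim(layer$W)[3]
  dYm <- matrix(dY, cc$B * cc$Lout, Cout)
  gWmat <- crossprod(cc$M, dYm)
  layer$gW <- aperm(array(gWmat, c(cc$Cin, K, Cout)), c(2, 1, 3))
  layer$gb <- colSums(dYm)
  dM <- tcrossprod(dYm, cc$Wmat)
  dXp <- array(0, c(cc$B, cc$Lp, cc$Cin))
  for (k in seq_len(K)) {
    dXp[, k + seq_len(cc$Lout) - 1L, ] <-
      dXp[, k + seq_len(cc$Lout) - 1L, , drop = FALSE] +
      array(dM[, (k - 1L) * cc$Cin + seq_len(cc$Cin)],
            c(cc$B, cc$Lout, cc$Cin))
  }
  if (layer$padding == "same") {
    pl <- (K - 1L) %/% 2L
    dXp[, pl + seq_len(cc$L), , drop = FALSE]
  } else {
    dXp
  }
}

maxpool_forward <- function(layer, X) {
  d <- dim(X)
  Lout <- d[2] %/% 2L
  i1 <- 2L * seq_len(Lout) - 1L
  x1 <- X[, i1, , drop = FALSE]
  x2 <- X[, i1 + 1L, , drop = FALSE]
  second <- x2 > x1
  Y <- x1
  Y[second] <- x2[second]
  layer$cache <- list(second = second, d = d, Lout = Lout)
  Y
}

maxpool_backward <- function(layer, dY) {
  cc <- layer$cache
  dX <- array(0, cc$d)
  i1 <- 2L * seq_len(cc$Lout) - 1L
  d1 <- dY
  d1[cc$second] <- 0
  d2 <- dY
  d2[!cc$second] <- 0
  dX[, i1, ] <- d1
  dX[, i1 + 1L, ] <- d2
  dX
}

lstm_layer_forward <- function(layer, X) {
  d <- dim(X)
  B <- d[1]; Tn <- d[2]
  H <- layer$hidden
  order_t <- if (layer$go_backward) rev(seq_len(Tn)) else seq_len(Tn)
  h <- matrix(0, B, H)
  c_state <- matrix(0, B, H)
  out <- array(0, c(B, Tn, H))
  steps <- vector("list", Tn)
  gi <- seq_len(H)
  for (s in seq_len(Tn)) {
    t <- order_t[s]
    x_t <- matrix(X[, t, ], B, d[3])
    Z <- x_t %*% layer$W_x + h %*% layer$W_h
    Z <- Z + rep(layer$b, each = B)
    f <- sigmoid(Z[, gi, drop = FALSE])
    i <- sigmoid(Z[, H + gi, drop = FALSE])
    a <- tanh(Z[, 2L * H + gi, drop = FALSE])
    o <- sigmoid(Z[, 3L * H + gi, drop = FALSE])
    c_new <- c_state * f + i * a
    tc <- tanh(c_new)
    h_new <- o * tc
    steps[[s]] <- list(x = x_t, h_prev = h, c_prev = c_state,
                       f = f, i = i, a = a, o = o, tc = tc)
    h <- h_new
    c_state <- c_new
    out[, t, ] <- h
  }
  layer$cache <- list(steps = steps, order_t = order_t, B = B, Tn = Tn,
                      in_dim = d[3])
  if (layer$return_seq) out else h
}

lstm_layer_backward <- function(layer, dOut) {
  cc <- layer$cache
  B <- cc$B; Tn <- cc$Tn; H <- layer$hidden
  gi <- seq_len(H)
  gW_x <- array(0, dim(layer$W_x))
  gW_h <- array(0, dim(layer$W_h))
  gb <- numeric(length(layer$b))
  dX <- array(0, c(B, Tn, cc$in_dim))
  dh <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  for (s in rev(seq_len(Tn))) {
    t <- cc$order_t[s]
    st <- cc$steps[[s]]
    if (layer$return_seq) {
      dh <- dh + matrix(dOut[, t, ], B, H)
    } else if (s == Tn) {
      dh <- dh + dOut
    }
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    df <- dc * st$c_prev
    di <- dc * st$a
    da <- dc * st$i
    dc_prev <- dc * st$f
    dZ <- cbind(
      df * st$f * (1 - st$f),
      di * st$i * (1 - st$i),
      da * (1 - st$a^2),
      do_ * st$o * (1 - st$o)
    )
    gW_x <- gW_x + crossprod(st$x, dZ)
    gW_h <- gW_h + crossprod(st$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dX[, t, ] <- dZ %*% t(layer$W_x)
    dh <- dZ %*% t(layer$W_h)
    dc <- dc_prev
  }
  layer$gW_x <- gW_x
  layer$gW_h <- gW_h
  layer$gb <- gb
  dX
}

bilstm_layer_forward <- function(layer, X) {
  yf <- lstm_layer_forward(layer$fw, X)
  yb <- lstm_layer_forward(layer$bw, X)
  if (layer$return_seq) {
    d <- dim(yf)
    out <- array(0, c(d[1], d[2], 2L * d[3]))
    out[, , seq_len(d[3])] <- yf
    out[, , d[3] + seq_len(d[3])] <- yb
    out
  } else {
    cbind(yf, yb)
  }
}

bilstm_layer_backward <- function(layer, dOut) {
  H <- layer$hidden
  if (layer$return_seq) {
    dXf <- lstm_layer_backward(layer$fw, dOut[, , seq_len(H), drop = FALSE])
    dXb <- lstm_layer_backward(layer$bw,
                               dOut[, , H + seq_len(H), drop = FALSE])
  } else {
    dXf <- lstm_layer_backward(layer$fw, dOut[, seq_len(H), drop = FALSE])
    dXb <- lstm_layer_backward(layer$bw, dOut[, H + seq_len(H), drop = FALSE])
  }
  dXf + dXb
}

layer_forward <- function(layer, X, train = FALSE) {
  switch(layer$type,
    to_3d = {
      layer$cache <- dim(X)
      array(X, c(dim(X), 1L))
    },
    conv1d = conv1d_forward(layer, X),
    relu = {
      mask <- X > 0
      layer$cache <- mask
      X * mask
    },
    maxpool = maxpool_forward(layer, X),
    flatten = {
      d <- dim(X)
      layer$cache <- d
      matrix(X, d[1], prod(d[-1]))
    },
    dense = {
      layer$cache <- X
      X %*% layer$W + rep(layer$b, each = nrow(X))
    },
    dropout = {
      if (train && layer$rate > 0) {
        mask <- matrix(
          rbinom(length(X), 1L, 1 - layer$rate) / (1 - layer$rate),
          nrow(X), ncol(X)
        )
        layer$cache <- mask
        X * mask
      } else {
        layer$cache <- NULL
        X
      }
    },
    reshape_seq = {
      B <- nrow(X)
      Fd <- ncol(X) %/% layer$timesteps
      layer$cache <- c(B, ncol(X))
      aperm(array(X, c(B, Fd, layer$timesteps)), c(1, 3, 2))
    },
    lstm = lstm_layer_forward(layer, X),
    bilstm = bilstm_layer_forward(layer, X),
    sigmoid = {
      Y <- sigmoid(X)
      layer$cache <- Y
      Y
    },
    abort(paste0("Unknown layer type '", layer$type, "'."))
  )
}

layer_backward <- function(layer, dY) {
  switch(layer$type,
    to_3d = matrix(dY, layer$cache[1], layer$cache[2]),
    conv1d = conv1d_backward(layer, dY),
    relu = dY * layer$cache,
    maxpool = maxpool_backward(layer, dY),
    flatten = array(dY, layer$cache),
    dense = {
      layer$gW <- crossprod(layer$cache, dY)
      layer$gb <- colSums(dY)
      tcrossprod(dY, layer$W)
    },
    dropout = if (is.null(layer$cache)) dY else dY * layer$cache,
    reshape_seq = {
      d <- layer$cache
      matrix(aperm(dY, c(1, 3, 2)), d[1], d[2])
    },
    lstm = lstm_layer_backward(layer, dY),
    bilstm = bilstm_layer_backward(layer, dY),
    sigmoid = dY * layer$cache * (1 - layer$cache),
    abort(paste0("Unknown layer type '", layer$type, "'."))
  )
}

nn_forward <- function(layers, X, train = FALSE) {
  for (layer in layers) X <- layer_forward(layer, X, train)
  X
}

# Backward from the gradient w.r.t. the pre-sigmoid logits: skips the final
# sigmoid layer (the binary cross-entropy gradient (p - y)/B is taken
# directly w.r.t. the logits for numerical stability).
nn_backward_from_logits <- function(layers, dlogits) {
  stopifnot(layers[[length(layers)]]$type == "sigmoid")
  g <- dlogits
  for (i in rev(seq_len(length(layers) - 1L))) {
    g <- layer_backward(layers[[i]], g)
  }
  invisible(g)
}

trainable_layers <- function(layers) {
  out <- list()
  for (layer in layers) {
    if (layer$type == "bilstm") {
      out <- c(out, list(layer$fw, layer$bw))
    } else if (length(layer$param_names) > 0) {
      out <- c(out, list(layer))
    }
  }
  out
}

adam_init <- function(layers) {
  for (layer in trainable_layers(layers)) {
    for (nm in layer$param_names) {
      assign(paste0("m_", nm), array(0, dim(layer[[nm]]) %||% length(layer[[nm]])),
             envir = layer)
      assign(paste0("v_", nm), array(0, dim(layer[[nm]]) %||% length(layer[[nm]])),
             envir = layer)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (layer in trainable_layers(layers)) {
    for (nm in layer$param_names) {
      g <- layer[[paste0("g", nm)]]
      m <- beta1 * layer[[paste0("m_", nm)]] + (1 - beta1) * g
      v <- beta2 * layer[[paste0("v_", nm)]] + (1 - beta2) * g^2
      assign(paste0("m_", nm), m, envir = layer)
      assign(paste0("v_", nm), v, envir = layer)
      upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      assign(nm, layer[[nm]] - upd, envir = layer)
    }
  }
}
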