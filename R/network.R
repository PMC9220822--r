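#' Hyperparameter bundle for the CNN-Bi-LSTM classifier
#'
#' Captures the published architecture: four 1-D convolution layers with
#' 64, 64, 128, 128 kernels of shape 3 and stride 1; max pooling (window 2,
#' stride 2) after the first and fourth convolutions; a 256-unit fully
#' connected layer (with dropout) that maps the convolutional features to
#' the Bi-LSTM input; two stacked bidirectional LSTMs of 64 units each;
#' a 256/128/64 fully connected head, dropout after each; and a single
#' sigmoid output unit. Training uses Adam with learning rate 0.001; the
#' published run used 100 epochs at batch size 200.
#'
#' The 256-unit dense output is reshaped into a `timesteps x features`
#' sequence before the Bi-LSTM (the product must equal the dense width);
#' the default 4 x 64 is the smallest-sequence reading and is configurable.
#'
#' @param input_length Length of the (wavelet-denoised) input vector;
#'   normally [feature_length()] of the preprocessing chain.
#' @param conv_stack List of `c(filters, kernel, stride)` triples.
#' @param pool_size,pool_stride Max-pooling geometry.
#' @param pool_after Indices of conv layers followed by pooling.
#' @param pre_rnn_dense Width of the dense layer feeding the Bi-LSTM.
#' @param bilstm_units Units of the two stacked Bi-LSTMs.
#' @param head_dense Widths of the fully connected head.
#' @param dropout_rate Dropout probability (all dropout layers).
#' @param learning_rate,epochs,batch_size Adam optimiser settings.
#' @param rnn_timesteps Timesteps of the dense-to-sequence reshape;
#'   features per step is `pre_rnn_dense / rnn_timesteps`.
#' @param padding_mode Convolution padding, `"same"` (length preserved;
#'   pooling is then the only length reducer) or `"valid"`.
#' @param seed Integer seed controlling weight initialisation.
#' @return A `model_config` list.
#' @export
model_config <- function(input_length,
                         conv_stack = list(c(64, 3, 1), c(64, 3, 1),
                                           c(128, 3, 1), c(128, 3, 1)),
                         pool_size = 2, pool_stride = 2,
                         pool_after = c(1, 4),
                         pre_rnn_dense = 256,
                         bilstm_units = c(64, 64),
                         head_dense = c(256, 128, 64),
                         dropout_rate = 0.5,
                         learning_rate = 0.001,
                         epochs = 100,
                         batch_size = 200,
                         rnn_timesteps = 4,
                         padding_mode = c("same", "valid"),
                         seed = 1L) {
  padding_mode <- match.arg(padding_mode)
  if (length(conv_stack) != 4L) abort("conv_stack must have 4 layers.")
  if (pre_rnn_dense %% rnn_timesteps != 0L) {
    abort("rnn_timesteps must divide pre_rnn_dense.")
  }
  if (any(c(pre_rnn_dense, bilstm_units, head_dense) <= 0)) {
    abort("Layer widths must be positive.")
  }
  structure(
    list(
      input_length = as.integer(input_length),
      conv_stack = conv_stack,
      pool_size = pool_size, pool_stride = pool_stride,
      pool_after = pool_after,
      pre_rnn_dense = pre_rnn_dense,
      bilstm_units = bilstm_units,
      head_dense = head_dense,
      dropout_rate = dropout_rate,
      learning_rate = learning_rate,
      epochs = epochs,
      batch_size = batch_size,
      rnn_timesteps = as.integer(rnn_timesteps),
      padding_mode = padding_mode,
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

conv_out_length <- function(L, kernel, stride, padding) {
  if (padding == "same") ceiling(L / stride) else (L - kernel) %/% stride + 1L
}

#' Build an untrained classifier
#'
#' Assembles one of five architectures from a [model_config()]:
#' \describe{
#'   \item{`proposed`}{the full stack — conv1/ReLU/pool, conv2, conv3,
#'     conv4/pool, dense-256 + dropout, reshape to a sequence, two stacked
#'     Bi-LSTM(64), dense 256/128/64 each with dropout, sigmoid. Fed with
#'     wavelet-denoised features.}
#'   \item{`cnn_bilstm`}{the identical layer graph; in the comparison
#'     harness it is fed raw standardized samples instead of wavelet
#'     features (the front-end difference lives in the preprocessing, not
#'     the graph).}
#'   \item{`cnn`}{the convolutional stack and dense head only.}
#'   \item{`lstm`}{the input treated as a 1-feature sequence through a
#'     single LSTM(64), then the sigmoid unit.}
#'   \item{`bilstm`}{likewise with one Bi-LSTM(64).}
#' }
#' Weight initialisation (Glorot-uniform for conv/dense and LSTM input
#' weights, orthogonal recurrent blocks, forget-gate bias 1) is fully
#' determined by `config$seed`: two builds from the same config are
#' identical.
#'
#' @param config A [model_config()].
#' @param architecture One of `"proposed"`, `"cnn"`, `"lstm"`, `"bilstm"`,
#'   `"cnn_bilstm"`.
#' @return An `eeg_model` object (layer list + config), untrained.
#' @export
build_model <- function(config,
                        architecture = c("proposed", "cnn", "lstm",
                                         "bilstm", "cnn_bilstm")) {
  stopifnot(inherits(config, "model_config"))
  architecture <- match.arg(architecture)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  layers <- list(layer_simple("to_3d"))
  L <- config$input_length
  C <- 1L
  p <- config$dropout_rate

  add_conv_stack <- function(layers, L, C) {
    for (i in seq_along(config$conv_stack)) {
      cs <- config$conv_stack[[i]]
      layers <- c(layers, list(
        layer_conv1d(C, cs[1], cs[2], config$padding_mode),
        layer_simple("relu")
      ))
      L <- conv_out_length(L, cs[2], cs[3], config$padding_mode)
      C <- cs[1]
      if (i %in% config$pool_after) {
        layers <- c(layers, list(layer_simple("maxpool")))
        L <- L %/% config$pool_stride
      }
    }
    list(layers = layers, L = L, C = C)
  }

  if (architecture %in% c("proposed", "cnn_bilstm")) {
    st <- add_conv_stack(layers, L, C)
    layers <- st$layers
    layers <- c(layers, list(
      layer_simple("flatten"),
      layer_dense(st$L * st$C, config$pre_rnn_dense),
      layer_simple("relu"),
      layer_simple("dropout", rate = p),
      layer_simple("reshape_seq", timesteps = config$rnn_timesteps)
    ))
    feat <- config$pre_rnn_dense %/% config$rnn_timesteps
    layers <- c(layers, list(
      layer_bilstm(feat, config$bilstm_units[1], return_seq = TRUE),
      layer_bilstm(2L * config$bilstm_units[1], config$bilstm_units[2],
                   return_seq = FALSE)
    ))
    width <- 2L * config$bilstm_units[2]
    for (h in config$head_dense) {
      layers <- c(layers, list(
        layer_dense(width, h),
        layer_simple("relu"),
        layer_simple("dropout", rate = p)
      ))
      width <- h
    }
    layers <- c(layers, list(layer_dense(width, 1L), layer_simple("sigmoid")))
  } else if (architecture == "cnn") {
    st <- add_conv_stack(layers, L, C)
    layers <- st$layers
    layers <- c(layers, list(layer_simple("flatten")))
    width <- st$L * st$C
    for (h in config$head_dense) {
      layers <- c(layers, list(
        layer_dense(width, h),
        layer_simple("relu"),
        layer_simple("dropout", rate = p)
      ))
      width <- h
    }
    layers <- c(layers, list(layer_dense(width, 1L), layer_simple("sigmoid")))
  } else if (architecture == "lstm") {
    layers <- c(layers, list(
      layer_lstm(1L, config$bilstm_units[1], return_seq = FALSE),
      layer_dense(config$bilstm_units[1], 1L),
      layer_simple("sigmoid")
    ))
  } else if (architecture == "bilstm") {
    layers <- c(layers, list(
      layer_bilstm(1L, config$bilstm_units[1], return_seq = FALSE),
      layer_dense(2L * config$bilstm_units[1], 1L),
      layer_simple("sigmoid")
    ))
  }

  structure(
    list(layers = layers, config = config, architecture = architecture,
         trained = FALSE),
    class = "eeg_model"
  )
}

#' @export
print.eeg_model <- function(x, ...) {
  cat("<eeg_model>", x$architecture, "| input", x$config$input_length,
      "|", if (x$trained) "trained" else "untrained", "\n")
  print(describe_model(x), n = 30)
  invisible(x)
}

#' Predicted class probabilities
#'
#' Runs the forward pass in inference mode (dropout disabled) and returns
#' the sigmoid output: the probability of the positive (alcoholic) class.
#'
#' @param object An `eeg_model`.
#' @param x Numeric matrix, samples x `input_length`.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.eeg_model <- function(object, x, ...) {
  stopifnot(is.matrix(x), ncol(x) == object$config$input_length)
  as.numeric(nn_forward(object$layers, x, train = FALSE))
}

#' Layer-by-layer shape and parameter table
#'
#' Walks the layer graph with a symbolic batch of size 1, reporting each
#' layer's output shape (excluding the batch dimension) and trainable
#' parameter count. Counts follow the closed forms
#' `kernel * C_in * C_out + C_out` for convolutions,
#' `F_in * F_out + F_out` for dense layers and `4 (H^2 + H F + H)` per LSTM
#' direction.
#'
#' @param model An `eeg_model`.
#' @return A tibble with columns `layer`, `output_shape`, `params`.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "eeg_model"))
  shape <- c(model$config$input_length)
  rows <- list()
  for (layer in model$layers) {
    n_par <- 0
    out <- switch(layer$type,
      to_3d = c(shape[1], 1L),
      conv1d = {
        n_par <- prod(dim(layer$W)) + length(layer$b)
        c(conv_out_length(shape[1], layer$kernel, 1L, layer$padding),
          dim(layer$W)[3])
      },
      relu = shape,
      maxpool = c(shape[1] %/% 2L, shape[2]),
      flatten = prod(shape),
      dense = {
        n_par <- prod(dim(layer$W)) + length(layer$b)
        ncol(layer$W)
      },
      dropout = shape,
      reshape_seq = c(layer$timesteps, shape[1] %/% layer$timesteps),
      lstm = {
        n_par <- length(layer$W_x) + length(layer$W_h) + length(layer$b)
        if (layer$return_seq) c(shape[1], layer$hidden) else layer$hidden
      },
      bilstm = {
        n_par <- 2 * (length(layer$fw$W_x) + length(layer$fw$W_h) +
                        length(layer$fw$b))
        if (layer$return_seq) c(shape[1], 2L * layer$hidden)
        else 2L * layer$hidden
      },
      sigmoid = shape
    )
    rows[[length(rows) + 1L]] <- tibble(
      layer = layer$type,
      output_shape = paste(out, collapse = "x"),
      params = n_par
    )
    shape <- out
  }
  dplyr::bind_rows(rows)
}

# ------------------------------------------------- reference LSTM kernels --

#' Per-gate LSTM weight bundle
#'
#' The reference parameterisation of one LSTM cell: for each gate g in
#' {forget f, input i, candidate a, output o}, `W_g` (hidden x hidden)
#' multiplies the previous hidden state, `U_g` (hidden x input) multiplies
#' the current input, and `b_g` is the bias.
#'
#' @param W_f,W_i,W_a,W_o Hidden-to-gate matrices, `hidden x hidden`.
#' @param U_f,U_i,U_a,U_o Input-to-gate matrices, `hidden x input`.
#' @param b_f,b_i,b_a,b_o Bias vectors, length `hidden`.
#' @return An `lstm_weights` object.
#' @export
lstm_weights <- function(W_f, W_i, W_a, W_o, U_f, U_i, U_a, U_o,
                         b_f, b_i, b_a, b_o) {
  W_f <- as.matrix(W_f); W_i <- as.matrix(W_i)
  W_a <- as.matrix(W_a); W_o <- as.matrix(W_o)
  U_f <- as.matrix(U_f); U_i <- as.matrix(U_i)
  U_a <- as.matrix(U_a); U_o <- as.matrix(U_o)
  H <- nrow(U_f)
  Fi <- ncol(U_f)
  for (m in list(W_f, W_i, W_a, W_o)) {
    if (!all(dim(m) == c(H, H))) abort("W_* must be hidden x hidden.")
  }
  for (m in list(U_i, U_a, U_o)) {
    if (!all(dim(m) == c(H, Fi))) abort("U_* must be hidden x input.")
  }
  for (v in list(b_f, b_i, b_a, b_o)) {
    if (length(v) != H) abort("b_* must have length hidden.")
  }
  structure(
    list(W_f = W_f, W_i = W_i, W_a = W_a, W_o = W_o,
         U_f = U_f, U_i = U_i, U_a = U_a, U_o = U_o,
         b_f = b_f, b_i = b_i, b_a = b_a, b_o = b_o,
         hidden_size = H, input_size = Fi),
    class = "lstm_weights"
  )
}

#' One step of the LSTM recurrence
#'
#' The gate equations, evaluated literally: with logistic sigma,
#' `f = sigma(W_f h + U_f x + b_f)`, `i` and `o` analogous,
#' `a = tanh(W_a h + U_a x + b_a)`, cell update
#' `c = c_prev * f + i * a` (elementwise), hidden state
#' `h = o * tanh(c)`. Every hidden-state component therefore lies in
#' (-1, 1) and every gate activation in (0, 1).
#'
#' @param x_t Input vector at time t (length `input_size`).
#' @param prev List with `h` and `c`, the previous hidden and cell state
#'   (length `hidden_size` each).
#' @param w An [lstm_weights()] bundle.
#' @return List with the new `h` and `c`, plus the gate activations
#'   (`f`, `i`, `a`, `o`) as attribute `"gates"`.
#' @examples
#' w <- lstm_weights(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0)
#' lstm_cell_step(0.5, list(h = 0, c = 0), w)
#' @export
lstm_cell_step <- function(x_t, prev, w) {
  stopifnot(inherits(w, "lstm_weights"))
  x_t <- as.numeric(x_t)
  h_prev <- as.numeric(prev$h)
  c_prev <- as.numeric(prev$c)
  if (length(x_t) != w$input_size) abort("x_t has the wrong length.")
  if (length(h_prev) != w$hidden_size || length(c_prev) != w$hidden_size) {
    abort("prev$h / prev$c have the wrong length.")
  }
  if (!all(is.finite(c(x_t, h_prev, c_prev)))) {
    abort("Non-finite inputs to lstm_cell_step.")
  }
  f <- sigmoid(as.numeric(w$W_f %*% h_prev + w$U_f %*% x_t + w$b_f))
  i <- sigmoid(as.numeric(w$W_i %*% h_prev + w$U_i %*% x_t + w$b_i))
  a <- tanh(as.numeric(w$W_a %*% h_prev + w$U_a %*% x_t + w$b_a))
  o <- sigmoid(as.numeric(w$W_o %*% h_prev + w$U_o %*% x_t + w$b_o))
  c_new <- c_prev * f + i * a
  h_new <- o * tanh(c_new)
  structure(list(h = h_new, c = c_new),
            gates = list(f = f, i = i, a = a, o = o))
}

#' Bidirectional LSTM forward pass over one sequence
#'
#' Two independent LSTMs — one running t = 1..T, one t = T..1, both from
#' zero initial states — with their per-step hidden states concatenated
#' (forward block first). Row t of the output corresponds to input step t
#' for both directions.
#'
#' @param sequence Numeric matrix, `T x input_size` (T >= 1).
#' @param fw,bw [lstm_weights()] for the forward and backward directions.
#' @param merge Only `"concat"` is supported.
#' @return Numeric matrix `T x (2 * hidden_size)`.
#' @export
bilstm_forward <- function(sequence, fw, bw, merge = "concat") {
  if (merge != "concat") abort("Only merge = 'concat' is supported.")
  sequence <- as.matrix(sequence)
  Tn <- nrow(sequence)
  if (Tn < 1L) abort("Sequence must have at least one step.")
  run <- function(w, times) {
    st <- list(h = numeric(w$hidden_size), c = numeric(w$hidden_size))
    out <- matrix(0, Tn, w$hidden_size)
    for (t in times) {
      st <- lstm_cell_step(sequence[t, ], st, w)
      out[t, ] <- st$h
    }
    out
  }
  cbind(run(fw, seq_len(Tn)), run(bw, rev(seq_len(Tn))))
}
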