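# Independent reference implementations used only as test oracles.

# Literal scalar transcription of the LSTM gate equations: plain loops,
# no matrix algebra, written independently of the package kernels.
scalar_lstm_step <- function(x, h_prev, c_prev, w) {
  H <- w$hidden_size
  sig <- function(z) 1 / (1 + exp(-z))
  lin <- function(W, U, b, j) {
    acc <- b[j]
    for (k in seq_along(h_prev)) acc <- acc + W[j, k] * h_prev[k]
    for (k in seq_along(x)) acc <- acc + U[j, k] * x[k]
    acc
  }
  h <- numeric(H)
  c_new <- numeric(H)
  for (j in seq_len(H)) {
    f <- sig(lin(w$W_f, w$U_f, w$b_f, j))
    i <- sig(lin(w$W_i, w$U_i, w$b_i, j))
    a <- tanh(lin(w$W_a, w$U_a, w$b_a, j))
    o <- sig(lin(w$W_o, w$U_o, w$b_o, j))
    c_new[j] <- c_prev[j] * f + i * a
    h[j] <- o * tanh(c_new[j])
  }
  list(h = h, c = c_new)
}

random_lstm_weights <- function(hidden, input, scale = 0.5) {
  m <- function(r, c) matrix(rnorm(r * c, sd = scale), r, c)
  lstm_weights(
    W_f = m(hidden, hidden), W_i = m(hidden, hidden),
    W_a = m(hidden, hidden), W_o = m(hidden, hidden),
    U_f = m(hidden, input), U_i = m(hidden, input),
    U_a = m(hidden, input), U_o = m(hidden, input),
    b_f = rnorm(hidden, sd = scale), b_i = rnorm(hidden, sd = scale),
    b_a = rnorm(hidden, sd = scale), b_o = rnorm(hidden, sd = scale)
  )
}

# Third-party multilevel DWT (PyWavelets) as an external oracle, called
# through the python interpreter on PATH. Returns list(approx, details)
# with details ordered level 1..L, matching dwt_multilevel().
pywt_wavedec <- function(x, wavelet, padding, level) {
  mode <- c(periodic = "periodization", symmetric = "symmetric",
            zero = "zero")[[padding]]
  infile <- tempfile(fileext = ".txt")
  writeLines(sprintf("%.17g", x), infile)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pywt, numpy as np",
    "x = np.loadtxt(sys.argv[1])",
    "coeffs = pywt.wavedec(x, sys.argv[2], mode=sys.argv[3], level=int(sys.argv[4]))",
    "print(' '.join('%.17g' % v for v in coeffs[0]))",
    "for d in reversed(coeffs[1:]):",
    "    print(' '.join('%.17g' % v for v in d))"
  ), script)
  out <- system2("python", c(script, infile, wavelet, mode, level),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("pywt oracle failed: ", paste(out, collapse = "\n"))
  }
  parse_line <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  list(
    approx = parse_line(out[1]),
    details = lapply(out[-1], parse_line)
  )
}

# Direct per-sample metric recomputation (no confusion-matrix algebra).
brute_metrics <- function(pred, truth) {
  list(
    accuracy = mean(pred == truth),
    precision = if (sum(pred == 1) > 0) {
      mean(truth[pred == 1] == 1)
    } else 0,
    recall = if (sum(truth == 1) > 0) {
      mean(pred[truth == 1] == 1)
    } else 0
  )
}
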