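#' Orthogonal wavelet filter specifications
#'
#' Builds the four-filter quadrature-mirror bank of a named orthogonal
#' wavelet. Analysis filters (`dec_lo`, `dec_hi`) are used by the forward
#' transform, synthesis filters (`rec_lo`, `rec_hi`) by the inverse. Only the
#' scaling filter is stored on disk (in `extdata/wavelets.txt`); the other
#' three follow from the orthogonal quadrature-mirror relations
#' `dec_hi[k] = (-1)^(k+1) dec_lo[L-1-k]` (0-based), `rec_lo = rev(dec_lo)`,
#' `rec_hi = rev(dec_hi)`.
#'
#' Padding modes, matching the conventions of the mainstream wavelet
#' libraries so coefficients are directly comparable:
#' \describe{
#'   \item{`periodic`}{periodized transform: non-expansive, output length
#'     `ceil(n/2)` per branch, orthonormal (energy preserving) for even `n`.}
#'   \item{`symmetric`}{half-point symmetric boundary extension; output
#'     length `floor((n + L - 1)/2)`.}
#'   \item{`zero`}{zero boundary extension; same output length as
#'     `symmetric`.}
#' }
#'
#' @param name Wavelet name; one of the names in the shipped filter table
#'   (`haar`, `db2`, `db3`, `db4`) or a name registered via `dec_lo`.
#' @param padding Boundary handling, see Details.
#' @param dec_lo Optional numeric vector of scaling-filter coefficients; when
#'   supplied, `name` is just a label and the table is not consulted. Must
#'   have even length.
#' @return An object of class `wavelet_spec`: a list with `name`, `dec_lo`,
#'   `dec_hi`, `rec_lo`, `rec_hi`, `filter_length`, `padding`.
#' @examples
#' wavelet_spec("haar")
#' wavelet_spec("db4", padding = "periodic")
#' @export
wavelet_spec <- function(name = "db4",
                         padding = c("symmetric", "periodic", "zero"),
                         dec_lo = NULL) {
  padding <- match.arg(padding)
  if (is.null(dec_lo)) {
    tab <- wavelet_filter_table()
    if (!name %in% names(tab)) {
      abort(paste0(
        "Unknown wavelet '", name, "'. Available: ",
        paste(names(tab), collapse = ", ")
      ))
    }
    dec_lo <- tab[[name]]
  }
  L <- length(dec_lo)
  if (L < 2L || L %% 2L != 0L) {
    abort("Scaling filter must have even length >= 2.")
  }
  k <- seq_len(L)
  dec_hi <- (-1)^k * dec_lo[L + 1L - k]
  structure(
    list(
      name = name,
      dec_lo = dec_lo,
      dec_hi = dec_hi,
      rec_lo = rev(dec_lo),
      rec_hi = rev(dec_hi),
      filter_length = L,
      padding = padding
    ),
    class = "wavelet_spec"
  )
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat("<wavelet_spec>", x$name, "| filter length", x$filter_length,
      "| padding", x$padding, "\n")
  invisible(x)
}

# Filter table is read once per session from extdata and memoised.
the_wavelet_cache <- new.env(parent = emptyenv())

wavelet_filter_table <- function() {
  if (!is.null(the_wavelet_cache$table)) {
    return(the_wavelet_cache$table)
  }
  path <- system.file("extdata", "wavelets.txt", package = "alcoeeg",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  tab <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    tab[[parts[1]]] <- as.numeric(parts[-1])
  }
  the_wavelet_cache$table <- tab
  tab
}

# Full (polynomial) convolution of two vectors.
conv_full <- function(a, b) {
  stats::convolve(a, rev(b), type = "open")
}

extend_signal <- function(x, pad, mode) {
  n <- length(x)
  switch(mode,
    zero = c(numeric(pad), x, numeric(pad)),
    symmetric = {
      if (pad > n) abort("Signal too short for symmetric extension.")
      c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
    },
    abort(paste0("Unknown padding mode '", mode, "'."))
  )
}

#' Single-level discrete wavelet transform
#'
#' Decomposes a signal into approximation (low-pass) and detail (high-pass)
#' coefficients at dyadic scale: the signal is convolved with the analysis
#' filters and downsampled by two. Boundary handling follows `spec$padding`.
#'
#' @param x Numeric vector, the signal (length at least the filter length
#'   for `symmetric`/`zero` padding).
#' @param spec A [wavelet_spec()].
#' @return A list with numeric vectors `approx` and `detail`, equal length.
#' @examples
#' dwt_single_level(c(4, 6, 10, 12), wavelet_spec("haar", padding = "periodic"))
#' @export
dwt_single_level <- function(x, spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  n <- length(x)
  if (n == 0L) abort("Empty signal.")
  if (!all(is.finite(x))) abort("Signal contains non-finite values.")
  L <- spec$filter_length
  if (spec$padding == "periodic") {
    xe <- if (n %% 2L == 1L) c(x, x[n]) else x
    ne <- length(xe)
    m <- ne %/% 2L
    approx <- numeric(m)
    detail <- numeric(m)
    base <- 2L * seq_len(m) - 2L + L %/% 2L  # 0-based centre position
    for (j in seq_len(L)) {
      idx <- (base - (j - 1L)) %% ne + 1L
      approx <- approx + spec$dec_lo[j] * xe[idx]
      detail <- detail + spec$dec_hi[j] * xe[idx]
    }
    list(approx = approx, detail = detail)
  } else {
    if (n < L) {
      abort("Signal shorter than the wavelet filter; cannot decompose.")
    }
    pad <- L - 1L
    xe <- extend_signal(x, pad, spec$padding)
    m <- (n + L - 1L) %/% 2L
    take <- L + 1L + 2L * (seq_len(m) - 1L)  # 1-based indices into the full conv
    list(
      approx = conv_full(xe, spec$dec_lo)[take],
      detail = conv_full(xe, spec$dec_hi)[take]
    )
  }
}

#' Maximum admissible decomposition depth
#'
#' Deeper levels would leave fewer approximation samples than the wavelet
#' filter needs.
#'
#' @param n Signal length in samples.
#' @param spec A [wavelet_spec()].
#' @return Integer, the deepest admissible level.
#' @export
max_dwt_level <- function(n, spec) {
  L <- spec$filter_length
  if (L <= 2L) return(max(0L, floor(log2(n))))
  max(0L, floor(log2(n / (L - 1))))
}

#' Multilevel discrete wavelet transform (approximation cascade)
#'
#' Applies [dwt_single_level()] recursively to successive approximations:
#' level 1 decomposes the signal, level 2 decomposes the level-1
#' approximation, and so on. Only the approximation branch is cascaded —
#' the denoising strategy of deepening low-frequency resolution while the
#' high-frequency detail at each scale is set aside.
#'
#' @inheritParams dwt_single_level
#' @param level Positive integer decomposition depth; must not exceed
#'   [max_dwt_level()].
#' @return An object of class `dwt_decomposition`: `approx` (level-`level`
#'   approximation coefficients), `details` (list of detail vectors, level 1
#'   first), `level`, `spec`, `original_length`, and `branch_lengths` (input
#'   length seen at each level, used for exact reconstruction).
#' @examples
#' d <- dwt_multilevel(sin(seq_len(64) / 4), wavelet_spec("db2"), level = 3)
#' length(d$approx)
#' @export
dwt_multilevel <- function(x, spec, level) {
  stopifnot(inherits(spec, "wavelet_spec"))
  level <- as.integer(level)
  if (level < 1L) abort("level must be a positive integer.")
  lmax <- max_dwt_level(length(x), spec)
  if (level > lmax) {
    abort(paste0(
      "level ", level, " too deep for a length-", length(x),
      " signal with filter length ", spec$filter_length,
      "; maximum admissible level is ", lmax, "."
    ))
  }
  details <- vector("list", level)
  branch_lengths <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    branch_lengths[l] <- length(a)
    step <- dwt_single_level(a, spec)
    details[[l]] <- step$detail
    a <- step$approx
  }
  structure(
    list(
      approx = a,
      details = details,
      level = level,
      spec = spec,
      original_length = length(x),
      branch_lengths = branch_lengths
    ),
    class = "dwt_decomposition"
  )
}

#' @export
print.dwt_decomposition <- function(x, ...) {
  cat("<dwt_decomposition>", x$spec$name, "level", x$level,
      "| approx length", length(x$approx),
      "| detail lengths", paste(lengths(x$details), collapse = ", "), "\n")
  invisible(x)
}

idwt_single_level <- function(approx, detail, spec, out_length) {
  if (length(approx) != length(detail)) {
    abort("approx and detail must have equal length.")
  }
  m <- length(approx)
  L <- spec$filter_length
  if (spec$padding == "periodic") {
    ne <- 2L * m
    x <- numeric(ne)
    base <- 2L * seq_len(m) - 2L + L %/% 2L
    for (j in seq_len(L)) {
      idx <- (base - (j - 1L)) %% ne + 1L
      x[idx] <- x[idx] + spec$dec_lo[j] * approx + spec$dec_hi[j] * detail
    }
    x[seq_len(out_length)]
  } else {
    up_a <- numeric(2L * m)
    up_d <- numeric(2L * m)
    up_a[seq.int(1L, 2L * m, by = 2L)] <- approx
    up_d[seq.int(1L, 2L * m, by = 2L)] <- detail
    full <- conv_full(up_a, spec$rec_lo) + conv_full(up_d, spec$rec_hi)
    if (2L * m - L + 2L < out_length) {
      abort("Decomposition too short to reconstruct the requested length.")
    }
    full[seq.int(L - 1L, L - 2L + out_length)]
  }
}

#' Inverse multilevel discrete wavelet transform
#'
#' Reconstructs the signal from a [dwt_multilevel()] decomposition by
#' inverting the cascade level by level. With unmodified coefficients the
#' reconstruction is exact to floating-point precision; zeroing detail
#' vectors first yields the wavelet-smoothed (denoised) signal.
#'
#' @param decomposition A `dwt_decomposition` object.
#' @return Numeric vector of length `decomposition$original_length`.
#' @examples
#' x <- rnorm(100)
#' d <- dwt_multilevel(x, wavelet_spec("db4"), level = 2)
#' max(abs(idwt(d) - x))
#' @export
idwt <- function(decomposition) {
  stopifnot(inherits(decomposition, "dwt_decomposition"))
  a <- decomposition$approx
  spec <- decomposition$spec
  for (l in rev(seq_len(decomposition$level))) {
    a <- idwt_single_level(
      a, decomposition$details[[l]], spec,
      out_length = decomposition$branch_lengths[l]
    )
  }
  a
}

#' Length of the denoised feature vector
#'
#' Closed-form recurrence for the approximation length after `level`
#' cascaded decompositions: `ceil(n/2)` per level for `periodic` padding,
#' `floor((n + L - 1)/2)` per level for `symmetric`/`zero` padding.
#'
#' @param n Signal length in samples.
#' @inheritParams dwt_multilevel
#' @return Integer feature-vector length.
#' @examples
#' feature_length(256, wavelet_spec("db4", padding = "symmetric"), 2) # 69
#' feature_length(256, wavelet_spec("haar", padding = "periodic"), 2) # 64
#' @export
feature_length <- function(n, spec, level) {
  stopifnot(inherits(spec, "wavelet_spec"))
  L <- spec$filter_length
  for (l in seq_len(level)) {
    n <- if (spec$padding == "periodic") ceiling(n / 2) else (n + L - 1L) %/% 2L
  }
  as.integer(n)
}

#' Wavelet-denoised network input features
#'
#' The level-`level` approximation coefficients of the (standardized) signal
#' — the denoised, downsampled representation fed to the classifier. The
#' output length is deterministic given `(n, spec, level)` and equals
#' [feature_length()], so the network input layer can be sized automatically.
#' `target_length` optionally zero-pads or truncates the vector, e.g. to pin
#' the input layer to a fixed published width.
#'
#' @inheritParams dwt_multilevel
#' @param target_length Optional integer; pad with zeros / truncate to this
#'   length.
#' @return Numeric feature vector.
#' @export
denoise_features <- function(x, spec, level, target_length = NULL) {
  a <- dwt_multilevel(x, spec, level)$approx
  if (!is.null(target_length)) {
    if (length(a) >= target_length) {
      a <- a[seq_len(target_length)]
    } else {
      a <- c(a, numeric(target_length - length(a)))
    }
  }
  a
}
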