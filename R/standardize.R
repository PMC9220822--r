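#' Fit a per-feature standardizer
#'
#' Computes per-column mean and population standard deviation so that
#' `apply_standardizer()` maps each feature to zero mean and unit standard
#' deviation: `X' = (X - mu) / sigma`. The population (divide by `n`)
#' standard deviation is used, matching the convention of the usual
#' machine-learning scalers, so a fitted-and-transformed column has sd
#' exactly 1 under the population definition.
#'
#' Zero-variance features are recorded and flagged with a warning at fit
#' time; the transform maps them to 0 rather than dividing by zero.
#'
#' In a classification pipeline fit the standardizer on the training split
#' only and apply it to every split — fitting on all data leaks test-set
#' statistics into training.
#'
#' @param x Numeric matrix or data frame (rows = samples, columns =
#'   features) with at least 2 rows.
#' @return An object of class `standardizer`: list with `mu`, `sigma`
#'   (numeric vectors), `fitted_on` (row count) and `zero_variance`
#'   (logical vector).
#' @examples
#' s <- fit_standardizer(matrix(c(1, 2, 3), ncol = 1))
#' apply_standardizer(s, matrix(c(1, 2, 3), ncol = 1))
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("Standardizer input must be numeric.")
  n <- nrow(x)
  if (n < 2L) abort("Need at least 2 samples to fit a standardizer.")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(x^2) - mu^2)
  sigma[sigma < 0] <- 0  # guard tiny negative from cancellation
  zero_var <- sigma <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(zero_var)) {
    warn(paste0(
      sum(zero_var), " zero-variance feature(s); they will be mapped to 0."
    ))
  }
  structure(
    list(mu = mu, sigma = sigma, fitted_on = n, zero_variance = zero_var),
    class = "standardizer"
  )
}

#' Apply a fitted standardizer
#'
#' @param state A `standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same number of columns the state was
#'   fitted on.
#' @return Matrix of the same shape, `(x - mu) / sigma` column-wise;
#'   zero-variance columns become 0.
#' @export
apply_standardizer <- function(state, x) {
  stopifnot(inherits(state, "standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(state$mu)) {
    abort(paste0(
      "Standardizer was fitted on ", length(state$mu),
      " features but input has ", ncol(x), " columns."
    ))
  }
  sigma <- ifelse(state$zero_variance, 1, state$sigma)
  out <- sweep(sweep(x, 2L, state$mu, "-"), 2L, sigma, "/")
  if (any(state$zero_variance)) out[, state$zero_variance] <- 0
  out
}

#' @export
print.standardizer <- function(x, ...) {
  cat("<standardizer>", length(x$mu), "features, fitted on", x$fitted_on,
      "samples;", sum(x$zero_variance), "zero-variance\n")
  invisible(x)
}

#' @rdname fit_standardizer
#' @details `tidy()` on a `standardizer` returns one row per feature with
#'   `mu`, `sigma` and the zero-variance flag.
#' @param x,... passed through.
#' @export
tidy.standardizer <- function(x, ...) {
  tibble(
    feature = seq_along(x$mu),
    mu = unname(x$mu),
    sigma = unname(x$sigma),
    zero_variance = unname(x$zero_variance)
  )
}
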