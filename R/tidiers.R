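#' Tidy a trained or untrained model
#'
#' One row per layer: type, output shape, parameter count (delegates to
#' [describe_model()]).
#'
#' @param x An `eeg_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eeg_model <- function(x, ...) describe_model(x)

#' One-row model summary
#'
#' @param x An `eeg_model`.
#' @param ... Unused.
#' @return Tibble with architecture, input length, total parameter count,
#'   trained flag, and — when trained — final training accuracy and loss.
#' @export
glance.eeg_model <- function(x, ...) {
  desc <- describe_model(x)
  out <- tibble(
    architecture = x$architecture,
    input_length = x$config$input_length,
    n_params = sum(desc$params),
    trained = x$trained
  )
  if (!is.null(x$curves) && nrow(x$curves) > 0) {
    last <- x$curves[nrow(x$curves), ]
    out$final_train_acc <- last$train_acc
    out$final_train_loss <- last$train_loss
    out$epochs <- nrow(x$curves)
  }
  out
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Long tibble with one row per metric.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(
    metric = c("accuracy", "precision", "recall", "f1"),
    value = c(x$accuracy, x$precision, x$recall, x$f1)
  )
}

#' One-row evaluation summary
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with counts, metrics and threshold.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    accuracy = x$accuracy, precision = x$precision,
    recall = x$recall, f1 = x$f1,
    threshold = x$threshold, n = x$n
  )
}

#' Training-curve plot for a trained model
#'
#' Per-epoch training accuracy and loss on a shared epoch axis, the usual
#' convergence diagnostic.
#'
#' @param object A trained `eeg_model` (with `curves`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_model <- function(object, ...) {
  if (is.null(object$curves)) abort("Model has no training curves; train it first.")
  long <- tidyr::pivot_longer(object$curves, c("train_acc", "train_loss"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(train_acc = "#c0392b", train_loss = "#2e6da4"),
      labels = c(train_acc = "training accuracy",
                 train_loss = "training loss"),
      name = NULL
    ) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste0("Training curves (", object$architecture, ")")) +
    ggplot2::theme_minimal()
}

#' Metric bar plot for an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_col(fill = "#2e6da4", width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Held-out classification metrics") +
    ggplot2::theme_minimal()
}

#' Plot per-channel band power by class
#'
#' Sanity view of the synthetic generator (or any dataset): distribution of
#' per-trial mean band power for each class in a chosen band.
#'
#' @param dataset An `eeg_dataset`.
#' @param center,width Band in Hz.
#' @return A ggplot object.
#' @export
plot_band_power <- function(dataset, center = 10, width = 2) {
  validate_eeg_dataset(dataset)
  d <- tibble(
    label = dataset$label,
    power = purrr::map_dbl(
      dataset$data,
      function(m) mean(band_power(m, center, width,
                                  dataset$sampling_rate[1]))
    )
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$power)) +
    ggplot2::geom_boxplot(fill = "#9ecae1") +
    ggplot2::labs(x = NULL, y = "mean band power (uV^2)",
                  title = sprintf("Band power %g +/- %g Hz", center, width / 2)) +
    ggplot2::theme_minimal()
}
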