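#' Train/test split plan
#'
#' @param mode `"trial_wise"` (default: stratified sampling of trials) or
#'   `"subject_wise"` (whole subjects assigned to one side — the
#'   recommended protocol for EEG, since a subject appearing on both sides
#'   leaks identity information and inflates scores).
#' @param train_fraction Fraction of trials (or subjects) in the training
#'   side.
#' @param stratified Preserve the class ratio (within one sample) when
#'   splitting trial-wise.
#' @param seed Integer; the split is deterministic given the seed.
#' @return A `split_plan` list.
#' @export
split_plan <- function(mode = c("trial_wise", "subject_wise"),
                       train_fraction = 0.8, stratified = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1).")
  }
  structure(
    list(mode = mode, train_fraction = train_fraction,
         stratified = stratified, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Split a dataset into disjoint train and test sides
#'
#' Deterministic given `plan$seed`. Trial-wise stratified splits preserve
#' the class ratio within one trial per class; subject-wise splits keep all
#' of a subject's trials on one side. Errors if either side would end up
#' single-class.
#'
#' @param dataset An `eeg_dataset` tibble.
#' @param plan A [split_plan()].
#' @return List with `train` and `test` tibbles.
#' @export
make_split <- function(dataset, plan) {
  stopifnot(inherits(plan, "split_plan"))
  validate_eeg_dataset(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(plan$seed)

  if (plan$mode == "subject_wise") {
    subj <- dplyr::distinct(as_tibble(dataset)[c("subject_id", "label")])
    if (anyDuplicated(subj$subject_id)) {
      abort("A subject carries both labels; cannot split subject-wise.")
    }
    train_subj <- unlist(lapply(split(subj$subject_id, subj$label), function(s) {
      k <- max(1L, round(plan$train_fraction * length(s)))
      if (k >= length(s)) k <- length(s) - 1L
      if (k < 1L) abort("Need at least 2 subjects per class for subject_wise.")
      sample(s, k)
    }))
    in_train <- dataset$subject_id %in% train_subj
  } else {
    in_train <- logical(nrow(dataset))
    groups <- if (plan$stratified) dataset$label else rep("all", nrow(dataset))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      k <- round(plan$train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      in_train[sample(idx, k)] <- TRUE
    }
  }
  train <- dataset[in_train, ]
  test <- dataset[!in_train, ]
  for (side in list(train, test)) {
    if (length(unique(side$label)) < 2L) {
      abort("A split side contains a single class; adjust the plan.")
    }
  }
  list(train = train, test = test)
}

#' Turn trial tibbles into per-channel training samples
#'
#' The network consumes one channel of one trial per sample (the label is
#' inherited from the trial). This expands the dataset, standardizes every
#' time point using statistics fitted on the training side only, and —
#' unless `raw = TRUE` — replaces each standardized channel signal by its
#' wavelet-denoised feature vector.
#'
#' @param train,test `eeg_dataset` tibbles (test may be `NULL`).
#' @param spec A [wavelet_spec()]; ignored when `raw = TRUE`.
#' @param level Decomposition depth.
#' @param target_length Optional fixed feature length (pad/truncate).
#' @param raw Skip the wavelet front-end (for the `cnn_bilstm` ablation).
#' @return List with `x_train`, `y_train`, `x_test`, `y_test` (labels 1 =
#'   alcoholic, 0 = control), `groups_train`/`groups_test` (trial ids per
#'   sample, for trial-level aggregation), and the fitted `standardizer`.
#' @export
prepare_features <- function(train, test = NULL,
                             spec = wavelet_spec("db4"), level = 2,
                             target_length = NULL, raw = FALSE) {
  stack <- function(ds) {
    # one row per channel; columns are the time points (the features)
    x <- do.call(rbind, ds$data)
    y <- rep(as.integer(ds$label == "alcoholic"),
             times = vapply(ds$data, nrow, integer(1)))
    g <- rep(ds$trial_id, times = vapply(ds$data, nrow, integer(1)))
    list(x = x, y = y, g = g)
  }
  tr <- stack(train)
  std <- suppressWarnings(fit_standardizer(tr$x))
  xform <- function(x) {
    xs <- apply_standardizer(std, x)
    if (raw) return(xs)
    t(apply(xs, 1L, denoise_features, spec = spec, level = level,
            target_length = target_length))
  }
  out <- list(
    x_train = xform(tr$x), y_train = tr$y, groups_train = tr$g,
    standardizer = std
  )
  if (!is.null(test)) {
    te <- stack(test)
    out$x_test <- xform(te$x)
    out$y_test <- te$y
    out$groups_test <- te$g
  }
  out
}

#' Train a classifier with Adam
#'
#' Minibatch training on binary cross-entropy, recording per-epoch training
#' accuracy and loss (the training-curve analogue of the published
#' accuracy/loss plot). Fully reproducible: shuffling, dropout and the
#' optimiser are driven by `seed`. Aborts with diagnostics if the loss
#' becomes non-finite.
#'
#' @param model An untrained (or previously trained) `eeg_model`.
#' @param x Feature matrix, samples x `input_length`.
#' @param y Integer labels, 1 = alcoholic (positive), 0 = control.
#' @param epochs,batch_size,learning_rate Override the model config.
#' @param seed Integer seed for shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return The model, with `trained = TRUE` and a `curves` tibble
#'   (`epoch`, `train_acc`, `train_loss`).
#' @export
train_model <- function(model, x, y,
                        epochs = model$config$epochs,
                        batch_size = model$config$batch_size,
                        learning_rate = model$config$learning_rate,
                        seed = model$config$seed,
                        verbose = FALSE) {
  stopifnot(inherits(model, "eeg_model"), is.matrix(x))
  if (length(y) != nrow(x)) abort("x and y disagree on sample count.")
  if (!all(y %in% c(0L, 1L))) abort("y must be 0/1.")
  if (length(unique(y)) < 2L) abort("Training data must contain both classes.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  layers <- model$layers
  adam_init(layers)
  n <- nrow(x)
  step <- 0L
  curves <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      p <- as.numeric(nn_forward(layers, xb, train = TRUE))
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(pc) + (1 - yb) * log(1 - pc))
      if (!is.finite(loss)) {
        abort(paste0("Non-finite loss at epoch ", ep,
                     "; learning rate ", learning_rate,
                     ", batch starting at ", start, "."))
      }
      ep_loss <- ep_loss + loss * length(idx)
      ep_correct <- ep_correct + sum((p >= 0.5) == (yb == 1L))
      dlogits <- matrix((p - yb) / length(idx), ncol = 1L)
      nn_backward_from_logits(layers, dlogits)
      step <- step + 1L
      adam_step(layers, learning_rate, step)
    }
    curves[[ep]] <- tibble(
      epoch = ep,
      train_acc = ep_correct / n,
      train_loss = ep_loss / n
    )
    if (verbose) {
      cat(sprintf("epoch %3d  acc %.4f  loss %.4f\n",
                  ep, ep_correct / n, ep_loss / n))
    }
  }
  model$trained <- TRUE
  model$curves <- dplyr::bind_rows(curves)
  model
}

#' Confusion-count classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2PR/(P+R)`. A metric whose denominator is zero is
#' reported as 0 and flagged via the `zero_division` attribute.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts; their sum must
#'   be positive.
#' @return Named list `accuracy`, `precision`, `recall`, `f1`, with
#'   attribute `zero_division` naming any zero-denominator metrics.
#' @examples
#' compute_metrics(90, 20, 80, 10)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("Confusion counts must be non-negative.")
  total <- sum(counts)
  if (total == 0) abort("All confusion counts are zero.")
  flagged <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    flagged <- c(flagged, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    flagged <- c(flagged, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    flagged <- c(flagged, "f1"); 0
  }
  structure(
    list(accuracy = (tp + tn) / total, precision = precision,
         recall = recall, f1 = f1),
    zero_division = flagged
  )
}

#' Evaluate a trained model on a test set
#'
#' Thresholds the sigmoid output (`>= threshold` is called positive /
#' alcoholic), tallies the confusion counts and computes the four metrics.
#' When `groups` is supplied, per-sample probabilities are first averaged
#' within each group (trial-level aggregation of per-channel predictions)
#' and one decision is made per group, against the group's label.
#'
#' @param model A trained `eeg_model`.
#' @param x Feature matrix.
#' @param y 0/1 labels.
#' @param threshold Decision cutoff on the predicted probability.
#' @param groups Optional grouping vector (e.g. trial ids) for aggregated
#'   decisions.
#' @return An `eval_report`: confusion counts, metrics, threshold, number
#'   of decisions, and the training curves if the model carries them.
#' @export
evaluate <- function(model, x, y, threshold = 0.5, groups = NULL) {
  p <- predict(model, x)
  if (!is.null(groups)) {
    agg <- tapply(p, groups, mean)
    lab <- tapply(y, groups, function(v) v[1])
    p <- as.numeric(agg)
    y <- as.integer(lab)
  }
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  m <- compute_metrics(tp, fp, tn, fn)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = m$accuracy, precision = m$precision,
         recall = m$recall, f1 = m$f1,
         zero_division = attr(m, "zero_division"),
         threshold = threshold, n = tp + fp + tn + fn,
         curves = model$curves),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$n, "decisions | threshold", x$threshold, "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Run the end-to-end pipeline once
#'
#' Split, standardize (train side only), wavelet-denoise, build the
#' requested architecture, train, and evaluate on the held-out side. The
#' wavelet front-end is what sets the proposed model apart from the
#' comparison baselines, so only `architecture = "proposed"` consumes
#' denoised features; `cnn`, `lstm`, `bilstm` and `cnn_bilstm` are trained
#' on the raw standardized samples.
#'
#' @param dataset An `eeg_dataset`.
#' @param architecture Architecture name, see [build_model()].
#' @param plan A [split_plan()].
#' @param spec,level,target_length Wavelet front-end, see
#'   [prepare_features()].
#' @param epochs,batch_size,learning_rate,dropout_rate,rnn_timesteps Model
#'   and training settings forwarded to [model_config()] / [train_model()].
#' @param seed Controls weight init, shuffling and dropout.
#' @param aggregate_trials Average per-channel probabilities into one
#'   decision per trial.
#' @param threshold Decision cutoff.
#' @return List with the trained `model`, the `report` (`eval_report`) and
#'   the `split`.
#' @export
run_pipeline <- function(dataset, architecture = "proposed",
                         plan = split_plan(seed = seed),
                         spec = wavelet_spec("db4"), level = 2,
                         target_length = NULL,
                         epochs = 15, batch_size = 64,
                         learning_rate = 0.001, dropout_rate = 0.5,
                         rnn_timesteps = 4,
                         seed = 1L, aggregate_trials = FALSE,
                         threshold = 0.5) {
  sp <- make_split(dataset, plan)
  raw <- architecture != "proposed"
  feats <- prepare_features(sp$train, sp$test, spec = spec, level = level,
                            target_length = target_length, raw = raw)
  config <- model_config(
    input_length = ncol(feats$x_train),
    dropout_rate = dropout_rate,
    learning_rate = learning_rate,
    epochs = epochs, batch_size = batch_size,
    rnn_timesteps = rnn_timesteps,
    seed = seed
  )
  model <- build_model(config, architecture)
  model <- train_model(model, feats$x_train, feats$y_train, seed = seed)
  report <- evaluate(
    model, feats$x_test, feats$y_test, threshold = threshold,
    groups = if (aggregate_trials) feats$groups_test else NULL
  )
  list(model = model, report = report, split = sp)
}

#' Multi-architecture, multi-seed comparison harness
#'
#' Runs [run_pipeline()] for every architecture x seed combination and
#' collects one row per run plus per-architecture aggregates (mean and sd
#' of each metric) — the comparison-table layout of the deep-learning
#' baselines (Accuracy, Precision, Recall, F1-Score). A plug-in slot
#' (`extra_models`) accepts named functions `f(x_train, y_train, x_test)`
#' returning test-set probabilities, so classical classifiers can join the
#' table without being part of the package.
#'
#' @inheritParams run_pipeline
#' @param architectures Character vector of architecture names.
#' @param seeds Integer vector; each seed drives one full split/init/train.
#' @param extra_models Optional named list of plug-in classifiers.
#' @param ... Forwarded to [run_pipeline()].
#' @return List with `runs` (one tibble row per run) and `summary`
#'   (per-architecture mean +/- sd).
#' @export
run_comparison <- function(dataset,
                           architectures = c("proposed", "cnn", "lstm",
                                             "bilstm", "cnn_bilstm"),
                           seeds = 1:5,
                           spec = wavelet_spec("db4"), level = 2,
                           extra_models = NULL, ...) {
  known <- c("proposed", "cnn", "lstm", "bilstm", "cnn_bilstm")
  bad <- setdiff(architectures, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown architecture(s): ", paste(bad, collapse = ", ")))
  }
  rows <- list()
  for (arch in architectures) {
    for (sd_ in seeds) {
      res <- run_pipeline(dataset, architecture = arch,
                          plan = split_plan(seed = sd_),
                          spec = spec, level = level, seed = sd_, ...)
      r <- res$report
      rows[[length(rows) + 1L]] <- tibble(
        architecture = arch, seed = sd_,
        tp = r$tp, fp = r$fp, tn = r$tn, fn = r$fn,
        accuracy = r$accuracy, precision = r$precision,
        recall = r$recall, f1 = r$f1
      )
    }
  }
  if (!is.null(extra_models)) {
    for (nm in names(extra_models)) {
      for (sd_ in seeds) {
        sp <- make_split(dataset, split_plan(seed = sd_))
        feats <- prepare_features(sp$train, sp$test, spec = spec,
                                  level = level)
        p <- extra_models[[nm]](feats$x_train, feats$y_train, feats$x_test)
        pred <- as.integer(p >= 0.5)
        y <- feats$y_test
        m <- compute_metrics(sum(pred & y), sum(pred & !y),
                             sum(!pred & !y), sum(!pred & y))
        rows[[length(rows) + 1L]] <- tibble(
          architecture = nm, seed = sd_,
          tp = sum(pred & y), fp = sum(pred & !y),
          tn = sum(!pred & !y), fn = sum(!pred & y),
          accuracy = m$accuracy, precision = m$precision,
          recall = m$recall, f1 = m$f1
        )
      }
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::group_by(.data$architecture) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "precision", "recall", "f1"),
      list(mean = mean, sd = stats::sd)
    ), .groups = "drop")
  list(runs = runs, summary = summary)
}
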