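test_that("subject-wise splits assign whole subjects and respect the fraction", {
  d <- many_subject_dataset(n_subjects_per_class = 5)  # 10 subjects
  sp <- make_split(d, split_plan("subject_wise", 0.8, seed = 4))
  train_subj <- unique(sp$train$subject_id)
  test_subj <- unique(sp$test$subject_id)
  expect_length(train_subj, 8L)
  expect_length(test_subj, 2L)
  expect_length(intersect(train_subj, test_subj), 0L)

  sp2 <- make_split(d, split_plan("subject_wise", 0.8, seed = 4))
  expect_identical(sp$train$trial_id, sp2$train$trial_id)
})

test_that("stratified trial-wise splits preserve the class ratio within one trial", {
  d <- many_subject_dataset(n_subjects_per_class = 4, trials_per_subject = 5)
  sp <- make_split(d, split_plan("trial_wise", 0.7, seed = 9))
  expect_length(intersect(sp$train$trial_id, sp$test$trial_id), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(d))
  tr_tab <- table(sp$train$label)
  expect_lte(abs(tr_tab[["alcoholic"]] - tr_tab[["control"]]), 1)

  single <- d[d$label == "alcoholic", ][1:4, ]
  single$label[1] <- "control"
  expect_error(make_split(eeg_dataset(single), split_plan(seed = 1)),
               "single class")
})

test_that("compute_metrics reproduces the worked confusion matrix", {
  m <- compute_metrics(tp = 90, fp = 20, tn = 80, fn = 10)
  expect_equal(m$accuracy, 0.85)
  expect_equal(round(m$precision, 5), 0.81818)
  expect_equal(m$recall, 0.90)
  expect_equal(round(m$f1, 5), 0.85714)

  perfect <- compute_metrics(50, 0, 50, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  degenerate <- compute_metrics(0, 5, 10, 0)
  expect_equal(degenerate$precision, 0)
  expect_equal(degenerate$recall, 0)
  expect_equal(degenerate$f1, 0)
  expect_true("recall" %in% attr(degenerate, "zero_division"))

  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 0, 1, 0), "non-negative")
})

test_that("metrics equal brute-force per-sample recomputation on random draws", {
  set.seed(31)
  for (rep in seq_len(1000)) {
    n <- sample(5:50, 1)
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 0)
    tn <- sum(pred == 0 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    m <- compute_metrics(tp, fp, tn, fn)
    b <- brute_metrics(pred, truth)
    expect_equal(m$accuracy, b$accuracy)
    expect_equal(m$precision, b$precision)
    expect_equal(m$recall, b$recall)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    }
    # invariant to sample ordering by construction of the counts
    o <- sample(n)
    expect_equal(
      unlist(m),
      unlist(compute_metrics(
        sum(pred[o] == 1 & truth[o] == 1), sum(pred[o] == 1 & truth[o] == 0),
        sum(pred[o] == 0 & truth[o] == 0), sum(pred[o] == 0 & truth[o] == 1)
      ))
    )
  }
})

test_that("evaluate applies the threshold and tallies every decision", {
  cfg <- model_config(input_length = 16, seed = 7)
  m <- build_model(cfg, "cnn")
  set.seed(5)
  x <- matrix(rnorm(30 * 16), 30)
  y <- rep(c(1L, 0L), 15)

  r0 <- evaluate(m, x, y, threshold = 0)
  expect_equal(r0$recall, 1)
  expect_equal(r0$tn + r0$fn, 0)

  r1 <- evaluate(m, x, y, threshold = 1 + 1e-9)
  expect_equal(r1$recall, 0)
  expect_equal(r1$tp + r1$fp, 0)

  r <- evaluate(m, x, y)
  expect_equal(r$tp + r$fp + r$tn + r$fn, 30)

  groups <- rep(1:10, each = 3)
  y_grouped <- rep(rep(c(1L, 0L), 5), each = 3)
  rg <- evaluate(m, x, y_grouped, groups = groups)
  expect_equal(rg$n, 10)
})

test_that("training is reproducible, logged per epoch, and learns separable data", {
  cfg <- model_config(
    input_length = 16,
    conv_stack = list(c(4, 3, 1), c(4, 3, 1), c(8, 3, 1), c(8, 3, 1)),
    head_dense = c(8, 6, 4), dropout_rate = 0.1, seed = 21
  )
  set.seed(22)
  n <- 40
  y <- rep(c(1L, 0L), n / 2)
  x <- matrix(rnorm(n * 16), n) + outer(ifelse(y == 1, 2, -2), rep(1, 16))

  m1 <- train_model(build_model(cfg, "cnn"), x, y, epochs = 1,
                    batch_size = 16, seed = 1)
  expect_equal(nrow(m1$curves), 1L)
  expect_named(m1$curves, c("epoch", "train_acc", "train_loss"))

  m20 <- train_model(build_model(cfg, "cnn"), x, y, epochs = 30,
                     batch_size = 16, learning_rate = 0.01, seed = 1)
  expect_lt(m20$curves$train_loss[30], m20$curves$train_loss[1])
  expect_gt(m20$curves$train_acc[30], 0.9)

  m20b <- train_model(build_model(cfg, "cnn"), x, y, epochs = 30,
                      batch_size = 16, learning_rate = 0.01, seed = 1)
  expect_identical(m20$curves$train_loss[30], m20b$curves$train_loss[30])

  expect_error(train_model(build_model(cfg, "cnn"), x, rep(1L, n)),
               "both classes")
})

test_that("the comparison harness books one row per run plus aggregates", {
  d <- tiny_dataset(n_trials_per_class = 6, n_channels = 4, n_samples = 32,
                    seed = 17)
  res <- run_comparison(
    d, architectures = c("proposed", "cnn"), seeds = 1:3,
    spec = wavelet_spec("haar", padding = "periodic"), level = 2,
    epochs = 2, batch_size = 16
  )
  expect_equal(nrow(res$runs), 6L)
  expect_equal(nrow(res$summary), 2L)
  expect_setequal(res$summary$architecture, c("proposed", "cnn"))
  expect_true(all(res$runs$accuracy >= 0 & res$runs$accuracy <= 1))
  expect_true(all(c("accuracy_mean", "accuracy_sd", "f1_mean") %in%
                    names(res$summary)))

  expect_error(run_comparison(d, architectures = "vae"), "Unknown architecture")

  # plug-in slot for external classifiers
  res2 <- run_comparison(
    d, architectures = character(0), seeds = 1,
    spec = wavelet_spec("haar", padding = "periodic"), level = 2,
    extra_models = list(
      majority = function(xtr, ytr, xte) rep(mean(ytr), nrow(xte))
    )
  )
  expect_equal(res2$runs$architecture, "majority")
})

test_that("feature preparation inherits labels, groups and train-only statistics", {
  d <- tiny_dataset(n_trials_per_class = 4, n_channels = 4, n_samples = 64,
                    seed = 19)
  sp <- make_split(d, split_plan(seed = 2))
  feats <- prepare_features(sp$train, sp$test,
                            spec = wavelet_spec("db2", padding = "periodic"),
                            level = 2)
  expect_equal(nrow(feats$x_train), nrow(sp$train) * 4)
  expect_equal(ncol(feats$x_train), feature_length(64, wavelet_spec("db2", padding = "periodic"), 2))
  expect_equal(length(feats$y_train), nrow(feats$x_train))
  expect_equal(sort(unique(feats$groups_test)), sort(sp$test$trial_id))
  # standardizer comes from the training side only
  expect_equal(feats$standardizer$fitted_on, nrow(sp$train) * 4)
  raw <- prepare_features(sp$train, sp$test, raw = TRUE)
  expect_equal(ncol(raw$x_train), 64L)
})
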