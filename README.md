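# alcoeeg

Deep-learning classification of alcoholic vs. control EEG trials, built as
a fully tested, self-contained R pipeline: standardization, multilevel
discrete-wavelet denoising, and a 1-D CNN + stacked bidirectional LSTM
classifier, exercisable end to end on seeded synthetic EEG with no
external download.

## The problem and the method

Chronic alcohol use alters cortical rhythms, and those alterations are
visible in the electroencephalogram. Given 1-second, 64-channel trials
sampled at 256 Hz, the task is binary classification: alcoholic
(positive) vs. control (negative).

The pipeline:

1. **Standardization.** Each sample is scaled per feature,
   `X' = (X − μ)/σ`, with μ and σ (population sd) fitted on the training
   split only.
2. **Wavelet denoising.** A from-scratch multilevel DWT decomposes each
   standardized signal with an orthogonal wavelet (default `db4`, level
   2); only the approximation branch is cascaded, and the deepest
   approximation coefficients become the network input
   `a_L = H_L ⋯ H_1 x` (H = low-pass analysis + dyadic decimation). The
   analysis bank is validated by perfect reconstruction
   (‖x − W⁻¹Wx‖∞ < 1e−8), Parseval energy equality under periodic
   padding, and coefficient-wise agreement with PyWavelets.
3. **Classifier.** Four 1-D convolutions (64/64/128/128 kernels, width 3,
   stride 1, ReLU) with 2×2 max pooling after conv 1 and conv 4; a
   256-unit dense layer (dropout) reshaped to a 4×64 sequence; two stacked
   Bi-LSTMs of 64 units per direction,
   `f,i,o = σ(W h + U x + b)`, `a = tanh(·)`,
   `c_t = c_{t−1}⊙f + i⊙a`, `h_t = o⊙tanh(c_t)`;
   a 256/128/64 dense head with dropout; one sigmoid unit. Adam,
   learning rate 0.001, binary cross-entropy.
4. **Evaluation.** Thresholded probabilities → TP/FP/TN/FN → accuracy,
   precision, recall, F1; per-epoch training curves; a comparison harness
   over the baseline architectures (`cnn`, `lstm`, `bilstm`,
   `cnn_bilstm`) which consume raw standardized input — the wavelet
   front-end is what distinguishes the proposed model.

The network (convolution, pooling, LSTM, backprop, Adam) is implemented
in the package itself on BLAS matrix products; backward passes are
checked against numerical differentiation, and the batched LSTM layer is
bridged to the literal per-gate cell equations in the tests.

## Worked example

Synthetic two-class EEG (the positive class has its alpha-band amplitude
tripled), split 80/20, denoised, trained and evaluated:

```r
library(alcoeeg)

d <- generate_eeg(synth_config(
  n_subjects_per_class = 2, trials_per_subject = 4,
  n_channels = 16, effect = 3, seed = 42
))
res <- run_pipeline(d, "proposed", epochs = 15, batch_size = 32, seed = 1)
res$report
#> <eval_report> 64 decisions | threshold 0.5
#>   TP 32  FP 0  TN 32  FN 0
#>   accuracy 1.0000  precision 1.0000  recall 1.0000  F1 1.0000

glance(res$model)
#> # A tibble: 1 × 7
#>   architecture input_length n_params trained final_train_acc final_train_loss
#>   <chr>               <int>    <dbl> <lgl>             <dbl>            <dbl>
#> 1 proposed               69   883009 TRUE              0.979           0.0349
```

The 64 held-out decisions are per-channel samples (each channel of each
test trial, inheriting the trial's label); all are classified correctly
because a tripled alpha band is a strong, learnable effect. The model has
883,009 trainable parameters and consumes the 69 `db4`/level-2
approximation coefficients of each 256-sample channel. `autoplot(res$model)`
draws the training accuracy/loss curves; `tidy(res$model)` lists the
layer-by-layer shape and parameter table; `run_comparison()` produces the
multi-architecture, multi-seed results table.

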