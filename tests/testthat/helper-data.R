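# Small fixture builders shared across test files.

toy_smni_path <- function() {
  testthat::test_path("fixtures", "toy_smni.txt")
}

# The voltages printed in the toy fixture, channel order FP1, FP2, CZ.
toy_smni_matrix <- function() {
  matrix(
    c(-8.921, 1.25, 5.5, -2.0,
      0.5, -0.75, 3.25, 4.125,
      10.0, -10.0, 0.25, 7.75),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("FP1", "FP2", "CZ"), NULL)
  )
}

tiny_dataset <- function(n_trials_per_class = 3, n_channels = 4,
                         n_samples = 32, seed = 1) {
  generate_eeg(synth_config(
    n_subjects_per_class = 1,
    trials_per_subject = n_trials_per_class,
    n_channels = n_channels, n_samples = n_samples,
    effect = 2, artifact_rate = 0, seed = seed
  ))
}

many_subject_dataset <- function(n_subjects_per_class = 5,
                                 trials_per_subject = 2, seed = 3) {
  generate_eeg(synth_config(
    n_subjects_per_class = n_subjects_per_class,
    trials_per_subject = trials_per_subject,
    n_channels = 4, n_samples = 32, effect = 1.5,
    artifact_rate = 0, seed = seed
  ))
}
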