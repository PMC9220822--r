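#' Assemble an EEG trial dataset tibble
#'
#' The package-wide container for trials is an ordinary tibble with one row
#' per trial and the columns
#' \describe{
#'   \item{trial_id}{integer, unique per row}
#'   \item{subject_id}{character}
#'   \item{label}{character, `"alcoholic"` (positive class) or `"control"`}
#'   \item{condition}{character stimulus condition (may be `NA`)}
#'   \item{sampling_rate}{numeric, Hz}
#'   \item{data}{list of numeric matrices, channels x samples, microvolts,
#'     with channel names as rownames}
#' }
#' so it pipes straight into dplyr/tidyr. `eeg_dataset()` validates the
#' invariants (consistent sampling rate and channel ordering across trials,
#' equal row lengths within a trial, no duplicate channel names) and stamps
#' a `provenance` attribute.
#'
#' @param trials A tibble/data frame with the columns above, or a list of
#'   one-row trial tibbles to be row-bound.
#' @param provenance Character note on where the data came from (file path,
#'   or `"synthetic:<seed>"`).
#' @return A validated `eeg_dataset` tibble.
#' @export
eeg_dataset <- function(trials, provenance = "unknown") {
  if (is.list(trials) && !is.data.frame(trials)) {
    trials <- dplyr::bind_rows(trials)
  }
  trials <- as_tibble(trials)
  validate_eeg_dataset(trials)
  trials$trial_id <- seq_len(nrow(trials))
  attr(trials, "provenance") <- provenance
  class(trials) <- c("eeg_dataset", class(trials))
  trials
}

validate_eeg_dataset <- function(trials) {
  needed <- c("subject_id", "label", "condition", "sampling_rate", "data")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("Dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(trials) == 0L) abort("Dataset has no trials.")
  if (!all(trials$label %in% c("alcoholic", "control"))) {
    abort("label must be 'alcoholic' or 'control'.")
  }
  if (any(trials$sampling_rate <= 0)) abort("sampling_rate must be > 0.")
  if (length(unique(trials$sampling_rate)) != 1L) {
    abort("All trials must share one sampling rate.")
  }
  ref_channels <- rownames(trials$data[[1]])
  for (i in seq_len(nrow(trials))) {
    m <- trials$data[[i]]
    if (!is.matrix(m) || !is.numeric(m)) {
      abort(paste0("Trial ", i, ": data must be a numeric matrix."))
    }
    ch <- rownames(m)
    if (is.null(ch) || anyDuplicated(ch)) {
      abort(paste0("Trial ", i,
                   ": data needs unique channel names as rownames."))
    }
    if (!identical(ch, ref_channels)) {
      abort(paste0("Trial ", i,
                   ": channel ordering differs from the first trial."))
    }
  }
  invisible(trials)
}

#' Read one UCI SMNI plain-text EEG trial file
#'
#' The SMNI dialect: lines starting with `#` are headers; the first header
#' carries the subject/file identifier, a `"... trials, N chans, M samples"`
#' header carries the geometry, a `"<condition> , trial k"` header the
#' stimulus condition, and `"# <NAME> chan <i>"` headers fix the channel
#' order. Data rows have exactly 4 whitespace-separated fields:
#' `trial-or-channel-index  channel-name  sample-index(0-based)  voltage`.
#' Gzip-compressed files are decompressed transparently.
#'
#' The class label is parsed from the subject identifier. UCI SMNI
#' identifiers look like `co2a0000364` / `co2c0000337`, with the letter after
#' the leading `co<digit>` distinguishing alcoholic (`a`) from control (`c`);
#' when that pattern is absent the first character of the identifier is used.
#' The letter-to-label mapping is configurable via `label_map`; an identifier
#' matching no map entry is an error unless `default_label` is given.
#'
#' Trials whose condition header contains the token `err` (artifact-flagged
#' recordings in the UCI distribution) return `NULL` with a warning unless
#' `keep_err = TRUE`.
#'
#' @param path Path to the trial file (optionally `.gz`).
#' @param label_map Named character vector mapping the identifier letter to
#'   a label.
#' @param default_label Fallback label when no map entry matches.
#' @param keep_err Keep trials whose condition is flagged `err`.
#' @param sampling_rate Sampling rate to record, Hz.
#' @return A one-row `eeg_dataset`-shaped tibble, or `NULL` for a skipped
#'   error-flagged trial.
#' @export
read_smni_trial <- function(path,
                            label_map = c(a = "alcoholic", c = "control"),
                            default_label = NULL,
                            keep_err = FALSE,
                            sampling_rate = 256) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "#")
  headers <- lines[is_header]

  subject_id <- if (length(headers) >= 1L) {
    sub("\\.rd.*$", "", trimws(sub("^#\\s*", "", headers[1])))
  } else {
    abort(paste0(path, ": no header lines; not an SMNI trial file."))
  }
  condition <- NA_character_
  cond_line <- grep(", trial", headers, value = TRUE)
  if (length(cond_line) >= 1L) {
    condition <- trimws(sub(",\\s*trial.*$", "", sub("^#\\s*", "", cond_line[1])))
  }
  if (!keep_err && grepl("\\berr\\b", condition)) {
    warn(paste0(path, ": trial flagged 'err'; skipped (use keep_err = TRUE to keep)."))
    return(NULL)
  }

  # channel order from '# NAME chan i' headers, else first appearance order
  chan_heads <- grep("\\bchan\\b", headers, value = TRUE)
  header_channels <- if (length(chan_heads) > 0) {
    vapply(strsplit(sub("^#\\s*", "", chan_heads), "\\s+"),
           function(p) p[1], character(1))
  } else {
    character(0)
  }

  data_idx <- which(!is_header & nzchar(trimws(lines)))
  if (length(data_idx) == 0L) abort(paste0(path, ": no data rows."))
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield != 4L)) {
    bad <- data_idx[which(nfield != 4L)[1]]
    abort(paste0(path, ": line ", bad, ": expected 4 fields, got ",
                 nfield[which(nfield != 4L)[1]], "."))
  }
  chan <- vapply(fields, `[`, character(1), 2L)
  samp <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  volt <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  if (anyNA(samp) || anyNA(volt)) {
    bad <- data_idx[which(is.na(samp) | is.na(volt))[1]]
    abort(paste0(path, ": line ", bad, ": non-numeric sample index or voltage."))
  }

  channels <- if (length(header_channels) > 0) header_channels else unique(chan)
  if (!all(chan %in% channels)) {
    abort(paste0(path, ": data rows for channel(s) absent from headers: ",
                 paste(setdiff(unique(chan), channels), collapse = ", ")))
  }
  n_samples <- max(samp) + 1L
  mat <- matrix(NA_real_, nrow = length(channels), ncol = n_samples,
                dimnames = list(channels, NULL))
  mat[cbind(match(chan, channels), samp + 1L)] <- volt
  if (anyNA(mat)) {
    gaps <- rownames(mat)[apply(mat, 1L, anyNA)]
    abort(paste0(path, ": incomplete trial; missing samples for channel(s): ",
                 paste(gaps, collapse = ", ")))
  }

  key <- sub("^co\\d", "", subject_id)
  key <- substr(key, 1L, 1L)
  label <- unname(label_map[key])
  if (is.na(label) || is.null(label)) {
    if (is.null(default_label)) {
      abort(paste0(path, ": cannot infer label from subject id '",
                   subject_id, "' (letter '", key,
                   "'); supply default_label or extend label_map."))
    }
    label <- default_label
  }

  tibble(
    trial_id = 1L,
    subject_id = subject_id,
    label = label,
    condition = condition,
    sampling_rate = sampling_rate,
    data = list(mat)
  )
}

#' Read a directory of SMNI trial files into a dataset
#'
#' Reads every regular file in `dir` with [read_smni_trial()], drops skipped
#' error-flagged trials, re-orders every trial's channels to the first
#' file's channel order (by name), and validates the assembled dataset.
#'
#' @param dir Directory of SMNI trial files.
#' @inheritParams read_smni_trial
#' @return An `eeg_dataset` tibble.
#' @export
read_smni_dir <- function(dir, label_map = c(a = "alcoholic", c = "control"),
                          default_label = NULL, keep_err = FALSE,
                          sampling_rate = 256) {
  paths <- sort(list.files(dir, full.names = TRUE))
  if (length(paths) == 0L) abort(paste0("No files in ", dir))
  rows <- purrr::compact(purrr::map(
    paths, read_smni_trial,
    label_map = label_map, default_label = default_label,
    keep_err = keep_err, sampling_rate = sampling_rate
  ))
  if (length(rows) == 0L) abort("All trials were skipped.")
  ref <- rownames(rows[[1]]$data[[1]])
  rows <- purrr::map(rows, function(r) {
    m <- r$data[[1]]
    if (!setequal(rownames(m), ref)) {
      abort(paste0(r$subject_id, ": channel set differs from first file."))
    }
    r$data[[1]] <- m[ref, , drop = FALSE]
    r
  })
  eeg_dataset(rows, provenance = dir)
}

#' Write an EEG dataset to disk
#'
#' The long CSV layout stores one row per `(trial, channel, sample)` with
#' all trial metadata, at full double precision, so
#' `read_dataset(write_dataset(d))` reproduces every voltage exactly.
#'
#' @param dataset An `eeg_dataset` tibble (non-empty).
#' @param path Output file path.
#' @param format Only `"csv"` is supported as the lossless on-disk
#'   container; requesting `"hdf5"` is an error naming the alternative.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    abort("hdf5 output is not supported by this build; use format = 'csv'.")
  }
  validate_eeg_dataset(dataset)
  long <- tidyr::unnest(
    dplyr::mutate(
      dataset,
      long = purrr::map(.data$data, function(m) {
        tibble(
          channel = rep(rownames(m), times = ncol(m)),
          sample = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
          value = as.vector(m)
        )
      }),
      data = NULL
    ),
    "long"
  )
  readr::write_csv(long, path)
  invisible(path)
}

#' Read an EEG dataset written by [write_dataset()]
#'
#' @param path CSV file path.
#' @param format As in [write_dataset()].
#' @return An `eeg_dataset` tibble.
#' @export
read_dataset <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    abort("hdf5 input is not supported by this build; use format = 'csv'.")
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (length(unique(long$sampling_rate)) != 1L) {
    abort("Mixed sampling rates in file.")
  }
  rows <- long |>
    dplyr::group_by(.data$trial_id, .data$subject_id, .data$label,
                    .data$condition, .data$sampling_rate) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$trial_id)
  rows$data <- purrr::map(rows$data, function(d) {
    channels <- unique(d$channel)
    m <- matrix(NA_real_, nrow = length(channels),
                ncol = max(d$sample) + 1L,
                dimnames = list(channels, NULL))
    m[cbind(match(d$channel, channels), d$sample + 1L)] <- d$value
    m
  })
  eeg_dataset(rows, provenance = path)
}
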