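#' Construct an EEG recording
#'
#' A recording is one subject's continuous multichannel signal: a time-major
#' numeric matrix (rows = time steps, columns = channels) plus sampling rate,
#' channel labels and optional event markers. All downstream modules assume
#' the time-major layout, 0-based sample indexing and half-open intervals
#' `[start, end)`.
#'
#' @param data Numeric matrix, `T x C`, all values finite.
#' @param fs Sampling rate in Hz, positive.
#' @param channels Character vector of channel labels (length `C`). Defaults
#'   to the column names of `data` or `ch1..chC`.
#' @param subject_id Subject identifier.
#' @param events Data frame with columns `sample_index` (0-based integer,
#'   `< nrow(data)`) and `code` (character), or `NULL`.
#' @param note Free-text provenance note (e.g. resampling applied on read).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = NULL, subject_id = "s01",
                          events = NULL, note = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) {
    channels <- colnames(data)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  }
  if (is.null(events)) {
    events <- data.frame(sample_index = integer(0), code = character(0),
                         stringsAsFactors = FALSE)
  }
  if (length(channels) == ncol(data)) colnames(data) <- channels
  rec <- structure(
    list(subject_id = as.character(subject_id), fs = as.numeric(fs),
         channels = as.character(channels), data = data,
         events = events, note = as.character(note)),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate an EEG recording
#'
#' Checks the type invariants: positive sampling rate, at least one sample
#' and one channel, channel labels matching the data columns, finite values,
#' and event indices inside the recording.
#'
#' @param rec An `eeg_recording`.
#' @return `rec`, invisibly; errors describe the violated field.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop("not an eeg_recording")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || !is.finite(rec$fs) || rec$fs <= 0)
    stop("format error in field 'fs': must be a positive number")
  if (!is.matrix(rec$data) || nrow(rec$data) < 1)
    stop("data error: recording must have at least one sample")
  if (length(rec$channels) < 1)
    stop("format error in field 'channels': at least one channel required")
  if (ncol(rec$data) != length(rec$channels))
    stop("format error in field 'channels': ", length(rec$channels),
         " labels but ", ncol(rec$data), " data columns")
  if (!all(is.finite(rec$data)))
    stop("data error: non-finite values in signal matrix")
  ev <- rec$events
  if (nrow(ev) > 0) {
    if (any(ev$sample_index < 0) || any(ev$sample_index >= nrow(rec$data)))
      stop("format error in field 'events': sample_index outside [0, T)")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d samples x %d channels @ %g Hz (%.1f s), %d events\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              nrow(x$data) / x$fs, nrow(x$events)))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Construct a labeled analysis window
#'
#' Fixed-length segment of a recording with a cognitive-state label: the
#' model's sample unit.
#'
#' @param data Numeric `T_w x C` matrix.
#' @param label State code (0--4), abbreviation, or `NA` for unlabeled.
#' @param subject_id Source subject.
#' @param start_index 0-based sample offset into the source recording.
#' @param fs Sampling rate in Hz.
#' @param events Optional event data frame (indices re-based to the window).
#' @param augmented Logical provenance flag set by the augmentation cascade.
#' @param parent_id Identifier of the originating window for augmented copies.
#' @return A `labeled_window` object.
#' @export
labeled_window <- function(data, label = NA, subject_id = "s01",
                           start_index = 0L, fs = 100, events = NULL,
                           augmented = FALSE, parent_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(events)) {
    events <- data.frame(sample_index = integer(0), code = character(0),
                         stringsAsFactors = FALSE)
  }
  structure(
    list(data = data,
         label = if (length(label) == 1 && is.na(label)) NA_integer_ else state_code(label),
         subject_id = as.character(subject_id),
         start_index = as.integer(start_index),
         fs = as.numeric(fs), events = events,
         augmented = isTRUE(augmented), parent_id = parent_id),
    class = "labeled_window"
  )
}

#' @export
print.labeled_window <- function(x, ...) {
  lab <- if (is.na(x$label)) "<unlabeled>" else state_abbrev(x$label)
  cat(sprintf("<labeled_window> %s @%d: %d x %d, label %s%s\n", x$subject_id,
              x$start_index, nrow(x$data), ncol(x$data), lab,
              if (x$augmented) " (augmented)" else ""))
  invisible(x)
}

#' Construct a windowed dataset
#'
#' An ordered collection of labeled windows sharing window length, channel
#' count and sampling rate.
#'
#' @param windows List of `labeled_window` objects.
#' @param fs Sampling rate in Hz (defaults to the first window's).
#' @return A `windowed_dataset` object with elements `windows`, `fs` and
#'   `class_names`.
#' @export
windowed_dataset <- function(windows, fs = NULL) {
  if (length(windows) > 0) {
    if (is.null(fs)) fs <- windows[[1]]$fs
    dims <- vapply(windows, function(w) dim(w$data), integer(2))
    if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
      stop("all windows must share the same dimensions")
    fss <- vapply(windows, function(w) w$fs, numeric(1))
    if (any(fss != fs)) stop("all windows must share the sampling rate")
  } else if (is.null(fs)) {
    fs <- NA_real_
  }
  structure(list(windows = windows, fs = fs, class_names = state_levels()),
            class = "windowed_dataset")
}

#' @export
length.windowed_dataset <- function(x) length(x$windows)

#' Extract the label vector of a dataset
#' @param ds A `windowed_dataset`.
#' @return Integer vector of state codes (NA where unlabeled).
#' @export
dataset_labels <- function(ds) {
  vapply(ds$windows, function(w) as.integer(w$label), integer(1))
}

#' Extract the subject id vector of a dataset
#' @param ds A `windowed_dataset`.
#' @return Character vector of subject ids, one per window.
#' @export
dataset_subjects <- function(ds) {
  vapply(ds$windows, function(w) w$subject_id, character(1))
}

#' @export
print.windowed_dataset <- function(x, ...) {
  n <- length(x$windows)
  cat(sprintf("<windowed_dataset> %d windows @ %g Hz\n", n, x$fs))
  if (n > 0) {
    cat(sprintf("  window: %d x %d\n", nrow(x$windows[[1]]$data),
                ncol(x$windows[[1]]$data)))
    lab <- dataset_labels(x)
    if (!all(is.na(lab)))
      print(table(factor(state_abbrev(lab[!is.na(lab)]), levels = state_levels())))
  }
  invisible(x)
}

#' Per-subject dominant-class table
#'
#' Summarizes a labeled dataset as one row per subject with the subject's
#' most frequent class, the input [subject_split()] uses for approximate
#' stratification.
#'
#' @param ds A labeled `windowed_dataset`.
#' @return Data frame with columns `subject_id` and `dominant_class`.
#' @export
subject_table_of <- function(ds) {
  subj <- unique(dataset_subjects(ds))
  lab <- dataset_labels(ds)
  sj <- dataset_subjects(ds)
  dom <- vapply(subj, function(s) {
    names(which.max(table(state_abbrev(lab[sj == s & !is.na(lab)]))))
  }, character(1))
  data.frame(subject_id = subj, dominant_class = dom,
             stringsAsFactors = FALSE)
}

#' Subset a windowed dataset
#' @param ds A `windowed_dataset`.
#' @param idx Indices of windows to keep.
#' @return A new `windowed_dataset`.
#' @export
dataset_subset <- function(ds, idx) windowed_dataset(ds$windows[idx], fs = ds$fs)
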