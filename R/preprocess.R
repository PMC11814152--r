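#' Preprocessing configuration
#'
#' Bundles the signal-conditioning parameters: band-pass edges, optional
#' notch, target sampling rate, window/step lengths and the z-score switch.
#' The defaults reflect the standard pipeline: band-pass 0.5--45 Hz,
#' 100 Hz sampling, 10-s non-overlapping windows (set `step_sec = 2` for
#' the sliding-window variant), per-recording z-scoring.
#'
#' @param band_low,band_high Band-pass edges in Hz; `0 < band_low <
#'   band_high < target_fs/2`.
#' @param notch_freq Mains notch frequency in Hz, or `NULL` (default: off;
#'   50 vs 60 Hz is region-dependent).
#' @param target_fs Target sampling rate in Hz (default 100).
#' @param window_sec Window length in seconds (default 10).
#' @param step_sec Step between window starts in seconds (default 10,
#'   non-overlapping; must satisfy `0 < step_sec <= window_sec`).
#' @param zscore Apply per-recording, per-channel z-score normalization.
#' @param filter_order Butterworth order for the band-pass (default 4).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(band_low = 0.5, band_high = 45,
                              notch_freq = NULL, target_fs = 100,
                              window_sec = 10, step_sec = 10,
                              zscore = TRUE, filter_order = 4) {
  if (!(band_low > 0 && band_low < band_high && band_high < target_fs / 2))
    stop("parameter error: need 0 < band_low < band_high < target_fs/2")
  if (!(step_sec > 0 && step_sec <= window_sec))
    stop("parameter error: need 0 < step_sec <= window_sec")
  structure(list(band_low = band_low, band_high = band_high,
                 notch_freq = notch_freq, target_fs = target_fs,
                 window_sec = window_sec, step_sec = step_sec,
                 zscore = zscore, filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass
#' independently to every channel. Zero-phase filtering is used so that
#' event-related potential latencies are not distorted. Length, channel
#' count and channel order are unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("parameter error: band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$data <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  colnames(rec$data) <- rec$channels
  validate_recording(rec)
}

# Anti-aliased downsampling of a single series: zero-phase Butterworth
# low-pass at 0.45 * to_fs, then linear interpolation onto the target grid.
# Output length = round(n * to_fs / from_fs).
resample_series <- function(x, from_fs, to_fs) {
  if (to_fs == from_fs) return(x)
  if (to_fs > from_fs) stop("parameter error: upsampling is not supported")
  bf <- signal::butter(8, (0.45 * to_fs) / (from_fs / 2), type = "low")
  xf <- signal::filtfilt(bf, x)
  n_out <- round(length(x) * to_fs / from_fs)
  t_out <- pmin((seq_len(n_out) - 1) / to_fs, (length(x) - 1) / from_fs)
  stats::approx(x = (seq_along(x) - 1) / from_fs, y = xf, xout = t_out)$y
}

#' Resample a recording to a lower sampling rate
#'
#' Anti-aliasing low-pass (zero-phase Butterworth at 0.45 of the target
#' Nyquist band) followed by interpolation onto the target grid. The new
#' length is `round(T * target_fs / fs)`; event sample indices are rescaled
#' by `target_fs / fs` and rounded.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate in Hz, `<= rec$fs`.
#' @return The resampled `eeg_recording`.
#' @export
resample_to <- function(rec, target_fs) {
  validate_recording(rec)
  if (target_fs > rec$fs)
    stop("parameter error: upsampling (target_fs > fs) is not supported")
  if (target_fs == rec$fs) return(rec)
  ratio <- target_fs / rec$fs
  rec$data <- vapply(seq_len(ncol(rec$data)),
                     function(j) resample_series(rec$data[, j], rec$fs, target_fs),
                     numeric(round(nrow(rec$data) * ratio)))
  colnames(rec$data) <- rec$channels
  if (nrow(rec$events) > 0) {
    rec$events$sample_index <- pmin(as.integer(round(rec$events$sample_index * ratio)),
                                    nrow(rec$data) - 1L)
  }
  rec$fs <- target_fs
  validate_recording(rec)
}

#' Per-channel z-score normalization
#'
#' Standardizes each channel over the whole recording (population standard
#' deviation), removing between-individual amplitude differences. An
#' epsilon guard (1e-8) in the denominator maps constant channels to all
#' zeros. Normalization is per recording, not per window, so relative
#' amplitude structure between windows of one subject is preserved.
#'
#' @param rec An `eeg_recording`.
#' @return The normalized `eeg_recording`.
#' @export
zscore_normalize <- function(rec) {
  validate_recording(rec)
  n <- nrow(rec$data)
  rec$data <- apply(rec$data, 2, function(x) {
    m <- mean(x)
    s <- sqrt(sum((x - m)^2) / n)        # population convention
    (x - m) / (s + 1e-8)
  })
  if (n == 1) rec$data <- matrix(rec$data, nrow = 1)
  colnames(rec$data) <- rec$channels
  validate_recording(rec)
}

#' Segment a recording into labeled windows
#'
#' Deterministic segmentation: windows start at samples `0, S, 2S, ...`
#' (with `S = step_sec * fs`), each `window_sec * fs` samples long; only
#' fully contained windows are emitted, giving `floor((T - T_w)/S) + 1`
#' windows when `T >= T_w` and none otherwise. Events falling inside a
#' window are copied into it with indices re-based to the window start.
#'
#' @param rec An `eeg_recording`.
#' @param labels Label source: `NULL` (unlabeled windows), or a data frame
#'   with columns `start`, `end` (0-based half-open sample interval) and
#'   `label`. A window receives the label of the interval that fully covers
#'   it; windows covered by no interval are dropped.
#' @param cfg A `preprocess_config` (window and step lengths are taken from
#'   it).
#' @return A `windowed_dataset`.
#' @export
segment_windows <- function(rec, labels = NULL, cfg = preprocess_config()) {
  validate_recording(rec)
  t_w <- cfg$window_sec * rec$fs
  s <- cfg$step_sec * rec$fs
  if (abs(t_w - round(t_w)) > 1e-9)
    stop("parameter error: window_sec * fs must be an integer sample count")
  t_w <- as.integer(round(t_w)); s <- as.integer(round(s))
  n <- nrow(rec$data)
  if (n < t_w) return(windowed_dataset(list(), fs = rec$fs))
  starts <- seq.int(0L, n - t_w, by = s)
  wins <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    st <- starts[i]
    lab <- NA
    if (!is.null(labels)) {
      hit <- which(labels$start <= st & labels$end >= st + t_w)
      if (length(hit) == 0) next
      lab <- labels$label[hit[1]]
    }
    inside <- rec$events$sample_index >= st & rec$events$sample_index < st + t_w
    ev <- rec$events[inside, , drop = FALSE]
    if (nrow(ev) > 0) ev$sample_index <- ev$sample_index - st
    rownames(ev) <- NULL
    wins[[i]] <- labeled_window(rec$data[(st + 1):(st + t_w), , drop = FALSE],
                                label = lab, subject_id = rec$subject_id,
                                start_index = st, fs = rec$fs, events = ev)
    keep[i] <- TRUE
  }
  windowed_dataset(wins[keep], fs = rec$fs)
}

#' Run the full conditioning pipeline on a recording
#'
#' Band-pass filter, optional resampling to `target_fs`, optional z-score
#' normalization, then windowing. Order: filtering and resampling happen on
#' the continuous signal, z-scoring per recording before windowing.
#'
#' @param rec An `eeg_recording`.
#' @param labels Label source passed to [segment_windows()].
#' @param cfg A `preprocess_config`.
#' @return A `windowed_dataset`.
#' @export
preprocess_recording <- function(rec, labels = NULL, cfg = preprocess_config()) {
  if (rec$fs > cfg$target_fs) rec <- resample_to(rec, cfg$target_fs)
  rec <- bandpass_filter(rec, cfg$band_low, cfg$band_high, cfg$filter_order)
  if (cfg$zscore) rec <- zscore_normalize(rec)
  segment_windows(rec, labels = labels, cfg = cfg)
}
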