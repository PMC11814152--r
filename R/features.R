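#' Default EEG frequency bands
#'
#' The standard clinical band partition used for band-power features:
#' delta `[0.5, 4)`, theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30)` Hz.
#' Bands are half-open, non-overlapping and ordered.
#'
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             f_low = c(0.5, 4, 8, 13),
             f_high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density estimate
#'
#' Averages modified periodograms of Hann-tapered, overlapping segments.
#' The estimate is a one-sided density on the grid `0 .. fs/2` with
#' resolution `fs / seg_len`, scaled so that the integral over frequency
#' approximates the signal variance.
#'
#' @param x Single-channel numeric series.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (default `min(length(x),
#'   2 * fs)`, i.e. 2-s segments).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @return Data frame with columns `freq` (Hz) and `power` (density,
#'   units^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = min(length(x), round(2 * fs)),
                      overlap_frac = 0.5) {
  n <- length(x)
  seg_len <- as.integer(seg_len)
  if (seg_len > n) stop("parameter error: seg_len exceeds series length")
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("parameter error: overlap_frac must be in [0, 1)")
  step <- max(1L, as.integer(floor(seg_len * (1 - overlap_frac))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))  # Hann
  scale <- fs * sum(w^2)
  n_freq <- floor(seg_len / 2) + 1
  acc <- numeric(n_freq)
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[1:n_freq]
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- 2:(n_freq - if (seg_len %% 2 == 0) 1 else 0)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  data.frame(freq = (0:(n_freq - 1)) * fs / seg_len,
             power = acc / length(starts))
}

#' Integrated band power from a spectrum
#'
#' Trapezoidal integral of the power density over the half-open band
#' `[f_low, f_high)` of the discrete frequency grid.
#'
#' @param spectrum Data frame with `freq` and `power` columns (as from
#'   [welch_psd()]).
#' @param f_low,f_high Band edges in Hz, or pass a one-row slice of
#'   [eeg_bands()] via `band`.
#' @param band Optional list/row with `f_low` and `f_high` (overrides).
#' @return Nonnegative scalar power. An empty band/grid intersection
#'   returns 0 with a warning.
#' @export
band_power <- function(spectrum, f_low = NULL, f_high = NULL, band = NULL) {
  if (!is.null(band)) { f_low <- band$f_low; f_high <- band$f_high }
  sel <- spectrum$freq >= f_low & spectrum$freq < f_high
  if (sum(sel) < 2) {
    if (!any(sel)) {
      warning("band [", f_low, ", ", f_high, ") does not intersect the frequency grid")
      return(0)
    }
    return(0)
  }
  pracma::trapz(spectrum$freq[sel], spectrum$power[sel])
}

#' Average event-related potential
#'
#' Extracts per-event epochs over the half-open window `[-pre_sec,
#' +post_sec)` relative to each marker and averages them pointwise. Epochs
#' that overrun either edge of the recording are skipped and counted. With
#' the half-open convention the epoch holds exactly `round((pre_sec +
#' post_sec) * fs)` samples and the event itself sits at 0-based epoch
#' index `round(pre_sec * fs)`.
#'
#' @param rec An `eeg_recording`.
#' @param events Optional event data frame (defaults to `rec$events`).
#' @param pre_sec Seconds before the event (default 0.200).
#' @param post_sec Seconds after the event (default 0.800).
#' @return An `erp_waveform` object: `data` (`T_e x C` average), `times`
#'   (seconds relative to event), `n_events` used, `n_skipped`.
#' @export
erp_average <- function(rec, events = NULL, pre_sec = 0.2, post_sec = 0.8) {
  validate_recording(rec)
  if (is.null(events)) events <- rec$events
  if (nrow(events) == 0) stop("data error: no events to average")
  n_pre <- as.integer(round(pre_sec * rec$fs))
  n_post <- as.integer(round(post_sec * rec$fs))
  t_e <- n_pre + n_post
  n <- nrow(rec$data)
  acc <- matrix(0, t_e, ncol(rec$data))
  used <- 0L; skipped <- 0L
  for (e in events$sample_index) {
    a <- e - n_pre            # 0-based epoch start
    b <- e + n_post           # half-open end
    if (a < 0 || b > n) { skipped <- skipped + 1L; next }
    acc <- acc + rec$data[(a + 1):b, , drop = FALSE]
    used <- used + 1L
  }
  if (used == 0) stop("data error: no usable events (all epochs overrun the edges)")
  structure(list(offsets = c(-pre_sec, post_sec),
                 data = acc / used,
                 times = ((0:(t_e - 1)) - n_pre) / rec$fs,
                 n_events = used, n_skipped = skipped,
                 fs = rec$fs, channels = rec$channels),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> [%+.3f, %+.3f) s, %d x %d, %d events (%d skipped)\n",
              x$offsets[1], x$offsets[2], nrow(x$data), ncol(x$data),
              x$n_events, x$n_skipped))
  invisible(x)
}

#' Feature-extraction configuration
#'
#' @param mode `"raw"` (the window itself becomes the encoder input,
#'   `T' = T_w`, `D = C`) or `"bands"` (the window is cut into sub-frames;
#'   per sub-frame the per-channel means are augmented with the four
#'   log-transformed band powers per channel, `T' = T_w / frame_len`,
#'   `D = C + 4C`).
#' @param frame_sec Sub-frame length in seconds for `"bands"` mode
#'   (default 1).
#' @param bands Band definition table (default [eeg_bands()]).
#' @return A `feature_config` list.
#' @export
feature_config <- function(mode = c("bands", "raw"), frame_sec = 1,
                           bands = eeg_bands()) {
  mode <- match.arg(mode)
  if (mode == "bands" && frame_sec * min(bands$f_low) < 2)
    message("note: the ", frame_sec, "-s frame holds under 2 cycles of the ",
            min(bands$f_low), "-Hz band edge; the lowest-band powers are ",
            "coarse estimates")
  structure(list(mode = mode, frame_sec = frame_sec, bands = bands),
            class = "feature_config")
}

#' Build the encoder input matrix for one window
#'
#' Transforms a labeled window into the feature matrix `Z` (`T' x D`) fed
#' to the encoder. In `"raw"` mode `Z` is the window itself. In `"bands"`
#' mode the window is split into `frame_sec`-long sub-frames; each row of
#' `Z` holds the frame-mean of every channel followed by the `log(1 + x)`
#' band powers (delta, theta, alpha, beta, each for every channel).
#' Column order: channels first, then band-by-band blocks of channels.
#'
#' @param win A `labeled_window`.
#' @param cfg A `feature_config`.
#' @return A `feature_matrix` object with `data`, `feature_names`,
#'   `t_prime`, `label`, `subject_id`.
#' @export
build_feature_matrix <- function(win, cfg = feature_config()) {
  x <- win$data
  chans <- colnames(x)
  if (is.null(chans)) chans <- paste0("ch", seq_len(ncol(x)))
  if (cfg$mode == "raw") {
    z <- x
    names_out <- chans
  } else {
    frame_len <- as.integer(round(cfg$frame_sec * win$fs))
    if (frame_len < 2) stop("parameter error: frame too short")
    n_frames <- floor(nrow(x) / frame_len)
    nb <- nrow(cfg$bands)
    c_ <- ncol(x)
    z <- matrix(0, n_frames, c_ + nb * c_)
    for (f in seq_len(n_frames)) {
      seg <- x[((f - 1) * frame_len + 1):(f * frame_len), , drop = FALSE]
      z[f, 1:c_] <- colMeans(seg)
      for (j in seq_len(c_)) {
        psd <- welch_psd(seg[, j], fs = win$fs,
                         seg_len = min(frame_len, round(2 * win$fs)))
        for (b in seq_len(nb)) {
          z[f, c_ + (b - 1) * c_ + j] <-
            log1p(band_power(psd, cfg$bands$f_low[b], cfg$bands$f_high[b]))
        }
      }
    }
    names_out <- c(chans,
                   as.vector(t(outer(cfg$bands$name, chans,
                                     function(b, ch) paste0("bp_", b, "_", ch)))))
  }
  colnames(z) <- names_out
  structure(list(data = z, feature_names = names_out, t_prime = nrow(z),
                 label = win$label, subject_id = win$subject_id,
                 augmented = win$augmented),
            class = "feature_matrix")
}

#' Featurize every window of a dataset
#'
#' @param ds A `windowed_dataset`.
#' @param cfg A `feature_config`.
#' @return List of `feature_matrix` objects.
#' @export
build_features <- function(ds, cfg = feature_config()) {
  lapply(ds$windows, build_feature_matrix, cfg = cfg)
}
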