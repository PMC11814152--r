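#' Default class signatures
#'
#' Band-power and ERP signatures that distinguish the five cognitive
#' states in the synthetic generator. Directions follow the cognitive-EEG
#' feature patterns the classifier targets (e.g. elevated beta/theta under
#' high cognitive load, suppressed alpha with elevated delta/theta under
#' mental fatigue); the numeric multipliers are package defaults chosen to
#' make the classes separable but overlapping under noise, and are fully
#' configurable.
#'
#' * HCL: beta x2.0, theta x1.5, ERP latency +0.05 s
#' * MF: alpha x0.5, delta x1.8, theta x1.4
#' * S: theta x2.0, ERP amplitude x1.5
#' * A: alpha x1.8, beta x0.6
#' * LA: alpha x0.5, theta x0.6, beta x0.6
#'
#' @return Named list (HCL, MF, S, A, LA) of `class_signature` objects
#'   with fields `state`, `band_gain` (delta/theta/alpha/beta
#'   multipliers), `erp_latency_shift` (s), `erp_amplitude`.
#' @export
default_signatures <- function() {
  mk <- function(state, delta = 1, theta = 1, alpha = 1, beta = 1,
                 lat = 0, amp = 1) {
    gains <- c(delta = delta, theta = theta, alpha = alpha, beta = beta)
    stopifnot(all(gains > 0))
    structure(list(state = state, band_gain = gains,
                   erp_latency_shift = lat, erp_amplitude = amp),
              class = "class_signature")
  }
  list(HCL = mk("HCL", beta = 2.0, theta = 1.5, lat = 0.05),
       MF = mk("MF", alpha = 0.5, delta = 1.8, theta = 1.4),
       S = mk("S", theta = 2.0, amp = 1.5),
       A = mk("A", alpha = 1.8, beta = 0.6),
       LA = mk("LA", alpha = 0.5, theta = 0.6, beta = 0.6))
}

#' Synthetic cohort configuration
#'
#' Geometry and mixture of the generated cohort: 30 subjects by 5,000
#' time steps by 32 channels at 100 Hz (150,000 time-step samples in
#' total), with the class mixture HCL 23.3%, MF 20.0%, S 26.7%, A 16.7%,
#' LA 13.3%.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param fs Sampling rate in Hz (default 100).
#' @param n_channels Channels per subject (default 32).
#' @param samples_per_subject Time steps per subject (default 5000).
#' @param window_sec Length of each labeled state segment in seconds
#'   (default 10, matching the analysis window).
#' @param class_proportions Named state mixture, summing to 1.
#' @param noise_scale Amplitude of the pink (1/f) background relative to
#'   the unit band-oscillation amplitude (default 0.1).
#' @param subject_variability Standard deviation of the per-subject
#'   lognormal gain jitter (default 0.1).
#' @param signatures Class signature list (default
#'   [default_signatures()]).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 30, fs = 100, n_channels = 32,
                             samples_per_subject = 5000, window_sec = 10,
                             class_proportions = c(HCL = 0.233, MF = 0.200,
                                                   S = 0.267, A = 0.167,
                                                   LA = 0.133),
                             noise_scale = 0.1, subject_variability = 0.1,
                             signatures = default_signatures(), seed = 0L) {
  stopifnot(n_subjects >= 1, fs > 0, n_channels >= 1,
            abs(sum(class_proportions) - 1) < 1e-6)
  structure(list(n_subjects = as.integer(n_subjects), fs = fs,
                 n_channels = as.integer(n_channels),
                 samples_per_subject = as.integer(samples_per_subject),
                 window_sec = window_sec,
                 class_proportions = class_proportions,
                 noise_scale = noise_scale,
                 subject_variability = subject_variability,
                 signatures = signatures, seed = as.integer(seed)),
            class = "generator_config")
}

# pink (1/f) noise via spectral shaping; slope -1 in power
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))           # avoid division by zero at DC
  f <- pmin(f, n - f + 1)             # symmetric frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one class-conditional EEG window
#'
#' Per channel: a sum of band-limited sinusoid mixtures (three random
#' center frequencies per band, random phases) whose per-band amplitudes
#' are scaled by the class signature's band gains, plus a pink-noise
#' (1/f) background at `noise_scale`, plus an ERP-like damped oscillatory
#' transient at a marked event sample whose latency and amplitude follow
#' the signature. Deterministic given `seed`.
#'
#' @param state State code or abbreviation.
#' @param sig A `class_signature` (default taken from
#'   [default_signatures()]).
#' @param fs Sampling rate (default 100 Hz).
#' @param n_channels Channels (default 32).
#' @param t_w Window length in samples (default 1000; must be at least
#'   2 s of signal).
#' @param noise_scale Pink-noise amplitude (default 0.1).
#' @param seed Integer seed.
#' @param subject_id,start_index Metadata for the emitted window.
#' @return A `labeled_window` carrying one event marker at the ERP onset.
#' @export
generate_window <- function(state, sig = NULL, fs = 100, n_channels = 32,
                            t_w = 1000, noise_scale = 0.1, seed = 0L,
                            subject_id = "s01", start_index = 0L) {
  code <- state_code(state)
  if (is.null(sig)) sig <- default_signatures()[[state_abbrev(code)]]
  if (t_w < 2 * fs) stop("parameter error: window must hold at least 2 s")
  set.seed(seed)
  bands <- eeg_bands()
  tt <- (0:(t_w - 1)) / fs
  x <- matrix(0, t_w, n_channels)
  for (ch in seq_len(n_channels)) {
    sig_ch <- numeric(t_w)
    for (b in seq_len(nrow(bands))) {
      gain <- sig$band_gain[[bands$name[b]]]
      freqs <- stats::runif(3, bands$f_low[b], bands$f_high[b])
      phases <- stats::runif(3, 0, 2 * pi)
      comp <- rowSums(sapply(seq_len(3), function(i)
        sin(2 * pi * freqs[i] * tt + phases[i])))
      sig_ch <- sig_ch + gain * comp / sqrt(3)
    }
    x[, ch] <- sig_ch + noise_scale * .pink_noise(t_w)
  }
  # ERP-like transient: damped 8 Hz oscillation, onset mid-window plus the
  # class latency shift
  onset <- as.integer(round(t_w / 2 + sig$erp_latency_shift * fs))
  span <- seq.int(onset, min(onset + round(0.5 * fs), t_w - 1))
  te <- (span - onset) / fs
  erp <- sig$erp_amplitude * exp(-te / 0.1) * sin(2 * pi * 8 * te)
  x[span + 1, ] <- x[span + 1, ] + matrix(erp, length(span), n_channels)
  labeled_window(x, label = code, subject_id = subject_id,
                 start_index = start_index, fs = fs,
                 events = data.frame(sample_index = onset, code = "erp",
                                     stringsAsFactors = FALSE))
}

#' Largest-remainder integer allocation
#'
#' Splits `n` items over categories proportionally: floor of each exact
#' share, remaining items to the categories with the largest fractional
#' remainders. Deviates from exact proportionality by less than one item
#' per category.
#'
#' @param n Total count.
#' @param proportions Numeric vector summing to 1.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  exact <- n * proportions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Generate a synthetic labeled EEG cohort
#'
#' Allocates window labels over the cohort by largest-remainder so the
#' realized mixture matches the configured proportions to within one
#' window per class, shuffles labels over (subject, slot) positions, and
#' generates each subject's recording as a concatenation of labeled state
#' segments. A per-subject lognormal gain jitter (sd
#' `subject_variability`) multiplies every band gain, producing realistic
#' between-subject variation and subject-wise train/test difficulty.
#'
#' @param cfg A `generator_config`.
#' @return List with `recordings` (list of `eeg_recording`), `dataset`
#'   (labeled `windowed_dataset`) and `manifest` (data frame: window,
#'   subject, start_index, state, seed).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  t_w <- as.integer(round(cfg$window_sec * cfg$fs))
  wins_per_subj <- cfg$samples_per_subject %/% t_w
  n_windows <- cfg$n_subjects * wins_per_subj
  counts <- largest_remainder(n_windows, cfg$class_proportions)
  if (any(counts == 0))
    stop("too few windows to realize all five classes; ",
         "increase samples_per_subject or n_subjects")
  states <- rep(names(counts), counts)
  set.seed(cfg$seed)
  states <- sample(states)
  jitter <- matrix(stats::rlnorm(cfg$n_subjects * 4, 0, cfg$subject_variability),
                   cfg$n_subjects, 4, dimnames = list(NULL, eeg_bands()$name))

  recordings <- vector("list", cfg$n_subjects)
  windows <- vector("list", n_windows)
  manifest <- data.frame()
  k <- 0
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("s%02d", s)
    segs <- vector("list", wins_per_subj)
    events <- data.frame()
    for (w in seq_len(wins_per_subj)) {
      k <- k + 1
      st <- states[k]
      sig <- cfg$signatures[[st]]
      sig$band_gain <- sig$band_gain * jitter[s, ]
      wseed <- (cfg$seed * 131071L + k * 8191L) %% .Machine$integer.max
      lw <- generate_window(st, sig = sig, fs = cfg$fs,
                            n_channels = cfg$n_channels, t_w = t_w,
                            noise_scale = cfg$noise_scale, seed = wseed,
                            subject_id = sid,
                            start_index = (w - 1L) * t_w)
      segs[[w]] <- lw$data
      events <- rbind(events, data.frame(
        sample_index = lw$events$sample_index + (w - 1L) * t_w,
        code = lw$events$code, stringsAsFactors = FALSE))
      windows[[k]] <- lw
      manifest <- rbind(manifest, data.frame(
        window = k, subject_id = sid, start_index = (w - 1L) * t_w,
        state = st, seed = wseed, stringsAsFactors = FALSE))
    }
    recordings[[s]] <- eeg_recording(do.call(rbind, segs), fs = cfg$fs,
                                     channels = paste0("ch", seq_len(cfg$n_channels)),
                                     subject_id = sid, events = events)
  }
  list(recordings = recordings,
       dataset = windowed_dataset(windows, fs = cfg$fs),
       manifest = manifest)
}

#' Condition and window a generated cohort
#'
#' Applies the standard conditioning (per-recording z-scoring by default;
#' band-pass optional via `cfg_pre`) to every recording of a generated
#' cohort and re-segments it into labeled windows using the cohort
#' manifest as the label source.
#'
#' @param cohort Output of [generate_cohort()].
#' @param cfg_pre A `preprocess_config`.
#' @param bandpass Also band-pass filter each recording (default `FALSE`:
#'   the generator's signals are already band-limited, so z-scoring alone
#'   is the informative step).
#' @return A labeled `windowed_dataset`.
#' @export
preprocess_cohort <- function(cohort, cfg_pre = preprocess_config(),
                              bandpass = FALSE) {
  t_w <- as.integer(round(cfg_pre$window_sec * cfg_pre$target_fs))
  wins <- list()
  for (rec in cohort$recordings) {
    if (bandpass)
      rec <- bandpass_filter(rec, cfg_pre$band_low, cfg_pre$band_high,
                             cfg_pre$filter_order)
    if (cfg_pre$zscore) rec <- zscore_normalize(rec)
    man <- cohort$manifest[cohort$manifest$subject_id == rec$subject_id, ]
    labs <- data.frame(start = man$start_index, end = man$start_index + t_w,
                       label = man$state)
    w <- segment_windows(rec, labels = labs, cfg = cfg_pre)
    wins <- c(wins, w$windows)
  }
  windowed_dataset(wins, fs = cfg_pre$target_fs)
}
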