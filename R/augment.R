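#' Augmentation configuration
#'
#' Parameters of the cascade augmentation policy: each original training
#' window spawns `ratio_aug_per_orig` copies, each produced by a random
#' time shift of up to +/-50 ms followed by additive Gaussian noise with a
#' standard deviation of 5% of the per-channel signal scale, yielding a
#' dataset three times the original size at the default ratio of 2. Time
#' warping and channel dropout belong to the broader perturbation family
#' and are off by default.
#'
#' @param max_shift_sec Maximum absolute time shift in seconds (default
#'   0.050).
#' @param noise_sd_frac Noise standard deviation as a fraction of the
#'   per-channel standard deviation (default 0.05).
#' @param ratio_aug_per_orig Augmented copies per original window
#'   (default 2).
#' @param time_warp_frac Maximum local rate deviation of the time warp
#'   (default 0.05); only used when `use_warp = TRUE`.
#' @param channel_dropout_p Per-channel dropout probability (default 0.1);
#'   only used when `use_dropout = TRUE`.
#' @param use_warp,use_dropout Enable the optional perturbations.
#' @param seed Integer seed making the cascade deterministic.
#' @return An `augment_config` list.
#' @export
augment_config <- function(max_shift_sec = 0.05, noise_sd_frac = 0.05,
                           ratio_aug_per_orig = 2, time_warp_frac = 0.05,
                           channel_dropout_p = 0.1, use_warp = FALSE,
                           use_dropout = FALSE, seed = 0L) {
  stopifnot(ratio_aug_per_orig >= 0, noise_sd_frac >= 0,
            max_shift_sec >= 0, time_warp_frac >= 0, time_warp_frac <= 1,
            channel_dropout_p >= 0, channel_dropout_p < 1)
  structure(list(max_shift_sec = max_shift_sec, noise_sd_frac = noise_sd_frac,
                 ratio_aug_per_orig = as.integer(ratio_aug_per_orig),
                 time_warp_frac = time_warp_frac,
                 channel_dropout_p = channel_dropout_p,
                 use_warp = use_warp, use_dropout = use_dropout,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Shift a window along the time axis
#'
#' Rolls the signal by `shift_samples` (positive = later), padding the
#' vacated edge with the edge value rather than wrapping around, so no
#' artificial transients are introduced near epoch boundaries. Label and
#' shape are unchanged.
#'
#' @param win A `labeled_window`.
#' @param shift_samples Integer shift; `|shift_samples|` must not exceed
#'   `round(max_shift_sec * fs)`.
#' @param max_shift_sec Admissible shift bound in seconds (default 0.050).
#' @return The shifted `labeled_window`.
#' @export
time_shift <- function(win, shift_samples, max_shift_sec = 0.05) {
  s <- as.integer(shift_samples)
  bound <- as.integer(round(max_shift_sec * win$fs))
  if (abs(s) > bound)
    stop("parameter error: |shift| = ", abs(s), " samples exceeds the ",
         bound, "-sample (", max_shift_sec * 1000, " ms) bound")
  if (s == 0) return(win)
  n <- nrow(win$data)
  out <- win$data
  if (s > 0) {
    out[(s + 1):n, ] <- win$data[1:(n - s), , drop = FALSE]
    out[1:s, ] <- matrix(win$data[1, ], s, ncol(out), byrow = TRUE)
  } else {
    out[1:(n + s), ] <- win$data[(1 - s):n, , drop = FALSE]
    out[(n + s + 1):n, ] <- matrix(win$data[n, ], -s, ncol(out), byrow = TRUE)
  }
  win$data <- out
  win
}

#' Add channel-scaled Gaussian noise to a window
#'
#' Per channel, adds zero-mean Gaussian noise with standard deviation
#' `sd_frac` times the channel's standard deviation (the "signal
#' amplitude" scale; robust to DC offsets after z-scoring). Constant
#' channels have zero scale and are left unchanged.
#'
#' @param win A `labeled_window`.
#' @param sd_frac Noise fraction (default 0.05).
#' @param seed Optional integer seed for determinism.
#' @return The noisy `labeled_window`.
#' @export
add_gaussian_noise <- function(win, sd_frac = 0.05, seed = NULL) {
  if (sd_frac < 0) stop("parameter error: sd_frac must be >= 0")
  if (sd_frac == 0) return(win)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(win$data)
  for (j in seq_len(ncol(win$data))) {
    sc <- stats::sd(win$data[, j])
    if (!is.finite(sc) || sc == 0) next
    win$data[, j] <- win$data[, j] + stats::rnorm(n, 0, sd_frac * sc)
  }
  win
}

#' Smooth monotone time warp
#'
#' Remaps the time axis through a smooth, strictly increasing warp whose
#' local rate deviates from 1 by at most `warp_frac` (a sinusoidal rate
#' perturbation with random frequency and phase), then resamples by linear
#' interpolation. Output length is preserved; a constant signal is
#' unchanged by construction.
#'
#' @param win A `labeled_window`.
#' @param warp_frac Maximum local rate deviation in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return The warped `labeled_window`.
#' @export
time_warp <- function(win, warp_frac = 0.05, seed = NULL) {
  if (warp_frac < 0 || warp_frac >= 0.5)
    stop("parameter error: warp_frac must be in [0, 0.5)")
  if (warp_frac == 0) return(win)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(win$data)
  cycles <- stats::runif(1, 1, 3)
  phase <- stats::runif(1, 0, 2 * pi)
  rate <- 1 + warp_frac * sin(2 * pi * cycles * (0:(n - 2)) / (n - 1) + phase)
  grid <- c(0, cumsum(rate))
  grid <- grid / grid[n] * (n - 1)          # strictly increasing, endpoints fixed
  for (j in seq_len(ncol(win$data))) {
    win$data[, j] <- stats::approx(0:(n - 1), win$data[, j], xout = grid)$y
  }
  win
}

#' Randomly zero whole channels
#'
#' Each channel is independently zeroed with probability `p`; if a draw
#' would drop every channel it is redrawn, so at least one channel is
#' always retained.
#'
#' @param win A `labeled_window`.
#' @param p Dropout probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return The `labeled_window` with dropped channels set to exactly zero.
#' @export
channel_dropout <- function(win, p = 0.1, seed = NULL) {
  if (p < 0 || p >= 1) stop("parameter error: p must be in [0, 1)")
  if (p == 0) return(win)
  if (!is.null(seed)) set.seed(seed)
  c_ <- ncol(win$data)
  repeat {
    drop <- stats::runif(c_) < p
    if (!all(drop)) break
  }
  win$data[, drop] <- 0
  win
}

#' Cascade-augment a windowed dataset
#'
#' For each original window, generates `ratio_aug_per_orig` copies by the
#' cascade: random time shift (uniform over the admissible +/- bound),
#' then Gaussian noise; time warp and channel dropout are applied in
#' addition when enabled. The output contains the originals followed by
#' the copies (size `(1 + ratio) x` the input), labels are inherited, and
#' every copy carries `augmented = TRUE` plus its parent index. The whole
#' cascade is deterministic given `cfg$seed`.
#'
#' @param ds A `windowed_dataset`.
#' @param cfg An `augment_config`.
#' @return The augmented `windowed_dataset`.
#' @export
augment_dataset <- function(ds, cfg = augment_config()) {
  n <- length(ds)
  if (n == 0) return(ds)
  bound <- as.integer(round(cfg$max_shift_sec * ds$fs))
  out <- vector("list", n * (1 + cfg$ratio_aug_per_orig))
  out[1:n] <- ds$windows
  k <- n
  for (i in seq_len(n)) {
    for (r in seq_len(cfg$ratio_aug_per_orig)) {
      # one deterministic sub-seed per (window, copy)
      set.seed((cfg$seed * 1000003L + i * 131L + r) %% .Machine$integer.max)
      w <- ds$windows[[i]]
      shift <- sample.int(2L * bound + 1L, 1L) - bound - 1L
      w <- time_shift(w, shift, max_shift_sec = cfg$max_shift_sec)
      w <- add_gaussian_noise(w, cfg$noise_sd_frac)
      if (cfg$use_warp) w <- time_warp(w, cfg$time_warp_frac)
      if (cfg$use_dropout) w <- channel_dropout(w, cfg$channel_dropout_p)
      w$augmented <- TRUE
      w$parent_id <- as.character(i)
      k <- k + 1
      out[[k]] <- w
    }
  }
  windowed_dataset(out, fs = ds$fs)
}
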