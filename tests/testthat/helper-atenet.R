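# shared fixtures built in code

# small random recording
make_recording <- function(n = 300, c_ = 3, fs = 100, seed = 1,
                           events = NULL, subject_id = "s01") {
  set.seed(seed)
  eeg_recording(matrix(rnorm(n * c_), n, c_), fs = fs,
                subject_id = subject_id, events = events)
}

# pure sinusoid recording (one channel unless c_ > 1)
sine_recording <- function(freq, fs = 100, dur = 10, c_ = 1, amp = 1) {
  tt <- (0:(dur * fs - 1)) / fs
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * tt), c_), ncol = c_),
                fs = fs)
}

# small labeled window
make_window <- function(n = 1000, c_ = 2, fs = 100, seed = 1, label = 0L) {
  set.seed(seed)
  labeled_window(matrix(rnorm(n * c_), n, c_), label = label, fs = fs)
}

# tiny model configuration for fast structural tests
tiny_cfg <- function(d_input = 3, ...) {
  aten_config(d_input = d_input, d_model = 4, n_layers = 1,
              kernel_sizes = c(3), d_int = 6, dropout_p = 0, d_hier = 4, ...)
}

# a small, fast-to-generate cohort (6 subjects keeps generator tests quick)
small_cohort <- function(n_subjects = 6, n_channels = 4, noise_scale = 0.1,
                         seed = 7) {
  generate_cohort(generator_config(
    n_subjects = n_subjects, n_channels = n_channels,
    noise_scale = noise_scale, seed = seed))
}

# dominant-class table for subject_split stratification
subject_table <- function(ds) subject_table_of(ds)

# direct (single-segment, rectangular-window) periodogram oracle used to
# validate the Welch implementation independently
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2 / (fs * n)
  n_freq <- floor(n / 2) + 1
  p <- p[1:n_freq]
  dbl <- 2:(n_freq - if (n %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  data.frame(freq = (0:(n_freq - 1)) * fs / n, power = p)
}
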