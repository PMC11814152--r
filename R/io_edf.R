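#' Read an EDF/EDF+ file into an EEG recording
#'
#' Minimal reader for the European Data Format: the fixed 256-byte header,
#' the per-signal header block, and the 16-bit little-endian sample records,
#' with digital-to-physical scaling per channel. Annotation channels
#' (`EDF Annotations`) are skipped. If channels are stored at different
#' sampling rates, every channel is resampled (anti-alias filtered) to the
#' minimum channel rate and the returned recording's `note` field records
#' that.
#'
#' @param path Path to an EDF file.
#' @return A validated `eeg_recording`; channel order equals file order.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("format error: no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stop("format error: truncated EDF header")
    trimws(rawToChar(raw))
  }
  version <- rd_str(8)
  patient <- rd_str(80)
  recording_id <- rd_str(80)
  rd_str(8); rd_str(8)                       # start date, start time
  header_bytes <- suppressWarnings(as.integer(rd_str(8)))
  rd_str(44)                                 # reserved
  n_records <- suppressWarnings(as.integer(rd_str(8)))
  record_dur <- suppressWarnings(as.numeric(rd_str(8)))
  ns <- suppressWarnings(as.integer(rd_str(4)))
  if (is.na(ns) || ns < 1) stop("data error: EDF file declares zero signals")
  if (is.na(n_records) || is.na(record_dur) || record_dur <= 0)
    stop("format error: invalid EDF record geometry")
  rd_field <- function(width) vapply(seq_len(ns), function(i) rd_str(width), character(1))
  labels <- rd_field(16)
  rd_field(80)                               # transducer
  rd_field(8)                                # physical dimension
  pmin <- as.numeric(rd_field(8))
  pmax <- as.numeric(rd_field(8))
  dmin <- as.numeric(rd_field(8))
  dmax <- as.numeric(rd_field(8))
  rd_field(80)                               # prefiltering
  spr <- as.integer(rd_field(8))             # samples per record per signal
  rd_field(32)                               # reserved
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("format error: corrupt EDF signal header")

  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop("data error: EDF file has no signal channels")
  total_per_record <- sum(spr)
  samples <- readBin(con, "integer", n = total_per_record * n_records,
                     size = 2, signed = TRUE, endian = "little")
  if (length(samples) < total_per_record * n_records)
    stop("format error: truncated EDF data section")

  offsets <- c(0, cumsum(spr))
  sig <- vector("list", ns)
  for (i in which(keep)) sig[[i]] <- numeric(spr[i] * n_records)
  for (r in seq_len(n_records)) {
    base <- (r - 1) * total_per_record
    for (i in which(keep)) {
      idx <- base + offsets[i] + seq_len(spr[i])
      sig[[i]][(r - 1) * spr[i] + seq_len(spr[i])] <- samples[idx]
    }
  }
  # digital -> physical scaling
  for (i in which(keep)) {
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    sig[[i]] <- (sig[[i]] - dmin[i]) * gain + pmin[i]
  }
  fs_all <- spr / record_dur
  fs_keep <- fs_all[keep]
  note <- ""
  fs_out <- min(fs_keep)
  chans <- labels[keep]
  out <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    j <- j + 1
    x <- sig[[i]]
    if (fs_all[i] > fs_out) {
      x <- resample_series(x, from_fs = fs_all[i], to_fs = fs_out)
    }
    out[[j]] <- x
  }
  if (length(unique(fs_keep)) > 1)
    note <- sprintf("mixed channel rates (%s Hz) resampled to %g Hz on read",
                    paste(sort(unique(fs_keep)), collapse = "/"), fs_out)
  n_out <- min(lengths(out))
  data <- vapply(out, function(x) x[seq_len(n_out)], numeric(n_out))
  eeg_recording(data, fs = fs_out, channels = chans,
                subject_id = if (nzchar(patient)) patient else recording_id,
                note = note)
}

#' Write an EEG recording as an EDF file
#'
#' Minimal EDF writer used to exercise the reader and to export synthetic
#' recordings into the standard EEG container. Samples are quantized to
#' 16-bit with per-channel physical scaling over the channel's observed
#' range, so the round trip is exact to about 1/65535 of each channel's
#' amplitude range. The record duration is 1 s; the recording length must
#' therefore be a whole number of seconds.
#'
#' @param rec An `eeg_recording`, or a list of per-channel numeric vectors
#'   when channels have different rates (then `fs` must be a vector).
#' @param path Output path.
#' @param fs Optional per-channel sampling-rate vector (list input only).
#' @param channels Optional channel labels (list input only).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, fs = NULL, channels = NULL) {
  if (inherits(rec, "eeg_recording")) {
    validate_recording(rec)
    sigs <- lapply(seq_along(rec$channels), function(i) rec$data[, i])
    fs <- rep(rec$fs, length(sigs))
    channels <- rec$channels
    patient <- rec$subject_id
  } else {
    sigs <- rec
    if (is.null(fs) || length(fs) != length(sigs))
      stop("fs vector required, one rate per channel")
    if (is.null(channels)) channels <- paste0("ch", seq_along(sigs))
    patient <- "synthetic"
  }
  dur <- lengths(sigs) / fs
  if (length(unique(round(dur, 9))) != 1)
    stop("all channels must span the same duration")
  n_records <- dur[1]
  if (abs(n_records - round(n_records)) > 1e-9)
    stop("recording length must be a whole number of seconds (1-s records)")
  n_records <- as.integer(round(n_records))
  spr <- as.integer(round(fs))                 # samples per 1-s record
  ns <- length(sigs)

  pmin <- vapply(sigs, min, numeric(1))
  pmax <- vapply(sigs, max, numeric(1))
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, width) {
    x <- as.character(x)
    if (nchar(x) > width) x <- substr(x, 1, width)
    formatC(x, width = width, flag = "-")
  }
  num8 <- function(x) pad(formatC(x, format = "g", digits = 7), 8)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad(patient, 80)); wr(pad("atenet export", 80))
  wr(pad("01.01.26", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 + 256 * ns, 8)); wr(pad("", 44))
  wr(pad(n_records, 8)); wr(num8(1)); wr(pad(ns, 4))
  for (ch in channels) wr(pad(ch, 16))
  for (i in 1:ns) wr(pad("", 80))
  for (i in 1:ns) wr(pad("uV", 8))
  for (i in 1:ns) wr(num8(pmin[i]))
  for (i in 1:ns) wr(num8(pmax[i]))
  for (i in 1:ns) wr(num8(dmin))
  for (i in 1:ns) wr(num8(dmax))
  for (i in 1:ns) wr(pad("", 80))
  for (i in 1:ns) wr(pad(spr[i], 8))
  for (i in 1:ns) wr(pad("", 32))

  # requantize against the (possibly 7-digit rounded) header values the
  # reader will see, so scaling is self-consistent
  hdr_val <- function(x) as.numeric(trimws(num8(x)))
  pmin_h <- vapply(pmin, hdr_val, numeric(1))
  pmax_h <- vapply(pmax, hdr_val, numeric(1))
  dig <- lapply(seq_len(ns), function(i) {
    d <- round((sigs[[i]] - pmin_h[i]) / (pmax_h[i] - pmin_h[i]) *
                 (dmax - dmin) + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      idx <- (r - 1) * spr[i] + seq_len(spr[i])
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
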