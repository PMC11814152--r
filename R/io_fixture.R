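#' Write a recording to the plain-text fixture format
#'
#' The fixture format pairs `<path>.json` (header: subject_id, fs, channels,
#' events, n_samples) with `<path>.csv` (signal body: `T` rows, `C` columns,
#' no header row). The round trip `read_fixture(write_fixture(rec))` is
#' bit-exact for header fields and preserves the signal to full numeric
#' precision (values serialized with 17 significant digits).
#'
#' @param rec A validated `eeg_recording`.
#' @param path Base path without extension; `.json` and `.csv` are appended.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rec, path) {
  validate_recording(rec)
  header <- list(
    subject_id = rec$subject_id,
    fs = rec$fs,
    channels = rec$channels,
    events = if (nrow(rec$events) > 0) rec$events else list(),
    n_samples = nrow(rec$data),
    note = rec$note
  )
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  body <- apply(rec$data, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = ","))
  writeLines(body, paste0(path, ".csv"))
  invisible(path)
}

#' Read a recording from the plain-text fixture format
#'
#' @param path Base path without extension (expects `<path>.json` and
#'   `<path>.csv`).
#' @return A validated `eeg_recording`.
#' @export
read_fixture <- function(path) {
  jpath <- paste0(path, ".json")
  cpath <- paste0(path, ".csv")
  if (!file.exists(jpath)) stop("format error: missing header file ", jpath)
  if (!file.exists(cpath)) stop("format error: missing body file ", cpath)
  header <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (field in c("fs", "channels", "n_samples")) {
    if (is.null(header[[field]]))
      stop("format error: header missing required field '", field, "'")
  }
  if (!is.numeric(header$fs) || header$fs <= 0)
    stop("format error in field 'fs': must be a positive number")
  data <- as.matrix(utils::read.csv(cpath, header = FALSE,
                                    colClasses = "numeric"))
  dimnames(data) <- NULL
  if (nrow(data) != header$n_samples)
    stop("format error in field 'n_samples': header says ", header$n_samples,
         " but body has ", nrow(data), " rows")
  if (ncol(data) != length(header$channels))
    stop("format error in field 'channels': header lists ",
         length(header$channels), " channels but body has ", ncol(data),
         " columns")
  if (!all(is.finite(data))) stop("data error: non-finite values in body")
  events <- header$events
  if (is.null(events) || length(events) == 0 || !is.data.frame(events)) {
    events <- data.frame(sample_index = integer(0), code = character(0),
                         stringsAsFactors = FALSE)
  } else {
    events <- data.frame(sample_index = as.integer(events$sample_index),
                         code = as.character(events$code),
                         stringsAsFactors = FALSE)
  }
  eeg_recording(data, fs = header$fs, channels = header$channels,
                subject_id = if (is.null(header$subject_id)) "" else header$subject_id,
                events = events,
                note = if (is.null(header$note)) "" else header$note)
}
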