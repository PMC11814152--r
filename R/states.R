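#' Cognitive-state code table
#'
#' The five cognitive states the classifier predicts, with their fixed
#' integer encoding. The encoding is part of the package contract so that
#' confusion matrices, checkpoints and reports are comparable across runs:
#' HCL = 0, MF = 1, S = 2, A = 3, LA = 4.
#'
#' @return A data frame with columns `code` (integer 0--4), `abbrev`
#'   (character: HCL, MF, S, A, LA) and `name` (display name).
#' @examples
#' cognitive_states()
#' @export
cognitive_states <- function() {
  data.frame(
    code = 0:4,
    abbrev = c("HCL", "MF", "S", "A", "LA"),
    name = c(
      "high cognitive load", "mental fatigue", "stress",
      "alertness", "low alertness"
    ),
    stringsAsFactors = FALSE
  )
}

#' State abbreviations in code order
#' @return Character vector `c("HCL","MF","S","A","LA")`.
#' @export
state_levels <- function() cognitive_states()$abbrev

#' Normalize a state specification to its integer code
#'
#' Accepts integer codes (0--4), abbreviations ("HCL", ...) or full display
#' names, and returns the fixed integer code.
#'
#' @param x Vector of codes, abbreviations or names.
#' @return Integer vector of codes in 0--4.
#' @export
state_code <- function(x) {
  st <- cognitive_states()
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- !(x %in% st$code)
    if (any(bad)) stop("unknown cognitive-state code: ", paste(x[bad], collapse = ", "))
    return(x)
  }
  x <- as.character(x)
  idx <- match(toupper(x), st$abbrev)
  idx[is.na(idx)] <- match(tolower(x[is.na(idx)]), st$name)
  if (anyNA(idx)) stop("unknown cognitive state: ", paste(x[is.na(idx)], collapse = ", "))
  st$code[idx]
}

#' Abbreviation for a state code
#' @param code Integer codes 0--4 (or abbreviations, passed through).
#' @return Character vector of abbreviations.
#' @export
state_abbrev <- function(code) {
  st <- cognitive_states()
  st$abbrev[match(state_code(code), st$code)]
}
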