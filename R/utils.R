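#' @keywords internal
"_PACKAGE"

# Classed conditions -----------------------------------------------------

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("evlink_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parse <- function(msg, ...) {
  stop(structure(
    class = c("evlink_parse_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_contract <- function(msg, ...) {
  stop(structure(
    class = c("evlink_contract_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_not_comparable <- function(study_id) {
  stop(structure(
    class = c("evlink_not_comparable", "error", "condition"),
    list(message = sprintf(
      "study '%s' has a single source with a single version; nothing to compare",
      study_id
    ), call = sys.call(-1))
  ))
}

# Small numeric helpers --------------------------------------------------

#' Round a percentage half away from zero
#'
#' Integer percentage `100 * num / den`, rounded half away from zero (the
#' convention of printed summary tables; base [round()] rounds half to even).
#' Returns `NA` when the denominator is zero, so empty strata propagate as
#' missing rather than dividing by zero.
#'
#' @param num,den Numerator and denominator counts.
#' @return Integer percentage, or `NA` if `den == 0`.
#' @export
#' @examples
#' pct_round(66, 338) # 20
#' pct_round(63, 139) # 45
pct_round <- function(num, den) {
  if (is.null(den) || is.na(den) || den == 0) return(NA_real_)
  x <- 100 * num / den
  sign(x) * floor(abs(x) + 0.5)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_probability <- function(x) {
  is_scalar_number(x) && x >= 0 && x <= 1
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  if (is_scalar_string(x)) {
    d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
    if (!is.na(d)) return(d)
  }
  stop_validation("%s must be a Date or an ISO-8601 'YYYY-MM-DD' string, got: %s",
                  what, deparse(substitute(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalized (lowercase, collapsed whitespace) form of a free-text field,
# used wherever two versions of a string are compared for equality.
normalize_ws <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_character_)
  tolower(trimws(gsub("[[:space:]]+", " ", x)))
}
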