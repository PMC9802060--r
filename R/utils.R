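#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition constructors: every user-facing failure carries a class so callers
# (and tests) can distinguish bad configuration, bad file format, and bad input
ctb_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "courtback_error", "error")))
}
stop_config <- function(msg) ctb_stop(msg, "ctb_config_error")
stop_format <- function(msg) ctb_stop(msg, "ctb_format_error")
stop_input  <- function(msg) ctb_stop(msg, "ctb_input_error")

#' Round half away from zero
#'
#' Rounding convention used by every reporting layer in the package: exact
#' halves move away from zero (so 29.5 -> 30), unlike base [round()] which
#' rounds halves to even. Percentages in rendered tables use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))   # 1  2 -1
#' round_half_away(29.59, 0)            # 30
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# strict ISO-8601 date parser; impossible dates (e.g. month 13) come back NA
parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

# season ids are strings keyed by season end-year; ordering is numeric
season_num <- function(season_id) suppressWarnings(as.integer(season_id))

fmt_mean_sd <- function(m, s, digits = 1) {
  if (is.na(m)) return("—")
  paste0(formatC(round_half_away(m, digits), format = "f", digits = digits),
         " (", formatC(round_half_away(s, digits), format = "f", digits = digits), ")")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_config(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_config(sprintf("'%s' must be a positive integer", name))
  invisible(as.integer(x))
}
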