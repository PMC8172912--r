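#' Round half away from zero
#'
#' Display rounding used throughout program tables: exact halves round up
#' (7/14 reported = 50, 9/16 = 56.25 -> 56, 8/13 = 61.54 -> 62), unlike
#' [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 61.54), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of part in whole; NA when whole is 0
pct_of <- function(part, whole) {
  ifelse(whole > 0, 100 * part / whole, NA_real_)
}

# signed fixed-decimal formatting for SDI display ("+1.25", "-2.60", "0.00")
format_sdi <- function(sdi, digits = 2) {
  out <- ifelse(
    is.infinite(sdi),
    ifelse(sdi > 0, "+Inf", "-Inf"),
    sprintf("%+.*f", digits, sdi)
  )
  out[!is.na(sdi) & sdi == 0] <- sprintf("%.*f", digits, 0)
  out[is.na(sdi)] <- NA_character_
  out
}

# canonical label for one measured quantity
quantity_label <- function(level, marker, value_kind) {
  paste(level, marker, value_kind, sep = ".")
}

# strict ISO-8601 date parsing; anything else becomes NA with ok = FALSE
parse_iso_date <- function(x) {
  x <- trimws(x)
  blank <- is.na(x) | x == ""
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- rep(as.Date(NA), length(x))
  d[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  list(date = d, ok = blank | (iso & !is.na(d)))
}

stop_eqa <- function(message, class) {
  abort(message, class = c(class, "cd4eqa_error"))
}
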