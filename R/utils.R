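#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables in pharmacovigilance
#' are conventionally rounded half-up, so percentage cells recompute exactly
#' from their printed counts.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up at `digits`.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Parse FAERS date strings: "YYYYMMDD" is full precision, "YYYYMM" and
# "YYYY" are partial, anything else (or empty) is missing.
# Returns a tibble with columns date (Date, NA unless full), year (integer),
# precision ("day", "month", "year", "missing").
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[is.na(x)] <- ""
  digits_only <- stringr::str_detect(x, "^[0-9]+$")
  nch <- stringr::str_length(x)
  precision <- dplyr::case_when(
    digits_only & nch == 8 ~ "day",
    digits_only & nch == 6 ~ "month",
    digits_only & nch == 4 ~ "year",
    TRUE ~ "missing"
  )
  date <- rep(as.Date(NA), length(x))
  full <- precision == "day"
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    # impossible dates like 20230231 fail to parse -> downgrade to missing
    precision[full][is.na(d)] <- "missing"
    date[full] <- d
  }
  year <- rep(NA_integer_, length(x))
  has_year <- precision != "missing"
  year[has_year] <- as.integer(stringr::str_sub(x[has_year], 1, 4))
  tibble::tibble(date = date, year = year, precision = precision)
}

# Stop with a classed error so callers/tests can match on class.
abort_faersignal <- function(message, class) {
  rlang::abort(message, class = c(class, "faersignal_error"))
}
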