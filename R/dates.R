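#' Classify and parse FAERS date strings
#'
#' FAERS encodes dates as `YYYYMMDD` integers; partially known dates are
#' truncated to `YYYYMM` or `YYYY`. This classifier distinguishes complete
#' calendar dates from partial and frankly invalid entries so that downstream
#' steps (time-to-onset in particular) can exclude anything that is not a
#' full, valid date.
#'
#' @param x character or numeric vector of raw date fields.
#' @return A tibble with one row per input: `input`, `status` (one of
#'   `"full"`, `"partial"`, `"invalid"`, `"missing"`), and `date` (a `Date`,
#'   `NA` unless `status == "full"`).
#' @examples
#' parse_faers_date(c("20200229", "202013", "2020", "", "20200101"))
#' @export
parse_faers_date <- function(x) {
  raw <- trimws(as.character(x))
  n <- length(raw)
  status <- rep("invalid", n)
  date <- rep(as.Date(NA), n)

  missing <- is.na(raw) | raw == "" | toupper(raw) == "NA"
  status[missing] <- "missing"

  digits <- !missing & grepl("^[0-9]+$", raw)
  len <- nchar(raw)

  # 8 digits: must be a real calendar date (leap days included)
  i8 <- digits & len == 8L
  if (any(i8)) {
    d <- as.Date(raw[i8], format = "%Y%m%d")
    yr <- suppressWarnings(as.integer(substr(raw[i8], 1, 4)))
    ok <- !is.na(d) & yr >= 1900L & yr <= 2100L
    status[i8][ok] <- "full"
    date[i8][ok] <- d[ok]
  }

  # 6 digits: YYYYMM with a plausible month
  i6 <- digits & len == 6L
  if (any(i6)) {
    yr <- suppressWarnings(as.integer(substr(raw[i6], 1, 4)))
    mo <- suppressWarnings(as.integer(substr(raw[i6], 5, 6)))
    ok <- !is.na(yr) & yr >= 1900L & yr <= 2100L & mo >= 1L & mo <= 12L
    status[i6][ok] <- "partial"
  }

  # 4 digits: bare year
  i4 <- digits & len == 4L
  if (any(i4)) {
    yr <- suppressWarnings(as.integer(raw[i4]))
    ok <- !is.na(yr) & yr >= 1900L & yr <= 2100L
    status[i4][ok] <- "partial"
  }

  tibble::tibble(input = raw, status = status, date = date)
}

# integer YYYYMMDD -> Date (assumes full precision)
ymd_int_to_date <- function(x) {
  as.Date(sprintf("%08d", as.integer(x)), format = "%Y%m%d")
}

# Date -> integer YYYYMMDD
date_to_ymd_int <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}
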