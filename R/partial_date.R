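#' Parse FAERS partial dates
#'
#' FAERS stores dates as bare numerics with 4, 6 or 8 digits
#' (`YYYY`, `YYYYMM`, `YYYYMMDD`), reflecting the precision the reporter
#' supplied. `parse_partial_date()` decomposes such strings into
#' year/month/day components plus a precision label. Anything malformed —
#' wrong length, non-numeric, month greater than 12, day greater than 31 —
#' maps to a missing value rather than an error, because dirty dates are the
#' norm in spontaneous reports; callers count how many failed to parse.
#'
#' @param x character vector of raw date strings (empty string or `NA`
#'   for absent).
#' @return A tibble with one row per input and columns `year`, `month`,
#'   `day` (integer, `NA` where below the stored precision) and `precision`
#'   (`"day"`, `"month"`, `"year"`, or `NA` for unparseable input).
#' @examples
#' parse_partial_date(c("20180315", "201903", "2019", "201913", ""))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep(NA_character_, n)

  digits <- grepl("^[0-9]+$", x)
  len <- nchar(x)

  ok4 <- digits & len == 4L
  ok6 <- digits & len == 6L
  ok8 <- digits & len == 8L

  year[ok4 | ok6 | ok8] <- as.integer(substr(x[ok4 | ok6 | ok8], 1L, 4L))
  month[ok6 | ok8] <- as.integer(substr(x[ok6 | ok8], 5L, 6L))
  day[ok8] <- as.integer(substr(x[ok8], 7L, 8L))

  bad_month <- !is.na(month) & (month < 1L | month > 12L)
  bad_day <- !is.na(day) & (day < 1L | day > 31L)
  bad <- bad_month | bad_day
  year[bad] <- NA_integer_
  month[bad] <- NA_integer_
  day[bad] <- NA_integer_

  precision[ok8 & !bad] <- "day"
  precision[ok6 & !bad] <- "month"
  precision[ok4 & !bad] <- "year"

  tibble::tibble(year = year, month = month, day = day, precision = precision)
}

#' Serialize parsed partial dates back to their FAERS numeric form
#'
#' Inverse of [parse_partial_date()]: day precision emits 8 digits, month
#' precision 6, year precision 4; missing precision emits the empty string.
#'
#' @param pd tibble as returned by [parse_partial_date()].
#' @return character vector of `YYYY[MM[DD]]` strings.
#' @export
format_partial_date <- function(pd) {
  out <- rep("", nrow(pd))
  d <- !is.na(pd$precision) & pd$precision == "day"
  m <- !is.na(pd$precision) & pd$precision == "month"
  y <- !is.na(pd$precision) & pd$precision == "year"
  out[d] <- sprintf("%04d%02d%02d", pd$year[d], pd$month[d], pd$day[d])
  out[m] <- sprintf("%04d%02d", pd$year[m], pd$month[m])
  out[y] <- sprintf("%04d", pd$year[y])
  out
}

# Day-precision strings -> Date; everything else NA. Invalid calendar
# combinations (e.g. Feb 30) also return NA via as.Date.
partial_date_to_date <- function(x) {
  pd <- parse_partial_date(x)
  out <- rep(as.Date(NA), length(x))
  d <- !is.na(pd$precision) & pd$precision == "day"
  if (any(d)) {
    out[d] <- as.Date(
      sprintf("%04d-%02d-%02d", pd$year[d], pd$month[d], pd$day[d]),
      format = "%Y-%m-%d"
    )
  }
  out
}
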