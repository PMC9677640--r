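#' Year-month arithmetic
#'
#' Diagnoses in Japanese claims are recorded at month granularity, so the
#' whole phenotyping algorithm runs on a month counter rather than on dates.
#' A year-month is encoded as an integer number of months since January of
#' year 0 (`value = 12 * year + (month - 1)`), which makes window arithmetic
#' plain integer addition and keeps calendar ordering.
#'
#' @param year,month integer vectors; `month` in 1..12.
#' @return `ym()` returns the integer encoding; `ym_year()` / `ym_month()`
#'   decode it.
#' @examples
#' ym(2017, 7)
#' ym_year(ym(2017, 7))   # 2017
#' ym(2018, 1) - ym(2017, 7)  # 6 months apart
#' @export
ym <- function(year, month) {
  if (any(month < 1L | month > 12L)) {
    stop("month must be in 1..12", call. = FALSE)
  }
  as.integer(12L * as.integer(year) + (as.integer(month) - 1L))
}

#' @rdname ym
#' @param x integer year-month values as produced by [ym()].
#' @export
ym_year <- function(x) as.integer(x %/% 12L)

#' @rdname ym
#' @export
ym_month <- function(x) as.integer(x %% 12L) + 1L

#' Parse and format "YYYY-MM" strings
#'
#' @param s character vector of `"YYYY-MM"` strings.
#' @return integer year-month values; `ym_parse()` returns `NA` for strings
#'   that do not parse (callers report the offending rows).
#' @examples
#' ym_format(ym_parse("2017-07") + 6L)  # "2018-01"
#' @export
ym_parse <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{4})-([0-9]{2})$", s))
  out <- rep(NA_integer_, length(s))
  ok <- lengths(m) == 3L
  if (any(ok)) {
    yr <- as.integer(vapply(m[ok], `[`, "", 2L))
    mo <- as.integer(vapply(m[ok], `[`, "", 3L))
    valid <- mo >= 1L & mo <= 12L
    out[which(ok)[valid]] <- 12L * yr[valid] + (mo[valid] - 1L)
  }
  out
}

#' @rdname ym_parse
#' @param x integer year-month values.
#' @export
ym_format <- function(x) {
  sprintf("%04d-%02d", ym_year(x), ym_month(x))
}

#' First day of a year-month as a Date
#'
#' Used to bridge month-granular diagnosis logic and day-granular
#' prescription windows.
#'
#' @param x integer year-month values.
#' @param day day of month (default 1).
#' @export
ym_date <- function(x, day = 1L) {
  as.Date(sprintf("%04d-%02d-%02d", ym_year(x), ym_month(x), day))
}

#' Year-month of a Date
#' @param d a Date vector.
#' @export
date_ym <- function(d) {
  lt <- as.POSIXlt(d)
  ym(lt$year + 1900L, lt$mon + 1L)
}

#' Closed month interval around an anchor
#'
#' All analysis windows (6-month pre-index, 12-month post-index, months
#' 10-12, 3-month evaluation windows) are closed intervals of months offset
#' from an anchor month.
#'
#' @param anchor integer year-month.
#' @param start_offset,end_offset integer month offsets, `start_offset <=
#'   end_offset`.
#' @return integer vector of the months `anchor + start_offset` ..
#'   `anchor + end_offset`, inclusive on both ends.
#' @examples
#' ym_format(month_window(ym(2018, 1), -6, -1))  # 2017-07 .. 2017-12
#' @export
month_window <- function(anchor, start_offset, end_offset) {
  stopifnot(length(anchor) == 1L, start_offset <= end_offset)
  seq.int(anchor + as.integer(start_offset), anchor + as.integer(end_offset))
}
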