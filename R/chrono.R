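# Civil-calendar arithmetic and placement on the quarterly Lexis grid.
#
# All positions are evaluated at the start of a calendar day; days are atomic.
# Dates are base R `Date` (proleptic Gregorian), so every derived quantity is
# exact integer day arithmetic.

WEEKDAY_NAMES <- c("Monday", "Tuesday", "Wednesday", "Thursday",
                   "Friday", "Saturday", "Sunday")
SEASON_NAMES <- c("Winter", "Spring", "Summer", "Autumn")
QUARTER_NAMES <- c("Q1", "Q2", "Q3", "Q4")

#' Parse civil dates
#'
#' Parses dates given either as ISO `YYYY-MM-DD` strings or as the compact
#' `ddmmyyyy` digit strings used in vital-registration microdata. The format
#' is auto-detected per element by pattern; validation is strict, so
#' impossible dates (e.g. `"31022010"`, `"2011-02-29"`) are rejected rather
#' than silently rolled over.
#'
#' @param x character vector of dates (`Date` input is passed through).
#' @return a `Date` vector.
#' @examples
#' parse_civil_date(c("15051980", "1980-05-15"))
#' @export
parse_civil_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- parse_dates_quiet(x)
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("invalid or unparseable date(s): ",
         paste(utils::head(x[bad], 5), collapse = ", "))
  }
  out
}

# Quiet parser: NA for anything that is not a valid date in either format.
# A 7-digit string is treated as ddmmyyyy with its leading zero stripped by
# numeric storage, and re-padded.
parse_dates_quiet <- function(x) {
  x <- as.character(x)
  pad <- !is.na(x) & grepl("^\\d{7}$", x)
  x[pad] <- paste0("0", x[pad])
  out <- rep(as.Date(NA), length(x))
  iso <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ddm <- !is.na(x) & grepl("^\\d{8}$", x)
  if (any(iso)) out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  if (any(ddm)) out[ddm] <- as.Date(x[ddm], format = "%d%m%Y")
  # as.Date() with an explicit format yields NA for impossible dates;
  # additionally reject rolled-over forms by round-tripping.
  if (any(iso)) {
    rt <- format(out[iso], "%Y-%m-%d")
    out[iso][!is.na(out[iso]) & rt != x[iso]] <- NA
  }
  if (any(ddm)) {
    rt <- format(out[ddm], "%d%m%Y")
    out[ddm][!is.na(out[ddm]) & rt != x[ddm]] <- NA
  }
  out
}

#' Format civil dates
#'
#' @param d a `Date` vector.
#' @param format `"iso"` for `YYYY-MM-DD` or `"ddmmyyyy"`.
#' @return character vector.
#' @export
format_civil_date <- function(d, format = c("iso", "ddmmyyyy")) {
  format <- match.arg(format)
  if (format == "iso") format(d, "%Y-%m-%d") else format(d, "%d%m%Y")
}

#' Signed day count between two dates
#'
#' @param a,b `Date` vectors (recycled).
#' @return integer vector of days from `a` to `b`; antisymmetric.
#' @export
days_between <- function(a, b) {
  as.integer(as.integer(b) - as.integer(a))
}

#' Gregorian leap-year test
#'
#' @param y integer year vector.
#' @return logical vector.
#' @export
is_leap_year <- function(y) {
  (y %% 4 == 0 & y %% 100 != 0) | (y %% 400 == 0)
}

#' Length of a calendar year in days
#'
#' @param y integer year vector.
#' @return 366 for leap years, 365 otherwise.
#' @export
year_length <- function(y) {
  365L + as.integer(is_leap_year(y))
}

year_of <- function(d) as.POSIXlt(d)$year + 1900L
month_of <- function(d) as.POSIXlt(d)$mon + 1L
mday_of <- function(d) as.POSIXlt(d)$mday

make_date <- function(y, m, d) {
  as.Date(sprintf("%04d-%02d-%02d", as.integer(y), as.integer(m),
                  as.integer(d)), format = "%Y-%m-%d")
}

#' Birthday anniversary in a target year
#'
#' Returns the calendar date of the birthday in `year`. February 29 births
#' map to February 28 in non-leap years, so the anniversary always stays
#' inside February.
#'
#' @param birth `Date` vector of birth dates.
#' @param year integer vector of target years (recycled).
#' @return `Date` vector.
#' @export
anniversary <- function(birth, year) {
  n <- max(length(birth), length(year))
  birth <- rep_len(birth, n)
  year <- rep_len(as.integer(year), n)
  m <- month_of(birth)
  d <- mday_of(birth)
  feb29 <- m == 2L & d == 29L
  d[feb29 & !is_leap_year(year)] <- 28L
  make_date(year, m, d)
}

#' Calendar quarter (season) of a date
#'
#' Winter = Jan-Mar, Spring = Apr-Jun, Summer = Jul-Sep, Autumn = Oct-Dec.
#'
#' @param d `Date` vector.
#' @return character vector of season names.
#' @export
calendar_quarter <- function(d) {
  SEASON_NAMES[(month_of(d) - 1L) %/% 3L + 1L]
}

#' Weekday of a date
#'
#' Fixed English weekday names, computed from the day number since the epoch
#' (locale-independent).
#'
#' @param d `Date` vector.
#' @return character vector, `"Monday"` ... `"Sunday"`.
#' @export
weekday_of <- function(d) {
  # 1970-01-01 is a Thursday; shift so Monday has index 0.
  WEEKDAY_NAMES[((as.integer(d) + 3L) %% 7L) + 1L]
}

#' Lexis position of a person at the start of a day
#'
#' Places one person-instant on the quarterly Lexis grid: completed integer
#' age, quarter of the current age-year (Q1-Q4), calendar quarter (season),
#' and the exact day offset into the age-year. The age increments on the
#' anniversary day itself (offset 0 belongs to the new age-year), and the
#' age quarter is `floor(4 * offset / D) + 1` where `D` is the length in
#' days of the current age-year (365 or 366).
#'
#' @param birth `Date` vector of birth dates.
#' @param asof `Date` vector of evaluation days (recycled against `birth`).
#' @return a data.frame with columns `integer_age`, `age_quarter`,
#'   `calendar_quarter`, `age_offset_days`, `age_year_days`.
#' @examples
#' lexis_position(as.Date("1980-05-15"), as.Date("2010-02-10"))
#' @export
lexis_position <- function(birth, asof) {
  n <- max(length(birth), length(asof))
  birth <- rep_len(birth, n)
  asof <- rep_len(asof, n)
  if (anyNA(birth) || anyNA(asof)) stop("NA dates in lexis_position()")
  if (any(birth > asof)) stop("birth date after evaluation date")
  ya <- year_of(asof)
  ann <- anniversary(birth, ya)
  before <- ann > asof
  last_bday <- ann
  last_bday[before] <- anniversary(birth[before], ya[before] - 1L)
  next_bday <- anniversary(birth, year_of(last_bday) + 1L)
  offset <- days_between(last_bday, asof)
  D <- days_between(last_bday, next_bday)
  data.frame(
    integer_age = year_of(last_bday) - year_of(birth),
    age_quarter = QUARTER_NAMES[(4L * offset) %/% D + 1L],
    calendar_quarter = calendar_quarter(asof),
    age_offset_days = offset,
    age_year_days = D,
    stringsAsFactors = FALSE
  )
}
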