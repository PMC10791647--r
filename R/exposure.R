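# Exposure engine: partition person-time into (year, sex, integer age,
# age quarter, calendar quarter) cells and count events on the same grid.
#
# Times are carried internally as integer day counts plus the year length,
# and converted to fractional person-years only at serialisation, so all
# conservation identities hold exactly.

LEDGER_KEYS <- c("valuation_year", "gender", "age", "quarter_age",
                 "quarter_calendar")

# Analytic partition of many inclusive day windows [ws, we], each contained
# in a single calendar year. Breakpoints are computed arithmetically:
# calendar-quarter starts, the anniversary, and age-quarter boundary days at
# offsets ceil(q*D/4) of both age-years touching the window. Returns a
# data.table with one row per (window, cell) and exact integer day counts.
partition_windows <- function(birth, ws, we) {
  keep <- !is.na(ws) & !is.na(we) & ws <= we
  idx <- which(keep)
  n <- length(idx)
  empty <- data.table::data.table(
    row = integer(), age = integer(), quarter_age = character(),
    quarter_calendar = character(), days = integer())
  if (n == 0L) return(empty)
  birth <- birth[keep]; ws <- ws[keep]; we <- we[keep]
  if (any(birth > ws)) stop("window starts before birth")
  Y <- year_of(ws)
  if (any(year_of(we) != Y)) stop("window spans more than one calendar year")
  aP <- as.integer(anniversary(birth, Y - 1L))
  aY <- as.integer(anniversary(birth, Y))
  aN <- as.integer(anniversary(birth, Y + 1L))
  DP <- aY - aP
  DN <- aN - aY
  cand <- c(
    as.integer(make_date(Y, 4L, 1L)),
    as.integer(make_date(Y, 7L, 1L)),
    as.integer(make_date(Y, 10L, 1L)),
    aY,
    aP + (1L * DP + 3L) %/% 4L,
    aP + (2L * DP + 3L) %/% 4L,
    aP + (3L * DP + 3L) %/% 4L,
    aY + (1L * DN + 3L) %/% 4L,
    aY + (2L * DN + 3L) %/% 4L,
    aY + (3L * DN + 3L) %/% 4L
  )
  id <- rep.int(seq_len(n), 10L)
  wsi <- as.integer(ws)
  wei <- as.integer(we)
  ok <- cand > wsi[id] & cand <= wei[id]
  dt <- data.table::data.table(
    id = c(seq_len(n), id[ok]),
    bp = c(wsi, cand[ok]))
  dt <- unique(dt)
  data.table::setorderv(dt, c("id", "bp"))
  id <- NULL; bp <- NULL; days <- NULL # appease R CMD check
  dt[, days := c(bp[-1L], wei[id[1L]] + 1L) - bp, by = id]
  pos <- lexis_position(birth[dt$id],
                        as.Date(dt$bp, origin = "1970-01-01"))
  out <- data.table::data.table(
    row = idx[dt$id],
    age = pos$integer_age,
    quarter_age = pos$age_quarter,
    quarter_calendar = pos$calendar_quarter,
    days = dt$days)
  out
}

#' Partition one person-year window into Lexis cells
#'
#' Splits an inclusive day range `[window_start, window_end]` (contained in
#' calendar year `year`) into segments of constant (integer age, age
#' quarter, calendar quarter), evaluated day by day but computed
#' analytically from the breakpoint dates. The returned day counts sum to
#' the number of days in the window.
#'
#' @param birth date of birth (`Date` or parseable character).
#' @param year calendar year containing the window.
#' @param window_start,window_end inclusive window bounds; an empty or
#'   inverted window yields a zero-row result.
#' @return a data.frame with columns `age`, `quarter_age`,
#'   `quarter_calendar`, `days`.
#' @examples
#' partition_person_year("1970-01-01", 2010, "2010-01-01", "2010-12-31")
#' @export
partition_person_year <- function(birth, year, window_start, window_end) {
  birth <- parse_civil_date(birth)
  ws <- parse_civil_date(window_start)
  we <- parse_civil_date(window_end)
  stopifnot(length(birth) == 1L, length(ws) == 1L, length(we) == 1L)
  if (ws <= we) {
    if (year_of(ws) != year || year_of(we) != year) {
      stop("window must lie within calendar year ", year)
    }
    if (ws < birth) stop("window starts before birth")
  }
  dt <- partition_windows(birth, ws, we)
  agg <- dt[, list(days = sum(days)),
            by = c("age", "quarter_age", "quarter_calendar")]
  data.table::setorderv(agg, c("age", "quarter_age", "quarter_calendar"))
  data.table::setDF(agg)
  agg
}

# Aggregate exposed/not-exposed day partitions into an exposure ledger.
new_ledger <- function(exp_part, nexp_part, rec_year, rec_gender) {
  days <- NULL
  tab <- function(part) {
    if (nrow(part) == 0L) {
      return(data.table::data.table(
        valuation_year = integer(), gender = character(), age = integer(),
        quarter_age = character(), quarter_calendar = character(),
        v = integer()))
    }
    part$valuation_year <- rec_year[part$row]
    part$gender <- rec_gender[part$row]
    out <- part[, list(v = sum(days)), by = LEDGER_KEYS]
    out
  }
  e <- tab(exp_part)
  ne <- tab(nexp_part)
  data.table::setnames(e, "v", "days_exposed")
  data.table::setnames(ne, "v", "days_not_exposed")
  led <- merge(e, ne, by = LEDGER_KEYS, all = TRUE)
  for (col in c("days_exposed", "days_not_exposed")) {
    data.table::set(led, which(is.na(led[[col]])), col, 0L)
  }
  led$year_length <- year_length(led$valuation_year)
  data.table::setorderv(led, LEDGER_KEYS)
  data.table::setDF(led)
  class(led) <- c("exposure_ledger", "data.frame")
  led
}

#' @export
print.exposure_ledger <- function(x, ...) {
  yrs <- year_length(x$valuation_year)
  cat("Exposure ledger:", nrow(x), "cells;",
      "time exposed =", sum(x$days_exposed / yrs),
      "py; time not exposed =", sum(x$days_not_exposed / yrs), "py\n")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Serialise an exposure ledger to fractional person-years
#'
#' Converts the internal integer day counts to the long-format table used in
#' the output files, with `time_exposed` and `time_not_exposed` as fractions
#' of the valuation year.
#'
#' @param ledger an `exposure_ledger`.
#' @return a data.frame with the ledger keys plus `time_exposed` and
#'   `time_not_exposed`.
#' @export
ledger_table <- function(ledger) {
  stopifnot(inherits(ledger, "exposure_ledger"))
  led <- ledger
  class(led) <- "data.frame"
  out <- led[LEDGER_KEYS]
  out$time_exposed <- led$days_exposed / led$year_length
  out$time_not_exposed <- led$days_not_exposed / led$year_length
  out
}

#' @export
as.data.frame.exposure_ledger <- function(x, ...) {
  ledger_table(x)
}

check_event_type <- function(records, allowed) {
  if (!all(records$event_type %in% allowed)) {
    stop("records must have event_type in {",
         paste(allowed, collapse = ", "), "}")
  }
}

#' Expected exposure of the January-1 population stock
#'
#' Each resident present on January 1 of `year` is assumed to survive the
#' whole year, contributing exactly 1.0 person-years of exposure distributed
#' over the Lexis cells crossed by their life-line; non-exposure is zero.
#'
#' @param records stock event records (see [event_records()]).
#' @param year the valuation year (stock referenced on January 1).
#' @return an `exposure_ledger`.
#' @export
time_exposed_stock <- function(records, year) {
  check_event_type(records, "stock")
  year <- as.integer(year)
  jan1 <- make_date(year, 1L, 1L)
  late <- which(records$birth_date > jan1)
  if (length(late)) {
    stop("stock rows born after January 1 of ", year, ": rows ",
         paste(utils::head(late, 5), collapse = ", "))
  }
  n <- nrow(records)
  expp <- partition_windows(records$birth_date,
                            rep(jan1, n),
                            rep(make_date(year, 12L, 31L), n))
  new_ledger(expp, expp[0L],
             rep(year, n), sex_to_gender(records$sex))
}

#' Exposure and non-exposure of exits (deaths, emigrants)
#'
#' A person leaving the population during the year of their event is exposed
#' from the later of January 1 and their birth up to (but excluding) the
#' event day, and not exposed from the event day through December 31. For a
#' person born before the event year, exposed + not-exposed time is exactly
#' 1.0 person-years.
#'
#' @param records death or emigration event records.
#' @return an `exposure_ledger`.
#' @export
time_exposed_exit <- function(records) {
  check_event_type(records, c("death", "emigration"))
  Y <- year_of(records$event_date)
  jan1 <- make_date(Y, 1L, 1L)
  dec31 <- make_date(Y, 12L, 31L)
  presence <- pmax(jan1, records$birth_date)
  expp <- partition_windows(records$birth_date, presence,
                            records$event_date - 1L)
  nexp <- partition_windows(records$birth_date, records$event_date, dec31)
  new_ledger(expp, nexp, Y, sex_to_gender(records$sex))
}

#' Exposure and non-exposure of entries (immigrants)
#'
#' An immigrant is exposed from the entry day (inclusive) through December
#' 31 and not exposed from the later of January 1 and birth up to the entry
#' day; the same exact complement contract as exits.
#'
#' @param records immigration event records.
#' @return an `exposure_ledger`.
#' @export
time_exposed_entry <- function(records) {
  check_event_type(records, "immigration")
  Y <- year_of(records$event_date)
  jan1 <- make_date(Y, 1L, 1L)
  dec31 <- make_date(Y, 12L, 31L)
  presence <- pmax(jan1, records$birth_date)
  expp <- partition_windows(records$birth_date, records$event_date, dec31)
  nexp <- partition_windows(records$birth_date, presence,
                            records$event_date - 1L)
  new_ledger(expp, nexp, Y, sex_to_gender(records$sex))
}

#' Exposure of newborns
#'
#' A child born during the year is exposed from the birth day through
#' December 31, all at integer age 0, with the age quarter advancing at
#' offsets `ceil(q*D/4)` from birth.
#'
#' @param records birth event records (`event_date == birth_date`).
#' @return an `exposure_ledger`.
#' @export
time_exposed_newborn <- function(records) {
  check_event_type(records, "birth")
  Y <- year_of(records$birth_date)
  expp <- partition_windows(records$birth_date, records$birth_date,
                            make_date(Y, 12L, 31L))
  new_ledger(expp, expp[0L], Y, sex_to_gender(records$sex))
}

#' Count events by Lexis quarter
#'
#' Tabulates events on the quarterly Lexis grid: each record adds one to the
#' cell given by its position (integer age, age quarter, calendar quarter)
#' at the event date, by sex and event year.
#'
#' @param records event records sharing one event_type among death,
#'   emigration, immigration.
#' @return a data.frame with the ledger keys plus `number_events`.
#' @export
count_events_by_quarter <- function(records) {
  check_event_type(records, c("death", "emigration", "immigration"))
  if (length(unique(records$event_type)) > 1L) {
    stop("records mix several event types")
  }
  keys <- c(LEDGER_KEYS, "number_events")
  if (nrow(records) == 0L) {
    out <- data.frame(valuation_year = integer(), gender = character(),
                      age = integer(), quarter_age = character(),
                      quarter_calendar = character(),
                      number_events = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  pos <- lexis_position(records$birth_date, records$event_date)
  dt <- data.table::data.table(
    valuation_year = year_of(records$event_date),
    gender = sex_to_gender(records$sex),
    age = pos$integer_age,
    quarter_age = pos$age_quarter,
    quarter_calendar = pos$calendar_quarter)
  out <- dt[, list(number_events = .N), by = LEDGER_KEYS]
  data.table::setorderv(out, LEDGER_KEYS)
  data.table::setDF(out)
  out
}

#' Total exposure-to-risk per Lexis cell
#'
#' Combines the five exposure ledgers of a valuation year into the total
#' time exposed to risk per cell: stock, immigrant and newborn exposure,
#' minus the non-exposure of deaths and emigrants. Cells absent from a
#' ledger contribute zero.
#'
#' @param P4 stock ledger ([time_exposed_stock()]).
#' @param I4 immigration ledger ([time_exposed_entry()]).
#' @param B4 newborn ledger ([time_exposed_newborn()]).
#' @param D4 death ledger ([time_exposed_exit()]).
#' @param E4 emigration ledger ([time_exposed_exit()]).
#' @return a data.frame with the ledger keys plus `time_exposed`
#'   (person-years; exact multiple of 1/year length).
#' @export
combine_total_exposure <- function(P4, I4, B4, D4, E4) {
  grab <- function(led, col, nm) {
    dt <- data.table::as.data.table(unclass(led)[c(LEDGER_KEYS, col)])
    data.table::setnames(dt, col, nm)
    dt
  }
  pieces <- list(grab(P4, "days_exposed", "p"),
                 grab(I4, "days_exposed", "i"),
                 grab(B4, "days_exposed", "b"),
                 grab(D4, "days_not_exposed", "d"),
                 grab(E4, "days_not_exposed", "e"))
  out <- Reduce(function(a, b) merge(a, b, by = LEDGER_KEYS, all = TRUE),
                pieces)
  for (col in c("p", "i", "b", "d", "e")) {
    data.table::set(out, which(is.na(out[[col]])), col, 0L)
  }
  days <- out$p + out$i + out$b - out$d - out$e
  res <- data.frame(out[, LEDGER_KEYS, with = FALSE],
                    time_exposed = days / year_length(out$valuation_year),
                    stringsAsFactors = FALSE)
  res <- res[order(res$valuation_year, res$gender, res$age,
                   res$quarter_age, res$quarter_calendar), ]
  rownames(res) <- NULL
  res
}
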