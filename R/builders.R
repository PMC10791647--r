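# Builders for the fifteen sub-annual summary tables: monthly and daily
# birth-date summaries of population stocks (P_1, P_2, P_4, P_6), quarterly
# event counts and exposure times (D/E/I_3, D/E/I/B_4), daily moving
# averages of migration flows (E_5, I_5) and weekday tabulations (B_6, P_6),
# plus the January-1 date-heaping correction.

AGE_BAND_DEFAULT <- list(c(0, 16), c(16, 65), c(65, Inf))

band_labels <- function(bands) {
  vapply(bands, function(b) {
    if (is.infinite(b[2])) sprintf("[%g,Inf)", b[1])
    else sprintf("[%g,%g)", b[1], b[2])
  }, character(1))
}

# Zero-filled daily count series over an inclusive support.
tabulate_days <- function(dates, support_start, support_end) {
  if (support_start > support_end) {
    return(data.frame(date = as.Date(integer(0), origin = "1970-01-01"),
                      count = integer(0)))
  }
  all_days <- seq(support_start, support_end, by = "day")
  cnt <- tabulate(as.integer(dates) - as.integer(support_start) + 1L,
                  nbins = length(all_days))
  data.frame(date = all_days, count = cnt)
}

#' Daily counts of persons by date of birth
#'
#' Tabulates a population stock into a contiguous daily series: the number
#' of persons born on each calendar day between the earliest and latest
#' birth date present (absent days are zero). This is the intermediate
#' "daily birth-date population" series feeding the moving-average tables.
#'
#' @param stock stock event records.
#' @param by_sex if `TRUE`, one series per sex (with its own support) and a
#'   `gender` column.
#' @return a data.frame with columns `date`, `count` (plus `gender` when
#'   `by_sex = TRUE`); counts sum to the stock size.
#' @export
tabulate_birthdates <- function(stock, by_sex = FALSE) {
  check_event_type(stock, "stock")
  if (by_sex) {
    parts <- lapply(split(stock, sex_to_gender(stock$sex)), function(s) {
      ser <- tabulate_birthdates(s, by_sex = FALSE)
      if (nrow(ser)) cbind(gender = sex_to_gender(s$sex[1]), ser) else
        cbind(gender = character(0), ser)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  if (nrow(stock) == 0L) return(tabulate_days(as.Date(integer(0),
                                                      origin = "1970-01-01"),
                                              as.Date("2000-01-02"),
                                              as.Date("2000-01-01")))
  tabulate_days(stock$birth_date, min(stock$birth_date),
                max(stock$birth_date))
}

#' Centred moving average of a daily series
#'
#' Computes `MA_t(k) = (1/(2k+1)) * sum_{j=0..2k} P_{t-k+j}`, the mean of
#' the `2k+1` days centred on day `t`. Values are emitted only for days with
#' a full window inside the series support; edges are omitted, never padded.
#'
#' @param series a data.frame whose first column is a contiguous `date` and
#'   whose second column is the daily value.
#' @param k non-negative integer window half-width.
#' @return a data.frame with columns `date`, `ma_value`.
#' @examples
#' s <- data.frame(date = as.Date("2010-01-01") + 0:6, count = 1:7)
#' moving_average(s, 3)
#' @export
moving_average <- function(series, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != round(k)) {
    stop("k must be a non-negative integer")
  }
  k <- as.integer(k)
  d <- series[[1]]
  x <- as.numeric(series[[2]])
  if (length(d) > 1L && any(diff(as.integer(d)) != 1L)) {
    stop("series support must be contiguous daily dates")
  }
  w <- 2L * k + 1L
  if (length(x) < w) {
    return(data.frame(date = as.Date(integer(0), origin = "1970-01-01"),
                      ma_value = numeric(0)))
  }
  ma <- stats::filter(x, rep(1 / w, w), sides = 2)
  keep <- !is.na(ma)
  data.frame(date = d[keep], ma_value = as.numeric(ma)[keep])
}

#' Number of people by sex, year and month of birth (P_1)
#'
#' @param stock stock event records referenced at `valuation_date`.
#' @param valuation_date the stock reference date (January 1).
#' @return a data.frame with columns `valuation_date`, `gender`,
#'   `birth_year`, `birth_month`, `number_of_persons`.
#' @export
build_P1 <- function(stock, valuation_date) {
  check_event_type(stock, "stock")
  valuation_date <- parse_civil_date(valuation_date)
  if (nrow(stock) == 0L) {
    return(data.frame(valuation_date = as.Date(integer(0),
                                               origin = "1970-01-01"),
                      gender = character(0), birth_year = integer(0),
                      birth_month = integer(0),
                      number_of_persons = integer(0)))
  }
  dt <- data.table::data.table(
    gender = sex_to_gender(stock$sex),
    birth_year = year_of(stock$birth_date),
    birth_month = month_of(stock$birth_date))
  out <- dt[, list(number_of_persons = .N),
            by = c("gender", "birth_year", "birth_month")]
  data.table::setorderv(out, c("gender", "birth_year", "birth_month"))
  data.table::setDF(out)
  out$valuation_date <- rep(valuation_date, nrow(out))
  out[c("valuation_date", "gender", "birth_year", "birth_month",
        "number_of_persons")]
}

#' Moving-average daily birth-date series with confidentiality horizon (P_2)
#'
#' Smooths the per-sex daily birth-date counts of a stock with a centred
#' moving average (`k = 3` by default) and then suppresses all rows for
#' birth dates more than `horizon_years` before the valuation date, so very
#' old, sparsely populated dates are never published. Suppression is applied
#' after averaging.
#'
#' @param stock stock event records.
#' @param valuation_date the stock reference date.
#' @param k moving-average half-width.
#' @param horizon_years suppression horizon in years (default 100).
#' @return a data.frame with columns `valuation_date`, `gender`,
#'   `birth_date`, `ma_value`.
#' @export
build_P2 <- function(stock, valuation_date, k = 3, horizon_years = 100) {
  check_event_type(stock, "stock")
  valuation_date <- parse_civil_date(valuation_date)
  horizon <- anniversary(valuation_date,
                         year_of(valuation_date) - horizon_years)
  parts <- lapply(c("male", "female"), function(sx) {
    sub <- stock[stock$sex == sx, , drop = FALSE]
    ser <- tabulate_birthdates(sub)
    ma <- moving_average(ser, k)
    ma <- ma[ma$date >= horizon, , drop = FALSE]
    if (nrow(ma) == 0L) {
      return(data.frame(valuation_date = as.Date(integer(0),
                                                 origin = "1970-01-01"),
                        gender = character(0),
                        birth_date = as.Date(integer(0),
                                             origin = "1970-01-01"),
                        ma_value = numeric(0)))
    }
    data.frame(valuation_date = valuation_date,
               gender = sex_to_gender(sx),
               birth_date = ma$date, ma_value = ma$ma_value)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

weekday_table <- function(year, gender, wd, count_name) {
  dt <- data.table::data.table(valuation_year = year, gender = gender,
                               weekday = wd)
  out <- dt[, list(n = .N), by = c("valuation_year", "gender", "weekday")]
  data.table::setnames(out, "n", count_name)
  out$weekday_order <- match(out$weekday, WEEKDAY_NAMES)
  data.table::setorderv(out, c("valuation_year", "gender", "weekday_order"))
  out$weekday_order <- NULL
  data.table::setDF(out)
  out
}

#' Weekday distribution of birthdays in a population stock (P_6)
#'
#' @param stock stock event records.
#' @param valuation_date the stock reference date.
#' @return a data.frame with columns `valuation_year`, `gender`, `weekday`,
#'   `number_of_birthdays`.
#' @export
build_P6 <- function(stock, valuation_date) {
  check_event_type(stock, "stock")
  valuation_date <- parse_civil_date(valuation_date)
  weekday_table(year_of(valuation_date)[rep(1L, nrow(stock))],
                sex_to_gender(stock$sex),
                weekday_of(stock$birth_date),
                "number_of_birthdays")
}

#' Weekday distribution of registered births (B_6)
#'
#' @param births birth event records.
#' @return a data.frame with columns `valuation_year`, `gender`, `weekday`,
#'   `number_of_births`.
#' @export
build_B6 <- function(births) {
  check_event_type(births, "birth")
  weekday_table(year_of(births$event_date),
                sex_to_gender(births$sex),
                weekday_of(births$event_date),
                "number_of_births")
}

#' Daily moving-average migration series by age band (E_5 / I_5)
#'
#' Counts migration events per day within broad age bands (age at the event
#' date; the standard partition is \[0,16), \[16,65), \[65,Inf)), smooths
#' each band's daily series with a centred moving average over the full
#' multi-year support (January 1 of the first event year through December 31
#' of the last), and emits the series per sex and for both sexes combined
#' (`gender = "all"`).
#'
#' @param migrations event records of a single direction (all emigration or
#'   all immigration).
#' @param k moving-average half-width.
#' @param bands list of `c(lower, upper)` age bands, lower inclusive, upper
#'   exclusive.
#' @return a data.frame with columns `date`, `age_group`, `gender`,
#'   `ma_value`.
#' @export
build_flow_daily <- function(migrations, k = 3, bands = AGE_BAND_DEFAULT) {
  check_event_type(migrations, c("emigration", "immigration"))
  if (length(unique(migrations$event_type)) > 1L) {
    stop("migrations mix both directions")
  }
  labs <- band_labels(bands)
  empty <- data.frame(date = as.Date(integer(0), origin = "1970-01-01"),
                      age_group = character(0), gender = character(0),
                      ma_value = numeric(0))
  if (nrow(migrations) == 0L) return(empty)
  pos <- lexis_position(migrations$birth_date, migrations$event_date)
  lower <- vapply(bands, `[`, numeric(1), 1)
  idx <- findInterval(pos$integer_age, lower)
  uppers <- vapply(bands, `[`, numeric(1), 2)
  bad <- idx == 0L | pos$integer_age >= uppers[pmax(idx, 1L)]
  if (any(bad)) {
    stop("age(s) outside the configured bands: ",
         paste(utils::head(unique(pos$integer_age[bad]), 5), collapse = ", "))
  }
  yrs <- year_of(migrations$event_date)
  sstart <- make_date(min(yrs), 1L, 1L)
  send <- make_date(max(yrs), 12L, 31L)
  gender <- sex_to_gender(migrations$sex)
  parts <- list()
  for (bi in seq_along(bands)) {
    for (g in c("men", "women", "all")) {
      sel <- idx == bi & (g == "all" | gender == g)
      ser <- tabulate_days(migrations$event_date[sel], sstart, send)
      ma <- moving_average(ser, k)
      if (nrow(ma)) {
        parts[[length(parts) + 1L]] <-
          data.frame(date = ma$date, age_group = labs[bi], gender = g,
                     ma_value = ma$ma_value)
      }
    }
  }
  if (length(parts) == 0L) return(empty)
  out <- do.call(rbind, parts)
  out <- out[order(out$age_group, out$gender, out$date), ]
  rownames(out) <- NULL
  out
}

#' Redistribute the January-1 birth-date heap
#'
#' Registers often assign January 1 as the birth date of migrants whose
#' exact birthday is unknown, producing an artificial spike. For each birth
#' year this estimates the genuine January-1 count as the rounded mean daily
#' count over the rest of that year, and re-dates the excess January-1
#' records to uniform random days of the same year (January 1 excluded).
#' Record count and birth-year marginals are conserved; the result is
#' deterministic under `seed`.
#'
#' @param records event records with birth dates.
#' @param seed integer seed for the random redistribution.
#' @return event records with de-heaped birth dates (birth events keep
#'   `event_date == birth_date`).
#' @export
deheap_jan1 <- function(records, seed) {
  set.seed(as.integer(seed))
  out <- records
  if (nrow(records) == 0L) return(out)
  by <- year_of(records$birth_date)
  is_jan1 <- month_of(records$birth_date) == 1L &
    mday_of(records$birth_date) == 1L
  for (y in sort(unique(by[is_jan1]))) {
    rows_y <- which(by == y)
    j <- rows_y[is_jan1[rows_y]]
    baseline <- round((length(rows_y) - length(j)) / (year_length(y) - 1L))
    excess <- max(0L, length(j) - baseline)
    if (excess > 0L) {
      pick <- j[sample.int(length(j), excess)]
      offs <- sample.int(year_length(y) - 1L, excess, replace = TRUE)
      out$birth_date[pick] <- make_date(y, 1L, 1L) + offs
    }
  }
  sync <- out$event_type == "birth"
  out$event_date[sync] <- out$birth_date[sync]
  out
}

#' Build the full set of fifteen sub-annual summary tables
#'
#' Runs the whole pipeline: monthly/daily/weekday stock summaries (P_1,
#' P_2 men and women, P_4, P_6), quarterly event counts (D_3, E_3, I_3),
#' quarterly exposure/non-exposure times (D_4, E_4, I_4, B_4), weekday
#' births (B_6) and daily moving-average migration series (E_5, I_5).
#'
#' @param stock stock event records with an extra integer `valuation_year`
#'   column (one stock per January 1).
#' @param deaths death event records.
#' @param births birth event records.
#' @param migrations emigration and immigration event records (mixed).
#' @param k moving-average half-width for P_2, E_5 and I_5.
#' @param horizon_years confidentiality horizon for P_2.
#' @return a named list of 15 data.frames: `P_1`, `P_2_men`, `P_2_women`,
#'   `P_4`, `P_6`, `D_3`, `D_4`, `E_3`, `E_4`, `I_3`, `I_4`, `B_4`, `B_6`,
#'   `E_5`, `I_5`.
#' @export
build_all <- function(stock, deaths, births, migrations, k = 3,
                      horizon_years = 100) {
  if (is.null(stock)) {
    stop("missing stock input: required for P_1, P_2, P_4 and P_6")
  }
  if (is.null(deaths)) stop("missing deaths input: required for D_3 and D_4")
  if (is.null(births)) stop("missing births input: required for B_4 and B_6")
  if (is.null(migrations)) {
    stop("missing migrations input: required for E_3, E_4, E_5, I_3, I_4, I_5")
  }
  if (!"valuation_year" %in% names(stock)) {
    stop("stock must carry a valuation_year column")
  }
  years <- sort(unique(stock$valuation_year))
  per_year <- function(f) {
    if (length(years) == 0L) {
      # schema-valid empty table from an empty stock at a dummy date
      return(f(stock[0L, , drop = FALSE], make_date(2000L, 1L, 1L), 2000L))
    }
    parts <- lapply(years, function(y) {
      f(stock[stock$valuation_year == y, , drop = FALSE],
        make_date(y, 1L, 1L), y)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  }
  P1 <- per_year(function(s, v, y) build_P1(s, v))
  P2 <- per_year(function(s, v, y) build_P2(s, v, k, horizon_years))
  P4 <- per_year(function(s, v, y) ledger_table(time_exposed_stock(s, y)))
  P6 <- per_year(function(s, v, y) build_P6(s, v))
  emig <- migrations[migrations$event_type == "emigration", , drop = FALSE]
  immi <- migrations[migrations$event_type == "immigration", , drop = FALSE]
  list(
    P_1 = P1,
    P_2_men = P2[P2$gender == "men", , drop = FALSE],
    P_2_women = P2[P2$gender == "women", , drop = FALSE],
    P_4 = P4,
    P_6 = P6,
    D_3 = count_events_by_quarter(deaths),
    D_4 = ledger_table(time_exposed_exit(deaths)),
    E_3 = count_events_by_quarter(emig),
    E_4 = ledger_table(time_exposed_exit(emig)),
    I_3 = count_events_by_quarter(immi),
    I_4 = ledger_table(time_exposed_entry(immi)),
    B_4 = ledger_table(time_exposed_newborn(births)),
    B_6 = build_B6(births),
    E_5 = build_flow_daily(emig, k),
    I_5 = build_flow_daily(immi, k)
  )
}
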