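# Synthetic vital-registration generator. Produces multi-year microdata
# (stocks, deaths, births, migrations) with known ground-truth structure --
# birth-month seasonality, weekend birth deficit, Gompertz mortality with a
# winter excess, a September migration peak and January-1 birth-date
# heaping -- so every pipeline stage can be validated without confidential
# registry data. The closed-population accounting identity
# stock(Y+1) = stock(Y) + births + in - deaths - out holds exactly by
# construction, per year and sex.

MONTH_DAYS_COMMON <- c(31L, 28L, 31L, 30L, 31L, 30L,
                       31L, 31L, 30L, 31L, 30L, 31L)
AGE_CAP <- 105L

#' Configuration of the synthetic registry generator
#'
#' All structural parameters of the generator, with defaults describing a
#' small but realistic national registry. Every random draw is fixed by
#' `seed`.
#'
#' @param n_stock initial population size on January 1 of the first year.
#' @param year_range inclusive integer interval of simulated event years.
#' @param sex_ratio_male probability a person is male.
#' @param birth_month_weights 12 non-negative relative weights for the month
#'   of birth.
#' @param weekend_birth_factor multiplier (<= 1) applied to Saturday/Sunday
#'   birth dates; 1 means no weekend deficit.
#' @param gompertz_a,gompertz_b Gompertz mortality parameters: the annual
#'   death probability at integer age x is `min(1, a * exp(b * x))`.
#' @param season_death_weights 4 non-negative weights (Winter, Spring,
#'   Summer, Autumn) multiplying the daily death intensity.
#' @param migration_rate_in,migration_rate_out per-capita annual
#'   immigration/emigration probabilities.
#' @param september_peak_factor multiplier on the migration intensity of
#'   September days.
#' @param jan1_heaping_rate probability an immigrant's birth date is
#'   overwritten to January 1 of the same birth year.
#' @param fertility_rate per-capita annual birth rate (expected births per
#'   person-year of stock).
#' @param seed integer random seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_stock = 10000L,
                         year_range = c(2010L, 2014L),
                         sex_ratio_male = 0.49,
                         birth_month_weights = c(1.02, 0.96, 1.00, 1.00,
                                                 1.02, 1.00, 1.04, 1.04,
                                                 1.06, 1.02, 0.97, 0.97),
                         weekend_birth_factor = 0.85,
                         gompertz_a = 1e-4,
                         gompertz_b = 0.09,
                         season_death_weights = c(1.30, 0.95, 0.85, 0.90),
                         migration_rate_in = 0.02,
                         migration_rate_out = 0.015,
                         september_peak_factor = 1.5,
                         jan1_heaping_rate = 0.05,
                         fertility_rate = 0.009,
                         seed = 2021L) {
  cfg <- list(n_stock = as.integer(n_stock),
              year_range = as.integer(year_range),
              sex_ratio_male = sex_ratio_male,
              birth_month_weights = as.numeric(birth_month_weights),
              weekend_birth_factor = weekend_birth_factor,
              gompertz_a = gompertz_a, gompertz_b = gompertz_b,
              season_death_weights = as.numeric(season_death_weights),
              migration_rate_in = migration_rate_in,
              migration_rate_out = migration_rate_out,
              september_peak_factor = september_peak_factor,
              jan1_heaping_rate = jan1_heaping_rate,
              fertility_rate = fertility_rate,
              seed = as.integer(seed))
  bad <- character(0)
  if (is.na(cfg$n_stock) || cfg$n_stock < 0L) bad <- c(bad, "n_stock")
  if (length(cfg$year_range) != 2L || anyNA(cfg$year_range) ||
      cfg$year_range[1] > cfg$year_range[2]) bad <- c(bad, "year_range")
  for (p in c("sex_ratio_male", "migration_rate_in", "migration_rate_out",
              "jan1_heaping_rate")) {
    v <- cfg[[p]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) bad <- c(bad, p)
  }
  if (length(cfg$birth_month_weights) != 12L ||
      any(cfg$birth_month_weights < 0)) bad <- c(bad, "birth_month_weights")
  if (length(cfg$season_death_weights) != 4L ||
      any(cfg$season_death_weights < 0)) bad <- c(bad, "season_death_weights")
  if (cfg$weekend_birth_factor < 0 || cfg$weekend_birth_factor > 1) {
    bad <- c(bad, "weekend_birth_factor")
  }
  if (cfg$gompertz_a < 0) bad <- c(bad, "gompertz_a")
  if (cfg$fertility_rate < 0 || cfg$fertility_rate > 1) {
    bad <- c(bad, "fertility_rate")
  }
  if (cfg$september_peak_factor < 0) bad <- c(bad, "september_peak_factor")
  if (is.na(cfg$seed)) bad <- c(bad, "seed")
  if (length(bad)) {
    stop("invalid synth_config field(s): ", paste(bad, collapse = ", "))
  }
  class(cfg) <- "synth_config"
  cfg
}

gompertz_q <- function(age, cfg) {
  q <- pmin(1, cfg$gompertz_a * exp(cfg$gompertz_b * age))
  q[age >= AGE_CAP] <- 1
  q
}

# Draw (month, day) pairs by month weight then uniform within the month
# (common-year month lengths; the generator never produces Feb 29 births),
# thinned on weekends by rejection given the birth year of each draw.
draw_birth_md <- function(n, year_for, cfg) {
  m <- integer(n); d <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    mm <- sample.int(12L, length(todo), replace = TRUE,
                     prob = cfg$birth_month_weights)
    dd <- 1L + as.integer(floor(stats::runif(length(todo)) *
                                  MONTH_DAYS_COMMON[mm]))
    m[todo] <- mm; d[todo] <- dd
    wd <- weekday_of(make_date(year_for(todo, mm, dd), mm, dd))
    wkend <- wd %in% c("Saturday", "Sunday")
    reject <- wkend & stats::runif(length(todo)) > cfg$weekend_birth_factor
    todo <- todo[reject]
  }
  list(month = m, day = d)
}

# Event days of one calendar year, drawn with per-day weights.
draw_days <- function(n, year, day_weights) {
  days <- seq(make_date(year, 1L, 1L), make_date(year, 12L, 31L), by = "day")
  days[sample.int(length(days), n, replace = TRUE, prob = day_weights)]
}

september_day_weights <- function(year, factor) {
  days <- seq(make_date(year, 1L, 1L), make_date(year, 12L, 31L), by = "day")
  ifelse(month_of(days) == 9L, factor, 1)
}

season_day_weights <- function(year, weights) {
  days <- seq(make_date(year, 1L, 1L), make_date(year, 12L, 31L), by = "day")
  weights[(month_of(days) - 1L) %/% 3L + 1L]
}

# Stationary-population age weights implied by the Gompertz schedule.
stock_age_weights <- function(cfg) {
  q <- gompertz_q(0:(AGE_CAP - 1L), cfg)
  cumprod(c(1, 1 - q))[seq_len(AGE_CAP)]
}

# Birth year such that completed age at Jan 1 of `ref_year` equals `age`:
# a Jan-1 birthday reaches the new age on Jan 1 itself.
birth_year_for_age <- function(age, ref_year, month, day) {
  ifelse(month == 1L & day == 1L, ref_year - age, ref_year - age - 1L)
}

draw_persons <- function(n, ref_year, ages, cfg) {
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio_male, "male", "female")
  md <- draw_birth_md(n, function(idx, m, d) {
    birth_year_for_age(ages[idx], ref_year, m, d)
  }, cfg)
  by <- birth_year_for_age(ages, ref_year, md$month, md$day)
  data.frame(birth_date = make_date(by, md$month, md$day), sex = sex,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-year vital registry
#'
#' Simulates a closed population year by year over `year_range`: each
#' January-1 resident may emigrate (day drawn uniformly with the September
#' intensity scaled), otherwise die with Gompertz probability
#' `min(1, a*exp(b*age))` (day drawn with seasonal weights), while
#' immigrants (Poisson, per-capita rate; birth dates possibly heaped to
#' January 1) and newborns (Poisson, per-capita rate; month-weighted and
#' weekend-thinned birth dates) enter the next stock. Everything is
#' deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @return a `synthetic_registry`: list with `stock` (event records plus a
#'   `valuation_year` column, one snapshot per January 1 from the first year
#'   through the year after the last), `deaths`, `births`, `immigrations`,
#'   `emigrations` event-record data.frames, and the `config` as attribute.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  y0 <- config$year_range[1]; y1 <- config$year_range[2]
  agew <- stock_age_weights(config)
  ages0 <- sample.int(AGE_CAP, config$n_stock, replace = TRUE,
                      prob = agew) - 1L
  pop <- draw_persons(config$n_stock, y0, ages0, config)
  stocks <- list(); deaths <- list(); births <- list()
  immis <- list(); emis <- list()
  snapshot <- function(pop, y) {
    if (nrow(pop) == 0L) {
      return(data.frame(valuation_year = integer(0),
                        birth_date = as.Date(integer(0),
                                             origin = "1970-01-01"),
                        sex = character(0), event_type = character(0),
                        event_date = as.Date(integer(0),
                                             origin = "1970-01-01"),
                        stringsAsFactors = FALSE))
    }
    data.frame(valuation_year = y, birth_date = pop$birth_date,
               sex = pop$sex, event_type = "stock",
               event_date = as.Date(NA), stringsAsFactors = FALSE)
  }
  for (y in y0:y1) {
    stocks[[as.character(y)]] <- snapshot(pop, y)
    n <- nrow(pop)
    age <- if (n) lexis_position(pop$birth_date,
                                 rep(make_date(y, 1L, 1L), n))$integer_age
           else integer(0)
    # migration first; death only among those who stay
    out_flag <- stats::runif(n) < config$migration_rate_out
    sepw <- september_day_weights(y, config$september_peak_factor)
    if (any(out_flag)) {
      em <- pop[out_flag, , drop = FALSE]
      emis[[as.character(y)]] <- event_records(
        em$birth_date, em$sex, "emigration",
        draw_days(nrow(em), y, sepw))
    }
    stay <- pop[!out_flag, , drop = FALSE]
    stay_age <- age[!out_flag]
    die_flag <- stats::runif(nrow(stay)) < gompertz_q(stay_age, config)
    if (any(die_flag)) {
      de <- stay[die_flag, , drop = FALSE]
      deaths[[as.character(y)]] <- event_records(
        de$birth_date, de$sex, "death",
        draw_days(nrow(de), y,
                  season_day_weights(y, config$season_death_weights)))
    }
    survivors <- stay[!die_flag, , drop = FALSE]
    # immigrants: young-adult-centred age profile, optional Jan-1 heaping
    n_in <- stats::rpois(1L, config$migration_rate_in * n)
    if (n_in > 0L) {
      iage <- sample.int(81L, n_in, replace = TRUE,
                         prob = stats::dlnorm(1:81, log(30), 0.5)) - 1L
      ip <- draw_persons(n_in, y, iage, config)
      heap <- stats::runif(n_in) < config$jan1_heaping_rate
      if (any(heap)) {
        ip$birth_date[heap] <- make_date(year_of(ip$birth_date[heap]),
                                         1L, 1L)
      }
      immis[[as.character(y)]] <- event_records(
        ip$birth_date, ip$sex, "immigration",
        draw_days(n_in, y, sepw))
    } else {
      ip <- NULL
    }
    # newborns
    n_b <- stats::rpois(1L, config$fertility_rate * n)
    if (n_b > 0L) {
      md <- draw_birth_md(n_b, function(idx, m, d) rep(y, length(idx)),
                          config)
      bd <- make_date(y, md$month, md$day)
      bs <- ifelse(stats::runif(n_b) < config$sex_ratio_male,
                   "male", "female")
      births[[as.character(y)]] <- event_records(bd, bs, "birth")
      nb <- data.frame(birth_date = bd, sex = bs, stringsAsFactors = FALSE)
    } else {
      nb <- NULL
    }
    pieces <- list(survivors[c("birth_date", "sex")])
    if (!is.null(ip)) pieces <- c(pieces, list(ip[c("birth_date", "sex")]))
    if (!is.null(nb)) pieces <- c(pieces, list(nb))
    pop <- do.call(rbind, pieces)
    rownames(pop) <- NULL
  }
  stocks[[as.character(y1 + 1L)]] <- snapshot(pop, y1 + 1L)
  bind <- function(lst, empty_type) {
    if (length(lst) == 0L) {
      return(event_records(as.Date(integer(0), origin = "1970-01-01"),
                           character(0), character(0)))
    }
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  reg <- list(stock = do.call(rbind, stocks),
              deaths = bind(deaths),
              births = bind(births),
              immigrations = bind(immis),
              emigrations = bind(emis))
  rownames(reg$stock) <- NULL
  attr(reg, "config") <- config
  class(reg) <- "synthetic_registry"
  reg
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic registry", cfg$year_range[1], "-", cfg$year_range[2], "\n")
  cat(" stock snapshots:", length(unique(x$stock$valuation_year)),
      "(", nrow(x$stock), "person-rows )\n")
  cat(" deaths:", nrow(x$deaths), " births:", nrow(x$births),
      " in:", nrow(x$immigrations), " out:", nrow(x$emigrations), "\n")
  invisible(x)
}

#' Verify the closed-population accounting identity
#'
#' Checks, per simulated year and sex, that
#' `stock(Y+1) = stock(Y) + births(Y) + in(Y) - deaths(Y) - out(Y)`.
#'
#' @param registry a `synthetic_registry`.
#' @return a data.frame with one row per (year, sex) and a logical `ok`
#'   column; all-`TRUE` for any registry from [generate_registry()].
#' @export
verify_accounting <- function(registry) {
  cfg <- attr(registry, "config")
  years <- cfg$year_range[1]:cfg$year_range[2]
  cnt <- function(df, y, sx, ycol) {
    if (nrow(df) == 0L) return(0L)
    yy <- if (ycol == "valuation_year") df$valuation_year
          else year_of(df$event_date)
    sum(yy == y & df$sex == sx)
  }
  rows <- list()
  for (y in years) for (sx in SEX_LEVELS) {
    s0 <- cnt(registry$stock, y, sx, "valuation_year")
    s1 <- cnt(registry$stock, y + 1L, sx, "valuation_year")
    b <- cnt(registry$births, y, sx, "event")
    i <- cnt(registry$immigrations, y, sx, "event")
    d <- cnt(registry$deaths, y, sx, "event")
    e <- cnt(registry$emigrations, y, sx, "event")
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, sex = sx, stock_start = s0, stock_end = s1,
      births = b, inflow = i, deaths = d, outflow = e,
      ok = s1 == s0 + b + i - d - e, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Closed-form expectations implied by a generator configuration
#'
#' Returns the population quantities the generator is built to exhibit, for
#' parameter-recovery tests: expected seasonal death shares, weekday birth
#' shares, the September migration share, and the age-specific annual death
#' probabilities.
#'
#' @param config a [synth_config()].
#' @return a list with `seasonal_death_shares` (named, 4), `weekday_birth_shares`
#'   (named, 7), `september_migration_share` (scalar) and `death_rates`
#'   (ages 0-105).
#' @export
ground_truth_summary <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  years <- config$year_range[1]:config$year_range[2]
  sw <- numeric(4)
  for (y in years) {
    dsw <- season_day_weights(y, config$season_death_weights)
    seas <- (month_of(seq(make_date(y, 1L, 1L), make_date(y, 12L, 31L),
                          by = "day")) - 1L) %/% 3L + 1L
    sw <- sw + tapply(dsw, seas, sum)
  }
  seasonal <- as.numeric(sw) / sum(sw)
  names(seasonal) <- SEASON_NAMES
  f <- config$weekend_birth_factor
  wk <- c(rep(1, 5), f, f) / (5 + 2 * f)
  names(wk) <- WEEKDAY_NAMES
  sept_w <- 30 * config$september_peak_factor
  tot_w <- sum(year_length(years) - 30L) + length(years) * sept_w
  list(seasonal_death_shares = seasonal,
       weekday_birth_shares = wk,
       september_migration_share = length(years) * sept_w / tot_w,
       death_rates = gompertz_q(0:AGE_CAP, config))
}
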