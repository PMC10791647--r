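# Independent oracles used across the suite. These deliberately avoid the
# package's own date machinery (and base::Date where the point is to check
# it): day counts come from explicit month-length summation, weekdays from
# a fixed epoch count, and person-time partitions from brute-force
# day-by-day classification.

oracle_is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

oracle_month_days <- function(y) {
  c(31, if (oracle_is_leap(y)) 29 else 28, 31, 30, 31, 30,
    31, 31, 30, 31, 30, 31)
}

# days since 1970-01-01, by direct summation
oracle_epoch_days <- function(y, m, d) {
  mapply(function(y, m, d) {
    total <- 0
    if (y > 1970) {
      for (yy in 1970:(y - 1)) total <- total + 365 + oracle_is_leap(yy)
    } else if (y < 1970) {
      for (yy in y:1969) total <- total - 365 - oracle_is_leap(yy)
    }
    md <- oracle_month_days(y)
    total + (if (m > 1) sum(md[1:(m - 1)]) else 0) + d - 1
  }, y, m, d)
}

oracle_weekday <- function(y, m, d) {
  # 1970-01-01 was a Thursday
  names <- c("Monday", "Tuesday", "Wednesday", "Thursday",
             "Friday", "Saturday", "Sunday")
  names[((oracle_epoch_days(y, m, d) + 3) %% 7) + 1]
}

# Lexis coordinates computed from scratch (integer arithmetic only)
oracle_lexis <- function(by, bm, bd, y, m, d) {
  adj_day <- function(yy) if (bm == 2 && bd == 29 && !oracle_is_leap(yy)) 28 else bd
  reached <- (m > bm) || (m == bm && d >= adj_day(y))
  lby <- if (reached) y else y - 1
  offset <- oracle_epoch_days(y, m, d) - oracle_epoch_days(lby, bm, adj_day(lby))
  D <- oracle_epoch_days(lby + 1, bm, adj_day(lby + 1)) -
    oracle_epoch_days(lby, bm, adj_day(lby))
  list(age = lby - by,
       quarter = floor(4 * offset / D) + 1,
       season = c("Winter", "Spring", "Summer", "Autumn")[(m - 1) %/% 3 + 1],
       offset = offset, D = D)
}

# Brute-force person-year partition: classify every day of the window with
# lexis_position and tally. (This is the comparison the analytic
# breakpoint computation must reproduce exactly.)
bruteforce_partition <- function(birth, ws, we) {
  if (ws > we) {
    return(data.frame(age = integer(0), quarter_age = character(0),
                      quarter_calendar = character(0), days = integer(0)))
  }
  days <- seq(ws, we, by = "day")
  pos <- lexis_position(rep(birth, length(days)), days)
  agg <- aggregate(list(days = rep(1L, length(days))),
                   by = list(age = pos$integer_age,
                             quarter_age = pos$age_quarter,
                             quarter_calendar = pos$calendar_quarter),
                   FUN = sum)
  agg[order(agg$age, agg$quarter_age, agg$quarter_calendar), ]
}

# Brute-force centred moving average with edge omission
bruteforce_ma <- function(x, k) {
  n <- length(x)
  w <- 2 * k + 1
  if (n < w) return(numeric(0))
  vapply((k + 1):(n - k), function(i) mean(x[(i - k):(i + k)]), numeric(1))
}

# Random birth dates including Feb 29 and year boundaries
random_birth_dates <- function(n, ymin = 1900, ymax = 2015) {
  y <- sample(ymin:ymax, n, replace = TRUE)
  m <- sample(1:12, n, replace = TRUE)
  dmax <- mapply(function(y, m) oracle_month_days(y)[m], y, m)
  d <- 1L + floor(runif(n) * dmax)
  as.Date(sprintf("%04d-%02d-%02d", y, m, as.integer(d)))
}

# force some Feb 29 births into a date vector
with_feb29 <- function(dates, k = 25) {
  leaps <- c(1904, 1952, 1960, 1980, 1996, 2000, 2004, 2008)
  idx <- sample(seq_along(dates), min(k, length(dates)))
  dates[idx] <- as.Date(sprintf("%04d-02-29",
                                sample(leaps, length(idx), replace = TRUE)))
  dates
}

small_registry <- function(n = 1500, years = c(2010, 2011), seed = 42, ...) {
  generate_registry(synth_config(n_stock = n, year_range = years,
                                 seed = seed, ...))
}
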