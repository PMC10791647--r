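test_that("person-year partition matches worked examples and conserves days", {
  pp <- partition_person_year("1970-01-01", 2010, "2010-01-01", "2010-12-31")
  expect_identical(sum(pp$days), 365L)
  expect_lte(nrow(pp), 8L)
  expect_identical(pp$days[pp$age == 40 & pp$quarter_age == "Q1" &
                             pp$quarter_calendar == "Winter"], 90L)
  expect_true(all(pp$age == 40L))
  nb <- partition_person_year("2010-07-04", 2010, "2010-07-04", "2010-12-31")
  expect_true(all(nb$age == 0L))
  expect_identical(sum(nb$days), 181L)
  # empty / inverted window
  expect_identical(nrow(partition_person_year("1970-01-01", 2010,
                                              "2010-06-01", "2010-05-31")), 0L)
})

test_that("analytic partition equals day-by-day classification exactly", {
  set.seed(101)
  n <- 400L
  birth <- with_feb29(random_birth_dates(n, 1900, 2011), 40)
  yr <- pmax(as.POSIXlt(birth)$year + 1900,
             sample(1995:2021, n, replace = TRUE))
  for (i in seq_len(n)) {
    jan1 <- as.Date(sprintf("%d-01-01", yr[i]))
    dec31 <- as.Date(sprintf("%d-12-31", yr[i]))
    ws <- max(jan1, birth[i])
    # random sub-window half the time, full presence otherwise
    if (i %% 2 == 0) {
      lo <- ws + sample.int(as.integer(dec31 - ws) + 1L, 1L) - 1L
      hi <- lo + sample.int(as.integer(dec31 - lo) + 1L, 1L) - 1L
    } else {
      lo <- ws; hi <- dec31
    }
    got <- partition_person_year(birth[i], yr[i], lo, hi)
    want <- bruteforce_partition(birth[i], lo, hi)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
    expect_identical(sum(got$days),
                     days_between(lo, hi) + 1L)
    expect_lte(nrow(got), 8L)
    expect_identical(anyDuplicated(got[c("age", "quarter_age",
                                         "quarter_calendar")]), 0L)
  }
})

test_that("stock exposure is exactly one person-year per resident", {
  one <- time_exposed_stock(event_records("1970-01-01", "male", "stock"), 2010)
  expect_identical(sum(one$days_exposed), 365L)
  expect_identical(sum(one$days_not_exposed), 0L)
  expect_equal(ledger_table(one)$time_exposed[
    one$age == 40 & one$quarter_age == "Q1" & one$quarter_calendar == "Winter"],
    90 / 365)
  set.seed(102)
  n <- 1000L
  recs <- event_records(with_feb29(random_birth_dates(n, 1900, 2011)),
                        sample(c("male", "female"), n, TRUE), "stock")
  led <- time_exposed_stock(recs, 2012)
  expect_identical(sum(led$days_exposed), n * 366L)  # 2012 is leap
  expect_identical(sum(led$days_not_exposed), 0L)
  expect_equal(sum(ledger_table(led)$time_exposed), n)
  late <- event_records("2012-06-01", "male", "stock")
  expect_error(time_exposed_stock(late, 2012), "born after January 1")
})

test_that("exit exposure excludes the event day and complements to one year", {
  d <- time_exposed_exit(event_records("1940-03-10", "male", "death",
                                       "2010-03-10"))
  expect_identical(sum(d$days_exposed), 68L)
  expect_identical(sum(d$days_not_exposed), 297L)
  expect_equal(sum(ledger_table(d)$time_exposed +
                     ledger_table(d)$time_not_exposed), 1)
  # born and dead within the same year: no exposure before the window
  s <- time_exposed_exit(event_records("2010-06-01", "female", "death",
                                       "2010-06-01"))
  expect_identical(sum(s$days_exposed), 0L)
  expect_identical(sum(s$days_not_exposed), 214L)
  # complement property on random exits born before the year
  set.seed(103)
  n <- 300L
  birth <- random_birth_dates(n, 1920, 2008)
  ev <- as.Date("2009-01-01") + sample(0:364, n, TRUE)
  led <- time_exposed_exit(event_records(birth, "male",
                                         sample(c("death", "emigration"), n,
                                                TRUE), ev))
  expect_identical(sum(led$days_exposed) + sum(led$days_not_exposed),
                   n * 365L)
})

test_that("entry exposure includes the event day and complements to one year", {
  jan <- time_exposed_entry(event_records("1980-05-15", "male", "immigration",
                                          "2010-01-01"))
  expect_identical(sum(jan$days_exposed), 365L)
  expect_identical(sum(jan$days_not_exposed), 0L)
  dec <- time_exposed_entry(event_records("1980-05-15", "male", "immigration",
                                          "2010-12-31"))
  expect_identical(sum(dec$days_exposed), 1L)
  expect_identical(sum(dec$days_not_exposed), 364L)
  set.seed(104)
  n <- 300L
  birth <- random_birth_dates(n, 1920, 2008)
  ev <- as.Date("2009-01-01") + sample(0:364, n, TRUE)
  led <- time_exposed_entry(event_records(birth, "female", "immigration", ev))
  expect_identical(sum(led$days_exposed) + sum(led$days_not_exposed),
                   n * 365L)
})

test_that("newborn exposure runs from birth to year end at age zero", {
  j <- time_exposed_newborn(event_records("2010-01-01", "male", "birth"))
  expect_identical(sum(j$days_exposed), 365L)
  expect_identical(sort(unique(j$quarter_age)), c("Q1", "Q2", "Q3", "Q4"))
  expect_true(all(j$age == 0L))
  m <- time_exposed_newborn(event_records("2010-07-04", "female", "birth"))
  expect_identical(sum(m$days_exposed), 181L)
  d <- time_exposed_newborn(event_records("2010-12-31", "male", "birth"))
  expect_identical(sum(d$days_exposed), 1L)
  expect_identical(d$age, 0L)
  expect_identical(d$quarter_age, "Q1")
  expect_identical(d$quarter_calendar, "Autumn")
})

test_that("event counting lands on the Lexis cell of the event day", {
  ct <- count_events_by_quarter(event_records("1940-03-10", "male", "death",
                                              "2010-03-10"))
  expect_identical(ct$valuation_year, 2010L)
  expect_identical(ct$gender, "men")
  expect_identical(ct$age, 70L)
  expect_identical(ct$quarter_age, "Q1")
  expect_identical(ct$quarter_calendar, "Winter")
  expect_identical(ct$number_events, 1L)
  empty <- count_events_by_quarter(
    event_records(as.Date(integer(0), origin = "1970-01-01"),
                  character(0), character(0)))
  expect_identical(nrow(empty), 0L)
  set.seed(105)
  n <- 500L
  recs <- event_records(random_birth_dates(n, 1950, 2005), "female",
                        "emigration",
                        as.Date("2010-01-01") + sample(0:364, n, TRUE))
  tot <- count_events_by_quarter(recs)
  expect_identical(sum(tot$number_events), n)
  mixed <- rbind(recs,
                 event_records("1950-01-01", "male", "death", "2010-05-05"))
  expect_error(count_events_by_quarter(mixed), "mix")
})

test_that("counts dominate presence-time totals (within-year births lose time)", {
  set.seed(106)
  n <- 200L
  # half born within the event year (infants), half before
  birth <- c(random_birth_dates(n / 2, 1950, 2009),
             as.Date("2010-01-01") + sample(0:200, n / 2, TRUE))
  ev <- pmax(birth, as.Date("2010-01-01")) +
    sample(0:120, n, TRUE)
  ev <- pmin(ev, as.Date("2010-12-31"))
  recs <- event_records(birth, "male", "death", ev)
  cts <- count_events_by_quarter(recs)
  led <- ledger_table(time_exposed_exit(recs))
  count3 <- sum(cts$number_events)
  time4 <- sum(led$time_exposed + led$time_not_exposed)
  expect_identical(count3, n)
  expect_lt(time4, count3)  # infants contribute less than 1 each
  # the shortfall is exactly the pre-birth part of the year
  infant <- birth >= as.Date("2010-01-01")
  missing_days <- sum(days_between(as.Date("2010-01-01"), birth[infant]))
  expect_equal(time4, n - missing_days / 365)
})

test_that("combined total exposure equals summed individual presence", {
  # identity cases
  nb <- time_exposed_newborn(event_records("2010-07-04", "male", "birth"))
  emptyL <- time_exposed_stock(
    event_records(as.Date(integer(0), origin = "1970-01-01"),
                  character(0), character(0)), 2010)
  tot <- combine_total_exposure(emptyL, emptyL, nb, emptyL, emptyL)
  expect_equal(sum(tot$time_exposed), 181 / 365)
  one <- time_exposed_stock(event_records("1970-06-15", "female", "stock"),
                            2010)
  tot1 <- combine_total_exposure(one, emptyL, emptyL, emptyL, emptyL)
  expect_equal(sum(tot1$time_exposed), 1)
  # closed simulated year: total person-years equal per-person presence
  reg <- small_registry(n = 800, years = c(2010, 2010), seed = 9)
  y <- 2010L
  st <- reg$stock[reg$stock$valuation_year == y, ]
  P4 <- time_exposed_stock(event_records(st$birth_date, st$sex, "stock"), y)
  D4 <- time_exposed_exit(reg$deaths)
  E4 <- time_exposed_exit(reg$emigrations)
  I4 <- time_exposed_entry(reg$immigrations)
  B4 <- time_exposed_newborn(reg$births)
  tot <- combine_total_exposure(P4, I4, B4, D4, E4)
  dec31 <- as.Date("2010-12-31")
  expected_days <- nrow(st) * 365L -
    sum(days_between(reg$deaths$event_date, dec31) + 1L) -
    sum(days_between(reg$emigrations$event_date, dec31) + 1L) +
    sum(days_between(reg$immigrations$event_date, dec31) + 1L) +
    sum(days_between(reg$births$event_date, dec31) + 1L)
  expect_equal(sum(tot$time_exposed) * 365, expected_days)
  expect_true(all(tot$time_exposed >= 0))
})
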