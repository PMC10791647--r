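# Internal-consistency validation reports: reconciliation of quarterly
# event counts against exposure + non-exposure times, and the three-way
# stock-summary consistency check.

#' Reconcile event counts against exposure times
#'
#' For each year and sex, compares the total number of events in a count
#' table against the total of exposure plus non-exposure time in the
#' matching ledger. For a person born before the event year the two
#' contributions are both exactly 1; a person born within the event year
#' contributes 1 to the count but less than one person-year of presence, so
#' the relative difference `100 * (time4 - count3) / count3` is never
#' positive and is zero exactly when no record was born within its event
#' year.
#'
#' @param counts a count table from [count_events_by_quarter()].
#' @param ledger the `exposure_ledger` built from the same event stream.
#' @return a data.frame with columns `valuation_year`, `gender`, `count3`,
#'   `time4`, `diff_pct` (exact value) and `diff_pct_display` (two
#'   decimals).
#' @export
reconcile <- function(counts, ledger) {
  stopifnot(inherits(ledger, "exposure_ledger"))
  cy <- sort(unique(counts$valuation_year))
  ly <- sort(unique(ledger$valuation_year))
  if (!identical(cy, ly)) {
    stop("year coverage mismatch between counts (",
         paste(cy, collapse = ","), ") and ledger (",
         paste(ly, collapse = ","), ")")
  }
  c3 <- stats::aggregate(number_events ~ valuation_year + gender,
                         data = counts, FUN = sum)
  lt <- ledger_table(ledger)
  lt$presence <- lt$time_exposed + lt$time_not_exposed
  t4 <- stats::aggregate(presence ~ valuation_year + gender,
                         data = lt, FUN = sum)
  out <- merge(c3, t4, by = c("valuation_year", "gender"), all = TRUE)
  out$number_events[is.na(out$number_events)] <- 0L
  out$presence[is.na(out$presence)] <- 0
  names(out)[names(out) == "number_events"] <- "count3"
  names(out)[names(out) == "presence"] <- "time4"
  out$diff_pct <- 100 * (out$time4 - out$count3) / out$count3
  out$diff_pct_display <- sprintf("%.2f%%", out$diff_pct)
  out <- out[order(out$valuation_year, out$gender), ]
  rownames(out) <- NULL
  out
}

#' Three-way consistency of the stock summary tables
#'
#' Aggregates, per valuation year and sex, the `number_of_persons` column of
#' the monthly table, the `time_exposed` column of the quarterly exposure
#' table and the `number_of_birthdays` column of the weekday table. All
#' three summarise the same January-1 stock, so the aggregates are equal
#' (the exposure aggregate is an exact person count because every stock
#' person contributes exactly 1.0 person-years).
#'
#' @param P1 table from [build_P1()] (with `valuation_date`).
#' @param P4 table from `ledger_table(time_exposed_stock(...))`.
#' @param P6 table from [build_P6()].
#' @return a data.frame with columns `valuation_year`, `gender`, `agg_P1`,
#'   `agg_P4`, `agg_P6`, `equal`.
#' @export
stock_consistency <- function(P1, P4, P6) {
  if (nrow(P1) == 0L && nrow(P4) == 0L && nrow(P6) == 0L) {
    return(data.frame(valuation_year = integer(0), gender = character(0),
                      agg_P1 = numeric(0), agg_P4 = numeric(0),
                      agg_P6 = numeric(0), equal = logical(0)))
  }
  P1$valuation_year <- year_of(P1$valuation_date)
  a1 <- stats::aggregate(number_of_persons ~ valuation_year + gender,
                         data = P1, FUN = sum)
  a4 <- stats::aggregate(time_exposed ~ valuation_year + gender,
                         data = P4, FUN = sum)
  # exposure is stored at day granularity, so the year total is an exact
  # whole number of days: re-quantise to remove float summation noise
  yl <- year_length(a4$valuation_year)
  a4$time_exposed <- round(a4$time_exposed * yl) / yl
  a6 <- stats::aggregate(number_of_birthdays ~ valuation_year + gender,
                         data = P6, FUN = sum)
  out <- merge(merge(a1, a4, by = c("valuation_year", "gender"), all = TRUE),
               a6, by = c("valuation_year", "gender"), all = TRUE)
  names(out)[3:5] <- c("agg_P1", "agg_P4", "agg_P6")
  for (col in c("agg_P1", "agg_P4", "agg_P6")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  out$equal <- out$agg_P1 == out$agg_P4 & out$agg_P1 == out$agg_P6
  out <- out[order(out$valuation_year, out$gender), ]
  rownames(out) <- NULL
  out
}
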