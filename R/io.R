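# Readers and writers for the microdata and output dialects: semicolon
# delimiter, dot decimal mark, UTF-8, header row, long format. Output row
# order is deterministic (sorted by key columns) so repeated runs are
# byte-identical.

TABLE_FILENAMES <- c(
  P_1 = "P_1_Number_of_people_per_month_of_birth.csv",
  P_2_men = "P_2_Moving_average_k3_per_day_of_birth_men.csv",
  P_2_women = "P_2_Moving_average_k3_per_day_of_birth_women.csv",
  P_4 = "P_4_Time_exposed_by_quarter.csv",
  P_6 = "P_6_Births_per_day_of_the_week_of_population.csv",
  D_3 = "D_3_Count_events_by_quarter.csv",
  D_4 = "D_4_Time_exposed_by_quarter.csv",
  E_3 = "E_3_Count_events_by_quarter.csv",
  E_4 = "E_4_Time_exposed_by_quarter.csv",
  I_3 = "I_3_Count_events_by_quarter.csv",
  I_4 = "I_4_Time_exposed_by_quarter.csv",
  B_4 = "B_4_Time_exposed_by_quarter.csv",
  B_6 = "B_6_Births_per_day_of_the_week.csv",
  E_5 = "E_5_Moving_average_k3_per_day.csv",
  I_5 = "I_5_Moving_average_k3_per_day.csv")

MICRODATA_COLUMNS <- list(
  stock = c("date_birth", "sex"),
  death = c("date_birth", "date_event", "sex"),
  birth = c("date_birth", "sex"),
  migration = c("date_birth", "date_event", "sex", "direction"))

#' Read vital-registration microdata
#'
#' Reads a semicolon-delimited microdata file into validated event records.
#' Dates may be ISO `YYYY-MM-DD` or `ddmmyyyy` digit strings. Required
#' columns by kind: stock and birth need `date_birth` and `sex`; death needs
#' also `date_event`; migration needs additionally a `direction` column with
#' values `in`/`out`. A stock file may carry a `valuation_year` column,
#' which is kept.
#'
#' @param path file path.
#' @param kind one of `"stock"`, `"death"`, `"birth"`, `"migration"`.
#' @param on_error `"stop"` (default) rejects the whole file naming the
#'   first offending rows; `"skip"` drops bad rows, reports them via
#'   [message()] and attaches them as the `"rejected"` attribute.
#' @return an event-record data.frame (see [event_records()]); migrations
#'   get `event_type` `"emigration"`/`"immigration"` from `direction`.
#' @export
read_microdata <- function(path, kind = c("stock", "death", "birth",
                                          "migration"),
                           on_error = c("stop", "skip")) {
  kind <- match.arg(kind)
  on_error <- match.arg(on_error)
  raw <- utils::read.table(path, header = TRUE, sep = ";", dec = ".",
                           colClasses = "character", encoding = "UTF-8",
                           stringsAsFactors = FALSE)
  need <- MICRODATA_COLUMNS[[kind]]
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(raw)
  bd <- parse_dates_quiet(raw$date_birth)
  ed <- if ("date_event" %in% names(raw)) parse_dates_quiet(raw$date_event)
        else rep(as.Date(NA), n)
  sex <- tolower(raw$sex)
  reason <- rep(NA_character_, n)
  reason[is.na(bd)] <- "malformed birth date"
  if (kind %in% c("death", "migration")) {
    reason[is.na(reason) & is.na(ed)] <- "malformed event date"
    early <- !is.na(ed) & !is.na(bd) & ed < bd
    reason[is.na(reason) & early] <- "event before birth"
  }
  reason[is.na(reason) & !sex %in% SEX_LEVELS] <- "unknown sex code"
  if (kind == "migration") {
    dir_ok <- tolower(raw$direction) %in% c("in", "out")
    reason[is.na(reason) & !dir_ok] <- "unknown direction code"
  }
  bad <- which(!is.na(reason))
  if (length(bad)) {
    if (on_error == "stop") {
      stop("invalid microdata in ", path, ": row ", bad[1], " (",
           reason[bad[1]], ")",
           if (length(bad) > 1) paste0(" and ", length(bad) - 1, " more"))
    }
    message("read_microdata: skipped ", length(bad), " invalid row(s) in ",
            path)
  }
  ok <- setdiff(seq_len(n), bad)
  type <- switch(kind,
                 stock = rep("stock", length(ok)),
                 death = rep("death", length(ok)),
                 birth = rep("birth", length(ok)),
                 migration = ifelse(tolower(raw$direction[ok]) == "out",
                                    "emigration", "immigration"))
  recs <- event_records(bd[ok], sex[ok], type,
                        if (kind %in% c("stock", "birth")) NULL else ed[ok])
  if (kind == "birth") recs$event_date <- recs$birth_date
  recs$source_row <- ok
  if ("valuation_year" %in% names(raw)) {
    recs$valuation_year <- as.integer(raw$valuation_year[ok])
  }
  if (length(bad)) {
    attr(recs, "rejected") <- data.frame(row = bad, reason = reason[bad],
                                         stringsAsFactors = FALSE)
  }
  recs
}

#' Write a pipeline table in the standard CSV dialect
#'
#' Semicolon-delimited, dot decimal mark, UTF-8, header row, Unix line
#' endings. Rows are sorted by all columns left to right, so output is
#' byte-identical across runs. `name` is mapped to the standard file name
#' when it is one of the fifteen pipeline tables (e.g. `"D_3"` becomes
#' `D_3_Count_events_by_quarter.csv`), otherwise `<name>.csv` is used.
#'
#' @param table a data.frame.
#' @param name table name or file stem.
#' @param dir output directory (created if absent).
#' @return the file path, invisibly.
#' @export
write_table <- function(table, name, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fname <- if (name %in% names(TABLE_FILENAMES)) TABLE_FILENAMES[[name]]
           else paste0(name, ".csv")
  path <- file.path(dir, fname)
  out <- as.data.frame(table)
  for (cn in names(out)) {
    if (inherits(out[[cn]], "Date")) out[[cn]] <- format(out[[cn]], "%Y-%m-%d")
  }
  if (nrow(out) > 1L) {
    out <- out[do.call(order, out), , drop = FALSE]
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = ";", dec = ".", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a pipeline table
#'
#' Inverse of [write_table()]: reads the standard dialect and re-types date
#' columns (`date`, `birth_date`, `valuation_date`) as `Date`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_table_csv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = ";", dec = ".",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  for (cn in intersect(c("date", "birth_date", "valuation_date"),
                       names(out))) {
    out[[cn]] <- as.Date(out[[cn]])
  }
  out
}

#' Write a synthetic registry as microdata files
#'
#' Emits `stock.csv`, `deaths.csv`, `births.csv` and `migrations.csv` in the
#' same delimited layout [read_microdata()] consumes, with `ddmmyyyy` dates.
#'
#' @param registry a `synthetic_registry` from [generate_registry()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_registry <- function(registry, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ddm <- function(d) format_civil_date(d, "ddmmyyyy")
  stock <- data.frame(valuation_year = registry$stock$valuation_year,
                      date_birth = ddm(registry$stock$birth_date),
                      sex = registry$stock$sex, stringsAsFactors = FALSE)
  write_table(stock, "stock", dir)
  write_table(data.frame(date_birth = ddm(registry$deaths$birth_date),
                         date_event = ddm(registry$deaths$event_date),
                         sex = registry$deaths$sex,
                         stringsAsFactors = FALSE), "deaths", dir)
  write_table(data.frame(date_birth = ddm(registry$births$birth_date),
                         sex = registry$births$sex,
                         stringsAsFactors = FALSE), "births", dir)
  mig <- rbind(registry$emigrations, registry$immigrations)
  write_table(data.frame(date_birth = ddm(mig$birth_date),
                         date_event = ddm(mig$event_date),
                         sex = mig$sex,
                         direction = ifelse(mig$event_type == "emigration",
                                            "out", "in"),
                         stringsAsFactors = FALSE), "migrations", dir)
  invisible(dir)
}

#' Read a generator configuration from a key-value file
#'
#' Plain-text lines of the form `key = value`; vectors are comma-separated;
#' `#` starts a comment. Keys are the arguments of [synth_config()]; absent
#' keys keep their defaults.
#'
#' @param path file path.
#' @return a validated `synth_config`.
#' @export
read_synth_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- as.numeric(trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(val)) stop("non-numeric value for config key ", key)
    args[[key]] <- val
  }
  unknown <- setdiff(names(args), names(formals(synth_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(synth_config, args)
}
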