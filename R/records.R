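# Event records: one row of microdata (birth date, optional event date, sex,
# event type). Stored as a plain data.frame with validated columns.

EVENT_TYPES <- c("stock", "death", "emigration", "immigration", "birth")
SEX_LEVELS <- c("male", "female")

#' Construct validated event records
#'
#' Builds the microdata row container used throughout the pipeline: one row
#' per person or event, with the exact dates that place it on the Lexis
#' plane. `event_date` is absent (NA) for stock rows and equals `birth_date`
#' for birth records.
#'
#' @param birth_date dates of birth (`Date` or parseable character).
#' @param sex `"male"` / `"female"` vector.
#' @param event_type one of `"stock"`, `"death"`, `"emigration"`,
#'   `"immigration"`, `"birth"` (scalar or vector).
#' @param event_date event dates, or `NULL`/NA for stock rows. For
#'   `event_type = "birth"` it defaults to `birth_date`.
#' @return a data.frame with columns `birth_date`, `event_date`, `sex`,
#'   `event_type`.
#' @examples
#' event_records("15051980", "male", "death", "2010-02-10")
#' @export
event_records <- function(birth_date, sex, event_type, event_date = NULL) {
  birth_date <- parse_civil_date(birth_date)
  n <- length(birth_date)
  sex <- rep_len(as.character(sex), n)
  event_type <- rep_len(as.character(event_type), n)
  if (!all(sex %in% SEX_LEVELS)) {
    stop("sex must be one of: ", paste(SEX_LEVELS, collapse = ", "))
  }
  if (!all(event_type %in% EVENT_TYPES)) {
    stop("event_type must be one of: ", paste(EVENT_TYPES, collapse = ", "))
  }
  if (is.null(event_date)) {
    event_date <- rep(as.Date(NA), n)
  } else {
    event_date <- rep_len(parse_civil_date(event_date), n)
  }
  is_birth <- event_type == "birth"
  event_date[is_birth] <- birth_date[is_birth]
  needs_event <- event_type != "stock"
  if (any(needs_event & is.na(event_date))) {
    stop("event_date required for non-stock records (rows ",
         paste(utils::head(which(needs_event & is.na(event_date)), 5),
               collapse = ", "), ")")
  }
  bad <- !is.na(event_date) & event_date < birth_date
  if (any(bad)) {
    stop("event before birth (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), ")")
  }
  data.frame(birth_date = birth_date, event_date = event_date,
             sex = sex, event_type = event_type, stringsAsFactors = FALSE)
}

# gender labels used in all serialised outputs
sex_to_gender <- function(sex) {
  unname(c(male = "men", female = "women")[sex])
}
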