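# Three-table linked-cohort I/O (children, maternal baseline, coded events)
# and the anonymised age arithmetic: child ages are computed from the first
# day of the birth month, in completed (floored) calendar months.

CHILDREN_COLS <- c("child_id", "mother_id", "birth_month", "sex", "withdrawn",
                   "died", "has_primary_care_link", "has_maternal_baseline")
MATERNAL_COLS <- c("mother_id", "ethnicity", "education", "age_at_birth",
                   "parity", "cohabiting", "subjective_finance", "imd_quintile")
EVENTS_COLS <- c("child_id", "code", "event_date")

as_flag <- function(x, col) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out) && length(x) > 0) {
    stop("column '", col, "': unparseable flag value(s) at row ",
         paste(utils::head(which(is.na(out)), 5), collapse = ", "))
  }
  as.logical(out)
}

first_of_birth_month <- function(birth_month) {
  if (length(birth_month) == 0) {
    return(structure(numeric(0), class = "Date"))
  }
  ok <- grepl("^\\d{4}-\\d{2}$", birth_month)
  if (!all(ok)) {
    stop("invalid birth_month (expected YYYY-MM) at row ",
         paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  d <- as.Date(paste0(birth_month, "-01"))
  if (anyNA(d)) {
    stop("invalid birth_month at row ",
         paste(utils::head(which(is.na(d)), 5), collapse = ", "))
  }
  d
}

#' Child age in completed months from an anonymised birth month
#'
#' Ages are anchored to the first day of the birth month (only year and
#' month of birth are carried, for anonymity) and counted as completed
#' calendar months, floored. An event on 2008-06-20 for a birth month of
#' 2008-03 is age 3 months; the fifth birthday is exactly 60 months.
#'
#' @param birth_month Character vector, `YYYY-MM`.
#' @param event_date `Date` vector (or `YYYY-MM-DD` strings).
#' @return Integer vector of whole months, `>= 0`.
#' @export
#' @examples
#' age_in_months("2008-03", as.Date("2008-06-20"))
age_in_months <- function(birth_month, event_date) {
  anchor <- first_of_birth_month(birth_month)
  event_date <- as.Date(event_date)
  if (anyNA(event_date)) stop("unparseable event_date")
  if (any(event_date < anchor)) {
    stop("event_date precedes the first day of the birth month")
  }
  ay <- as.integer(format(anchor, "%Y"))
  am <- as.integer(format(anchor, "%m"))
  ey <- as.integer(format(event_date, "%Y"))
  em <- as.integer(format(event_date, "%m"))
  # anchor day is 1, so completed months floor to the calendar-month gap
  as.integer(12L * (ey - ay) + (em - am))
}

check_schema <- function(df, cols, path) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
}

#' Read a three-table linked cohort
#'
#' Reads `children.csv`, `maternal.csv` and `events.csv` (schemas below),
#' parses dates and flags, and checks referential integrity: events whose
#' `child_id` is unknown are listed as orphans (not dropped silently),
#' events dated before the child's birth-month anchor are flagged
#' `pre_birth` (retained, but excluded later from windowed ascertainment),
#' and a mother with more than one baseline row is an error.
#'
#' Schemas (CSV, header row, UTF-8): children
#' `child_id,mother_id,birth_month,sex,withdrawn,died,has_primary_care_link,has_maternal_baseline`
#' with `birth_month` as `YYYY-MM`; maternal
#' `mother_id,ethnicity,education,age_at_birth,parity,cohabiting,subjective_finance,imd_quintile`;
#' events `child_id,code,event_date` with ISO dates.
#'
#' @param children_path,maternal_path,events_path CSV paths.
#' @return A `cohort`: list with `children`, `maternal`, `events` data
#'   frames and a `report` (orphan events, pre-birth flags, baseline
#'   mismatches).
#' @export
read_cohort <- function(children_path, maternal_path, events_path) {
  for (p in c(children_path, maternal_path, events_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  children <- utils::read.csv(children_path, colClasses = "character",
                              strip.white = TRUE)
  maternal <- utils::read.csv(maternal_path, colClasses = "character",
                              strip.white = TRUE)
  events <- utils::read.csv(events_path, colClasses = "character",
                            strip.white = TRUE)
  check_schema(children, CHILDREN_COLS, children_path)
  check_schema(maternal, MATERNAL_COLS, maternal_path)
  check_schema(events, EVENTS_COLS, events_path)

  if (nrow(children) > 0) {
    if (anyDuplicated(children$child_id)) {
      stop("duplicate child_id in ", children_path, ": ",
           paste(utils::head(unique(
             children$child_id[duplicated(children$child_id)]), 5),
             collapse = ", "))
    }
    first_of_birth_month(children$birth_month)  # validates format
    for (col in c("withdrawn", "died", "has_primary_care_link",
                  "has_maternal_baseline")) {
      children[[col]] <- as_flag(children[[col]], col)
    }
    bad_sex <- !children$sex %in% c("male", "female")
    if (any(bad_sex)) {
      stop("invalid sex value at row ",
           paste(utils::head(which(bad_sex), 5), collapse = ", "),
           " of ", children_path)
    }
  } else {
    for (col in c("withdrawn", "died", "has_primary_care_link",
                  "has_maternal_baseline")) {
      children[[col]] <- logical(0)
    }
  }

  dup_mothers <- unique(maternal$mother_id[duplicated(maternal$mother_id)])
  if (length(dup_mothers) > 0) {
    stop("mother_id with more than one baseline row in ", maternal_path,
         ": ", paste(utils::head(dup_mothers, 5), collapse = ", "))
  }
  if (nrow(maternal) > 0) {
    maternal$age_at_birth <- suppressWarnings(as.numeric(maternal$age_at_birth))
    bad_age <- !is.na(maternal$age_at_birth) &
      (maternal$age_at_birth < 12 | maternal$age_at_birth > 60)
    if (any(bad_age)) {
      stop("implausible age_at_birth (outside 12-60) at row ",
           paste(utils::head(which(bad_age), 5), collapse = ", "),
           " of ", maternal_path)
    }
  } else {
    maternal$age_at_birth <- numeric(0)
  }

  if (nrow(events) > 0) {
    d <- as.Date(events$event_date, format = "%Y-%m-%d")
    if (anyNA(d)) {
      stop("unparseable event_date at row ",
           paste(utils::head(which(is.na(d)), 5), collapse = ", "),
           " of ", events_path)
    }
    events$event_date <- d
    events$code <- canonical_read_code(events$code)
  } else {
    events$event_date <- as.Date(character(0))
  }

  orphan <- !events$child_id %in% children$child_id
  anchor <- first_of_birth_month(children$birth_month)[
    match(events$child_id, children$child_id)]
  pre_birth <- !orphan & events$event_date < anchor
  events$pre_birth <- pre_birth

  baseline_no_row <- children$child_id[
    children$has_maternal_baseline &
      !children$mother_id %in% maternal$mother_id]

  report <- structure(
    list(
      n_children = nrow(children),
      n_maternal = nrow(maternal),
      n_events = nrow(events),
      orphan_events = events$child_id[orphan],
      n_orphan_events = sum(orphan),
      pre_birth_events = which(pre_birth),
      n_pre_birth_events = sum(pre_birth),
      baseline_flag_without_row = baseline_no_row
    ),
    class = "cohort_load_report"
  )

  structure(
    list(children = children, maternal = maternal, events = events,
         report = report),
    class = "cohort"
  )
}

#' @export
print.cohort_load_report <- function(x, ...) {
  cat(sprintf("cohort load: %d children, %d maternal rows, %d events\n",
              x$n_children, x$n_maternal, x$n_events))
  cat(sprintf("  orphan events (unknown child_id): %d\n", x$n_orphan_events))
  cat(sprintf("  pre-birth events (flagged, kept): %d\n", x$n_pre_birth_events))
  if (length(x$baseline_flag_without_row) > 0) {
    cat(sprintf("  children flagged as having a baseline but no maternal row: %d\n",
                length(x$baseline_flag_without_row)))
  }
  invisible(x)
}

#' Write a three-table cohort to a directory
#'
#' Inverse of [read_cohort()]: writes `children.csv`, `maternal.csv`,
#' `events.csv` (and `load_report.json` when a report is present) so that
#' reading them back reproduces the tables field-for-field.
#'
#' @param cohort A `cohort`, or a list with `children`, `maternal`,
#'   `events` data frames.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  children <- cohort$children
  for (col in c("withdrawn", "died", "has_primary_care_link",
                "has_maternal_baseline")) {
    children[[col]] <- as.integer(children[[col]])
  }
  events <- cohort$events
  events$pre_birth <- NULL
  events$event_date <- format(as.Date(events$event_date), "%Y-%m-%d")
  paths <- c(
    children = file.path(dir, "children.csv"),
    maternal = file.path(dir, "maternal.csv"),
    events = file.path(dir, "events.csv")
  )
  utils::write.csv(children[, CHILDREN_COLS, drop = FALSE], paths[["children"]],
                   row.names = FALSE, quote = TRUE)
  utils::write.csv(cohort$maternal[, MATERNAL_COLS, drop = FALSE],
                   paths[["maternal"]], row.names = FALSE, quote = TRUE)
  utils::write.csv(events[, EVENTS_COLS, drop = FALSE], paths[["events"]],
                   row.names = FALSE, quote = TRUE)
  if (!is.null(cohort$report)) {
    jsonlite::write_json(unclass(cohort$report),
                         file.path(dir, "load_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(paths)
}
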