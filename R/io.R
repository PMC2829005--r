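#' Read prescription dispensations from CSV
#'
#' Expected columns: `patient_id`, `drug_code`, `dispense_date` (ISO-8601,
#' `YYYY-MM-DD`), `days_supply`, and optionally `observation_start` /
#' `observation_end` giving each patient's registry window (constant within
#' patient). Rows whose drug code does not match the antidepressant prefix
#' are retained and flagged in an `antidepressant` column; the classifier
#' ignores them.
#'
#' @param path CSV file path.
#' @param windows Optional `data.frame` (or CSV path) with `patient_id`,
#'   `observation_start`, `observation_end`, used when the prescription file
#'   carries no window columns.
#' @param ad_prefix Drug-code prefix used to flag antidepressant rows.
#' @return Named list of [patient_timeline()] objects.
#' @export
read_prescriptions <- function(path, windows = NULL, ad_prefix = "N06A") {
  df <- read_checked_csv(path, c("patient_id", "drug_code", "dispense_date",
                                 "days_supply"))
  check_rows(path, df, "dispense_date", is_iso_date,
             "unparseable ISO date in `dispense_date`")
  check_rows(path, df, "days_supply",
             function(v) !is.na(suppressWarnings(as.numeric(v))) &
               suppressWarnings(as.numeric(v)) >= 1 &
               suppressWarnings(as.numeric(v)) == floor(suppressWarnings(as.numeric(v))),
             "`days_supply` must be a positive integer")
  df$dispense_date <- as.Date(df$dispense_date)
  df$days_supply <- as.integer(df$days_supply)
  if (is.character(windows) && length(windows) == 1L)
    windows <- read_windows(windows)
  if (is.null(windows) &&
      !all(c("observation_start", "observation_end") %in% names(df)))
    stop(sprintf(
      "%s: no observation windows: add observation_start/observation_end columns or pass `windows`",
      path), call. = FALSE)
  if (all(c("observation_start", "observation_end") %in% names(df))) {
    check_rows(path, df, "observation_start", is_iso_date,
               "unparseable ISO date in `observation_start`")
    check_rows(path, df, "observation_end", is_iso_date,
               "unparseable ISO date in `observation_end`")
    df$observation_start <- as.Date(df$observation_start)
    df$observation_end <- as.Date(df$observation_end)
  }
  tl <- as_timelines(df, windows = windows)
  for (i in seq_along(tl)) {
    rx <- tl[[i]]$prescriptions
    rx$antidepressant <- startsWith(rx$drug_code, ad_prefix)
    tl[[i]]$prescriptions <- rx
  }
  tl
}

read_windows <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "observation_start",
                                 "observation_end"))
  check_rows(path, df, "observation_start", is_iso_date,
             "unparseable ISO date in `observation_start`")
  check_rows(path, df, "observation_end", is_iso_date,
             "unparseable ISO date in `observation_end`")
  df$observation_start <- as.Date(df$observation_start)
  df$observation_end <- as.Date(df$observation_end)
  df
}

#' Read chart-review reference assessments from CSV
#'
#' Expected columns: `patient_id`, `reference_remission` (0 or 1), optional
#' `reason` free text recorded for discordant patients.
#'
#' @param path CSV file path.
#' @return `data.frame` with one row per patient, class `reference_assessments`.
#' @export
read_assessments <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "reference_remission"))
  check_rows(path, df, "reference_remission",
             function(v) v %in% c("0", "1", 0, 1),
             "`reference_remission` must be 0 or 1")
  if (anyDuplicated(df$patient_id)) {
    dup <- unique(df$patient_id[duplicated(df$patient_id)])
    stop(sprintf("%s: duplicated patient_id: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(df$patient_id),
                    reference_remission = as.integer(df$reference_remission),
                    reason = if ("reason" %in% names(df))
                      as.character(df$reason) else NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_assessments", "data.frame")
  out
}

#' Write / read remission calls
#'
#' Calls are serialised as CSV with columns `patient_id`, `label`,
#' `episode_start`, `treatment_end`, `rationale`; dates ISO-8601, empty when
#' no episode was found. `read_calls()` inverts `write_calls()` exactly.
#'
#' @param calls A `remission_calls` data.frame as returned by
#'   [classify_cohort()].
#' @param path Output CSV path.
#' @return `write_calls()` returns `path` invisibly; `read_calls()` returns
#'   the calls data.frame.
#' @export
write_calls <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  out <- data.frame(
    patient_id = as.character(calls$patient_id),
    label = as.character(calls$label),
    episode_start = ifelse(is.na(calls$episode_start), "",
                           format(calls$episode_start)),
    treatment_end = ifelse(is.na(calls$treatment_end), "",
                           format(calls$treatment_end)),
    rationale = as.character(calls$rationale),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_calls: cannot write ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "label", "episode_start",
                                 "treatment_end", "rationale"))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    label = as.character(df$label),
    episode_start = as.Date(ifelse(df$episode_start == "", NA,
                                   df$episode_start)),
    treatment_end = as.Date(ifelse(df$treatment_end == "", NA,
                                   df$treatment_end)),
    rationale = as.character(df$rationale),
    stringsAsFactors = FALSE
  )
  class(out) <- c("remission_calls", "data.frame")
  out
}

#' Write a synthetic cohort to the on-disk formats
#'
#' Writes `<prefix>_prescriptions.csv` (with embedded observation-window
#' columns) and `<prefix>_assessments.csv`, the two files
#' [read_prescriptions()] and [read_assessments()] consume.
#'
#' @param cohort List with elements `timelines` and `assessments`, as
#'   returned by [generate_cohort()] or [generate_exact_table()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  tabs <- timelines_to_tables(cohort$timelines)
  rx <- merge(tabs$rx, tabs$windows, by = "patient_id", all.x = TRUE)
  rx <- rx[order(patient_id, dispense_date, drug_code)]
  rx_path <- paste0(prefix, "_prescriptions.csv")
  as_path <- paste0(prefix, "_assessments.csv")
  out <- data.frame(
    patient_id = rx$patient_id, drug_code = rx$drug_code,
    dispense_date = format(rx$dispense_date),
    days_supply = rx$days_supply,
    observation_start = format(rx$observation_start),
    observation_end = format(rx$observation_end)
  )
  utils::write.csv(out, rx_path, row.names = FALSE, quote = FALSE)
  asm <- cohort$assessments
  utils::write.csv(
    data.frame(patient_id = asm$patient_id,
               reference_remission = asm$reference_remission,
               reason = ifelse(is.na(asm$reason), "", asm$reason)),
    as_path, row.names = FALSE, quote = FALSE)
  invisible(c(prescriptions = rx_path, assessments = as_path))
}

## ---- shared CSV helpers -------------------------------------------------

read_checked_csv <- function(path, required) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

## Row-level validation; line numbers count the header as line 1.
check_rows <- function(path, df, col, ok_fun, msg) {
  if (!nrow(df)) return(invisible())
  bad <- which(!ok_fun(df[[col]]))
  if (length(bad))
    stop(sprintf("%s: line %d: %s (value: %s)", path, bad[1L] + 1L, msg,
                 df[[col]][bad[1L]]), call. = FALSE)
  invisible()
}

is_iso_date <- function(v) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", v) &
    !is.na(suppressWarnings(as.Date(v, format = "%Y-%m-%d")))
}
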