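#' A single patient's prescription timeline
#'
#' Bundles every dispensation for one patient with the observation window in
#' which the registry can see them. Prescriptions are stored date-sorted; each
#' covers the half-open day interval `[dispense_date, dispense_date +
#' days_supply)`.
#'
#' @param patient_id Scalar identifier (coerced to character).
#' @param prescriptions `data.frame` with columns `drug_code` (character),
#'   `dispense_date` (`Date`) and `days_supply` (positive integer). May have
#'   zero rows.
#' @param observation_start,observation_end `Date`s delimiting the window;
#'   `observation_start < observation_end`. Dispense dates must fall inside
#'   the window.
#' @return An object of class `patient_timeline`.
#' @examples
#' patient_timeline(
#'   "p1",
#'   data.frame(drug_code = "N06AB06",
#'              dispense_date = as.Date("2004-03-01"), days_supply = 90L),
#'   as.Date("2003-06-01"), as.Date("2006-06-01")
#' )
#' @export
patient_timeline <- function(patient_id, prescriptions,
                             observation_start, observation_end) {
  patient_id <- as.character(patient_id)
  observation_start <- as.Date(observation_start)
  observation_end <- as.Date(observation_end)
  stopifnot(length(patient_id) == 1L, !is.na(patient_id),
            length(observation_start) == 1L, !is.na(observation_start),
            length(observation_end) == 1L, !is.na(observation_end))
  if (!observation_start < observation_end)
    stop("patient_timeline: observation_start must precede observation_end",
         call. = FALSE)
  need <- c("drug_code", "dispense_date", "days_supply")
  miss <- setdiff(need, names(prescriptions))
  if (length(miss))
    stop("patient_timeline: prescriptions lack column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  rx <- data.frame(
    drug_code = as.character(prescriptions$drug_code),
    dispense_date = as.Date(prescriptions$dispense_date),
    days_supply = as.integer(prescriptions$days_supply),
    stringsAsFactors = FALSE
  )
  if (nrow(rx)) {
    if (anyNA(rx$dispense_date))
      stop("patient_timeline: unparseable dispense_date", call. = FALSE)
    if (anyNA(rx$days_supply) || any(rx$days_supply < 1L))
      stop("patient_timeline: days_supply must be >= 1", call. = FALSE)
    if (any(rx$dispense_date < observation_start |
            rx$dispense_date >= observation_end))
      stop("patient_timeline: dispense_date outside observation window for ",
           patient_id, call. = FALSE)
    rx <- rx[order(rx$dispense_date, rx$drug_code, -rx$days_supply), ,
             drop = FALSE]
    rownames(rx) <- NULL
  }
  structure(
    list(patient_id = patient_id, prescriptions = rx,
         observation_start = observation_start,
         observation_end = observation_end),
    class = "patient_timeline"
  )
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<patient_timeline> %s: %d prescription(s), observed %s .. %s\n",
              x$patient_id, nrow(x$prescriptions),
              format(x$observation_start), format(x$observation_end)))
  if (nrow(x$prescriptions)) print(utils::head(x$prescriptions, 10L))
  invisible(x)
}

#' Build timelines from a long prescriptions table
#'
#' @param prescriptions `data.frame` with columns `patient_id`, `drug_code`,
#'   `dispense_date`, `days_supply`, and either `observation_start`/
#'   `observation_end` columns (constant within patient) or a separate
#'   `windows` table.
#' @param windows Optional `data.frame` with `patient_id`,
#'   `observation_start`, `observation_end`; overrides window columns in
#'   `prescriptions`.
#' @return Named list of [patient_timeline()] objects (one per patient,
#'   ordered by id).
#' @export
as_timelines <- function(prescriptions, windows = NULL) {
  df <- as.data.frame(prescriptions)
  if (is.null(windows)) {
    if (!all(c("observation_start", "observation_end") %in% names(df)))
      stop("as_timelines: need observation_start/observation_end columns ",
           "or a `windows` table", call. = FALSE)
    windows <- unique(df[c("patient_id", "observation_start",
                           "observation_end")])
    if (anyDuplicated(windows$patient_id))
      stop("as_timelines: observation window not constant within patient",
           call. = FALSE)
  }
  windows <- as.data.frame(windows)
  ids <- sort(unique(as.character(df$patient_id)))
  win_idx <- match(ids, as.character(windows$patient_id))
  if (anyNA(win_idx))
    stop("as_timelines: missing observation window for patient(s): ",
         paste(ids[is.na(win_idx)], collapse = ", "), call. = FALSE)
  out <- lapply(seq_along(ids), function(i) {
    rows <- df[as.character(df$patient_id) == ids[i], , drop = FALSE]
    patient_timeline(ids[i],
                     rows[c("drug_code", "dispense_date", "days_supply")],
                     windows$observation_start[win_idx[i]],
                     windows$observation_end[win_idx[i]])
  })
  names(out) <- ids
  out
}

## Long-format view used by the vectorised classifier: one data.table of
## prescriptions plus one of windows.
timelines_to_tables <- function(timelines) {
  if (inherits(timelines, "patient_timeline")) timelines <- list(timelines)
  stopifnot(all(vapply(timelines, inherits, TRUE, "patient_timeline")))
  win <- data.table::data.table(
    patient_id = vapply(timelines, `[[`, "", "patient_id"),
    observation_start = as.Date(
      vapply(timelines, function(t) as.character(t$observation_start), "")),
    observation_end = as.Date(
      vapply(timelines, function(t) as.character(t$observation_end), ""))
  )
  if (anyDuplicated(win$patient_id))
    stop("duplicate patient_id across timelines", call. = FALSE)
  rx_list <- lapply(timelines, function(t) {
    if (!nrow(t$prescriptions)) return(NULL)
    data.table::data.table(patient_id = t$patient_id, t$prescriptions)
  })
  rx <- data.table::rbindlist(rx_list)
  if (!nrow(rx))
    rx <- data.table::data.table(patient_id = character(),
                                 drug_code = character(),
                                 dispense_date = as.Date(character()),
                                 days_supply = integer())
  list(rx = rx, windows = win)
}
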