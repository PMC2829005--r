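## Episode detection and remission classification over dispensing records.
##
## All interval arithmetic is at day resolution on half-open coverage
## intervals [dispense_date, dispense_date + days_supply). A gap is the
## number of uncovered days between the running coverage end and the next
## dispense date.

RATIONALES <- c("NO_EPISODE", "INSUFFICIENT_WASHOUT_OBSERVATION",
                "MIN_TREATMENT_FAIL", "INSUFFICIENT_FOLLOWUP",
                "GAP_OBSERVED", "RESTART_WITHIN_GAP", "CENSORED")
LABELS <- c("REMISSION", "NO_REMISSION", "NOT_EVALUABLE")

## Core single-patient scan on numeric day offsets.
## d, s: antidepressant dispense days (sorted) and supplies; obs bounds numeric.
## Returns a list describing the index episode and the post-treatment gap.
episode_scan <- function(d, s, obs_start, obs_end, crit, detail = FALSE) {
  n <- length(d)
  if (n == 0L) return(list(status = "NO_EPISODE"))
  ## running coverage end after each prescription
  if (crit$stockpile) {
    cs <- numeric(n)
    cur <- -Inf
    for (j in seq_len(n)) cur <- cs[j] <- max(cur, d[j]) + s[j]
  } else {
    cs <- cummax(d + s)
  }
  prev <- c(-Inf, cs[-n])
  ## observed antidepressant-free days immediately before each dispense
  free <- d - pmax(obs_start, prev)
  i0 <- which(free >= crit$washout_days)[1L]
  if (is.na(i0)) return(list(status = "NO_WASHOUT"))

  idx <- if (i0 < n) (i0 + 1L):n else integer()
  gaps <- d[idx] - cs[idx - 1L]                 # uncovered days before rx j
  jpos <- idx[which(gaps > 0)[1L]]              # first treatment interruption
  jbrk <- idx[which(gaps >= crit$within_episode_gap_days)[1L]]  # episode end
  ep_last <- if (!is.na(jbrk)) jbrk - 1L else n
  ep_idx <- i0:ep_last
  in_ep <- idx[idx <= ep_last]
  inter <- (d[in_ep] - cs[in_ep - 1L])
  inter <- inter[inter > 0]
  episode_start <- d[i0]
  treatment_end <- cs[ep_last]
  covered_days <- treatment_end - episode_start - sum(inter)
  if (!is.na(jpos)) {
    anchor <- cs[jpos - 1L]                     # end of first treatment course
    restart <- d[jpos]
  } else {
    anchor <- treatment_end
    restart <- NA_real_
  }
  out <- list(status = "EPISODE", i0 = i0,
              episode_start = episode_start, treatment_end = treatment_end,
              covered_days = covered_days, interruptions = inter,
              anchor = anchor, restart = restart)
  if (detail) {
    ## coverage segments of the episode, split at interruptions
    pos <- in_ep[(d[in_ep] - cs[in_ep - 1L]) > 0]
    seg_start <- d[c(i0, pos)]
    seg_end <- c(cs[pos - 1L], treatment_end)
    out$segments <- cbind(start = seg_start, end = seg_end)
    out$interruption_intervals <-
      cbind(start = cs[pos - 1L], end = d[pos])
  }
  out
}

ad_rx <- function(timeline, crit) {
  rx <- timeline$prescriptions
  rx[startsWith(rx$drug_code, crit$ad_prefix), , drop = FALSE]
}

#' Detect the index treatment episode in one timeline
#'
#' The index episode starts at the earliest antidepressant prescription
#' preceded by at least `washout_days` of observed antidepressant-free time
#' (measured from the later of the observation start and the end of any
#' earlier antidepressant coverage). Later antidepressant prescriptions
#' separated from the running coverage by gaps shorter than
#' `within_episode_gap_days` extend the same episode; a gap at least that
#' long ends it.
#'
#' @param timeline A [patient_timeline()].
#' @param criteria An [episode_criteria()].
#' @return An object of class `episode` (list with `patient_id`,
#'   `episode_start`, `treatment_end`, `covered_days`, `segments`,
#'   `interruptions`), or `NULL` when the timeline contains no qualifying
#'   index prescription.
#' @examples
#' tl <- patient_timeline("p1",
#'   data.frame(drug_code = "N06AB06",
#'              dispense_date = as.Date("2003-01-01") + 200, days_supply = 90L),
#'   as.Date("2003-01-01"), as.Date("2006-01-01"))
#' detect_index_episode(tl, episode_criteria())
#' @export
detect_index_episode <- function(timeline, criteria = episode_criteria()) {
  stopifnot(inherits(timeline, "patient_timeline"))
  rx <- ad_rx(timeline, criteria)
  sc <- episode_scan(as.numeric(rx$dispense_date), as.numeric(rx$days_supply),
                     as.numeric(timeline$observation_start),
                     as.numeric(timeline$observation_end),
                     criteria, detail = TRUE)
  if (sc$status != "EPISODE") return(NULL)
  as_date <- function(x) as.Date(x, origin = "1970-01-01")
  structure(list(
    patient_id = timeline$patient_id,
    episode_start = as_date(sc$episode_start),
    treatment_end = as_date(sc$treatment_end),
    covered_days = as.integer(sc$covered_days),
    segments = data.frame(start = as_date(sc$segments[, "start"]),
                          end = as_date(sc$segments[, "end"])),
    interruptions = data.frame(
      start = as_date(sc$interruption_intervals[, "start"]),
      end = as_date(sc$interruption_intervals[, "end"]),
      days = as.integer(sc$interruption_intervals[, "end"] -
                          sc$interruption_intervals[, "start"]))
  ), class = "episode")
}

#' @export
print.episode <- function(x, ...) {
  cat(sprintf("<episode> %s: start %s, treatment end %s, %d covered day(s), %d interruption(s)\n",
              x$patient_id, format(x$episode_start), format(x$treatment_end),
              x$covered_days, nrow(x$interruptions)))
  invisible(x)
}

#' Eligibility filters for an index episode
#'
#' `meets_minimum_treatment()` is the strict rule that the episode must show
#' more than `min_treatment_days` covered days of antidepressant treatment.
#' `has_followup()` requires the observation window to extend at least
#' `followup_days` past the episode start.
#'
#' @param episode An `episode` from [detect_index_episode()].
#' @param timeline The patient's [patient_timeline()].
#' @param criteria An [episode_criteria()].
#' @return Logical scalar.
#' @export
meets_minimum_treatment <- function(episode, criteria = episode_criteria()) {
  stopifnot(inherits(episode, "episode"))
  episode$covered_days > criteria$min_treatment_days
}

#' @rdname meets_minimum_treatment
#' @export
has_followup <- function(episode, timeline, criteria = episode_criteria()) {
  stopifnot(inherits(episode, "episode"),
            inherits(timeline, "patient_timeline"))
  as.numeric(timeline$observation_end) -
    as.numeric(episode$episode_start) >= criteria$followup_days
}

## label/rationale from a completed scan; returns list(label, rationale, ...)
decide_call <- function(sc, obs_end, crit) {
  if (sc$status == "NO_EPISODE")
    return(list(label = "NOT_EVALUABLE", rationale = "NO_EPISODE"))
  if (sc$status == "NO_WASHOUT")
    return(list(label = "NOT_EVALUABLE",
                rationale = "INSUFFICIENT_WASHOUT_OBSERVATION"))
  if (!(sc$covered_days > crit$min_treatment_days))
    return(list(label = "NOT_EVALUABLE", rationale = "MIN_TREATMENT_FAIL"))
  if (!(obs_end - sc$episode_start >= crit$followup_days))
    return(list(label = "NOT_EVALUABLE", rationale = "INSUFFICIENT_FOLLOWUP"))
  if (!is.na(sc$restart)) {
    gap <- sc$restart - sc$anchor
    if (gap >= crit$remission_gap_days)
      list(label = "REMISSION", rationale = "GAP_OBSERVED", gap = gap)
    else
      list(label = "NO_REMISSION", rationale = "RESTART_WITHIN_GAP", gap = gap)
  } else {
    gap <- obs_end - sc$anchor
    if (gap >= crit$remission_gap_days)
      list(label = "REMISSION", rationale = "GAP_OBSERVED", gap = gap)
    else
      list(label = "NOT_EVALUABLE", rationale = "CENSORED", gap = gap)
  }
}

#' Classify one patient as in remission, not in remission, or not evaluable
#'
#' Applies, in order: episode detection (six observed antidepressant-free
#' months before the index prescription), the minimum-treatment filter
#' (strictly more than 60 covered days by default), the follow-up filter
#' (at least 540 days of observation from episode start), then the remission
#' rule: the patient is in remission when at least `remission_gap_days`
#' antidepressant-free days follow the end of the first treatment course
#' within the observation window; a new antidepressant dispensed sooner
#' means no sustained remission; a window ending sooner leaves the patient
#' censored.
#'
#' @param timeline A [patient_timeline()].
#' @param criteria An [episode_criteria()].
#' @return A `remission_call`: list with `patient_id`, `label` (one of
#'   `REMISSION`, `NO_REMISSION`, `NOT_EVALUABLE`), `rationale`, and the
#'   `episode` (or `NULL`).
#' @export
classify_remission <- function(timeline, criteria = episode_criteria()) {
  stopifnot(inherits(timeline, "patient_timeline"))
  rx <- ad_rx(timeline, criteria)
  sc <- episode_scan(as.numeric(rx$dispense_date), as.numeric(rx$days_supply),
                     as.numeric(timeline$observation_start),
                     as.numeric(timeline$observation_end),
                     criteria)
  dec <- decide_call(sc, as.numeric(timeline$observation_end), criteria)
  structure(list(
    patient_id = timeline$patient_id,
    label = dec$label,
    rationale = dec$rationale,
    episode = if (sc$status == "EPISODE")
      detect_index_episode(timeline, criteria) else NULL
  ), class = "remission_call")
}

#' @export
print.remission_call <- function(x, ...) {
  cat(sprintf("<remission_call> %s: %s (%s)\n",
              x$patient_id, x$label, x$rationale))
  if (!is.null(x$episode)) print(x$episode)
  invisible(x)
}

#' Classify a whole cohort and summarise remission prevalence
#'
#' @param timelines A list of [patient_timeline()] objects, or (for large
#'   simulated cohorts) a list with elements `rx` and `windows` in the long
#'   table layout produced by the synthetic generator.
#' @param criteria An [episode_criteria()].
#' @param conf_level Confidence level for the prevalence Wald interval.
#' @return A `remission_calls` data.frame (one row per patient: `patient_id`,
#'   `label`, `rationale`, `episode_start`, `treatment_end`, `covered_days`)
#'   with the prevalence summary attached as `attr(, "prevalence")`; see
#'   [cohort_prevalence()]. Prevalence is computed over evaluable patients
#'   only: `REMISSION / (REMISSION + NO_REMISSION)`.
#' @export
classify_cohort <- function(timelines, criteria = episode_criteria(),
                            conf_level = 0.95) {
  if (inherits(timelines, "patient_timeline"))
    timelines <- list(timelines)
  tabs <- if (is.list(timelines) && !is.null(timelines$rx) &&
              !is.null(timelines$windows)) {
    list(rx = data.table::as.data.table(timelines$rx),
         windows = data.table::as.data.table(timelines$windows))
  } else {
    timelines_to_tables(timelines)
  }
  win <- tabs$windows
  rx <- tabs$rx[startsWith(drug_code, criteria$ad_prefix)]
  data.table::setorder(rx, patient_id, dispense_date)
  ids <- win$patient_id
  ord <- order(ids)
  idf <- factor(rx$patient_id, levels = ids[ord])
  rows <- split(seq_len(nrow(rx)), idf)
  dd <- as.numeric(rx$dispense_date)
  ss <- as.numeric(rx$days_supply)
  ws <- as.numeric(win$observation_start)[ord]
  we <- as.numeric(win$observation_end)[ord]
  res <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    sc <- episode_scan(dd[r], ss[r], ws[k], we[k], criteria)
    dec <- decide_call(sc, we[k], criteria)
    res[[k]] <- c(match(dec$label, LABELS), match(dec$rationale, RATIONALES),
                  if (sc$status == "EPISODE")
                    c(sc$episode_start, sc$treatment_end, sc$covered_days)
                  else c(NA_real_, NA_real_, NA_real_))
  }
  m <- do.call(rbind, res)
  as_date <- function(x) as.Date(x, origin = "1970-01-01")
  calls <- data.frame(
    patient_id = ids[ord],
    label = LABELS[m[, 1L]],
    rationale = RATIONALES[m[, 2L]],
    episode_start = as_date(m[, 3L]),
    treatment_end = as_date(m[, 4L]),
    covered_days = as.integer(m[, 5L]),
    stringsAsFactors = FALSE
  )
  ## restore input order
  calls <- calls[match(ids, calls$patient_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("remission_calls", "data.frame")
  attr(calls, "prevalence") <- cohort_prevalence(calls, conf_level)
  calls
}

#' Remission prevalence among evaluable patients
#'
#' @param calls A `remission_calls` data.frame.
#' @param conf_level Confidence level for the Wald interval.
#' @return List with `n_remission`, `n_evaluable`, `n_not_evaluable`,
#'   `estimate` (proportion, `NA` when no patient is evaluable) and `ci`
#'   (Wald interval clamped to `[0, 1]`).
#' @export
cohort_prevalence <- function(calls, conf_level = 0.95) {
  k <- sum(calls$label == "REMISSION")
  m <- sum(calls$label %in% c("REMISSION", "NO_REMISSION"))
  if (m == 0L)
    return(list(n_remission = k, n_evaluable = 0L,
                n_not_evaluable = nrow(calls),
                estimate = NA_real_, ci = c(NA_real_, NA_real_)))
  list(n_remission = k, n_evaluable = m,
       n_not_evaluable = nrow(calls) - m,
       estimate = k / m,
       ci = prevalence_ci(k, m, conf_level = conf_level)$ci)
}

#' @export
print.remission_calls <- function(x, ...) {
  tab <- table(factor(x$label, levels = LABELS))
  cat(sprintf("<remission_calls> %d patient(s): %d remission, %d no remission, %d not evaluable\n",
              nrow(x), tab[["REMISSION"]], tab[["NO_REMISSION"]],
              tab[["NOT_EVALUABLE"]]))
  pv <- attr(x, "prevalence")
  if (!is.null(pv) && !is.na(pv$estimate))
    cat(sprintf("  prevalence among evaluable: %.1f%% (95%% CI %.1f - %.1f)\n",
                100 * pv$estimate, 100 * pv$ci[1], 100 * pv$ci[2]))
  invisible(x)
}
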