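#' Day-count thresholds for episode detection and remission
#'
#' All calendar logic in the classifier is parameterised by five day counts.
#' Month-based rules are fixed at 30 days per month, so the six-month washout
#' and remission gap default to 180 days and the 18-month follow-up to 540.
#'
#' @param washout_days Observed antidepressant-free days required immediately
#'   before a prescription for it to open a *new* episode. Default 180.
#' @param min_treatment_days Covered treatment days an episode must exceed
#'   (strictly) to be evaluable. Default 60, i.e. the rule is `> 60`.
#' @param followup_days Minimum days between episode start and the end of the
#'   observation window (inclusive rule, `>=`). Default 540.
#' @param remission_gap_days Antidepressant-free days after the end of
#'   treatment that define remission (inclusive rule, `>=`). Default 180.
#' @param within_episode_gap_days Gaps shorter than this join successive
#'   prescriptions into one episode; a gap at least this long ends the
#'   episode. Default 180, deliberately equal to `remission_gap_days` so a
#'   single six-month gap both ends an episode and defines remission.
#' @param ad_prefix Drug-code prefix identifying antidepressants; "N06A" is
#'   the ATC class for antidepressants.
#' @param stockpile If `TRUE`, overlapping dispensations are shifted forward
#'   so no supply is lost; if `FALSE` (default) coverage is the plain union
#'   of dispensing intervals and overlap days count once.
#'
#' @return An object of class `episode_criteria` (a validated named list).
#' @examples
#' episode_criteria()
#' episode_criteria(min_treatment_days = 90)
#' @export
episode_criteria <- function(washout_days = 180L,
                             min_treatment_days = 60L,
                             followup_days = 540L,
                             remission_gap_days = 180L,
                             within_episode_gap_days = 180L,
                             ad_prefix = "N06A",
                             stockpile = FALSE) {
  crit <- list(
    washout_days = as.integer(washout_days),
    min_treatment_days = as.integer(min_treatment_days),
    followup_days = as.integer(followup_days),
    remission_gap_days = as.integer(remission_gap_days),
    within_episode_gap_days = as.integer(within_episode_gap_days),
    ad_prefix = as.character(ad_prefix),
    stockpile = isTRUE(stockpile)
  )
  class(crit) <- "episode_criteria"
  validate_criteria(crit)
}

validate_criteria <- function(crit) {
  days <- c("washout_days", "min_treatment_days", "followup_days",
            "remission_gap_days", "within_episode_gap_days")
  for (f in days) {
    v <- crit[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L)
      stop(sprintf("episode_criteria: `%s` must be a single integer >= 1", f),
           call. = FALSE)
  }
  if (!nzchar(crit$ad_prefix))
    stop("episode_criteria: `ad_prefix` must be a non-empty string",
         call. = FALSE)
  crit
}

#' Read episode criteria from a YAML or JSON config file
#'
#' The file holds any subset of the fields of [episode_criteria()]; missing
#' fields keep their defaults, unknown fields are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `episode_criteria` object.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(episode_criteria))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown criteria field(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(episode_criteria, cfg)
}

#' @export
print.episode_criteria <- function(x, ...) {
  cat("Episode/remission criteria (days):\n")
  cat(sprintf("  washout %d | treatment > %d | follow-up >= %d | remission gap >= %d | within-episode gap < %d\n",
              x$washout_days, x$min_treatment_days, x$followup_days,
              x$remission_gap_days, x$within_episode_gap_days))
  cat(sprintf("  antidepressant prefix: %s; stockpiling: %s\n",
              x$ad_prefix, if (x$stockpile) "on" else "off"))
  invisible(x)
}
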