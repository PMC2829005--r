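## Synthetic pharmacy-claims generator.
##
## Emulates the population the classifier is designed for: adults starting a
## first antidepressant episode in a primary-care registry, observed over a
## fixed window, with a controllable true-remission prevalence and a
## controllable index-vs-reference misclassification structure. Timelines
## are built to be unambiguous under the boundary conventions: interrupted
## patients restart 30..179 days after the first course ends, remitting
## patients stay at least 30 days clear of the 180-day gap threshold.

AD_CODES <- c("N06AB03", "N06AB04", "N06AB05", "N06AB06", "N06AB10",
              "N06AX11", "N06AX16", "N06AA09")
NON_AD_CODES <- c("A02BC01", "C10AA01", "N02BE01", "B01AC06")

## discrepancy reasons and their observed frequencies among false positives
## (index says remission, chart review disagrees) and false negatives
FP_REASONS <- c("dysthymia" = 2, "recurrent depression" = 1,
                "adaptive disorder" = 1, "vital occurrence" = 1)
FN_REASONS <- c("dysthymia" = 4, "adaptive disorder" = 1,
                "recurrent depression" = 1)

#' Configuration of the synthetic cohort generator
#'
#' Defaults mirror the validation setting the package targets: a true
#' remission prevalence of 54.6%, an index rule that detects remission with
#' sensitivity 92.5% and specificity 90.6%, and a three-year observation
#' window.
#'
#' @param n_patients Number of patients (>= 1).
#' @param true_remission_prob Probability a patient is truly in remission
#'   (chart-review label 1). Default 0.546.
#' @param sensitivity_target Probability the prescription timeline is built
#'   so the classifier calls REMISSION given true remission. Default 0.925.
#' @param specificity_target Probability the timeline yields NO_REMISSION
#'   given true non-remission. Default 0.906.
#' @param observation_days Length of each patient's observation window.
#'   Default 1080.
#' @param supply_days_range Candidate days-supply values per dispensation.
#' @param start_date Calendar anchor for observation windows.
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients,
                             true_remission_prob = 0.546,
                             sensitivity_target = 0.925,
                             specificity_target = 0.906,
                             observation_days = 1080L,
                             supply_days_range = c(30L, 60L, 90L),
                             start_date = as.Date("2003-01-01"),
                             seed = 1L) {
  probs <- c(true_remission_prob, sensitivity_target, specificity_target)
  if (any(probs < 0 | probs > 1))
    stop("synthetic_config: probabilities must lie in [0, 1]", call. = FALSE)
  if (n_patients < 1L)
    stop("synthetic_config: n_patients must be >= 1", call. = FALSE)
  if (observation_days < 900L)
    stop("synthetic_config: observation_days must be >= 900 so that washout, ",
         "treatment, follow-up and the remission gap all fit", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 true_remission_prob = true_remission_prob,
                 sensitivity_target = sensitivity_target,
                 specificity_target = specificity_target,
                 observation_days = as.integer(observation_days),
                 supply_days_range = as.integer(supply_days_range),
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a cohort with a controlled misclassification structure
#'
#' Each patient draws a true clinical status (remission with probability
#' `true_remission_prob`); the prescription timeline is then constructed so
#' that the episode classifier reproduces the true status with probability
#' `sensitivity_target` (true remission) or `specificity_target` (true
#' non-remission). Chart-review labels equal the true status; discordant
#' patients carry a free-text discrepancy reason drawn with the observed
#' clinical frequencies.
#'
#' @param config A [synthetic_config()].
#' @param as One of `"timelines"` (default: list of [patient_timeline()])
#'   or `"tables"` (long `rx`/`windows` tables, cheaper for large cohorts;
#'   [classify_cohort()] accepts both).
#' @return List with elements `timelines`, `assessments` (data.frame with
#'   `patient_id`, `reference_remission`, `reason`), `truth` (data.frame
#'   with the intended classifier label per patient) and `seed`.
#' @export
generate_cohort <- function(config, as = c("timelines", "tables")) {
  stopifnot(inherits(config, "synthetic_config"))
  as <- match.arg(as)
  run_seeded(config$seed, {
    n <- config$n_patients
    truth <- stats::rbinom(n, 1L, config$true_remission_prob)
    correct <- ifelse(truth == 1L,
                      stats::rbinom(n, 1L, config$sensitivity_target),
                      stats::rbinom(n, 1L, config$specificity_target))
    alg_positive <- ifelse(truth == 1L, correct == 1L, correct == 0L)
    build_synthetic(alg_positive, truth, config, as)
  })
}

#' Generate a cohort reproducing an exact 2x2 validation table
#'
#' Constructs exactly `tp + fp + fn + tn` patients whose classifier labels
#' against reference labels reproduce the requested confusion table with
#' equality. Only dates, supplies and drug codes are randomised; the cell
#' assignment is deterministic.
#'
#' @param tp,fp,fn,tn Non-negative cell counts (index positive/reference
#'   positive, etc.).
#' @param seed Integer seed for the date/supply randomisation.
#' @param config Optional [synthetic_config()] supplying window geometry;
#'   its `n_patients` and probabilities are ignored.
#' @param as See [generate_cohort()].
#' @return As [generate_cohort()].
#' @examples
#' coh <- generate_exact_table(2, 1, 1, 2, seed = 7)
#' table(classify_cohort(coh$timelines)$label)
#' @export
generate_exact_table <- function(tp, fp, fn, tn, seed = 1L, config = NULL,
                                 as = c("timelines", "tables")) {
  as <- match.arg(as)
  cnt <- c(tp, fp, fn, tn)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("generate_exact_table: counts must be non-negative integers",
         call. = FALSE)
  n <- sum(cnt)
  if (is.null(config))
    config <- synthetic_config(n_patients = max(n, 1L), seed = seed)
  config$seed <- as.integer(seed)
  if (n == 0L)
    return(list(timelines = list(),
                assessments = empty_assessments(),
                truth = data.frame(patient_id = character(),
                                   algorithm_positive = logical(),
                                   reference_remission = integer()),
                seed = as.integer(seed)))
  alg_positive <- rep(c(TRUE, TRUE, FALSE, FALSE), cnt)
  truth <- rep(c(1L, 0L, 1L, 0L), cnt)
  run_seeded(seed, build_synthetic(alg_positive, truth, config, as))
}

empty_assessments <- function() {
  out <- data.frame(patient_id = character(),
                    reference_remission = integer(),
                    reason = character(), stringsAsFactors = FALSE)
  class(out) <- c("reference_assessments", "data.frame")
  out
}

## Vectorised timeline construction. Assumes an active RNG scope.
build_synthetic <- function(alg_positive, truth, config, as) {
  n <- length(alg_positive)
  ids <- sprintf("P%0*d", max(4L, nchar(n)), seq_len(n))
  obs_days <- config$observation_days
  supplies <- config$supply_days_range

  obs_start <- as.numeric(config$start_date) +
    sample.int(365L, n, replace = TRUE) - 1L
  obs_end <- obs_start + obs_days
  ## index prescription: washout satisfied with margin
  index <- obs_start + 180L + sample.int(61L, n, replace = TRUE) - 1L
  ## first treatment course: contiguous fills of one agent, > 60 covered days
  s1 <- supplies[sample.int(length(supplies), n, replace = TRUE)]
  target <- sample(90:270, n, replace = TRUE)
  k1 <- pmax(ceiling(target / s1), ceiling(61L / s1))
  anchor <- index + k1 * s1
  agent <- AD_CODES[sample.int(length(AD_CODES), n, replace = TRUE)]

  ## interrupted (classifier-negative) patients restart 30..179 days later
  gap <- sample(30:179, n, replace = TRUE)
  s2 <- supplies[sample.int(length(supplies), n, replace = TRUE)]
  k2 <- sample(1:2, n, replace = TRUE)

  rx1 <- data.table::data.table(
    patient = rep(seq_len(n), k1),
    fill = unlist(lapply(k1, seq_len), use.names = FALSE)
  )
  rx1[, `:=`(date = index[patient] + (fill - 1L) * s1[patient],
             supply = s1[patient], code = agent[patient])]

  neg <- which(!alg_positive)
  if (length(neg)) {
    rx2 <- data.table::data.table(
      patient = rep(neg, k2[neg]),
      fill = unlist(lapply(k2[neg], seq_len), use.names = FALSE)
    )
    rx2[, `:=`(date = anchor[patient] + gap[patient] +
                 (fill - 1L) * s2[patient],
               supply = s2[patient], code = agent[patient])]
  } else rx2 <- NULL

  ## unrelated co-medication noise for ~30% of patients
  noisy <- which(stats::runif(n) < 0.3)
  if (length(noisy)) {
    rx3 <- data.table::data.table(
      patient = noisy,
      fill = 1L,
      date = obs_start[noisy] +
        sample.int(obs_days - 30L, length(noisy), replace = TRUE) - 1L,
      supply = 30L,
      code = NON_AD_CODES[sample.int(length(NON_AD_CODES), length(noisy),
                                     replace = TRUE)]
    )
  } else rx3 <- NULL

  rx <- data.table::rbindlist(list(rx1, rx2, rx3), use.names = TRUE)
  rx <- data.table::data.table(
    patient_id = ids[rx$patient],
    drug_code = rx$code,
    dispense_date = as.Date(rx$date, origin = "1970-01-01"),
    days_supply = as.integer(rx$supply)
  )
  data.table::setorder(rx, patient_id, dispense_date, drug_code)
  windows <- data.table::data.table(
    patient_id = ids,
    observation_start = as.Date(obs_start, origin = "1970-01-01"),
    observation_end = as.Date(obs_end, origin = "1970-01-01")
  )

  reason <- rep(NA_character_, n)
  is_fp <- alg_positive & truth == 0L
  is_fn <- !alg_positive & truth == 1L
  if (any(is_fp))
    reason[is_fp] <- sample(names(FP_REASONS), sum(is_fp), replace = TRUE,
                            prob = FP_REASONS / sum(FP_REASONS))
  if (any(is_fn))
    reason[is_fn] <- sample(names(FN_REASONS), sum(is_fn), replace = TRUE,
                            prob = FN_REASONS / sum(FN_REASONS))
  assessments <- data.frame(patient_id = ids, reference_remission = truth,
                            reason = reason, stringsAsFactors = FALSE)
  class(assessments) <- c("reference_assessments", "data.frame")

  timelines <- if (as == "tables") list(rx = rx, windows = windows)
  else as_timelines(rx, windows)
  list(timelines = timelines, assessments = assessments,
       truth = data.frame(patient_id = ids,
                          algorithm_positive = alg_positive,
                          reference_remission = truth,
                          stringsAsFactors = FALSE),
       seed = as.integer(config$seed))
}
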