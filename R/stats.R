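## Diagnostic-validity statistics for a 2x2 index-test vs reference table.
##
## Orientation throughout: the "index test" is the database remission rule,
## the "reference" is the chart-review label;
##   tp = index positive & reference positive, fp = index positive & ref
##   negative, fn = index negative & ref positive, tn = both negative.

#' Cross-classify remission calls against reference assessments
#'
#' Builds the 2x2 table of the database rule (rows) against chart review
#' (columns). `NOT_EVALUABLE` calls are excluded from the table and counted
#' separately. Alternatively, pass the four counts directly.
#'
#' @param calls A `remission_calls` data.frame (from [classify_cohort()] or
#'   [read_calls()]). Omit when passing counts.
#' @param assessments A `reference_assessments` data.frame (from
#'   [read_assessments()]) or any data.frame with `patient_id` and
#'   `reference_remission`.
#' @param tp,fp,fn,tn Non-negative integer counts, used instead of
#'   `calls`/`assessments`.
#' @return An object of class `confusion_table`: list with `tp`, `fp`, `fn`,
#'   `tn`, `n`, `discordant`, `n_not_evaluable`.
#' @examples
#' confusion_table(tp = 74, fp = 5, fn = 6, tn = 48)
#' @export
confusion_table <- function(calls = NULL, assessments = NULL,
                            tp = NULL, fp = NULL, fn = NULL, tn = NULL) {
  if (!is.null(tp)) {
    cnt <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0) ||
        any(cnt != floor(cnt)))
      stop("confusion_table: tp/fp/fn/tn must be non-negative integers",
           call. = FALSE)
    return(new_confusion_table(tp, fp, fn, tn, 0L))
  }
  stopifnot(is.data.frame(calls), is.data.frame(assessments))
  ev <- calls[calls$label %in% c("REMISSION", "NO_REMISSION"), , drop = FALSE]
  idx <- match(ev$patient_id, assessments$patient_id)
  if (anyNA(idx))
    stop("confusion_table: no reference assessment for evaluable patient(s): ",
         paste(ev$patient_id[is.na(idx)], collapse = ", "), call. = FALSE)
  ref <- assessments$reference_remission[idx]
  pos <- ev$label == "REMISSION"
  new_confusion_table(sum(pos & ref == 1L), sum(pos & ref == 0L),
                      sum(!pos & ref == 1L), sum(!pos & ref == 0L),
                      nrow(calls) - nrow(ev))
}

new_confusion_table <- function(tp, fp, fn, tn, n_not_evaluable = 0L) {
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 n = as.integer(tp + fp + fn + tn),
                 discordant = as.integer(fp + fn),
                 n_not_evaluable = as.integer(n_not_evaluable)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> n = %d (+%d not evaluable), %d discordant\n",
              x$n, x$n_not_evaluable, x$discordant))
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("index positive", "index negative"),
                              c("ref positive", "ref negative")))
  print(m)
  invisible(x)
}

## ---- interval helpers ---------------------------------------------------

## round half away from zero (presentation convention for percentages)
round_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Wald interval on a proportion, clamped to [0, 1].
## `round_estimate` reproduces published tables computed from percentages
## already rounded to one decimal: that rounded value enters the SE.
wald_ci <- function(p, m, conf_level = 0.95, round_estimate = FALSE) {
  if (is.na(p) || m <= 0) return(c(NA_real_, NA_real_))
  pe <- if (round_estimate) round_away(100 * p, 1L) / 100 else p
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(pe * (1 - pe) / m)
  c(max(0, pe - half), min(1, pe + half))
}

## ---- validity measures --------------------------------------------------

#' Sensitivity, specificity and predictive values with Wald intervals
#'
#' Computes sensitivity `S = tp/(tp+fn)`, specificity `Sp = tn/(tn+fp)`,
#' positive and negative predictive value, and the false-positive (`1 - S`)
#' and false-negative (`1 - Sp`) rates. A statistic with a zero denominator
#' is reported as `NA`, not 0.
#'
#' Two interval conventions are offered. `"standard"` (default) puts each
#' statistic's own denominator in the Wald SE. `"paper_total_n"` replicates
#' a publication style sometimes seen in validation studies: the *total*
#' sample size enters every SE and the point estimate is first rounded to
#' one decimal percent; it is provided for faithful replication of published
#' tables, not as a recommendation.
#'
#' @param x A `confusion_table`.
#' @param ci_convention `"standard"` or `"paper_total_n"`.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with columns `statistic`, `estimate`, `lower`, `upper`
#'   (all proportions; percentages belong to presentation), with the
#'   convention stored in `attr(, "ci_convention")`.
#' @export
validity_measures <- function(x, ci_convention = c("standard", "paper_total_n"),
                              conf_level = 0.95) {
  stopifnot(inherits(x, "confusion_table"))
  ci_convention <- match.arg(ci_convention)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  est <- c(sensitivity = ratio(x$tp, x$tp + x$fn),
           specificity = ratio(x$tn, x$tn + x$fp),
           ppv = ratio(x$tp, x$tp + x$fp),
           npv = ratio(x$tn, x$tn + x$fn))
  est <- c(est,
           false_positive_rate = 1 - est[["sensitivity"]],
           false_negative_rate = 1 - est[["specificity"]])
  den <- c(x$tp + x$fn, x$tn + x$fp, x$tp + x$fp, x$tn + x$fn,
           x$tp + x$fn, x$tn + x$fp)
  m <- if (ci_convention == "paper_total_n") rep(x$n, 6L) else den
  ci <- t(vapply(seq_along(est), function(i)
    wald_ci(est[[i]], m[i], conf_level,
            round_estimate = ci_convention == "paper_total_n"),
    numeric(2)))
  out <- data.frame(statistic = names(est), estimate = unname(est),
                    lower = ci[, 1], upper = ci[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "ci_convention") <- ci_convention
  attr(out, "conf_level") <- conf_level
  out
}

#' Positive and negative likelihood ratios
#'
#' `PPR = S / (1 - Sp)` and `NPR = (1 - S) / Sp`: the factors by which a
#' positive or negative index result multiplies the pre-test odds. With a
#' perfect specificity the positive ratio is reported as `Inf`, not an error.
#'
#' @param x A `confusion_table`.
#' @return List with `ppr` and `npr`.
#' @export
likelihood_ratios <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  vm <- validity_measures(x)
  S <- vm$estimate[vm$statistic == "sensitivity"]
  Sp <- vm$estimate[vm$statistic == "specificity"]
  list(ppr = if (!is.na(Sp) && Sp == 1) Inf else S / (1 - Sp),
       npr = if (!is.na(Sp) && Sp == 0) Inf else (1 - S) / Sp)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement
#' `Po = (tp + tn)/n` and chance agreement `Pe` from the marginal products.
#' The default interval uses the large-sample standard error
#' `sqrt(Po(1 - Po)/n) / (1 - Pe)`; `se_method = "fleiss"` gives the
#' Fleiss-Cohen-Everitt non-null variance.
#'
#' @param x A `confusion_table` with `n >= 2`.
#' @param conf_level Confidence level.
#' @param se_method `"large_sample"` (default) or `"fleiss"`.
#' @return List with `estimate`, `se`, `ci` (clamped to `[-1, 1]`), `po`,
#'   `pe`.
#' @export
cohen_kappa <- function(x, conf_level = 0.95,
                        se_method = c("large_sample", "fleiss")) {
  stopifnot(inherits(x, "confusion_table"), x$n >= 2L)
  se_method <- match.arg(se_method)
  n <- x$n
  po <- (x$tp + x$tn) / n
  pe <- ((x$tp + x$fp) * (x$tp + x$fn) + (x$fn + x$tn) * (x$fp + x$tn)) / n^2
  if (pe == 1)
    return(list(estimate = NA_real_, se = NA_real_,
                ci = c(NA_real_, NA_real_), po = po, pe = pe))
  k <- (po - pe) / (1 - pe)
  se <- if (se_method == "large_sample") {
    sqrt(po * (1 - po) / n) / (1 - pe)
  } else {
    p <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE) / n
    pi_ <- rowSums(p); pj <- colSums(p)
    A <- p[1, 1] * (1 - (pi_[1] + pj[1]) * (1 - k))^2 +
      p[2, 2] * (1 - (pi_[2] + pj[2]) * (1 - k))^2
    B <- (1 - k)^2 * (p[1, 2] * (pi_[1] + pj[2])^2 +
                        p[2, 1] * (pi_[2] + pj[1])^2)
    C <- (k - pe * (1 - k))^2
    sqrt((A + B - C) / (n * (1 - pe)^2))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(estimate = k, se = se,
       ci = c(max(-1, k - z * se), min(1, k + z * se)), po = po, pe = pe)
}

#' Phi coefficient (Pearson correlation of two binary indicators)
#'
#' @param x A `confusion_table` with all four marginals positive (otherwise
#'   `NA`).
#' @return Numeric scalar.
#' @export
phi_coefficient <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  marg <- c(x$tp + x$fp, x$fn + x$tn, x$tp + x$fn, x$fp + x$tn)
  if (any(marg == 0)) return(NA_real_)
  (x$tp * x$tn - x$fp * x$fn) / sqrt(prod(marg))
}

#' Cronbach's alpha for the two dichotomous items of a 2x2 table
#'
#' Treats the index and reference labels as two 0/1 items and computes the
#' two-item alpha `2 * (1 - (v1 + v2) / v_total)` from population variances.
#' `NA` when either item has zero variance.
#'
#' @param x A `confusion_table` with `n >= 2`.
#' @return Numeric scalar.
#' @export
cronbach_alpha_binary <- function(x) {
  stopifnot(inherits(x, "confusion_table"), x$n >= 2L)
  n <- x$n
  p1 <- (x$tp + x$fp) / n           # index positive
  p2 <- (x$tp + x$fn) / n           # reference positive
  v1 <- p1 * (1 - p1)
  v2 <- p2 * (1 - p2)
  if (v1 == 0 || v2 == 0) return(NA_real_)
  cov12 <- x$tp / n - p1 * p2
  vt <- v1 + v2 + 2 * cov12
  2 * (1 - (v1 + v2) / vt)
}

#' McNemar's chi-square for systematic disagreement
#'
#' `chi2 = (|fp - fn| - c)^2 / (fp + fn)` with `c = 1` under the continuity
#' correction, referred to a chi-square with 1 df. When there are no
#' discordant pairs the statistic is 0 by convention.
#'
#' @param x A `confusion_table`.
#' @param continuity_correction Apply Edwards' correction (default `FALSE`).
#' @return List with `statistic` and `p_value`.
#' @export
mcnemar_chi2 <- function(x, continuity_correction = FALSE) {
  stopifnot(inherits(x, "confusion_table"))
  disc <- x$fp + x$fn
  if (disc == 0L) return(list(statistic = 0, p_value = 1))
  cc <- if (continuity_correction) 1 else 0
  stat <- (abs(x$fp - x$fn) - cc)^2 / disc
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Area under the curve of a single-threshold binary test
#'
#' The trapezoidal AUC through (0,0), (1-Sp, S), (1,1): `(S + Sp) / 2`.
#'
#' @param x A `confusion_table`.
#' @return Numeric scalar.
#' @export
binary_auc <- function(x) {
  stopifnot(inherits(x, "confusion_table"))
  vm <- validity_measures(x)
  (vm$estimate[vm$statistic == "sensitivity"] +
      vm$estimate[vm$statistic == "specificity"]) / 2
}

#' Sample size to estimate a prevalence with a Wald interval
#'
#' `n = ceil(z^2 p (1 - p) / d^2)` with `z` the bilateral normal quantile.
#'
#' @param prevalence Expected proportion `p` (0 < p < 1).
#' @param precision Half-width `d` of the interval (0 < d < 1).
#' @param alpha Bilateral type-I error (default 0.05, i.e. 95% interval).
#' @return Integer sample size.
#' @examples
#' sample_size_prevalence(0.54, 0.085)  # 133
#' @export
sample_size_prevalence <- function(prevalence, precision, alpha = 0.05) {
  stopifnot(prevalence > 0, prevalence < 1, precision > 0, precision < 1,
            alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * prevalence * (1 - prevalence) / precision^2))
}

#' Wald confidence interval for a prevalence
#'
#' @param k Number of positives (`0 <= k <= n`). May be omitted when `p` is
#'   given directly (e.g. to reproduce an interval computed from a rounded
#'   published percentage).
#' @param n Sample size.
#' @param conf_level Confidence level.
#' @param p Proportion; defaults to `k/n`.
#' @return List with `estimate` and `ci` (proportions, clamped to `[0, 1]`).
#' @examples
#' prevalence_ci(2496, 4572)
#' prevalence_ci(n = 4572, p = 0.546)
#' @export
prevalence_ci <- function(k = NULL, n, conf_level = 0.95, p = NULL) {
  stopifnot(n >= 1)
  if (is.null(p)) {
    stopifnot(!is.null(k), k >= 0, k <= n)
    p <- k / n
  }
  list(estimate = p, ci = wald_ci(p, n, conf_level))
}
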