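#' Full validity report for a database definition against chart review
#'
#' Bundles every statistic of a standard diagnostic-validation table:
#' validity (sensitivity, specificity, predictive values, false
#' positive/negative rates, all with Wald intervals), reliability
#' (Cronbach's alpha for the two dichotomous items, binary AUC), concordance
#' (Cohen's kappa with interval, phi/Pearson correlation, McNemar's test)
#' and clinical utility (positive and negative likelihood ratios).
#'
#' @param x A `confusion_table`, or a `remission_calls` data.frame (then
#'   `assessments` is required).
#' @param assessments Reference assessments, when `x` is a calls table.
#' @param ci_convention Passed to [validity_measures()].
#' @param conf_level Confidence level.
#' @param kappa_se Passed to [cohen_kappa()] as `se_method`.
#' @return An object of class `validity_report`.
#' @examples
#' validity_report(confusion_table(tp = 74, fp = 5, fn = 6, tn = 48),
#'                 ci_convention = "paper_total_n")
#' @export
validity_report <- function(x, assessments = NULL,
                            ci_convention = c("standard", "paper_total_n"),
                            conf_level = 0.95,
                            kappa_se = c("large_sample", "fleiss")) {
  ci_convention <- match.arg(ci_convention)
  kappa_se <- match.arg(kappa_se)
  ct <- if (inherits(x, "confusion_table")) x
  else confusion_table(x, assessments)
  structure(list(
    table = ct,
    measures = validity_measures(ct, ci_convention, conf_level),
    likelihood_ratios = likelihood_ratios(ct),
    kappa = cohen_kappa(ct, conf_level, kappa_se),
    phi = phi_coefficient(ct),
    cronbach_alpha = cronbach_alpha_binary(ct),
    auc = binary_auc(ct),
    mcnemar = mcnemar_chi2(ct),
    ci_convention = ci_convention,
    conf_level = conf_level
  ), class = "validity_report")
}

#' Flatten a validity report to a named numeric vector
#'
#' Proportion-type statistics are expressed as percentages (unrounded);
#' likelihood ratios and the McNemar statistic keep their natural scale.
#'
#' @param report A `validity_report`.
#' @return Named numeric vector.
#' @export
report_values <- function(report) {
  stopifnot(inherits(report, "validity_report"))
  m <- report$measures
  v <- stats::setNames(100 * m$estimate, m$statistic)
  ci <- stats::setNames(
    100 * as.numeric(rbind(m$lower, m$upper)),
    as.character(rbind(paste0(m$statistic, "_lower"),
                       paste0(m$statistic, "_upper"))))
  c(v, ci,
    kappa = 100 * report$kappa$estimate,
    kappa_lower = 100 * report$kappa$ci[1],
    kappa_upper = 100 * report$kappa$ci[2],
    phi = 100 * report$phi,
    cronbach_alpha = 100 * report$cronbach_alpha,
    auc = 100 * report$auc,
    ppr = report$likelihood_ratios$ppr,
    npr = report$likelihood_ratios$npr,
    mcnemar_chi2 = report$mcnemar$statistic,
    mcnemar_p = report$mcnemar$p_value,
    n = report$table$n,
    discordant = report$table$discordant)
}

#' @export
print.validity_report <- function(x, ...) {
  ct <- x$table
  p1 <- function(v) formatC(round_away(v, 1L), format = "f", digits = 1)
  cat(sprintf("Validity report (n = %d, %d discordant; CI convention: %s)\n",
              ct$n, ct$discordant, x$ci_convention))
  cat(sprintf("  index\\reference   positive  negative\n"))
  cat(sprintf("  positive          %8d  %8d\n", ct$tp, ct$fp))
  cat(sprintf("  negative          %8d  %8d\n\n", ct$fn, ct$tn))
  lab <- c(sensitivity = "Sensitivity", specificity = "Specificity",
           ppv = "Positive predictive value",
           npv = "Negative predictive value",
           false_positive_rate = "False positives",
           false_negative_rate = "False negatives")
  m <- x$measures
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-26s %5s%%  (%s - %s)\n", lab[[m$statistic[i]]],
                p1(100 * m$estimate[i]), p1(100 * m$lower[i]),
                p1(100 * m$upper[i])))
  cat(sprintf("  %-26s %5s%%\n", "Cronbach's alpha",
              p1(100 * x$cronbach_alpha)))
  cat(sprintf("  %-26s %5s%%\n", "Area under the curve", p1(100 * x$auc)))
  cat(sprintf("  %-26s %5s%%  (%s - %s)\n", "Kappa (Cohen)",
              p1(100 * x$kappa$estimate), p1(100 * x$kappa$ci[1]),
              p1(100 * x$kappa$ci[2])))
  cat(sprintf("  %-26s %5s%%\n", "Pearson correlation (phi)",
              p1(100 * x$phi)))
  cat(sprintf("  %-26s %5s   (p = %.3f)\n", "McNemar chi-square",
              p1(x$mcnemar$statistic), x$mcnemar$p_value))
  cat(sprintf("  %-26s %5s\n", "Positive likelihood ratio",
              p1(x$likelihood_ratios$ppr)))
  cat(sprintf("  %-26s %5s\n", "Negative likelihood ratio",
              p1(x$likelihood_ratios$npr)))
  invisible(x)
}
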