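t1 <- confusion_table(tp = 74, fp = 5, fn = 6, tn = 48)

test_that("confusion table is built from calls vs assessments", {
  calls <- make_calls(
    c("a", "b", "c", "d", "e"),
    c("REMISSION", "REMISSION", "NO_REMISSION", "NO_REMISSION",
      "NOT_EVALUABLE"),
    c("GAP_OBSERVED", "GAP_OBSERVED", "RESTART_WITHIN_GAP",
      "RESTART_WITHIN_GAP", "CENSORED"))
  asm <- data.frame(patient_id = c("a", "b", "c", "d", "e"),
                    reference_remission = c(1L, 0L, 1L, 0L, 1L))
  ct <- confusion_table(calls, asm)
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(1L, 1L, 1L, 1L))
  expect_equal(ct$n_not_evaluable, 1L)   # NOT_EVALUABLE outside the table
  expect_equal(ct$discordant, 2L)

  ## all-concordant toy table has no discordant cells
  calls4 <- calls[1:4, ]
  asm4 <- data.frame(patient_id = c("a", "b", "c", "d"),
                     reference_remission = c(1L, 1L, 0L, 0L))
  ct4 <- confusion_table(calls4, asm4)
  expect_equal(ct4$fp + ct4$fn, 0L)

  ## an evaluable call without an assessment names the patient
  expect_error(confusion_table(calls, asm[-2, ]), "\\bb\\b")
  expect_error(confusion_table(tp = 1, fp = -1, fn = 0, tn = 1),
               "non-negative")
})

test_that("validity measures reproduce the closed-form ratios", {
  vm <- validity_measures(t1)
  get <- function(s) vm$estimate[vm$statistic == s]
  expect_equal(get("sensitivity"), 74 / 80)
  expect_equal(get("specificity"), 48 / 53)
  expect_equal(get("ppv"), 74 / 79)
  expect_equal(get("npv"), 48 / 54)
  expect_equal(get("false_positive_rate"), 1 - 74 / 80)
  expect_equal(get("false_negative_rate"), 1 - 48 / 53)

  perfect <- validity_measures(confusion_table(tp = 10, fp = 0,
                                               fn = 0, tn = 10))
  expect_true(all(perfect$estimate[1:4] == 1))

  ## zero denominator: undefined, not zero
  degenerate <- validity_measures(confusion_table(tp = 5, fp = 3,
                                                  fn = 0, tn = 0))
  expect_true(is.na(degenerate$estimate[degenerate$statistic == "npv"]))
})

test_that("the two interval conventions differ in the SE denominator", {
  std <- validity_measures(t1, "standard")
  pap <- validity_measures(t1, "paper_total_n")
  s <- function(df, stat) df[df$statistic == stat, ]
  ## standard: own denominator (80 for sensitivity)
  expect_equal(s(std, "sensitivity")$upper,
               min(1, 74 / 80 + qnorm(0.975) * sqrt((74 / 80) * (6 / 80) / 80)))
  ## paper convention: total n and the 1-decimal-rounded estimate in the SE
  expect_equal(s(pap, "sensitivity")$lower,
               0.925 - qnorm(0.975) * sqrt(0.925 * 0.075 / 133))
  ## bounds stay inside [0, 1]
  tiny <- validity_measures(confusion_table(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_true(all(tiny$lower >= 0 & tiny$upper <= 1))
})

test_that("likelihood ratios match their definitions and edge cases", {
  lr <- likelihood_ratios(t1)
  expect_equal(round(lr$ppr, 1), 9.8)
  expect_equal(round(lr$npr, 1), 0.1)

  lr2 <- likelihood_ratios(confusion_table(tp = 9, fp = 1, fn = 1, tn = 9))
  expect_equal(lr2$ppr, 9)
  expect_equal(round(lr2$npr, 1), 0.1)

  ## uninformative test: S = 1 - Sp gives PPR of exactly 1
  lr3 <- likelihood_ratios(confusion_table(tp = 30, fp = 30, fn = 70, tn = 70))
  expect_equal(lr3$ppr, 1)

  ## perfect specificity: infinite, not an error
  expect_equal(likelihood_ratios(confusion_table(tp = 5, fp = 0,
                                                 fn = 5, tn = 5))$ppr, Inf)
})

test_that("kappa, phi and alpha behave at the classical anchors", {
  expect_equal(cohen_kappa(confusion_table(tp = 50, fp = 0,
                                           fn = 0, tn = 50))$estimate, 1)
  expect_equal(cohen_kappa(confusion_table(tp = 25, fp = 25,
                                           fn = 25, tn = 25))$estimate, 0)
  expect_equal(phi_coefficient(confusion_table(tp = 50, fp = 0,
                                               fn = 0, tn = 50)), 1)
  expect_equal(phi_coefficient(confusion_table(tp = 25, fp = 25,
                                               fn = 25, tn = 25)), 0)
  expect_equal(cronbach_alpha_binary(confusion_table(tp = 50, fp = 0,
                                                     fn = 0, tn = 50)), 1)
  ## zero marginal / zero item variance are undefined
  expect_true(is.na(phi_coefficient(confusion_table(tp = 5, fp = 5,
                                                    fn = 0, tn = 0))))
  expect_true(is.na(cronbach_alpha_binary(
    confusion_table(tp = 5, fp = 0, fn = 5, tn = 0))))
  ## the Fleiss SE option is close to (but distinct from) the default here
  k1 <- cohen_kappa(t1)
  k2 <- cohen_kappa(t1, se_method = "fleiss")
  expect_equal(k1$estimate, k2$estimate)
  expect_equal(k1$se, k2$se, tolerance = 0.05)
  expect_false(identical(k1$se, k2$se))
})

test_that("alpha reduces to 2r/(1+r) when the item variances are equal", {
  ct <- confusion_table(tp = 40, fp = 10, fn = 10, tn = 40)  # equal margins
  r <- phi_coefficient(ct)
  expect_equal(cronbach_alpha_binary(ct), 2 * r / (1 + r))
})

test_that("McNemar statistic handles correction and symmetric tables", {
  m <- mcnemar_chi2(t1)
  expect_equal(m$statistic, (5 - 6)^2 / 11)
  ## agrees with the base-R implementation on both variants
  base_m <- mcnemar.test(matrix(c(74, 5, 6, 48), 2, 2), correct = FALSE)
  expect_equal(m$statistic, unname(base_m$statistic))
  expect_equal(m$p_value, base_m$p.value)

  corr <- mcnemar_chi2(confusion_table(tp = 0, fp = 10, fn = 0, tn = 0),
                       continuity_correction = TRUE)
  expect_equal(corr$statistic, 8.1)

  sym <- mcnemar_chi2(confusion_table(tp = 10, fp = 4, fn = 4, tn = 10))
  expect_equal(sym$statistic, 0)
  expect_equal(mcnemar_chi2(confusion_table(tp = 9, fp = 0,
                                            fn = 0, tn = 9))$statistic, 0)
})

test_that("binary AUC is the mean of sensitivity and specificity", {
  expect_equal(binary_auc(t1), (74 / 80 + 48 / 53) / 2)
  expect_equal(binary_auc(confusion_table(tp = 9, fp = 0, fn = 0, tn = 9)), 1)
  expect_equal(binary_auc(confusion_table(tp = 30, fp = 30,
                                          fn = 70, tn = 70)), 0.5)
})

test_that("prevalence sample size matches the Wald formula", {
  expect_equal(sample_size_prevalence(0.54, 0.085), 133L)
  expect_equal(sample_size_prevalence(0.5, 0.05), 385L)
  ## precision approaching 1 needs almost no subjects
  expect_lte(sample_size_prevalence(0.5, 0.99), 1L)
  expect_error(sample_size_prevalence(0, 0.05))
})

test_that("prevalence interval is Wald with clamping", {
  ci <- prevalence_ci(50, 100)
  expect_equal(100 * ci$ci, c(40.2, 59.8), tolerance = 1e-3)
  expect_equal(prevalence_ci(0, 10)$ci[1], 0)   # clamped at zero
  expect_equal(prevalence_ci(10, 10)$ci[2], 1)  # clamped at one
  ## from integer counts the lower bound sits just under 53.15%
  ci2 <- prevalence_ci(2496, 4572)
  expect_equal(100 * ci2$ci, c(53.1500, 56.0364), tolerance = 1e-3)
  ## from the rounded published prevalence, the printed interval comes back
  ci3 <- prevalence_ci(n = 4572, p = 0.546)
  expect_equal(round(100 * ci3$ci, 1), c(53.2, 56.0))
})
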