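crit <- episode_criteria()

test_that("index episode detection follows the washout and joining rules", {
  ## single prescription at day 200, 90 days supply
  ep <- detect_index_episode(tl_days(200, 90), crit)
  expect_equal(ep$episode_start, DAY0 + 200)
  expect_equal(ep$treatment_end, DAY0 + 290)
  expect_equal(ep$covered_days, 90L)
  expect_equal(nrow(ep$interruptions), 0L)

  ## washout window not fully observed: day 30 < 180 days into observation
  expect_null(detect_index_episode(tl_days(30, 90), crit))

  ## gap of 70 days (< 180) joins two prescriptions into one episode
  ep <- detect_index_episode(tl_days(c(200, 300), c(30, 30)), crit)
  expect_equal(ep$episode_start, DAY0 + 200)
  expect_equal(ep$treatment_end, DAY0 + 330)
  expect_equal(ep$covered_days, 60L)
  expect_equal(ep$interruptions$days, 70L)
  expect_equal(nrow(ep$segments), 2L)

  ## a 180-day gap ends the episode; the later prescription is not joined
  ep <- detect_index_episode(tl_days(c(200, 470), c(90, 30)), crit)
  expect_equal(ep$treatment_end, DAY0 + 290)
  expect_equal(ep$covered_days, 90L)

  ## a prescription failing washout does not block a later clean index
  ep <- detect_index_episode(tl_days(c(30, 400), c(30, 90)), crit)
  expect_equal(ep$episode_start, DAY0 + 400)
})

test_that("overlapping dispensations count covered days once", {
  ## 60-day overlap: union is 120 days, not 180
  ep <- detect_index_episode(tl_days(c(200, 230), c(90, 90)), crit)
  expect_equal(ep$covered_days, 120L)
  expect_equal(ep$treatment_end, DAY0 + 320)
  ## with stockpiling enabled the overlap is carried forward
  ep2 <- detect_index_episode(tl_days(c(200, 230), c(90, 90)),
                              episode_criteria(stockpile = TRUE))
  expect_equal(ep2$covered_days, 180L)
  expect_equal(ep2$treatment_end, DAY0 + 380)
})

test_that("minimum-treatment filter is strict and follow-up is inclusive", {
  ep <- function(covered) detect_index_episode(tl_days(200, covered), crit)
  expect_true(meets_minimum_treatment(ep(90), crit))
  expect_false(meets_minimum_treatment(ep(60), crit))
  expect_true(meets_minimum_treatment(ep(61), crit))

  tl540 <- tl_days(0, 90, obs = c(-200, 540))  # episode starts day 0
  e <- detect_index_episode(tl540, crit)
  expect_true(has_followup(e, tl540, crit))
  tl539 <- tl_days(0, 90, obs = c(-200, 539))
  expect_false(has_followup(detect_index_episode(tl539, crit), tl539, crit))
})

test_that("remission labels follow the post-treatment gap", {
  ## treatment ends day 290; no further antidepressant before day 800
  call <- classify_remission(tl_days(200, 90, obs = c(0, 800)), crit)
  expect_equal(call$label, "REMISSION")
  expect_equal(call$rationale, "GAP_OBSERVED")

  ## restart 110 days after treatment end: interruption too short
  call <- classify_remission(
    tl_days(c(200, 400, 490, 580), c(90, 90, 90, 90), obs = c(0, 800)), crit)
  expect_equal(call$label, "NO_REMISSION")
  expect_equal(call$rationale, "RESTART_WITHIN_GAP")

  ## restart exactly at the 180-day boundary is a new episode, so remission
  call <- classify_remission(tl_days(c(200, 470), c(90, 30),
                                     obs = c(0, 800)), crit)
  expect_equal(call$label, "REMISSION")

  ## observation ends before the six-month gap can be observed
  long_course <- tl_days(seq(180, 690, by = 30), 30, obs = c(0, 899))
  call <- classify_remission(long_course, crit)
  expect_equal(call$label, "NOT_EVALUABLE")
  expect_equal(call$rationale, "CENSORED")
  ## one more observed day reaches the 180-day gap exactly
  long_course2 <- tl_days(seq(180, 690, by = 30), 30, obs = c(0, 900))
  expect_equal(classify_remission(long_course2, crit)$label, "REMISSION")
})

test_that("eligibility failures yield NOT_EVALUABLE with the right rationale", {
  expect_call <- function(tl, label, rationale) {
    call <- classify_remission(tl, crit)
    expect_equal(call$label, label)
    expect_equal(call$rationale, rationale)
  }
  expect_call(tl_days(numeric(), integer()),
              "NOT_EVALUABLE", "NO_EPISODE")
  expect_call(tl_days(400, 90, codes = "A02BC01"),    # nothing antidepressant
              "NOT_EVALUABLE", "NO_EPISODE")
  expect_call(tl_days(30, 90), "NOT_EVALUABLE",
              "INSUFFICIENT_WASHOUT_OBSERVATION")
  expect_call(tl_days(200, 60, obs = c(0, 1080)),     # 60 days not > 60
              "NOT_EVALUABLE", "MIN_TREATMENT_FAIL")
  expect_call(tl_days(200, 90, obs = c(0, 700)),      # 500 days follow-up
              "NOT_EVALUABLE", "INSUFFICIENT_FOLLOWUP")
  ## label/rationale pairing invariant
  call <- classify_remission(tl_days(200, 90, obs = c(0, 800)), crit)
  expect_true(call$label != "NOT_EVALUABLE" ||
                call$rationale %in% c("NO_EPISODE",
                                      "INSUFFICIENT_WASHOUT_OBSERVATION",
                                      "MIN_TREATMENT_FAIL",
                                      "INSUFFICIENT_FOLLOWUP", "CENSORED"))
})

test_that("cohort classification aggregates calls and prevalence", {
  tls <- c(
    lapply(1:6, function(i) tl_days(200, 90, obs = c(0, 800),
                                    id = paste0("r", i))),
    lapply(1:4, function(i) tl_days(c(200, 400, 490), c(90, 90, 300),
                                    obs = c(0, 1080), id = paste0("n", i)))
  )
  calls <- classify_cohort(tls, crit)
  expect_s3_class(calls, "remission_calls")
  expect_equal(sum(calls$label == "REMISSION"), 6L)
  expect_equal(sum(calls$label == "NO_REMISSION"), 4L)
  pv <- attr(calls, "prevalence")
  expect_equal(pv$estimate, 0.6)
  expect_equal(pv$n_evaluable, 10L)

  ## degenerate cohort: nothing evaluable, prevalence undefined
  calls2 <- classify_cohort(list(tl_days(30, 90, id = "x"),
                                 tl_days(numeric(), integer(), id = "y")),
                            crit)
  expect_true(all(calls2$label == "NOT_EVALUABLE"))
  expect_true(is.na(attr(calls2, "prevalence")$estimate))
})

test_that("single-patient and cohort paths agree", {
  set.seed(404)
  for (i in 1:25) {
    tl <- random_timeline(id = sprintf("p%02d", i))
    one <- classify_remission(tl, crit)
    coh <- classify_cohort(list(tl), crit)
    expect_equal(coh$label, one$label)
    expect_equal(coh$rationale, one$rationale)
  }
})
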