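## Shared fixture builders. All toy timelines are specified in day offsets
## from a common origin so tests read like the hand-traces they encode.

DAY0 <- as.Date("2003-01-01")

## timeline from parallel vectors of day offsets and supplies
tl_days <- function(days, supplies, obs = c(0, 1080), id = "p1",
                    codes = "N06AB06") {
  rx <- data.frame(drug_code = rep_len(codes, length(days)),
                   dispense_date = DAY0 + days,
                   days_supply = as.integer(supplies))
  if (!length(days))
    rx <- data.frame(drug_code = character(),
                     dispense_date = as.Date(character()),
                     days_supply = integer())
  patient_timeline(id, rx, DAY0 + obs[1], DAY0 + obs[2])
}

## remission_calls row constructor for io tests
make_calls <- function(ids, labels, rationales,
                       episode_start = rep(NA_real_, length(ids)),
                       treatment_end = rep(NA_real_, length(ids))) {
  out <- data.frame(patient_id = ids, label = labels,
                    rationale = rationales,
                    episode_start = DAY0 + episode_start,
                    treatment_end = DAY0 + treatment_end,
                    stringsAsFactors = FALSE)
  class(out) <- c("remission_calls", "data.frame")
  out
}

## presentation rounding used in published tables: half away from zero, 1 dp
round_to_1dp <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

## random small timeline for property tests (active RNG scope)
random_timeline <- function(id = "p", max_rx = 4L, grid = 900L) {
  n <- sample(0:max_rx, 1L)
  days <- sort(sample(0:(grid - 120L), n))
  supplies <- sample(c(7L, 14L, 30L, 60L, 90L, 180L), n, replace = TRUE)
  codes <- sample(c("N06AB06", "N06AX16", "A02BC01"), n, replace = TRUE)
  tl_days(days, supplies, obs = c(0, grid), id = id, codes = codes)
}
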