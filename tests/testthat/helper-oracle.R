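## Independent oracles.
##
## `oracle_classify()` re-derives the remission label by brute force on a
## day-by-day boolean coverage grid — no interval arithmetic shared with the
## implementation. The statistics oracles recompute kappa, phi and alpha
## from expanded 0/1 label vectors rather than closed-form table formulas.

oracle_classify <- function(timeline, crit = episode_criteria()) {
  stopifnot(!crit$stockpile)
  obs_s <- as.numeric(timeline$observation_start)
  obs_e <- as.numeric(timeline$observation_end)
  rx <- timeline$prescriptions
  rx <- rx[startsWith(rx$drug_code, crit$ad_prefix), , drop = FALSE]
  if (!nrow(rx))
    return(list(label = "NOT_EVALUABLE", rationale = "NO_EPISODE",
                covered_days = NA_integer_))
  d <- as.numeric(rx$dispense_date)
  s <- as.numeric(rx$days_supply)
  horizon <- max(obs_e, max(d + s)) + 1
  len <- horizon - obs_s
  covered <- rep(FALSE, len)
  dispensed <- rep(FALSE, len)
  pos <- function(day) day - obs_s + 1          # grid position of a calendar day
  for (i in seq_along(d)) {
    covered[pos(d[i]):(pos(d[i] + s[i]) - 1)] <- TRUE
    dispensed[pos(d[i])] <- TRUE
  }

  ## index: first dispense day whose full washout window is observed and
  ## antidepressant-free
  index_day <- NA
  for (x in sort(unique(d))) {
    if (x - crit$washout_days < obs_s) next
    win <- pos(x - crit$washout_days):(pos(x) - 1)
    if (!any(covered[win])) { index_day <- x; break }
  }
  if (is.na(index_day))
    return(list(label = "NOT_EVALUABLE",
                rationale = "INSUFFICIENT_WASHOUT_OBSERVATION",
                covered_days = NA_integer_))

  p0 <- pos(index_day)
  ## walk covered/uncovered runs from the index to delimit the episode
  runs <- rle(covered[p0:len])
  covered_days <- 0L
  cursor <- p0
  last_covered_end <- p0                         # day-after-last-covered-day
  for (j in seq_along(runs$lengths)) {
    l <- runs$lengths[j]
    if (runs$values[j]) {
      covered_days <- covered_days + l
      last_covered_end <- cursor + l
    } else {
      is_final <- j == length(runs$lengths)
      if (is_final || l >= crit$within_episode_gap_days) break
    }
    cursor <- cursor + l
  }

  ## anchor: first uncovered day after the index
  a <- p0 + which(!covered[p0:len])[1] - 1
  anchor_day <- obs_s + a - 1
  later <- which(dispensed & seq_len(len) >= a)
  if (!(covered_days > crit$min_treatment_days))
    return(list(label = "NOT_EVALUABLE", rationale = "MIN_TREATMENT_FAIL",
                covered_days = covered_days))
  if (!(obs_e - index_day >= crit$followup_days))
    return(list(label = "NOT_EVALUABLE", rationale = "INSUFFICIENT_FOLLOWUP",
                covered_days = covered_days))
  if (length(later)) {
    gap <- (obs_s + later[1] - 1) - anchor_day
    if (gap >= crit$remission_gap_days)
      return(list(label = "REMISSION", rationale = "GAP_OBSERVED",
                  covered_days = covered_days))
    return(list(label = "NO_REMISSION", rationale = "RESTART_WITHIN_GAP",
                covered_days = covered_days))
  }
  if (obs_e - anchor_day >= crit$remission_gap_days)
    return(list(label = "REMISSION", rationale = "GAP_OBSERVED",
                covered_days = covered_days))
  list(label = "NOT_EVALUABLE", rationale = "CENSORED",
       covered_days = covered_days)
}

## ---- statistics oracles on expanded label vectors -----------------------

expand_table <- function(tp, fp, fn, tn) {
  list(index = c(rep(1, tp + fp), rep(0, fn + tn)),
       ref = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn)))
}

pop_var <- function(v) mean((v - mean(v))^2)

kappa_oracle <- function(x, y) {
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(1 - x) * mean(1 - y)
  (po - pe) / (1 - pe)
}

phi_oracle <- function(x, y) stats::cor(x, y)

alpha_oracle <- function(x, y) 2 * (1 - (pop_var(x) + pop_var(y)) / pop_var(x + y))

random_confusion <- function(max_n = 500L) {
  repeat {
    cnt <- as.vector(stats::rmultinom(1, sample(4:max_n, 1),
                                      prob = stats::runif(4, 0.05, 1)))
    ## all margins positive so every statistic is defined
    if (all(c(cnt[1] + cnt[2], cnt[3] + cnt[4],
              cnt[1] + cnt[3], cnt[2] + cnt[4]) > 0))
      return(confusion_table(tp = cnt[1], fp = cnt[2],
                             fn = cnt[3], tn = cnt[4]))
  }
}
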