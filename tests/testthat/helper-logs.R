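# Minimal engagement log with prescribed ITIs (minutes) and correctness,
# already scored; used to probe binning and trend analyses directly.
logWithItis <- function(itiMinutes, correct = TRUE, pid = "T1",
                        config = phasePreset("phase1")) {
  n <- length(itiMinutes) + 1L
  t <- cumsum(c(0, itiMinutes * 60))
  idx <- seq_len(n) - 1L
  sched <- scheduledSide(idx, config@alternationRule, "L")
  correct <- rep_len(correct, n - 1L)
  resp <- sched
  other <- ifelse(sched == "L", "R", "L")
  resp[-1][!correct] <- other[-1][!correct]
  rec <- data.frame(
    participant_id = pid, engagement_time = t, iti = c(NA, diff(t)),
    trial_index = idx, scheduled_side = sched, alternation_response = resp,
    alternation_correct = NA, stay_shift_label = NA_character_,
    change_state = "none", image_response = "", image_correct = NA,
    error_class = NA_character_, feedback_given = NA,
    stringsAsFactors = FALSE)
  scoreEngagements(rec, config, startSide = "L")
}

# Evenly spaced log: `perDay` engagements per day for `days` days, with a
# per-day accuracy function; independent of the package's simulator.
gridLogDaily <- function(pid, days, perDay, accuracyByDay = function(d) 1,
                        config = phasePreset("phase1")) {
  t <- as.vector(vapply(seq_len(days), function(d)
    (d - 1) * 86400 + seq_len(perDay) * 600, numeric(perDay)))
  n <- length(t)
  idx <- seq_len(n) - 1L
  day <- rep(seq_len(days), each = perDay)
  sched <- scheduledSide(idx, config@alternationRule, "L")
  other <- ifelse(sched == "L", "R", "L")
  acc <- vapply(day, accuracyByDay, 0)
  good <- stats::runif(n) < acc
  rec <- data.frame(
    participant_id = pid, engagement_time = t, iti = c(NA, diff(t)),
    trial_index = idx, scheduled_side = sched,
    alternation_response = ifelse(good, sched, other),
    alternation_correct = NA, stay_shift_label = NA_character_,
    change_state = "none", image_response = "", image_correct = NA,
    error_class = NA_character_, feedback_given = NA,
    stringsAsFactors = FALSE)
  scoreEngagements(rec, config, startSide = "L")
}
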