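# Canonical ITI bin edges in minutes: <2, 2-5, 5-10, 10-30, 30-330.
BIN_EDGES_MIN <- c(0, 2, 5, 10, 30, 330)

#' Study day of a timestamp
#'
#' A "day" is a 24 h window counted from study start (not calendar
#' midnight); the first day is day 1.
#'
#' @param time seconds since study start.
#' @return integer day index.
#' @export
dayIndex <- function(time) as.integer(floor(time / 86400)) + 1L

.asRecords <- function(x) {
  if (is(x, "LogBundle")) engagementRecords(x) else x
}

#' ITI-binned performance curve
#'
#' Assigns every alternation trial with a defined inter-trial interval to
#' one of the five canonical ITI bins (<2, 2-5, 5-10, 10-30, 30-330
#' minutes; intervals left-open, right-closed) and reports per-bin accuracy,
#' sample count and the median ITI as the bin position. First trials (no
#' ITI) and gaps beyond the 5.5 h ceiling are excluded and counted in
#' `nExcluded`. Bins with 100 or fewer trials are flagged as under-sampled
#' but reported.
#'
#' @param records scored engagement records or a [LogBundle-class].
#' @param task "alternation" (all trials), "stay" or "shift" (the win-stay /
#'   win-shift components of the double-alternation rule).
#' @param groupLabel annotation carried on the curve.
#' @return a [PerformanceCurve-class].
#' @examples
#' b <- simulateCohort(c(older = 2), phasePreset("phase1"), seed = 1)
#' binPerformance(b)
#' @export
binPerformance <- function(records, task = c("alternation", "stay", "shift"),
                           groupLabel = "all") {
  task <- match.arg(task)
  records <- .asRecords(records)
  if (!nrow(records)) stop("no records to bin", call. = FALSE)
  if (task != "alternation")
    records <- records[records$stay_shift_label == task, , drop = FALSE]
  itiMin <- records$iti / 60
  ok <- !is.na(itiMin) & itiMin > 0 & itiMin <= 330
  nExcluded <- sum(!ok)
  itiMin <- itiMin[ok]
  correct <- records$alternation_correct[ok]
  bin <- findInterval(itiMin, BIN_EDGES_MIN, left.open = TRUE)
  nPerBin <- tabulate(bin, 5L)
  acc <- pos <- rep(NA_real_, 5L)
  for (b in which(nPerBin > 0L)) {
    acc[b] <- mean(correct[bin == b])
    pos[b] <- stats::median(itiMin[bin == b])
  }
  new("PerformanceCurve", binEdges = BIN_EDGES_MIN, binPositions = pos,
      nPerBin = nPerBin, accuracyPerBin = acc,
      underSampled = nPerBin <= 100L, nExcluded = as.integer(nExcluded),
      groupLabel = groupLabel)
}

#' Per-participant inclusion report
#'
#' Applies the study's inclusion criteria to each participant:
#' \itemize{
#'   \item alternation criterion: at least `inclusionMinDays` active days
#'     (days with any engagement; 42 of 56 by default, the "6 out of 8
#'     weeks" rule) and strictly more than `inclusionMinDaily` engagements
#'     per active day on average (>10 by default);
#'   \item image criterion: the alternation criterion plus strictly more
#'     than 10 engagements bearing an image-recognition change (l-IR, r-IR,
#'     d-IR) and more than 10 bearing a visuospatial swap;
#'   \item outlier screen: mean alternation accuracy across all ITIs
#'     strictly above `outlierHigh` (external-reminder suspects) or
#'     strictly below `outlierLow` (random-press suspects).
#' }
#' `dailyRule = "per-day"` switches the daily criterion to requiring
#' `inclusionMinDays` individual days each with strictly more than
#' `inclusionMinDaily` engagements.
#'
#' @param records scored records or a [LogBundle-class].
#' @param config a [StudyConfig-class].
#' @param dailyRule "mean" (default) or "per-day".
#' @return data.frame, one row per participant: `participant_id`,
#'   `active_days`, `mean_daily_engagements`, `ir_count`, `vs_count`,
#'   `mean_performance`, `pass_alternation`, `pass_image`, `outlier_class`,
#'   `overall_included`.
#' @export
applyInclusionCriteria <- function(records, config,
                                   dailyRule = c("mean", "per-day")) {
  dailyRule <- match.arg(dailyRule)
  records <- .asRecords(records)
  if (!nrow(records)) stop("no records", call. = FALSE)
  sp <- split(records, records$participant_id)
  rows <- lapply(sp, function(r) {
    dayCounts <- table(dayIndex(r$engagement_time))
    activeDays <- length(dayCounts)
    meanDaily <- nrow(r) / activeDays
    scored <- !is.na(r$iti)
    data.frame(
      participant_id = r$participant_id[1],
      active_days = activeDays,
      mean_daily_engagements = meanDaily,
      ir_count = sum(r$change_state %in% c("l-IR", "r-IR", "d-IR")),
      vs_count = sum(r$change_state == "VS"),
      mean_performance = if (any(scored)) mean(r$alternation_correct[scored])
                         else NA_real_,
      pass_alternation = activeDays >= config@inclusionMinDays &&
        (if (dailyRule == "mean") meanDaily > config@inclusionMinDaily
         else sum(dayCounts > config@inclusionMinDaily) >= config@inclusionMinDays),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pass_image <- out$pass_alternation & out$ir_count > 10 & out$vs_count > 10
  out$outlier_class <- flagOutliers(out$mean_performance, config)
  out$overall_included <- out$pass_alternation & out$outlier_class == "none"
  out
}

#' Performance outlier classification
#'
#' Strictly-above-high / strictly-below-low classification of mean
#' alternation performance across all ITIs: above 90% suggests external
#' reminders, below 60% suggests mostly random pressing; values at the
#' thresholds are not outliers.
#'
#' @param meanPerformance proportions in [0,1] (NA allowed).
#' @param config a [StudyConfig-class] carrying the thresholds.
#' @return character vector over "none", "high", "low".
#' @examples
#' flagOutliers(c(0.95, 0.90, 0.59), phasePreset("phase1"))
#' @export
flagOutliers <- function(meanPerformance, config) {
  out <- rep("none", length(meanPerformance))
  out[!is.na(meanPerformance) & meanPerformance > config@outlierHigh] <- "high"
  out[!is.na(meanPerformance) & meanPerformance < config@outlierLow] <- "low"
  out
}

#' Cohort adherence surface
#'
#' For every combination of a duration requirement (weeks of engagement,
#' interpreted cumulatively: `w` weeks means at least `7 w` active days
#' anywhere in the study) and a strict daily-engagement threshold, the
#' fraction of the cohort meeting both. The surface is non-increasing along
#' both axes by construction (the qualifying sets are nested).
#'
#' @param records scored records or a [LogBundle-class].
#' @param weeks integer vector of required weeks.
#' @param thresholds numeric vector of strict mean-daily-engagement
#'   thresholds.
#' @return an [AdherenceSurface-class].
#' @export
adherenceSurface <- function(records, weeks = 1:8,
                             thresholds = seq(4, 20, by = 2)) {
  records <- .asRecords(records)
  if (!nrow(records)) stop("no records", call. = FALSE)
  sp <- split(records, records$participant_id)
  activeDays <- vapply(sp, function(r)
    length(unique(dayIndex(r$engagement_time))), 0L)
  meanDaily <- vapply(sp, nrow, 0L) / activeDays
  m <- outer(weeks, thresholds, Vectorize(function(w, th)
    mean(activeDays >= 7 * w & meanDaily > th)))
  new("AdherenceSurface", weeks = as.integer(weeks),
      thresholds = as.numeric(thresholds), surface = m,
      nParticipants = length(sp))
}

#' First-day performance and minimal-criteria adherence
#'
#' Restricts the cohort to first-day records of participants who engaged at
#' least twice on day 1, returns the day-1 ITI performance curve, and the
#' fraction of those eligible participants with strictly more than
#' `minFirstDayEngagements` engagements on day 1 (the minimal adjusted
#' inclusion criterion).
#'
#' @param records scored records or a [LogBundle-class].
#' @param minFirstDayEngagements strict threshold for the adherence
#'   fraction.
#' @return list with elements `curve` (a [PerformanceCurve-class]),
#'   `adherence` (fraction), `nEligible`.
#' @export
firstDayAnalysis <- function(records, minFirstDayEngagements = 19) {
  records <- .asRecords(records)
  if (!nrow(records)) stop("no records", call. = FALSE)
  day1 <- records[dayIndex(records$engagement_time) == 1L, , drop = FALSE]
  counts <- table(day1$participant_id)
  eligible <- names(counts)[counts >= 2L]
  day1 <- day1[day1$participant_id %in% eligible, , drop = FALSE]
  curve <- if (nrow(day1)) binPerformance(day1, groupLabel = "day 1") else NULL
  list(curve = curve,
       adherence = if (length(eligible))
         mean(counts[eligible] > minFirstDayEngagements) else NA_real_,
       nEligible = length(eligible))
}

#' Practice effect over days
#'
#' Spearman rank correlation between the study day and the daily mean
#' accuracy, for the overall alternation performance or its win-stay /
#' win-shift components, within a day window. Ties are handled by average
#' ranks; p-values use the t approximation for 10 or more days and exact /
#' Monte-Carlo permutation below. Constant daily means leave rho undefined
#' (NA) with p = 1.
#'
#' @param records scored records or a [LogBundle-class].
#' @param component "overall", "stay" or "shift".
#' @param window numeric(2), inclusive day window (1-based).
#' @return a [PracticeEffectResult-class].
#' @export
practiceEffect <- function(records, component = c("overall", "stay", "shift"),
                           window = c(1, 56)) {
  component <- match.arg(component)
  records <- .asRecords(records)
  day <- dayIndex(records$engagement_time)
  keep <- day >= window[1] & day <= window[2] &
    records$stay_shift_label != "unclassified"
  if (component != "overall")
    keep <- keep & records$stay_shift_label == component
  day <- day[keep]
  correct <- records$alternation_correct[keep]
  if (length(unique(day)) < 3L)
    stop("practice effect needs at least 3 distinct days", call. = FALSE)
  daily <- tapply(correct, day, mean)
  days <- as.numeric(names(daily))
  st <- .spearmanTest(days, as.numeric(daily))
  new("PracticeEffectResult", component = component, rho = st$rho,
      pValue = st$p, nDays = length(days), window = as.numeric(window))
}

# Spearman rho with average ranks; t approximation for n >= 10, exact
# permutation for n <= 8, Monte-Carlo permutation (20000) for n = 9.
.spearmanTest <- function(x, y) {
  n <- length(x)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(list(rho = NA_real_, p = 1))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else if (n <= 8) {
    perms <- .allPermutations(n)
    rhos <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    rhos <- replicate(20000, stats::cor(rx, sample(ry)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = min(p, 1))
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Early-versus-late block split
#'
#' Splits each participant's trials on a task into two consecutive
#' equal-count blocks (the first block takes the extra trial when the count
#' is odd) and reports per-block accuracy. Participants are marked excluded
#' unless both blocks hold at least 10 measurements, which rules out odd
#' counts below 21.
#'
#' @param records scored records or a [LogBundle-class].
#' @param task "alternation", "IR" (any image-recognition change) or "VS".
#' @param minPerBlock minimum measurements per block.
#' @return data.frame per participant: `n`, `block1_n`, `block2_n`,
#'   `block1_accuracy`, `block2_accuracy`, `included`.
#' @export
earlyLateSplit <- function(records, task = c("alternation", "IR", "VS"),
                           minPerBlock = 10L) {
  task <- match.arg(task)
  records <- .asRecords(records)
  records <- records[order(records$participant_id, records$engagement_time), ]
  records <- switch(task,
    alternation = records[!is.na(records$iti), , drop = FALSE],
    IR = records[records$change_state %in% c("l-IR", "r-IR", "d-IR"), , drop = FALSE],
    VS = records[records$change_state == "VS", , drop = FALSE])
  correctOf <- if (task == "alternation") function(r) r$alternation_correct
               else function(r) r$image_correct
  sp <- split(records, records$participant_id)
  rows <- lapply(sp, function(r) {
    n <- nrow(r)
    n1 <- ceiling(n / 2); n2 <- n - n1
    ok <- n1 >= minPerBlock && n2 >= minPerBlock
    cc <- correctOf(r)
    data.frame(participant_id = r$participant_id[1], n = n,
               block1_n = n1, block2_n = n2,
               block1_accuracy = if (n1) mean(cc[seq_len(n1)]) else NA_real_,
               block2_accuracy = if (n2) mean(cc[n1 + seq_len(n2)]) else NA_real_,
               included = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Error-class breakdown per change state
#'
#' The distribution of response classes for each pending change state
#' (including "none"), optionally split by a grouping of participants (e.g.
#' age group). Rows are normalised to sum to 1.
#'
#' @param records scored records or a [LogBundle-class].
#' @param groups optional named character vector mapping participant ids to
#'   group labels.
#' @return data.frame with `group`, `change_state`, `n` and one proportion
#'   column per error class.
#' @export
errorBreakdown <- function(records, groups = NULL) {
  records <- .asRecords(records)
  g <- if (is.null(groups)) rep("all", nrow(records))
       else unname(groups[records$participant_id])
  tab <- table(group = g, change_state = records$change_state,
               error_class = factor(records$error_class, levels = ERROR_CLASSES))
  rows <- list()
  for (gr in dimnames(tab)$group) for (cs in dimnames(tab)$change_state) {
    counts <- tab[gr, cs, ]
    n <- sum(counts)
    if (n == 0) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(group = gr, change_state = cs, n = n,
                 stringsAsFactors = FALSE),
      as.data.frame(t(counts / n)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Image-task performance under both denominators
#'
#' Overall image-task accuracy with the denominator restricted to
#' change-bearing engagements (default: a detection score) or extended to
#' all engagements including no-change trials (a combined
#' detection-plus-correct-rejection score). Whether the deployed program
#' logged untouched no-change engagements as correct trials is not
#' documented, so both readings are available.
#'
#' @param records scored records or a [LogBundle-class].
#' @param denominator "change-only" or "all".
#' @return named numeric: accuracy and n.
#' @export
imageTaskPerformance <- function(records,
                                 denominator = c("change-only", "all")) {
  denominator <- match.arg(denominator)
  records <- .asRecords(records)
  if (denominator == "change-only")
    records <- records[records$change_state != "none", , drop = FALSE]
  c(accuracy = mean(records$image_correct), n = nrow(records))
}
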