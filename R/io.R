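# StudyConfig <-> plain list (for embedding in log headers and sidecars)
.configToList <- function(config) {
  list(phase_label = config@phaseLabel, iti_min = config@itiMin,
       iti_max = config@itiMax, alternation_rule = config@alternationRule,
       change_rate = config@changeRate, change_mix = as.list(config@changeMix),
       image_policy = config@imagePolicy, side_bias = config@sideBias,
       study_days = config@studyDays, payment_quota = config@paymentQuota,
       inclusion_min_days = config@inclusionMinDays,
       inclusion_min_daily = config@inclusionMinDaily,
       outlier_high = config@outlierHigh, outlier_low = config@outlierLow,
       seed = config@seed)
}

.configFromList <- function(x) {
  studyConfig(phaseLabel = x$phase_label, itiMin = x$iti_min,
              itiMax = x$iti_max, alternationRule = x$alternation_rule,
              changeRate = x$change_rate, changeMix = unlist(x$change_mix),
              imagePolicy = x$image_policy, sideBias = x$side_bias,
              studyDays = x$study_days, paymentQuota = x$payment_quota,
              inclusionMinDays = x$inclusion_min_days,
              inclusionMinDaily = x$inclusion_min_daily,
              outlierHigh = x$outlier_high, outlierLow = x$outlier_low,
              seed = x$seed)
}

.profileToList <- function(p) {
  list(participant_id = p@participantId, age_group = p@ageGroup,
       baseline_logit = p@baselineLogit, iti_decay = p@itiDecay,
       lapse_rate = p@lapseRate, shift_deficit = p@shiftDeficit,
       stay_drift = p@stayDrift,
       detection_sensitivity = as.list(p@detectionSensitivity),
       similarity_effect = p@similarityEffect,
       false_alarm_rate = p@falseAlarmRate,
       daily_engagement_rate = p@dailyEngagementRate,
       dropout_day = if (is.finite(p@dropoutDay)) p@dropoutDay else "Inf",
       seed = p@seed)
}

.profileFromList <- function(x) {
  participantProfile(
    participantId = x$participant_id, ageGroup = x$age_group,
    baselineLogit = x$baseline_logit, itiDecay = x$iti_decay,
    lapseRate = x$lapse_rate, shiftDeficit = x$shift_deficit,
    stayDrift = x$stay_drift,
    detectionSensitivity = unlist(x$detection_sensitivity),
    similarityEffect = x$similarity_effect,
    falseAlarmRate = x$false_alarm_rate,
    dailyEngagementRate = x$daily_engagement_rate,
    dropoutDay = if (identical(x$dropout_day, "Inf")) Inf else x$dropout_day,
    seed = x$seed)
}

.validateRecords <- function(records, path) {
  checks <- list(
    change_state = CHANGE_STATES,
    image_response = BUTTON_SETS,
    scheduled_side = c("L", "R"),
    alternation_response = c("L", "R"),
    stay_shift_label = STAY_SHIFT)
  for (col in names(checks)) {
    v <- records[[col]]
    if (col == "image_response") v[is.na(v)] <- ""
    bad <- which(!v %in% checks[[col]])
    if (length(bad))
      stop(sprintf("parse error in %s: invalid %s value '%s' on data row %d",
                   path, col, records[[col]][bad[1]], bad[1]), call. = FALSE)
  }
  invisible(records)
}

#' Write and read engagement-log bundles
#'
#' Lossless on-disk round trip for a [LogBundle-class] in two dialects.
#' The CSV dialect is a comma-separated UTF-8 file whose first line is a
#' versioned header comment (`#hage-log-v1 <config as JSON>`) followed by a
#' mandatory column header and one row per engagement; numeric fields are
#' written with full (17 significant digit) precision. The JSON-lines
#' dialect starts with a header object (`format_version`, `config`,
#' optionally `profiles`) followed by one JSON object per engagement.
#' Timestamps are seconds since study start. Unknown extra columns are
#' preserved. Enum spellings (l-IR, r-IR, d-IR, VS; L/R/LR button sets) are
#' validated on read and malformed rows are reported by their data row
#' number; a missing or foreign header is a version error.
#'
#' The canonical column schema is: participant_id, engagement_time, iti,
#' trial_index, scheduled_side, alternation_response, alternation_correct,
#' stay_shift_label, change_state, image_response, image_correct,
#' error_class, feedback_given.
#'
#' @param bundle a [LogBundle-class].
#' @param path file path.
#' @param dialect "csv" or "jsonl".
#' @param sidecar optional path for a JSON sidecar holding the true
#'   generating profiles (written only when the bundle has profiles; for
#'   csv the sidecar is the only way to carry them).
#' @return `writeLog()` returns `path` invisibly; `readLog()` a
#'   [LogBundle-class].
#' @examples
#' b <- makeFixtures("perfect_responder", seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeLog(b, f)
#' identical(dim(engagementRecords(readLog(f))),
#'           dim(engagementRecords(b)))
#' @export
writeLog <- function(bundle, path, dialect = c("csv", "jsonl"),
                     sidecar = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(is(bundle, "LogBundle"))
  rec <- bundle@records
  cols <- c(recordColumns(), setdiff(names(rec), recordColumns()))
  rec <- rec[, cols, drop = FALSE]
  cfgJson <- jsonlite::toJSON(.configToList(bundle@config), auto_unbox = TRUE,
                              digits = NA)
  if (dialect == "csv") {
    fmt <- rec
    for (col in names(fmt)) {
      if (is.numeric(fmt[[col]]) && !is.integer(fmt[[col]]))
        fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA,
                             sprintf("%.17g", fmt[[col]]))
    }
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("#", bundle@formatVersion, " ", cfgJson), con)
    utils::write.table(fmt, con, sep = ",", row.names = FALSE,
                       quote = TRUE, na = "")
  } else {
    header <- list(format_version = bundle@formatVersion,
                   config = .configToList(bundle@config))
    if (length(bundle@profiles))
      header$profiles <- lapply(bundle@profiles, .profileToList)
    lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA),
               vapply(seq_len(nrow(rec)), function(i)
                 as.character(jsonlite::toJSON(as.list(rec[i, , drop = FALSE]),
                                               auto_unbox = TRUE, digits = NA,
                                               na = "null")),
                 character(1)))
    writeLines(lines, path, useBytes = TRUE)
  }
  if (!is.null(sidecar) && length(bundle@profiles))
    jsonlite::write_json(lapply(bundle@profiles, .profileToList), sidecar,
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLog
#' @export
readLog <- function(path, dialect = c("csv", "jsonl"), sidecar = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    first <- readLines(path, n = 1L)
    if (!startsWith(first, paste0("#", LOG_FORMAT_VERSION)))
      stop("version error: expected ", LOG_FORMAT_VERSION, " header in ",
           path, call. = FALSE)
    cfg <- .configFromList(jsonlite::fromJSON(
      sub(paste0("^#", LOG_FORMAT_VERSION, " "), "", first)))
    rec <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                           na.strings = "", colClasses = NA)
    rec$engagement_time <- as.numeric(rec$engagement_time)
    rec$iti <- as.numeric(rec$iti)
    for (col in c("scheduled_side", "alternation_response", "stay_shift_label",
                  "change_state", "image_response", "error_class",
                  "participant_id"))
      rec[[col]] <- as.character(rec[[col]])
    rec$image_response[is.na(rec$image_response)] <- ""
    profiles <- list()
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                       error = function(e)
                         stop("version error: malformed header in ", path,
                              call. = FALSE))
    if (!identical(header$format_version, LOG_FORMAT_VERSION))
      stop("version error: expected ", LOG_FORMAT_VERSION, ", found '",
           header$format_version %||% "none", "' in ", path, call. = FALSE)
    cfg <- .configFromList(header$config)
    profiles <- lapply(header$profiles %||% list(), .profileFromList)
    rows <- lapply(seq_along(lines[-1]), function(i) {
      x <- tryCatch(jsonlite::fromJSON(lines[i + 1L], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("parse error in %s on data row %d", path, i),
                           call. = FALSE))
      x$image_response <- x$image_response %||% ""
      x$iti <- x$iti %||% NA_real_
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, rows)
  }
  if (!is.null(sidecar) && file.exists(sidecar))
    profiles <- lapply(jsonlite::read_json(sidecar), .profileFromList)
  .validateRecords(rec, path)
  rec$trial_index <- as.integer(rec$trial_index)
  newLogBundle(cfg, rec, profiles)
}

#' Deterministic test fixtures
#'
#' Small engagement-log bundles used across the test suite; the same id and
#' seed always give an identical bundle.
#' \describe{
#'   \item{boundary_inclusion}{Hand-constructed cohort probing the
#'     inclusion boundaries: P001 with 43 active days at 12/day (passes),
#'     P002 with 41 days at 20/day (fails on days), P003 with 42 days at
#'     exactly 10/day (fails the strict >10 daily rule), P004 with 50 days
#'     at 15/day (passes).}
#'   \item{perfect_responder}{One simulated participant who never lapses,
#'     never forgets and detects every change.}
#'   \item{pure_guesser}{One simulated participant with lapse rate 1 (all
#'     alternation presses random), ~2000 trials.}
#'   \item{miss_dominated}{One simulated Phase 2 participant with weak
#'     detection, so detection failures are dominated by misses.}
#' }
#'
#' @param name fixture id.
#' @param seed RNG seed.
#' @return a [LogBundle-class].
#' @export
makeFixtures <- function(name = c("boundary_inclusion", "perfect_responder",
                                  "pure_guesser", "miss_dominated"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    boundary_inclusion = {
      cfg <- phasePreset("phase1", seed = seed)
      spec <- list(P001 = c(days = 43, perDay = 12),
                   P002 = c(days = 41, perDay = 20),
                   P003 = c(days = 42, perDay = 10),
                   P004 = c(days = 50, perDay = 15))
      recs <- do.call(rbind, lapply(names(spec), function(pid)
        .gridLog(pid, spec[[pid]]["days"], spec[[pid]]["perDay"], cfg)))
      newLogBundle(cfg, recs)
    },
    perfect_responder = {
      cfg <- phasePreset("phase1", seed = seed)
      p <- participantProfile("perfect", "older", baselineLogit = 30,
                              itiDecay = 0, lapseRate = 0,
                              detectionSensitivity = c("l-IR" = 1, "r-IR" = 1,
                                                       "d-IR" = 1, "VS" = 1),
                              similarityEffect = 0, falseAlarmRate = 0,
                              dailyEngagementRate = 15, seed = seed)
      newLogBundle(cfg, simulateParticipant(p, cfg, seed = seed),
                   list(p))
    },
    pure_guesser = {
      cfg <- phasePreset("phase1", seed = seed)
      p <- participantProfile("guesser", "younger", lapseRate = 1,
                              dailyEngagementRate = 36, seed = seed)
      newLogBundle(cfg, simulateParticipant(p, cfg, seed = seed), list(p))
    },
    miss_dominated = {
      cfg <- phasePreset("phase2", seed = seed)
      p <- participantProfile("misser", "middle", lapseRate = 0.05,
                              detectionSensitivity = c("l-IR" = 0.6,
                                                       "r-IR" = 0.6,
                                                       "d-IR" = 0.75,
                                                       "VS" = 0.5),
                              similarityEffect = 0.3, falseAlarmRate = 0.05,
                              dailyEngagementRate = 20, seed = seed)
      newLogBundle(cfg, simulateParticipant(p, cfg, seed = seed), list(p))
    })
}

# Regular synthetic log: `perDay` engagements each day, evenly spaced,
# participant always correct; used by hand-computable inclusion fixtures.
.gridLog <- function(pid, days, perDay, config) {
  t <- as.vector(vapply(seq_len(days), function(d)
    (d - 1) * 86400 + seq_len(perDay) * 600, numeric(perDay)))
  n <- length(t)
  idx <- seq_len(n) - 1L
  sched <- scheduledSide(idx, config@alternationRule, "L")
  rec <- data.frame(
    participant_id = pid, engagement_time = t, iti = c(NA, diff(t)),
    trial_index = idx, scheduled_side = sched,
    alternation_response = sched, alternation_correct = NA,
    stay_shift_label = NA_character_, change_state = "none",
    image_response = "", image_correct = NA, error_class = NA_character_,
    feedback_given = NA, stringsAsFactors = FALSE)
  scoreEngagements(rec, config, startSide = "L")
}
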