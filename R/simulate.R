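#' Construct a participant profile
#'
#' Builds a validated [ParticipantProfile-class]. See
#' [alternationAccuracy()] for the alternation response model the
#' forgetting parameters enter, and [imageResponse()] for the detection
#' model.
#'
#' @param participantId opaque alias.
#' @param ageGroup "younger", "middle" or "older".
#' @param baselineLogit,itiDecay,lapseRate,shiftDeficit,stayDrift
#'   alternation-model parameters; see [ParticipantProfile-class].
#' @param detectionSensitivity named numeric over l-IR, r-IR, d-IR, VS.
#' @param similarityEffect,falseAlarmRate image-model parameters.
#' @param dailyEngagementRate expected engagements per day.
#' @param dropoutDay day after which engagement ceases (Inf = none).
#' @param seed integer RNG seed.
#' @return a [ParticipantProfile-class].
#' @export
participantProfile <- function(participantId = "P000",
                               ageGroup = "older",
                               baselineLogit = 2.3, itiDecay = 0.35,
                               lapseRate = 0.05, shiftDeficit = 0,
                               stayDrift = 0,
                               detectionSensitivity = c("l-IR" = 0.95,
                                                        "r-IR" = 0.95,
                                                        "d-IR" = 0.95,
                                                        "VS" = 0.90),
                               similarityEffect = 0.3,
                               falseAlarmRate = 0.05,
                               dailyEngagementRate = 18,
                               dropoutDay = Inf, seed = 1L) {
  new("ParticipantProfile",
      participantId = participantId, ageGroup = ageGroup,
      baselineLogit = baselineLogit, itiDecay = itiDecay,
      lapseRate = lapseRate, shiftDeficit = shiftDeficit,
      stayDrift = stayDrift,
      detectionSensitivity = detectionSensitivity[CHANGE_TYPES],
      similarityEffect = similarityEffect, falseAlarmRate = falseAlarmRate,
      dailyEngagementRate = dailyEngagementRate,
      dropoutDay = as.numeric(dropoutDay), seed = as.integer(seed))
}

#' Illustrative age-group presets
#'
#' Fixed profiles per age group and phase, calibrated so that a simulated
#' Phase 1 cohort lands in the 70-80% mean alternation-accuracy range, with
#' the younger preset carrying the highest lapse rate (the deployment's
#' younger participants reported pressing at random most often) and the
#' Phase 2 presets showing a positive win-stay minus win-shift gap and a
#' win-stay practice drift in the middle and older groups only. The presets
#' are calibration targets for tests, not claims about real humans.
#'
#' @param ageGroup "younger", "middle" or "older".
#' @param phase "phase1" or "phase2".
#' @param participantId,seed passed through to the profile.
#' @return a [ParticipantProfile-class].
#' @examples
#' presetProfile("older", "phase2")
#' @export
presetProfile <- function(ageGroup = c("younger", "middle", "older"),
                          phase = c("phase1", "phase2"),
                          participantId = paste0(ageGroup, "-preset"),
                          seed = 1L) {
  ageGroup <- match.arg(ageGroup)
  phase <- match.arg(phase)
  base <- switch(ageGroup,
    younger = list(a = 2.35, lapse = 0.18, rate = 15, drift = 0.000),
    middle  = list(a = 2.50, lapse = 0.05, rate = 13, drift = 0.007),
    older   = list(a = 2.45, lapse = 0.04, rate = 21, drift = 0.010))
  if (phase == "phase1") {
    participantProfile(
      participantId = participantId, ageGroup = ageGroup,
      baselineLogit = base$a, itiDecay = 0.35, lapseRate = base$lapse,
      shiftDeficit = 0, stayDrift = 0,
      detectionSensitivity = c("l-IR" = 0.95, "r-IR" = 0.95,
                               "d-IR" = 0.95, "VS" = 0.90),
      similarityEffect = 0.3, falseAlarmRate = 0.04,
      dailyEngagementRate = base$rate, seed = seed)
  } else {
    participantProfile(
      participantId = participantId, ageGroup = ageGroup,
      baselineLogit = base$a, itiDecay = 0.35, lapseRate = base$lapse,
      shiftDeficit = 0.45, stayDrift = base$drift,
      detectionSensitivity = c("l-IR" = 0.80, "r-IR" = 0.80,
                               "d-IR" = 0.92, "VS" = 0.70),
      similarityEffect = 0.35, falseAlarmRate = 0.06,
      dailyEngagementRate = base$rate, seed = seed)
  }
}

#' Alternation response accuracy
#'
#' The probability of a correct alternation choice under the lapse-mixed
#' logistic forgetting model:
#' \deqn{p = \lambda/2 + (1-\lambda)\,
#'   \mathrm{logit}^{-1}\!\big(a - \beta \ln(\mathrm{ITI}/1\,\mathrm{min})
#'   - \gamma\,[\mathrm{shift}] + \delta\, d\,[\mathrm{stay}]\big)}
#' where \eqn{\lambda} is the lapse (random-press) rate, \eqn{a} the
#' baseline logit at a 1-minute ITI, \eqn{\beta \ge 0} the forgetting slope
#' per log-minute, \eqn{\gamma \ge 0} the win-shift deficit, and
#' \eqn{\delta} the win-stay practice drift per study day \eqn{d} (counted
#' from 0). The log-ITI abscissa mirrors how alternation performance is
#' binned and displayed (log minutes); accuracy is non-increasing in the
#' ITI whenever \eqn{\beta > 0}.
#'
#' @param profile a [ParticipantProfile-class].
#' @param iti inter-trial interval(s), seconds, > 0.
#' @param day study day(s) counted from 0.
#' @param label "stay", "shift" or "unclassified".
#' @return probabilities in [0,1].
#' @examples
#' p <- presetProfile("older", "phase1")
#' alternationAccuracy(p, c(120, 3600), day = 0, label = "unclassified")
#' @export
alternationAccuracy <- function(profile, iti, day = 0, label = "unclassified") {
  if (any(iti <= 0)) stop("iti must be > 0", call. = FALSE)
  stopifnot(all(label %in% STAY_SHIFT))
  eta <- profile@baselineLogit - profile@itiDecay * log(iti / 60) -
    profile@shiftDeficit * (label == "shift") +
    profile@stayDrift * day * (label == "stay")
  profile@lapseRate / 2 + (1 - profile@lapseRate) * stats::plogis(eta)
}

#' Image-task response model
#'
#' On a change-bearing engagement the participant emits the correct button
#' set with probability `detectionSensitivity[type] - similarityEffect *
#' similarity` (clamped to [0,1]); on failure the response follows a
#' miss-dominated confusion kernel: a miss (no press) with probability
#' `missWeight`, otherwise one of the remaining wrong nonempty button sets,
#' uniformly. On a no-change engagement a (uniformly chosen) spurious press
#' occurs with probability `falseAlarmRate`.
#'
#' @param profile a [ParticipantProfile-class].
#' @param changeState character vector of pending change states.
#' @param similarity image-similarity values in [0,1], recycled.
#' @param missWeight probability that a detection failure is a miss.
#' @return character vector of pressed button sets ("", "L", "R", "LR").
#' @export
imageResponse <- function(profile, changeState, similarity = 0.2,
                          missWeight = 0.75) {
  n <- length(changeState)
  similarity <- rep_len(similarity, n)
  out <- character(n)
  noChange <- changeState == "none"
  # no change: false alarms press a uniformly random nonempty set
  fa <- noChange & stats::runif(n) < profile@falseAlarmRate
  out[noChange] <- ""
  out[fa] <- sample(c("L", "R", "LR"), sum(fa), replace = TRUE)
  if (any(!noChange)) {
    i <- which(!noChange)
    sens <- profile@detectionSensitivity[changeState[i]] -
      profile@similarityEffect * similarity[i]
    sens <- pmin(pmax(sens, 0), 1)
    expected <- expectedButtons(changeState[i])
    hit <- stats::runif(length(i)) < sens
    out[i[hit]] <- expected[hit]
    fail <- i[!hit]
    if (length(fail)) {
      miss <- stats::runif(length(fail)) < missWeight
      out[fail[miss]] <- ""
      conf <- fail[!miss]
      for (j in conf) {
        wrong <- setdiff(c("L", "R", "LR"), expectedButtons(changeState[j]))
        out[j] <- if (length(wrong) == 1L) wrong else sample(wrong, 1L)
      }
    }
  }
  out
}

#' Simulate one participant's engagement log
#'
#' Generates a fully scored engagement log: per-day engagement counts are
#' Poisson at the profile's daily rate (truncated at the dropout day),
#' engagement times come from the activation scheduler plus the
#' response-delay model, image changes are scheduled by
#' [scheduleChangeEvents()] and attributed to the first engagement at which
#' they are visible (multiple changes collapse to the net difference), and
#' alternation/image responses are drawn from [alternationAccuracy()] and
#' [imageResponse()]. All records are scored via [scoreEngagements()].
#' Identical seeds give identical logs.
#'
#' @param profile a [ParticipantProfile-class].
#' @param config a [StudyConfig-class].
#' @param seed RNG seed; defaults to the profile's.
#' @param startSide schedule start side; NULL randomises it from the seed.
#' @param delayModel response-latency model, see [defaultDelayModel()].
#' @param imagePool image pool, see [makeImagePool()].
#' @return data.frame of scored engagement records (see [writeLog()] for
#'   the column schema).
#' @examples
#' log1 <- simulateParticipant(presetProfile("older", "phase1"),
#'                             phasePreset("phase1"), seed = 7)
#' mean(log1$alternation_correct)
#' @export
simulateParticipant <- function(profile, config, seed = profile@seed,
                                startSide = NULL,
                                delayModel = defaultDelayModel(),
                                imagePool = makeImagePool()) {
  stopifnot(is(profile, "ParticipantProfile"), is(config, "StudyConfig"))
  set.seed(seed)
  if (is.null(startSide)) startSide <- sample(c("L", "R"), 1L)
  days <- min(config@studyDays, floor(profile@dropoutDay))
  if (days < 1L) return(.emptyRecords())
  nPerDay <- stats::rpois(days, profile@dailyEngagementRate)
  n <- sum(nPerDay)
  if (n == 0L) return(.emptyRecords())
  dayId <- rep(seq_len(days), nPerDay)
  gaps <- sampleActivationInterval(config, n)
  delays <- delayModel(n)
  if (any(delays < 0)) stop("delay model produced a negative delay", call. = FALSE)
  gaps <- pmin(gaps + delays, ITI_CEILING)
  within <- stats::ave(gaps, dayId, FUN = cumsum)
  t <- (dayId - 1L) * 86400 + within
  keep <- within < 86400  # engagements spilling past the day are not realised
  t <- t[keep]; dayId <- dayId[keep]
  n <- length(t)
  if (n == 0L) return(.emptyRecords())

  ev <- scheduleChangeEvents(config, days, imagePool = imagePool)
  # displayed pair at each engagement = pair after the last event before it
  evIdx <- if (nrow(ev)) findInterval(t, ev$event_time) else integer(n)
  pool0 <- if (nrow(ev)) c(ev$before_left[1], ev$before_right[1])
           else .initialPairFor(config, imagePool)
  pairL <- c(pool0[1], ev$after_left)[evIdx + 1L]
  pairR <- c(pool0[2], ev$after_right)[evIdx + 1L]
  seenL <- c(pool0[1], pairL[-n])
  seenR <- c(pool0[2], pairR[-n])
  changeState <- netChangeState(seenL, seenR, pairL, pairR)
  catOf <- function(id) sub("_img.*$", "", id)
  similarity <- ifelse(catOf(pairL) == catOf(pairR), 0.7, 0.2)

  iti <- c(NA, diff(t))
  idx <- seq_len(n) - 1L
  label <- classifyStayShift(idx, config@alternationRule)
  sched <- scheduledSide(idx, config@alternationRule, startSide)
  itiForModel <- ifelse(is.na(iti), 60, pmax(iti, 1e-9))  # first trial is overridden below
  pAcc <- alternationAccuracy(profile, itiForModel, day = dayId - 1L,
                              label = label)
  correctDraw <- stats::runif(n) < pAcc
  other <- ifelse(sched == "L", "R", "L")
  response <- ifelse(correctDraw, sched, other)
  response[1] <- sched[1]  # first trial has no memory demand

  rec <- data.frame(
    participant_id = profile@participantId,
    engagement_time = t,
    iti = iti,
    trial_index = idx,
    scheduled_side = sched,
    alternation_response = response,
    alternation_correct = NA,
    stay_shift_label = label,
    change_state = changeState,
    image_response = imageResponse(profile, changeState, similarity),
    image_correct = NA,
    error_class = NA_character_,
    feedback_given = NA,
    stringsAsFactors = FALSE)
  scoreEngagements(rec, config, startSide = startSide)
}

.emptyRecords <- function() {
  cols <- recordColumns()
  out <- data.frame(participant_id = character(0), engagement_time = numeric(0),
                    iti = numeric(0), trial_index = integer(0),
                    scheduled_side = character(0),
                    alternation_response = character(0),
                    alternation_correct = logical(0),
                    stay_shift_label = character(0),
                    change_state = character(0), image_response = character(0),
                    image_correct = logical(0), error_class = character(0),
                    feedback_given = logical(0), stringsAsFactors = FALSE)
  out[, cols]
}

.initialPairFor <- function(config, imagePool) {
  poolCat <- split(imagePool$image_id, imagePool$category)
  .drawPair(poolCat, names(poolCat), config@imagePolicy == "within-category")
}

#' Simulate a cohort
#'
#' Simulates independent participants in the three age groups with
#' per-participant seeds derived from the master seed. Profiles start from
#' [presetProfile()] and, when `heterogeneity > 0`, receive lognormal
#' person-to-person variation on the forgetting slope and mild normal
#' variation on the baseline logit. The true generating profiles are kept in
#' the returned [LogBundle-class] for parameter-recovery work.
#'
#' @param nPerGroup named integer vector over younger/middle/older (a single
#'   unnamed number is recycled to all three groups).
#' @param config a [StudyConfig-class].
#' @param seed master seed.
#' @param heterogeneity coefficient of variation of the forgetting slope
#'   across participants (0 = identical profiles within group).
#' @param profiles optional list of [ParticipantProfile-class] objects that
#'   overrides the preset-based construction entirely.
#' @return a [LogBundle-class].
#' @examples
#' b <- simulateCohort(c(younger = 1, middle = 1, older = 1),
#'                     phasePreset("phase1"), seed = 1)
#' table(engagementRecords(b)$participant_id)
#' @export
simulateCohort <- function(nPerGroup, config, seed = 1L,
                           heterogeneity = 0.1, profiles = NULL) {
  stopifnot(is(config, "StudyConfig"))
  if (is.null(profiles)) {
    if (is.null(names(nPerGroup)))
      nPerGroup <- stats::setNames(rep_len(nPerGroup, 3L), AGE_GROUPS)
    stopifnot(all(nPerGroup >= 0), any(nPerGroup >= 1))
    groups <- rep(names(nPerGroup), nPerGroup)
    set.seed(seed)
    nTot <- length(groups)
    seeds <- sample.int(.Machine$integer.max - 1L, nTot)
    ids <- sprintf("P%03d", seq_len(nTot))
    profiles <- vector("list", nTot)
    for (i in seq_len(nTot)) {
      p <- presetProfile(groups[i], config@phaseLabel, participantId = ids[i],
                         seed = seeds[i])
      if (heterogeneity > 0) {
        set.seed(seeds[i])
        p@itiDecay <- p@itiDecay *
          stats::rlnorm(1, -heterogeneity^2 / 2, heterogeneity)
        p@baselineLogit <- p@baselineLogit + stats::rnorm(1, 0, 0.1)
      }
      profiles[[i]] <- p
    }
  } else {
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, length(profiles))
  }
  logs <- lapply(seq_along(profiles), function(i)
    simulateParticipant(profiles[[i]], config, seed = seeds[i]))
  recs <- do.call(rbind, logs)
  newLogBundle(config, recs, profiles)
}

#' @rdname LogBundle-class
#' @param config,records,profiles bundle components.
#' @export
newLogBundle <- function(config, records, profiles = list()) {
  new("LogBundle", formatVersion = LOG_FORMAT_VERSION, config = config,
      records = records, profiles = profiles)
}
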