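#' @import methods
NULL

# Enum spellings are fixed across the package and the on-disk log formats.
CHANGE_TYPES <- c("l-IR", "r-IR", "d-IR", "VS")
CHANGE_STATES <- c("none", CHANGE_TYPES)
BUTTON_SETS <- c("", "L", "R", "LR")
ERROR_CLASSES <- c("correct", "missing_change", "wrong_side",
                   "partial_detection", "overreaction_to_no_change")
STAY_SHIFT <- c("stay", "shift", "unclassified")
AGE_GROUPS <- c("younger", "middle", "older")
LOG_FORMAT_VERSION <- "hage-log-v1"

#' StudyConfig: full parameterisation of a testing phase
#'
#' Holds every protocol parameter of one deployment phase: the bounds of the
#' randomised window-activation interval, the alternation rule, the
#' image-change rate and type mix, the image-pairing policy, and the
#' inclusion/outlier thresholds used by the analysis pipeline. Use
#' [studyConfig()] or [phasePreset()] to construct one.
#'
#' @slot phaseLabel character, e.g. "phase1".
#' @slot itiMin,itiMax numeric, activation-interval bounds in seconds.
#' @slot alternationRule "single" (LRLR) or "double" (LLRR).
#' @slot changeRate numeric, expected image-change events per day.
#' @slot changeMix named numeric over l-IR, r-IR, d-IR, VS; sums to 1.
#'   l-IR/r-IR are read relative to the biased side: the `sideBias` entry of
#'   the mix carries the larger single-change probability.
#' @slot imagePolicy "cross-category" or "within-category".
#' @slot sideBias "L" or "R": which single-change side has the larger rate.
#' @slot studyDays integer, nominal study length in days.
#' @slot paymentQuota numeric, rewarded engagements per day.
#' @slot inclusionMinDays integer, minimum active days for inclusion.
#' @slot inclusionMinDaily numeric, strict lower bound on mean daily
#'   engagements.
#' @slot outlierHigh,outlierLow numeric proportions: mean accuracy strictly
#'   above/below these marks a participant as a high/low outlier.
#' @slot seed integer, default RNG seed.
#' @export
setClass("StudyConfig", representation(
  phaseLabel = "character",
  itiMin = "numeric",
  itiMax = "numeric",
  alternationRule = "character",
  changeRate = "numeric",
  changeMix = "numeric",
  imagePolicy = "character",
  sideBias = "character",
  studyDays = "integer",
  paymentQuota = "numeric",
  inclusionMinDays = "integer",
  inclusionMinDaily = "numeric",
  outlierHigh = "numeric",
  outlierLow = "numeric",
  seed = "integer"
))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (!(object@itiMin > 0 && object@itiMin <= object@itiMax))
    msg <- c(msg, "need 0 < itiMin <= itiMax")
  if (!object@alternationRule %in% c("single", "double"))
    msg <- c(msg, "alternationRule must be 'single' or 'double'")
  mix <- object@changeMix
  if (!identical(sort(names(mix)), sort(CHANGE_TYPES)))
    msg <- c(msg, "changeMix must be named over l-IR, r-IR, d-IR, VS")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-12)
    msg <- c(msg, "changeMix entries must be nonnegative and sum to 1")
  if (object@changeRate < 0) msg <- c(msg, "changeRate must be >= 0")
  if (!object@imagePolicy %in% c("cross-category", "within-category"))
    msg <- c(msg, "imagePolicy must be 'cross-category' or 'within-category'")
  if (!object@sideBias %in% c("L", "R"))
    msg <- c(msg, "sideBias must be 'L' or 'R'")
  ol <- object@outlierLow; oh <- object@outlierHigh
  if (!(ol > 0 && ol < oh && oh < 1))
    msg <- c(msg, "need 0 < outlierLow < outlierHigh < 1")
  if (object@studyDays < 1L) msg <- c(msg, "studyDays must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ParticipantProfile: generative behaviour parameters
#'
#' Parameterises the synthetic participant: a lapse-mixed logistic forgetting
#' model for the alternation tasks, a detection model for the image tasks,
#' and an engagement/dropout model. See [alternationAccuracy()] for the
#' response model the alternation parameters enter.
#'
#' @slot participantId opaque alias.
#' @slot ageGroup "younger", "middle" or "older".
#' @slot baselineLogit numeric, accuracy logit at the 1-minute reference ITI.
#' @slot itiDecay numeric >= 0, logit loss per log(ITI/1 min) unit.
#' @slot lapseRate probability in [0,1] that a response is a random press.
#' @slot shiftDeficit numeric >= 0, logit penalty on win-shift trials.
#' @slot stayDrift numeric, logit gain per study day on win-stay trials.
#' @slot detectionSensitivity named numeric over change types: hit
#'   probability at zero image similarity.
#' @slot similarityEffect numeric, drop in hit probability per unit
#'   similarity.
#' @slot falseAlarmRate probability of pressing when nothing changed.
#' @slot dailyEngagementRate numeric > 0, expected engagements per day.
#' @slot dropoutDay numeric, day after which engagement ceases (Inf = none).
#' @slot seed integer.
#' @export
setClass("ParticipantProfile", representation(
  participantId = "character",
  ageGroup = "character",
  baselineLogit = "numeric",
  itiDecay = "numeric",
  lapseRate = "numeric",
  shiftDeficit = "numeric",
  stayDrift = "numeric",
  detectionSensitivity = "numeric",
  similarityEffect = "numeric",
  falseAlarmRate = "numeric",
  dailyEngagementRate = "numeric",
  dropoutDay = "numeric",
  seed = "integer"
))

setValidity("ParticipantProfile", function(object) {
  msg <- character()
  pr <- c(object@lapseRate, object@falseAlarmRate, object@detectionSensitivity)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "all probabilities must lie in [0,1]")
  if (object@itiDecay < 0) msg <- c(msg, "itiDecay must be >= 0")
  if (object@shiftDeficit < 0) msg <- c(msg, "shiftDeficit must be >= 0")
  if (!identical(sort(names(object@detectionSensitivity)), sort(CHANGE_TYPES)))
    msg <- c(msg, "detectionSensitivity must be named over change types")
  if (!object@ageGroup %in% AGE_GROUPS)
    msg <- c(msg, "ageGroup must be younger/middle/older")
  if (object@dropoutDay > 0 && object@dailyEngagementRate <= 0)
    msg <- c(msg, "dailyEngagementRate must be > 0 before dropout")
  if (length(msg)) msg else TRUE
})

#' PerformanceCurve: per-ITI-bin alternation accuracy
#'
#' Accuracy, sample count and median ITI position for the five canonical
#' inter-trial-interval bins (<2, 2-5, 5-10, 10-30 and 30-330 minutes).
#' Produced by [binPerformance()] and [firstDayAnalysis()].
#'
#' @slot binEdges numeric(6), bin edges in minutes (left-open intervals).
#' @slot binPositions numeric(5), median ITI (minutes) of the trials in each
#'   bin; NA for empty bins.
#' @slot nPerBin integer(5), trial counts.
#' @slot accuracyPerBin numeric(5), proportion correct; NA for empty bins.
#' @slot underSampled logical(5), TRUE where n <= 100.
#' @slot nExcluded integer, trials outside (0, 330] minutes (first trials and
#'   over-ceiling gaps) that were not binned.
#' @slot groupLabel character annotation.
#' @export
setClass("PerformanceCurve", representation(
  binEdges = "numeric",
  binPositions = "numeric",
  nPerBin = "integer",
  accuracyPerBin = "numeric",
  underSampled = "logical",
  nExcluded = "integer",
  groupLabel = "character"
))

setValidity("PerformanceCurve", function(object) {
  msg <- character()
  if (length(object@binEdges) != 6L || is.unsorted(object@binEdges))
    msg <- c(msg, "binEdges must be 6 increasing values")
  if (length(object@nPerBin) != 5L || length(object@accuracyPerBin) != 5L ||
      length(object@binPositions) != 5L)
    msg <- c(msg, "curve must have exactly 5 bins")
  acc <- object@accuracyPerBin
  if (any(!is.na(acc) & (acc < 0 | acc > 1)))
    msg <- c(msg, "accuracies must lie in [0,1]")
  pos <- object@binPositions
  lo <- object@binEdges[-6]; hi <- object@binEdges[-1]
  bad <- !is.na(pos) & !(pos > lo & pos <= hi)
  if (any(bad)) msg <- c(msg, "bin positions must lie inside their bins")
  if (length(msg)) msg else TRUE
})

#' AdherenceSurface: cohort adherence across duration and daily thresholds
#'
#' Fraction of a cohort meeting both a cumulative engagement-duration
#' requirement (weeks) and a strict daily-engagement threshold, for a grid of
#' both. Produced by [adherenceSurface()].
#'
#' @slot weeks integer axis (required weeks of engagement).
#' @slot thresholds numeric axis (strict minimum mean daily engagements).
#' @slot surface matrix, rows = weeks, columns = thresholds, values in [0,1].
#' @slot nParticipants integer cohort size.
#' @export
setClass("AdherenceSurface", representation(
  weeks = "integer",
  thresholds = "numeric",
  surface = "matrix",
  nParticipants = "integer"
))

setValidity("AdherenceSurface", function(object) {
  s <- object@surface
  msg <- character()
  if (!all(dim(s) == c(length(object@weeks), length(object@thresholds))))
    msg <- c(msg, "surface dimensions must match the axes")
  if (any(s < 0 | s > 1)) msg <- c(msg, "cells must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' StatsResult: outcome of one statistical test
#'
#' @slot testName character.
#' @slot statistic numeric.
#' @slot df numeric, possibly corrected (length 1 or 2).
#' @slot pValue numeric in [0,1].
#' @slot correction "none", "greenhouse-geisser" or "bonferroni".
#' @slot epsilon numeric, Greenhouse-Geisser epsilon when applicable, else NA.
#' @slot details list of test-specific extras (e.g. pairwise p-values).
#' @export
setClass("StatsResult", representation(
  testName = "character",
  statistic = "numeric",
  df = "numeric",
  pValue = "numeric",
  correction = "character",
  epsilon = "numeric",
  details = "list"
))

setValidity("StatsResult", function(object) {
  msg <- character()
  p <- object@pValue
  if (any(!is.na(p) & (p < 0 | p > 1))) msg <- c(msg, "pValue must lie in [0,1]")
  if (!object@correction %in% c("none", "greenhouse-geisser", "bonferroni"))
    msg <- c(msg, "unknown correction")
  if (length(msg)) msg else TRUE
})

#' PracticeEffectResult: Spearman trend of daily performance
#'
#' @slot component "overall", "stay" or "shift".
#' @slot rho Spearman rank correlation of daily mean accuracy vs day; NA when
#'   the daily means are constant.
#' @slot pValue numeric.
#' @slot nDays number of distinct days entering the correlation.
#' @slot window numeric(2), (start day, end day), inclusive, 1-based.
#' @export
setClass("PracticeEffectResult", representation(
  component = "character",
  rho = "numeric",
  pValue = "numeric",
  nDays = "integer",
  window = "numeric"
))

setValidity("PracticeEffectResult", function(object) {
  if (!is.na(object@rho) && abs(object@rho) > 1 + 1e-12)
    "rho must lie in [-1, 1]" else TRUE
})

#' LogBundle: a study configuration plus its engagement logs
#'
#' The round-trippable unit of on-disk storage: a format version, a snapshot
#' of the [StudyConfig-class] that scored the records, the engagement records
#' of one or more participants as a single data.frame, and (for simulated
#' data) the true generating [ParticipantProfile-class] objects.
#'
#' @slot formatVersion character.
#' @slot config StudyConfig snapshot.
#' @slot records data.frame of engagement records (see [writeLog()] for the
#'   column schema).
#' @slot profiles list of ParticipantProfile (empty for real data).
#' @export
setClass("LogBundle", representation(
  formatVersion = "character",
  config = "StudyConfig",
  records = "data.frame",
  profiles = "list"
))

setValidity("LogBundle", function(object) {
  msg <- character()
  need <- recordColumns()
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must contain columns:",
                        paste(setdiff(need, names(object@records)), collapse = ", ")))
  if (nrow(object@records)) {
    sp <- split(object@records$engagement_time, object@records$participant_id)
    if (!all(vapply(sp, function(x) !is.unsorted(x, strictly = TRUE), TRUE)))
      msg <- c(msg, "engagement times must be strictly increasing per participant")
  }
  if (length(msg)) msg else TRUE
})

# Canonical engagement-record column schema (order is the on-disk order).
recordColumns <- function() {
  c("participant_id", "engagement_time", "iti", "trial_index",
    "scheduled_side", "alternation_response", "alternation_correct",
    "stay_shift_label", "change_state", "image_response", "image_correct",
    "error_class", "feedback_given")
}
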