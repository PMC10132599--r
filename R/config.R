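#' Construct a study configuration
#'
#' Builds a validated [StudyConfig-class]. Defaults correspond to the shared
#' protocol constants of both deployment phases: activation intervals drawn
#' between 25 seconds and 3 hours, 56 study days, a rewarded quota of 15
#' engagements/day, inclusion at >= 42 active days with a strict mean of more
#' than 10 engagements per active day, and performance-outlier cutoffs at
#' 90% (high) and 60% (low).
#'
#' @param phaseLabel character label.
#' @param itiMin,itiMax activation-interval bounds, seconds.
#' @param alternationRule "single" (alternate every trial, LRLR) or "double"
#'   (alternate every second trial, LLRR).
#' @param changeRate expected image-change events per day.
#' @param changeMix named probabilities over the change types
#'   `l-IR`, `r-IR`, `d-IR`, `VS`; must sum to 1.
#' @param imagePolicy "cross-category" (displayed images from different
#'   categories) or "within-category" (same category, hence more similar).
#' @param sideBias which single-change side carries the larger probability.
#' @param studyDays,paymentQuota,inclusionMinDays,inclusionMinDaily,outlierHigh,outlierLow
#'   see [StudyConfig-class].
#' @param seed default RNG seed for protocol sampling.
#' @return a [StudyConfig-class] object.
#' @examples
#' cfg <- studyConfig(changeRate = 2)
#' changeMix(cfg)
#' @export
studyConfig <- function(phaseLabel = "custom",
                        itiMin = 25, itiMax = 3 * 3600,
                        alternationRule = c("single", "double"),
                        changeRate = 1,
                        changeMix = c("l-IR" = 0.53, "r-IR" = 0.13,
                                      "d-IR" = 0.13, "VS" = 0.20) / 0.99,
                        imagePolicy = c("cross-category", "within-category"),
                        sideBias = "L",
                        studyDays = 56L, paymentQuota = 15,
                        inclusionMinDays = 42L, inclusionMinDaily = 10,
                        outlierHigh = 0.90, outlierLow = 0.60,
                        seed = 1L) {
  alternationRule <- match.arg(alternationRule)
  imagePolicy <- match.arg(imagePolicy)
  if (!(itiMin > 0 && itiMin <= itiMax))
    stop("invalid configuration: need 0 < itiMin <= itiMax", call. = FALSE)
  new("StudyConfig",
      phaseLabel = phaseLabel,
      itiMin = as.numeric(itiMin), itiMax = as.numeric(itiMax),
      alternationRule = alternationRule,
      changeRate = as.numeric(changeRate),
      changeMix = changeMix[CHANGE_TYPES],
      imagePolicy = imagePolicy, sideBias = sideBias,
      studyDays = as.integer(studyDays),
      paymentQuota = as.numeric(paymentQuota),
      inclusionMinDays = as.integer(inclusionMinDays),
      inclusionMinDaily = as.numeric(inclusionMinDaily),
      outlierHigh = as.numeric(outlierHigh),
      outlierLow = as.numeric(outlierLow),
      seed = as.integer(seed))
}

#' Shipped phase presets
#'
#' The two deployed protocol phases. Phase 1: single spatial alternation,
#' cross-category image pairs, ~1 image change per day with the disbalanced
#' single-change mix 53/13 (biased/unbiased side), 13% double changes and 20%
#' visuospatial swaps. Phase 2: double spatial alternation (LLRR),
#' within-category image pairs, ~5 changes per day with mix 40/25/17/17.
#' Both phases share the 25 s - 3 h activation window, the 56-day duration
#' and the inclusion/outlier thresholds.
#'
#' @param phase "phase1" or "phase2".
#' @param sideBias biased single-change side for this participant; the
#'   deployment balanced the choice across participants.
#' @param seed default RNG seed stored in the config.
#' @return a [StudyConfig-class].
#' @examples
#' phasePreset("phase2")
#' @export
phasePreset <- function(phase = c("phase1", "phase2"), sideBias = "L",
                        seed = 1L) {
  phase <- match.arg(phase)
  single <- switch(phase,
                   phase1 = c(biased = 0.53, other = 0.13),
                   phase2 = c(biased = 0.40, other = 0.25))
  mix <- if (sideBias == "L")
    c("l-IR" = unname(single["biased"]), "r-IR" = unname(single["other"]))
  else
    c("l-IR" = unname(single["other"]), "r-IR" = unname(single["biased"]))
  mix <- switch(phase,
                phase1 = c(mix, "d-IR" = 0.13, "VS" = 0.20),
                phase2 = c(mix, "d-IR" = 0.17, "VS" = 0.17))
  # the deployment's published percentages total 99%; renormalise so the
  # mix is a proper probability vector
  mix <- mix / sum(mix)
  studyConfig(
    phaseLabel = phase,
    alternationRule = if (phase == "phase1") "single" else "double",
    changeRate = if (phase == "phase1") 1 else 5,
    changeMix = mix,
    imagePolicy = if (phase == "phase1") "cross-category" else "within-category",
    sideBias = sideBias,
    seed = seed)
}

#' Read and write study configurations as YAML
#'
#' The on-disk configuration mirrors the [StudyConfig-class] slots as nested
#' key/value pairs; `readStudyConfig()` validates on read.
#'
#' @param path file path.
#' @param config a [StudyConfig-class].
#' @return `readStudyConfig()` returns a [StudyConfig-class];
#'   `writeStudyConfig()` returns `path` invisibly.
#' @export
readStudyConfig <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("phase_label", "iti_min", "iti_max", "alternation_rule",
              "change_rate", "change_mix")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("configuration file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mix <- unlist(x$change_mix)
  # tolerate the text format's limited float precision, then make exact
  if (abs(sum(mix) - 1) > 1e-4)
    stop("change_mix must sum to 1", call. = FALSE)
  studyConfig(
    phaseLabel = x$phase_label, itiMin = x$iti_min, itiMax = x$iti_max,
    alternationRule = x$alternation_rule, changeRate = x$change_rate,
    changeMix = mix / sum(mix),
    imagePolicy = x$image_policy %||% "cross-category",
    sideBias = x$side_bias %||% "L",
    studyDays = x$study_days %||% 56L,
    paymentQuota = x$payment_quota %||% 15,
    inclusionMinDays = x$inclusion_min_days %||% 42L,
    inclusionMinDaily = x$inclusion_min_daily %||% 10,
    outlierHigh = x$outlier_high %||% 0.90,
    outlierLow = x$outlier_low %||% 0.60,
    seed = x$seed %||% 1L)
}

#' @rdname readStudyConfig
#' @export
writeStudyConfig <- function(config, path) {
  stopifnot(is(config, "StudyConfig"))
  x <- list(
    phase_label = config@phaseLabel,
    iti_min = config@itiMin, iti_max = config@itiMax,
    alternation_rule = config@alternationRule,
    change_rate = config@changeRate,
    change_mix = as.list(config@changeMix),
    image_policy = config@imagePolicy, side_bias = config@sideBias,
    study_days = config@studyDays, payment_quota = config@paymentQuota,
    inclusion_min_days = config@inclusionMinDays,
    inclusion_min_daily = config@inclusionMinDaily,
    outlier_high = config@outlierHigh, outlier_low = config@outlierLow,
    seed = config@seed)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
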