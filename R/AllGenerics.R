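#' @rdname StudyConfig-class
#' @param object,x an object.
#' @export
setGeneric("changeMix", function(object) standardGeneric("changeMix"))

#' @rdname StudyConfig-class
#' @export
setGeneric("itiBounds", function(object) standardGeneric("itiBounds"))

#' @rdname StudyConfig-class
#' @export
setGeneric("alternationRule", function(object) standardGeneric("alternationRule"))

#' @rdname PerformanceCurve-class
#' @export
setGeneric("accuracyPerBin", function(object) standardGeneric("accuracyPerBin"))

#' @rdname PerformanceCurve-class
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname PerformanceCurve-class
#' @export
setGeneric("binPositions", function(object) standardGeneric("binPositions"))

#' @rdname AdherenceSurface-class
#' @export
setGeneric("adherenceMatrix", function(object) standardGeneric("adherenceMatrix"))

#' @rdname LogBundle-class
#' @export
setGeneric("engagementRecords", function(object) standardGeneric("engagementRecords"))

#' @rdname LogBundle-class
#' @export
setGeneric("bundleConfig", function(object) standardGeneric("bundleConfig"))

#' @rdname LogBundle-class
#' @export
setGeneric("trueProfiles", function(object) standardGeneric("trueProfiles"))

setMethod("changeMix", "StudyConfig", function(object) object@changeMix)
setMethod("itiBounds", "StudyConfig",
          function(object) c(min = object@itiMin, max = object@itiMax))
setMethod("alternationRule", "StudyConfig", function(object) object@alternationRule)

setMethod("accuracyPerBin", "PerformanceCurve", function(object) object@accuracyPerBin)
setMethod("binCounts", "PerformanceCurve", function(object) object@nPerBin)
setMethod("binPositions", "PerformanceCurve", function(object) object@binPositions)

setMethod("adherenceMatrix", "AdherenceSurface", function(object) object@surface)

setMethod("engagementRecords", "LogBundle", function(object) object@records)
setMethod("bundleConfig", "LogBundle", function(object) object@config)
setMethod("trueProfiles", "LogBundle", function(object) object@profiles)

#' @describeIn PerformanceCurve-class one row per ITI bin.
#' @param row.names,optional,... passed on conventions of as.data.frame.
#' @export
setMethod("as.data.frame", "PerformanceCurve",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      bin = seq_len(5L),
      lower_min = x@binEdges[-6],
      upper_min = x@binEdges[-1],
      median_iti_min = x@binPositions,
      log_median_iti_min = log(x@binPositions),
      n = x@nPerBin,
      accuracy = x@accuracyPerBin,
      under_sampled = x@underSampled
    )
  })

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf("StudyConfig '%s': %s alternation, %g image changes/day\n",
              object@phaseLabel, object@alternationRule, object@changeRate))
  cat(sprintf("  activation interval: [%g s, %g s]; image policy: %s; bias: %s\n",
              object@itiMin, object@itiMax, object@imagePolicy, object@sideBias))
  cat(sprintf("  change mix: %s\n",
              paste(sprintf("%s=%.2f", names(object@changeMix), object@changeMix),
                    collapse = " ")))
  cat(sprintf("  inclusion: >=%d active days of %d, mean daily > %g; outliers: >%g or <%g\n",
              object@inclusionMinDays, object@studyDays, object@inclusionMinDaily,
              object@outlierHigh, object@outlierLow))
})

setMethod("show", "ParticipantProfile", function(object) {
  cat(sprintf("ParticipantProfile '%s' (%s)\n", object@participantId, object@ageGroup))
  cat(sprintf("  forgetting: a=%.2f, beta=%.2f/log-min, lapse=%.2f, gamma=%.2f, delta=%.3f/day\n",
              object@baselineLogit, object@itiDecay, object@lapseRate,
              object@shiftDeficit, object@stayDrift))
  cat(sprintf("  detection: %s; similarity slope %.2f; false alarms %.2f\n",
              paste(sprintf("%s=%.2f", names(object@detectionSensitivity),
                            object@detectionSensitivity), collapse = " "),
              object@similarityEffect, object@falseAlarmRate))
  cat(sprintf("  engagement: %.1f/day, dropout day %s\n",
              object@dailyEngagementRate,
              if (is.finite(object@dropoutDay)) object@dropoutDay else "none"))
})

setMethod("show", "PerformanceCurve", function(object) {
  cat(sprintf("PerformanceCurve [%s]: %d binned trials (%d excluded)\n",
              object@groupLabel, sum(object@nPerBin), object@nExcluded))
  print(as.data.frame(object), digits = 3)
})

setMethod("show", "AdherenceSurface", function(object) {
  cat(sprintf("AdherenceSurface: %d participants, weeks %s x thresholds %s\n",
              object@nParticipants,
              paste(range(object@weeks), collapse = "-"),
              paste(range(object@thresholds), collapse = "-")))
  m <- object@surface
  dimnames(m) <- list(paste0("wk", object@weeks), paste0(">", object@thresholds))
  print(round(m, 3))
})

setMethod("show", "StatsResult", function(object) {
  dfs <- paste(signif(object@df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g",
              object@testName, object@statistic, dfs, object@pValue))
  if (!is.na(object@epsilon)) cat(sprintf(", GG epsilon = %.3f", object@epsilon))
  if (object@correction != "none") cat(sprintf(" [%s]", object@correction))
  cat("\n")
})

setMethod("show", "PracticeEffectResult", function(object) {
  cat(sprintf("Practice effect (%s), days %g-%g (n = %d): rho = %.3f, p = %.4g\n",
              object@component, object@window[1], object@window[2],
              object@nDays, object@rho, object@pValue))
})

setMethod("show", "LogBundle", function(object) {
  cat(sprintf("LogBundle (%s): %d engagements, %d participant(s), config '%s'%s\n",
              object@formatVersion, nrow(object@records),
              length(unique(object@records$participant_id)),
              object@config@phaseLabel,
              if (length(object@profiles)) ", with true profiles" else ""))
})
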