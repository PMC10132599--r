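# Analysis ceiling on realized inter-trial intervals: 5.5 hours. The window
# itself never waits more than 3 h, but participants may re-engage later.
ITI_CEILING <- 330 * 60

#' Sample window-activation intervals
#'
#' Draws the waiting time until the testing window next becomes active.
#' Intervals are log-uniform on `[itiMin, itiMax]` (default 25 s to 3 h):
#' the log-uniform shape concentrates mass at short intervals, matching the
#' protocol's emphasis on frequent short-gap probes, and has a closed-form
#' inverse CDF (`itiMin * (itiMax/itiMin)^u`) so the sampler is exactly
#' invertible for testing. The shape is pluggable via `quantileFun`.
#'
#' @param config a [StudyConfig-class].
#' @param n number of draws.
#' @param quantileFun optional quantile function (inverse CDF) on [0,1]
#'   replacing the log-uniform default; must map into `[itiMin, itiMax]`.
#' @return numeric vector of intervals in seconds, all in `[itiMin, itiMax]`.
#' @examples
#' set.seed(1)
#' range(sampleActivationInterval(phasePreset("phase1"), 1000))
#' @export
sampleActivationInterval <- function(config, n = 1L, quantileFun = NULL) {
  stopifnot(is(config, "StudyConfig"))
  if (!(config@itiMin > 0 && config@itiMin <= config@itiMax))
    stop("invalid configuration: need 0 < itiMin <= itiMax", call. = FALSE)
  u <- stats::runif(n)
  if (is.null(quantileFun))
    config@itiMin * (config@itiMax / config@itiMin)^u
  else
    pmin(pmax(quantileFun(u), config@itiMin), config@itiMax)
}

#' Response-delay models and realized engagement times
#'
#' The window stays active until the participant responds; participants may
#' also ignore the prompt and re-engage later, so the realized inter-trial
#' interval can exceed the 3 h activation bound (analysis treats 5.5 h as
#' the ceiling). `defaultDelayModel()` returns the default latency model: a
#' mixture of a prompt response (exponential, median 30 s, weight 0.95) and
#' a heavy delayed-re-engagement tail (exponential, mean 30 min).
#'
#' `engagementTime()` adds a delay drawn from the model to each activation
#' time; when `prevTime` is supplied the result is capped so the realized
#' ITI does not exceed 5.5 h.
#'
#' @param promptMedian median prompt-response delay, seconds.
#' @param tailWeight probability of a delayed re-engagement.
#' @param tailMean mean of the delayed tail, seconds.
#' @return `defaultDelayModel()` returns a function(n) producing nonnegative
#'   delays; `engagementTime()` returns engagement timestamps.
#' @export
defaultDelayModel <- function(promptMedian = 30, tailWeight = 0.05,
                              tailMean = 1800) {
  force(promptMedian); force(tailWeight); force(tailMean)
  function(n) {
    tail <- stats::runif(n) < tailWeight
    ifelse(tail, stats::rexp(n, 1 / tailMean),
           stats::rexp(n, log(2) / promptMedian))
  }
}

#' @rdname defaultDelayModel
#' @param activationTime activation timestamps (seconds since study start).
#' @param delayModel function(n) returning nonnegative delays in seconds.
#' @param prevTime previous engagement timestamps (same length or NULL);
#'   when given, engagement times are capped at `prevTime + 5.5 h`.
#' @export
engagementTime <- function(activationTime, delayModel = defaultDelayModel(),
                           prevTime = NULL) {
  d <- delayModel(length(activationTime))
  if (any(d < 0)) stop("delay model produced a negative delay", call. = FALSE)
  t <- activationTime + d
  if (!is.null(prevTime)) t <- pmin(t, prevTime + ITI_CEILING)
  t
}

#' Deterministic alternation schedules
#'
#' `scheduledSide()` gives the correct side at a 0-based trial index under
#' the single-alternation rule (flip every trial, LRLR...) or the
#' double-alternation rule (flip every second trial, LLRR...). The schedule
#' is program-side and advances deterministically regardless of what the
#' participant pressed.
#'
#' `classifyStayShift()` labels each classified trial by whether the correct
#' response repeats the previous correct side (win-stay) or reverses it
#' (win-shift). Index 0 has no predecessor and is "unclassified"; under the
#' single rule every later trial is a shift; under the double rule labels
#' alternate stay, shift, stay, shift from index 1.
#'
#' @param trialIndex integer vector of 0-based trial indices.
#' @param rule "single" or "double".
#' @param startSide "L" or "R".
#' @return character vector of sides / labels.
#' @examples
#' scheduledSide(0:7, "double")          # L L R R L L R R
#' classifyStayShift(0:4, "double")
#' @export
scheduledSide <- function(trialIndex, rule = c("single", "double"),
                          startSide = "L") {
  rule <- match.arg(rule)
  stopifnot(all(trialIndex >= 0), startSide %in% c("L", "R"))
  other <- if (startSide == "L") "R" else "L"
  onStart <- switch(rule,
                    single = trialIndex %% 2L == 0L,
                    double = trialIndex %% 4L < 2L)
  ifelse(onStart, startSide, other)
}

#' @rdname scheduledSide
#' @export
classifyStayShift <- function(trialIndex, rule = c("single", "double")) {
  rule <- match.arg(rule)
  stopifnot(all(trialIndex >= 0))
  prev <- scheduledSide(pmax(trialIndex - 1L, 0L), rule)
  cur <- scheduledSide(trialIndex, rule)
  out <- ifelse(cur == prev, "stay", "shift")
  out[trialIndex == 0L] <- "unclassified"
  out
}

#' Button semantics of the image tasks
#'
#' Maps a pending change state to the button set a correct responder must
#' press: nothing for no change, the side button for a single image change,
#' and both buttons when both images changed (d-IR) or swapped places (VS).
#' Button sets are encoded as the strings "", "L", "R", "LR".
#'
#' @param changeState character vector over none, l-IR, r-IR, d-IR, VS.
#' @return character vector of button sets.
#' @examples
#' expectedButtons(c("none", "l-IR", "VS"))
#' @export
expectedButtons <- function(changeState) {
  bad <- !changeState %in% CHANGE_STATES
  if (any(bad))
    stop("unknown change state: ", paste(unique(changeState[bad]), collapse = ", "),
         call. = FALSE)
  unname(c(none = "", `l-IR` = "L", `r-IR` = "R",
           `d-IR` = "LR", VS = "LR")[changeState])
}

#' Image-task error taxonomy
#'
#' Classifies an image-task response against the pending change state:
#' \itemize{
#'   \item \code{correct}: response equals the expected button set;
#'   \item \code{missing_change}: a change occurred, no button pressed;
#'   \item \code{overreaction_to_no_change}: no change, any button pressed;
#'   \item \code{wrong_side}: a single-image change answered with the wrong
#'     side (or with both buttons);
#'   \item \code{partial_detection}: a two-button change (d-IR, VS) answered
#'     with only one button.
#' }
#'
#' @param imageResponse character vector of pressed button sets
#'   ("", "L", "R", "LR").
#' @param changeState character vector of pending change states.
#' @return character vector of error classes.
#' @examples
#' errorType("R", "l-IR")      # wrong_side
#' errorType("LR", "none")     # overreaction_to_no_change
#' @export
errorType <- function(imageResponse, changeState) {
  stopifnot(all(imageResponse %in% BUTTON_SETS))
  expected <- expectedButtons(changeState)
  out <- rep("correct", length(expected))
  mismatch <- imageResponse != expected
  noChange <- changeState == "none"
  single <- changeState %in% c("l-IR", "r-IR")
  double <- changeState %in% c("d-IR", "VS")
  out[mismatch & !noChange & imageResponse == ""] <- "missing_change"
  out[mismatch & noChange] <- "overreaction_to_no_change"
  out[mismatch & single & imageResponse != ""] <- "wrong_side"
  out[mismatch & double & imageResponse %in% c("L", "R")] <- "partial_detection"
  out
}

#' Score engagement records
#'
#' Fills the scoring fields of an engagement log: the scheduled side, the
#' alternation correctness, the win-stay/win-shift label, the image-task
#' correctness and error class, and the feedback flag (feedback was given on
#' alternation choices only, never on the image tasks). The alternation
#' schedule advances deterministically by default; `reanchor = TRUE` instead
#' re-anchors the state machine to the participant's previous actual press
#' (correct side = previous press under a stay label, its opposite under a
#' shift label). `stayShiftReference` selects whether stay/shift is defined
#' against the previous scheduled side (default) or the previous press.
#'
#' @param records data.frame with at least `participant_id`, `trial_index`,
#'   `alternation_response`, `image_response`, `change_state`.
#' @param config a [StudyConfig-class] (supplies the alternation rule).
#' @param startSide schedule start side ("L" or "R"), recycled per
#'   participant.
#' @param reanchor logical; see Details.
#' @param stayShiftReference "scheduled" or "response".
#' @return the input data.frame with `scheduled_side`,
#'   `alternation_correct`, `stay_shift_label`, `image_correct`,
#'   `error_class` and `feedback_given` (re)computed.
#' @export
scoreEngagements <- function(records, config, startSide = "L",
                             reanchor = FALSE,
                             stayShiftReference = c("scheduled", "response")) {
  stayShiftReference <- match.arg(stayShiftReference)
  need <- c("participant_id", "trial_index", "alternation_response",
            "image_response", "change_state")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing fields: ", paste(miss, collapse = ", "), call. = FALSE)
  rule <- config@alternationRule
  idx <- records$trial_index
  if (!reanchor) {
    records$scheduled_side <- scheduledSide(idx, rule, startSide)
  } else {
    records$scheduled_side <- .reanchoredSide(records, rule, startSide)
  }
  records$stay_shift_label <- classifyStayShift(idx, rule)
  if (stayShiftReference == "response") {
    prevResp <- stats::ave(records$alternation_response, records$participant_id,
                    FUN = function(x) c(NA, x[-length(x)]))
    lab <- ifelse(records$scheduled_side == prevResp, "stay", "shift")
    lab[idx == 0L] <- "unclassified"
    records$stay_shift_label <- lab
  }
  # first trial carries no memory demand: always scored correct (and later
  # excluded from performance curves via its undefined ITI)
  records$alternation_correct <-
    records$alternation_response == records$scheduled_side | idx == 0L
  records$error_class <- errorType(records$image_response, records$change_state)
  records$image_correct <- records$error_class == "correct"
  records$feedback_given <- TRUE  # alternation feedback only; image tasks get none
  records
}

# Re-anchored schedule: the correct side follows the participant's previous
# actual press through the rule's stay/shift sequence.
.reanchoredSide <- function(records, rule, startSide) {
  labels <- classifyStayShift(records$trial_index, rule)
  out <- character(nrow(records))
  for (pid in unique(records$participant_id)) {
    i <- which(records$participant_id == pid)
    side <- startSide
    for (k in seq_along(i)) {
      r <- i[k]
      if (records$trial_index[r] > 0L) {
        prevPress <- records$alternation_response[i[k - 1L]]
        side <- if (labels[r] == "stay") prevPress
                else if (prevPress == "L") "R" else "L"
      }
      out[r] <- side
    }
  }
  out
}

#' Generate the image pool
#'
#' Images are opaque identifiers with a category attribute; no pixel content
#' is modelled. The default pool mirrors a deployment with a handful of
#' everyday categories (planes, dogs, highways, buildings, ...).
#'
#' @param nCategories number of image categories.
#' @param perCategory images per category.
#' @return data.frame with columns `image_id`, `category`.
#' @export
makeImagePool <- function(nCategories = 8L, perCategory = 25L) {
  if (nCategories < 1L || perCategory < 1L)
    stop("image pool is empty", call. = FALSE)
  cat <- rep(paste0("cat", seq_len(nCategories)), each = perCategory)
  data.frame(image_id = paste0(cat, "_img", rep(seq_len(perCategory), nCategories)),
             category = cat, stringsAsFactors = FALSE)
}

#' Schedule image-change events
#'
#' Draws the image-change event stream of a study: event times form a
#' Poisson process at `changeRate` per day, event types are i.i.d. from the
#' configured change mix, and the displayed image pair evolves event by
#' event. Under the cross-category policy the two displayed images come from
#' distinct categories; within-category pairs share one category (and are
#' therefore more similar). A visuospatial (VS) event swaps the two image
#' positions without changing identities; l-IR/r-IR replace one image; d-IR
#' replaces both.
#'
#' @param config a [StudyConfig-class].
#' @param horizonDays number of days to schedule (>= 1).
#' @param imagePool data.frame from [makeImagePool()].
#' @param initialPair optional character(2) of starting image ids.
#' @return data.frame of events: `event_time` (seconds), `change_type`,
#'   `category`, `before_left`, `before_right`, `after_left`, `after_right`,
#'   `similarity` (0.7 for same-category pairs, 0.2 otherwise).
#' @examples
#' ev <- scheduleChangeEvents(phasePreset("phase1"), 7)
#' table(ev$change_type)
#' @export
scheduleChangeEvents <- function(config, horizonDays,
                                 imagePool = makeImagePool(),
                                 initialPair = NULL) {
  stopifnot(is(config, "StudyConfig"), horizonDays >= 1)
  if (nrow(imagePool) < 4L)
    stop("image pool is empty or too small", call. = FALSE)
  nEvents <- stats::rpois(1L, config@changeRate * horizonDays)
  if (nEvents == 0L) {
    out <- data.frame(event_time = numeric(0), change_type = character(0),
                      category = character(0), before_left = character(0),
                      before_right = character(0), after_left = character(0),
                      after_right = character(0), similarity = numeric(0))
    return(out)
  }
  times <- sort(stats::runif(nEvents, 0, horizonDays * 86400))
  types <- sample(CHANGE_TYPES, nEvents, replace = TRUE, prob = config@changeMix)
  within <- config@imagePolicy == "within-category"
  poolCat <- split(imagePool$image_id, imagePool$category)
  cats <- names(poolCat)
  pair <- initialPair
  if (is.null(pair)) pair <- .drawPair(poolCat, cats, within)
  catOf <- stats::setNames(imagePool$category, imagePool$image_id)
  beforeL <- beforeR <- afterL <- afterR <- character(nEvents)
  evCat <- character(nEvents)
  for (i in seq_len(nEvents)) {
    beforeL[i] <- pair[1]; beforeR[i] <- pair[2]
    switch(types[i],
      "VS" = { pair <- rev(pair) },
      "l-IR" = { pair[1] <- .drawImage(poolCat, catOf, pair, side = 1L, within) },
      "r-IR" = { pair[2] <- .drawImage(poolCat, catOf, pair, side = 2L, within) },
      "d-IR" = {
        pair[1] <- .drawImage(poolCat, catOf, pair, side = 1L, within)
        pair[2] <- .drawImage(poolCat, catOf, pair, side = 2L, within)
      })
    afterL[i] <- pair[1]; afterR[i] <- pair[2]
    evCat[i] <- paste(unique(catOf[pair]), collapse = "+")
  }
  data.frame(event_time = times, change_type = types, category = evCat,
             before_left = beforeL, before_right = beforeR,
             after_left = afterL, after_right = afterR,
             similarity = ifelse(catOf[afterL] == catOf[afterR], 0.7, 0.2),
             row.names = NULL, stringsAsFactors = FALSE)
}

.drawPair <- function(poolCat, cats, within) {
  if (within) {
    ct <- sample(cats, 1L)
    sample(poolCat[[ct]], 2L)
  } else {
    ct <- sample(cats, 2L)
    c(sample(poolCat[[ct[1]]], 1L), sample(poolCat[[ct[2]]], 1L))
  }
}

# Replacement image for one side, honouring the pairing policy.
.drawImage <- function(poolCat, catOf, pair, side, within) {
  otherCat <- catOf[[pair[3L - side]]]
  candCat <- if (within) otherCat else setdiff(names(poolCat), otherCat)
  if (length(candCat) > 1L) candCat <- sample(candCat, 1L)
  cand <- setdiff(poolCat[[candCat]], pair)
  if (!length(cand)) stop("image pool exhausted", call. = FALSE)
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Net change state between two displayed pairs
#'
#' A change is only visible at the first engagement after it happens, and
#' several changes between two engagements collapse to the net difference
#' between what was last seen and what is now displayed: identical pairs are
#' "none", a pure position swap is "VS", one differing identity is
#' l-IR/r-IR, and two differing identities are "d-IR".
#'
#' @param seenLeft,seenRight image ids at the previous engagement.
#' @param nowLeft,nowRight image ids displayed now.
#' @return character vector of change states.
#' @export
netChangeState <- function(seenLeft, seenRight, nowLeft, nowRight) {
  same <- seenLeft == nowLeft & seenRight == nowRight
  swap <- !same & seenLeft == nowRight & seenRight == nowLeft
  ldiff <- seenLeft != nowLeft
  rdiff <- seenRight != nowRight
  out <- rep("none", length(same))
  out[swap] <- "VS"
  out[!same & !swap & ldiff & !rdiff] <- "l-IR"
  out[!same & !swap & !ldiff & rdiff] <- "r-IR"
  out[!same & !swap & ldiff & rdiff] <- "d-IR"
  out
}
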