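test_that("alternation schedules match a brute-force state machine", {
  # oracle: explicit state machine stepping one trial at a time
  machineSides <- function(n, rule, start = "L") {
    side <- start
    phase <- 0L
    out <- character(n)
    for (i in seq_len(n)) {
      out[i] <- side
      if (rule == "single") {
        side <- if (side == "L") "R" else "L"
      } else {
        phase <- phase + 1L
        if (phase == 2L) {
          side <- if (side == "L") "R" else "L"
          phase <- 0L
        }
      }
    }
    out
  }
  n <- 10001L
  for (rule in c("single", "double")) {
    expect_identical(scheduledSide(0:(n - 1), rule, "L"),
                     machineSides(n, rule, "L"))
    expect_identical(scheduledSide(0:(n - 1), rule, "R"),
                     machineSides(n, rule, "R"))
  }
  # printed patterns
  expect_identical(scheduledSide(0:7, "double", "L"),
                   c("L", "L", "R", "R", "L", "L", "R", "R"))
  expect_identical(scheduledSide(0:3, "single", "L"), c("L", "R", "L", "R"))
  expect_identical(scheduledSide(0L, "double", "R"), "R")
  # period 4
  expect_identical(scheduledSide(0:9999, "double"),
                   scheduledSide(0:9999 + 4L, "double"))
})

test_that("stay/shift labels follow the schedule and balance over windows", {
  expect_identical(classifyStayShift(0L, "double"), "unclassified")
  expect_identical(classifyStayShift(1:4, "double"),
                   c("stay", "shift", "stay", "shift"))
  expect_true(all(classifyStayShift(1:50, "single") == "shift"))
  # 1001 trials -> 500 stay, 500 shift among the 1000 classified
  lab <- classifyStayShift(0:1000, "double")
  expect_equal(sum(lab == "stay"), 500)
  expect_equal(sum(lab == "shift"), 500)
  # any window of 2k consecutive classified trials is balanced
  lab <- classifyStayShift(0:5000, "double")[-1]
  for (startAt in c(1, 2, 7, 100)) {
    w <- lab[startAt:(startAt + 399)]
    expect_equal(sum(w == "stay"), 200)
  }
})

test_that("activation-interval sampler respects bounds and its inverse CDF", {
  cfg <- phasePreset("phase1")
  set.seed(41)
  x <- sampleActivationInterval(cfg, 1e5)
  expect_true(all(x >= 25 & x <= 10800))
  # one-sample KS against the log-uniform CDF, below the 1% critical value
  ks <- stats::ks.test(x, function(t) log(t / 25) / log(10800 / 25))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1e5))
  # degenerate point mass
  cfg60 <- studyConfig(itiMin = 60, itiMax = 60)
  expect_true(all(sampleActivationInterval(cfg60, 100) == 60))
  # inverted bounds are a configuration error
  expect_error(studyConfig(itiMin = 100, itiMax = 50), "itiMin")
})

test_that("engagement times add nonnegative delays and cap at 5.5 h", {
  expect_equal(engagementTime(1000, function(n) rep(0, n)), 1000)
  # point-mass 2.5 h delay on an activation 3 h after the previous
  # engagement: realized ITI is 5.5 h, inside the last analysis bin
  et <- engagementTime(3 * 3600, function(n) rep(2.5 * 3600, n), prevTime = 0)
  expect_equal(et, 5.5 * 3600)
  expect_error(engagementTime(0, function(n) rep(-1, n)), "negative")
  set.seed(7)
  act <- cumsum(sampleActivationInterval(phasePreset("phase1"), 1e4))
  eng <- engagementTime(act, defaultDelayModel())
  expect_true(all(eng >= act))
})

test_that("change-event streams follow the configured rate and mix", {
  set.seed(11)
  cfg2 <- phasePreset("phase2")
  ev <- scheduleChangeEvents(cfg2, 56)
  # Poisson count: mean 5/day, 3 sd band for one 56-day draw
  expect_lt(abs(nrow(ev) / 56 - 5), 3 * sqrt(5 / 56))
  expect_true(all(diff(ev$event_time) >= 0))
  expect_true(all(ev$change_type %in% c("l-IR", "r-IR", "d-IR", "VS")))
  # zero rate -> empty stream
  ev0 <- scheduleChangeEvents(studyConfig(changeRate = 0), 10)
  expect_equal(nrow(ev0), 0)
  # chi-square goodness of fit to the mix: >= 19/20 seeds not rejected at 1%
  pass <- 0L
  for (s in 1:20) {
    set.seed(s)
    ev <- scheduleChangeEvents(phasePreset("phase1"), 5000)
    obs <- table(factor(ev$change_type, c("l-IR", "r-IR", "d-IR", "VS")))
    p <- stats::chisq.test(obs, p = changeMix(phasePreset("phase1")))$p.value
    pass <- pass + (p > 0.01)
  }
  expect_gte(pass, 19L)
})

test_that("change events respect pairing policy and VS swaps identities", {
  set.seed(3)
  catOf <- function(id) sub("_img.*$", "", id)
  evW <- scheduleChangeEvents(phasePreset("phase2"), 200)
  expect_true(all(catOf(evW$after_left) == catOf(evW$after_right)))
  evC <- scheduleChangeEvents(phasePreset("phase1"), 400)
  expect_true(all(catOf(evC$after_left) != catOf(evC$after_right)))
  for (ev in list(evW, evC)) {
    vs <- ev$change_type == "VS"
    expect_true(all(ev$after_left[vs] == ev$before_right[vs]))
    expect_true(all(ev$after_right[vs] == ev$before_left[vs]))
    single <- ev$change_type == "l-IR"
    expect_true(all(ev$after_left[single] != ev$before_left[single]))
    expect_true(all(ev$after_right[single] == ev$before_right[single]))
    dbl <- ev$change_type == "d-IR"
    expect_true(all(ev$after_left[dbl] != ev$before_left[dbl] &
                    ev$after_right[dbl] != ev$before_right[dbl]))
  }
  expect_error(scheduleChangeEvents(phasePreset("phase1"), 10,
                                    imagePool = makeImagePool(1, 2)[1:2, ]),
               "pool")
})

test_that("net change state collapses multiple changes correctly", {
  expect_equal(netChangeState("a", "b", "a", "b"), "none")
  expect_equal(netChangeState("a", "b", "b", "a"), "VS")
  expect_equal(netChangeState("a", "b", "c", "b"), "l-IR")
  expect_equal(netChangeState("a", "b", "a", "c"), "r-IR")
  expect_equal(netChangeState("a", "b", "c", "d"), "d-IR")
  # swap plus replacement reads as a double change
  expect_equal(netChangeState("a", "b", "b", "c"), "d-IR")
})

test_that("button semantics and the error taxonomy cover all 20 cases", {
  expect_equal(expectedButtons(c("none", "l-IR", "r-IR", "d-IR", "VS")),
               c("", "L", "R", "LR", "LR"))
  expect_error(expectedButtons("both"), "unknown")
  # exhaustive response-subset x change-state enumeration with expectations
  # derived from the taxonomy rules, written out case by case
  states <- c("none", "l-IR", "r-IR", "d-IR", "VS")
  responses <- c("", "L", "R", "LR")
  expectedClass <- function(resp, state) {
    want <- c(none = "", `l-IR` = "L", `r-IR` = "R", `d-IR` = "LR",
              VS = "LR")[[state]]
    if (resp == want) return("correct")
    if (state == "none") return("overreaction_to_no_change")
    if (resp == "") return("missing_change")
    if (state %in% c("l-IR", "r-IR")) return("wrong_side")
    "partial_detection"
  }
  for (st in states) for (r in responses) {
    expect_identical(errorType(r, st), expectedClass(r, st),
                     label = paste(st, r))
    # correct iff the response equals the expected button set
    expect_identical(errorType(r, st) == "correct",
                     r == expectedButtons(st))
  }
  expect_equal(errorType("R", "l-IR"), "wrong_side")
  expect_equal(errorType("LR", "none"), "overreaction_to_no_change")
  expect_equal(errorType("LR", "d-IR"), "correct")
})

test_that("scoring fills correctness, labels and the feedback flag", {
  rec <- data.frame(
    participant_id = "A", engagement_time = c(0, 60, 120), iti = c(NA, 60, 60),
    trial_index = 0:2, alternation_response = c("L", "R", "R"),
    image_response = c("", "L", ""), change_state = c("none", "d-IR", "VS"),
    stringsAsFactors = FALSE)
  out <- scoreEngagements(rec, phasePreset("phase1"), startSide = "L")
  expect_equal(out$scheduled_side, c("L", "R", "L"))
  expect_equal(out$alternation_correct, c(TRUE, TRUE, FALSE))
  expect_equal(out$error_class,
               c("correct", "partial_detection", "missing_change"))
  expect_equal(out$image_correct, c(TRUE, FALSE, FALSE))
  expect_true(all(out$feedback_given))  # alternation only; image tasks get none
  expect_error(scoreEngagements(rec[, 1:3], phasePreset("phase1")), "missing")
})

test_that("re-anchored scheduling follows the participant's previous press", {
  rec <- data.frame(
    participant_id = "A", engagement_time = c(0, 60, 120, 180),
    iti = c(NA, 60, 60, 60), trial_index = 0:3,
    alternation_response = c("L", "L", "L", "R"),
    image_response = "", change_state = "none", stringsAsFactors = FALSE)
  out <- scoreEngagements(rec, phasePreset("phase1"), startSide = "L",
                          reanchor = TRUE)
  # single rule: correct side is always the opposite of the previous press
  expect_equal(out$scheduled_side, c("L", "R", "R", "R"))
  expect_equal(out$alternation_correct, c(TRUE, FALSE, FALSE, TRUE))
})
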