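test_that("trials land in the documented ITI bins", {
  # 90 s -> bin 1; 7 min -> bin 3; 3.2 h -> bin 5; boundary values go left
  # (2 -> bin 1, 5 -> bin 2, 10 -> bin 3, 30 -> bin 4, 330 -> bin 5)
  log1 <- logWithItis(c(1.5, 7, 192, 2, 5, 10, 30, 330))
  pc <- binPerformance(log1)
  expect_equal(binCounts(pc), c(2L, 1L, 2L, 1L, 2L))
  expect_equal(pc@nExcluded, 1L)  # the first trial has no ITI
  expect_equal(sum(binCounts(pc)) + pc@nExcluded, nrow(log1))
  # median positions lie inside their bins
  pos <- binPositions(pc)
  expect_true(all(pos > c(0, 2, 5, 10, 30) & pos <= c(2, 5, 10, 30, 330)))
  # all-correct log gives accuracy 1 in every populated bin
  expect_true(all(accuracyPerBin(pc) == 1))
  # under-sampling flag reflects the >100 samples gate
  expect_true(all(pc@underSampled))
  expect_error(binPerformance(logWithItis(numeric(0))[0, ]), "no records")
})

test_that("simulated forgetting yields declining bin accuracy", {
  neg <- 0L
  for (s in 1:20) {
    b <- simulateCohort(c(older = 3), phasePreset("phase1"), seed = 100 + s)
    acc <- accuracyPerBin(binPerformance(b))
    neg <- neg + (stats::cor(acc, 1:5, method = "spearman") < 0)
  }
  expect_gte(neg, 19L)
})

test_that("inclusion criteria enforce the printed thresholds strictly", {
  b <- makeFixtures("boundary_inclusion", seed = 1)
  rep <- applyInclusionCriteria(b, bundleConfig(b))
  rep <- rep[order(rep$participant_id), ]
  # 43 days at 12/day passes; 41 days at 20/day fails (days);
  # 42 days at exactly 10/day fails the strict >10 rule; 50 at 15 passes
  expect_equal(rep$pass_alternation, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(rep$active_days, c(43L, 41L, 42L, 50L))
  expect_equal(rep$mean_daily_engagements, c(12, 20, 10, 15))
  # the fixture logs carry no change events, so image criteria fail
  expect_false(any(rep$pass_image))
  expect_true(all(rep$overall_included == (rep$pass_alternation &
                                           rep$outlier_class == "none")))
})

test_that("inclusion filter agrees with a brute-force re-count", {
  cfg <- phasePreset("phase1")
  set.seed(77)
  for (i in 1:50) {
    days <- sample(35:56, 1)
    perDay <- sample(8:14, 1)
    r <- gridLogDaily(sprintf("R%02d", i), days, perDay)
    rep <- applyInclusionCriteria(r, cfg)
    # independent re-count from raw times
    dayIdx <- floor(r$engagement_time / 86400)
    pass <- length(unique(dayIdx)) >= 42 &&
      nrow(r) / length(unique(dayIdx)) > 10
    expect_identical(rep$pass_alternation, pass, label = paste("cohort", i))
  }
})

test_that("outlier classes use strict boundaries", {
  cfg <- phasePreset("phase1")
  expect_equal(flagOutliers(c(0.95, 0.90, 0.89, 0.61, 0.60, 0.59), cfg),
               c("high", "none", "none", "none", "none", "low"))
})

test_that("adherence surfaces are exact on fixtures and monotone", {
  # 10 participants, exactly 4 meeting >=42 days and >10/day
  logs <- list()
  for (i in 1:4) logs[[i]] <- gridLogDaily(sprintf("Y%02d", i), 45, 12)
  for (i in 5:8) logs[[i]] <- gridLogDaily(sprintf("N%02d", i), 30, 12)
  for (i in 9:10) logs[[i]] <- gridLogDaily(sprintf("M%02d", i), 45, 9)
  r <- do.call(rbind, logs)
  s <- adherenceSurface(r, weeks = 6, thresholds = 10)
  expect_equal(unname(adherenceMatrix(s)[1, 1]), 0.4)
  expect_equal(unname(adherenceMatrix(adherenceSurface(r, weeks = 0,
                                                       thresholds = 0))[1, 1]),
               1.0)
  # monotone non-increasing along both axes on an arbitrary cohort
  b <- simulateCohort(c(younger = 3, middle = 3, older = 3),
                      phasePreset("phase1"), seed = 31)
  m <- adherenceMatrix(adherenceSurface(b))
  expect_true(all(apply(m, 2, function(col) all(diff(col) <= 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) <= 0))))
})

test_that("first-day analysis excludes single-engagement participants", {
  one <- gridLogDaily("ONE", 1, 1)
  many <- gridLogDaily("MANY", 1, 25)
  res <- firstDayAnalysis(rbind(one, many), minFirstDayEngagements = 19)
  expect_equal(res$nEligible, 1L)
  expect_equal(res$adherence, 1.0)  # 25 > 19
  # the curve is built from the eligible participant's 24 binnable trials only
  expect_equal(sum(binCounts(res$curve)) + res$curve@nExcluded, 25L)
  # min = 0 -> every eligible participant counts
  expect_equal(firstDayAnalysis(rbind(one, many), 0)$adherence, 1.0)
  res2 <- firstDayAnalysis(rbind(many, gridLogDaily("MID", 1, 12)), 19)
  expect_equal(res2$adherence, 0.5)
})

test_that("practice-effect trends behave on constructed daily series", {
  cfg2 <- phasePreset("phase2")
  set.seed(5)
  up <- gridLogDaily("UP", 20, 40,
                     accuracyByDay = function(d) 0.4 + 0.025 * d,
                     config = cfg2)
  res <- practiceEffect(up, "overall", window = c(1, 20))
  expect_gt(res@rho, 0.8)
  expect_lt(res@pValue, 0.01)
  # perfectly monotone daily means give rho exactly 1
  det <- gridLogDaily("DET", 5, 30,
                      accuracyByDay = function(d) c(0, 0.25, 0.5, 0.75, 1)[d],
                      config = cfg2)
  resDet <- practiceEffect(det, "overall", window = c(1, 5))
  expect_equal(resDet@rho, 1)
  # constant daily means: rho undefined, p = 1
  flat <- gridLogDaily("FLAT", 6, 30, accuracyByDay = function(d) 1,
                       config = cfg2)
  resFlat <- practiceEffect(flat, "stay", window = c(1, 6))
  expect_true(is.na(resFlat@rho))
  expect_gte(resFlat@pValue, 0.05)
  expect_error(practiceEffect(flat[dayIndex(flat$engagement_time) <= 2, ]),
               "3 distinct days")
})

test_that("early/late splits need ten measurements per block", {
  cfg <- phasePreset("phase1")
  r20 <- logWithItis(rep(5, 20), correct = c(rep(FALSE, 10), rep(TRUE, 10)))
  s20 <- earlyLateSplit(r20, "alternation")
  expect_equal(c(s20$block1_n, s20$block2_n), c(10, 10))
  expect_true(s20$included)
  expect_equal(s20$block2_accuracy, 1.0)  # perfect late block
  r19 <- logWithItis(rep(5, 19))
  s19 <- earlyLateSplit(r19, "alternation")
  expect_equal(c(s19$block1_n, s19$block2_n), c(10, 9))
  expect_false(s19$included)
})

test_that("error breakdown rows are normalised distributions", {
  perfect <- makeFixtures("perfect_responder", seed = 2)
  tab <- errorBreakdown(perfect)
  propCols <- c("correct", "missing_change", "wrong_side",
                "partial_detection", "overreaction_to_no_change")
  expect_true(all(abs(rowSums(tab[, propCols]) - 1) < 1e-12))
  expect_true(all(tab$correct == 1))  # diagonal: every class answered exactly
  # miss-dominated responder: VS missed more than d-IR
  dull <- makeFixtures("miss_dominated", seed = 2)
  tabD <- errorBreakdown(dull)
  expect_gt(tabD$missing_change[tabD$change_state == "VS"],
            tabD$missing_change[tabD$change_state == "d-IR"])
})

test_that("image-task performance supports both denominators", {
  b <- makeFixtures("miss_dominated", seed = 4)
  chg <- imageTaskPerformance(b, "change-only")
  all <- imageTaskPerformance(b, "all")
  expect_gt(all[["n"]], chg[["n"]])
  expect_gte(all[["accuracy"]], chg[["accuracy"]])  # correct rejections help
})
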