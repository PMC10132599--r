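test_that("Greenhouse-Geisser epsilon obeys its bounds and identities", {
  expect_equal(ggEpsilon(diag(5)), 1)
  # k = 2: bounds coincide, epsilon is always 1
  set.seed(1)
  for (i in 1:10) {
    A <- matrix(rnorm(4), 2)
    expect_equal(ggEpsilon(crossprod(A)), 1)
  }
  # random covariances stay in [1/(k-1), 1]
  for (i in 1:25) {
    A <- matrix(rnorm(25), 5)
    eps <- ggEpsilon(crossprod(A))
    expect_gte(eps, 0.25)
    expect_lte(eps, 1)
  }
  expect_error(ggEpsilon(matrix(1:6, 2, 3)), "symmetric")
  expect_error(ggEpsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("gg epsilon matches an independent textbook formula", {
  # oracle: eigenvalue form of the correction on orthonormal contrasts
  oracle <- function(S) {
    k <- ncol(S)
    M <- stats::contr.helmert(k)
    M <- M %*% diag(1 / sqrt(colSums(M^2)))  # orthonormalised contrasts
    lam <- eigen(t(M) %*% S %*% M, symmetric = TRUE, only.values = TRUE)$values
    sum(lam)^2 / ((k - 1) * sum(lam^2))
  }
  set.seed(2)
  for (i in 1:20) {
    S <- crossprod(matrix(rnorm(25), 5)) + diag(5)
    expect_equal(ggEpsilon(S), oracle(S), tolerance = 1e-10)
  }
})

test_that("repeated-measures ANOVA agrees with car::Anova", {
  skip_if_not_installed("car")
  set.seed(3)
  for (i in 1:5) {
    n <- 15; k <- 5
    y <- matrix(rnorm(n * k, mean = rep(seq_len(k) / 10, each = n)), n, k)
    res <- rmAnovaGG(y)
    fit <- stats::lm(y ~ 1)
    av <- car::Anova(fit, idata = data.frame(bin = factor(1:k)),
                     idesign = ~bin, type = "III")
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    expect_equal(res@statistic, unname(s$univariate.tests["bin", "F value"]),
                 tolerance = 1e-8)
    expect_equal(res@epsilon, unname(s$pval.adjustments["bin", "GG eps"]),
                 tolerance = 1e-8)
    expect_equal(res@pValue, unname(s$pval.adjustments["bin", "Pr(>F[GG])"]),
                 tolerance = 1e-8)
  }
})

test_that("rm-ANOVA input handling: missing cells and tiny samples", {
  set.seed(4)
  y <- matrix(rnorm(25), 5, 5)
  y[2, 3] <- NA
  expect_warning(res <- rmAnovaGG(y), "dropped")
  expect_equal(res@details$n_subjects, 4)
  expect_error(suppressWarnings(rmAnovaGG(matrix(rnorm(10), 2, 5))),
               "3 complete subjects")
})

test_that("epsilon is 1 under compound symmetry", {
  # population compound-symmetric covariance: epsilon is exactly 1
  cs <- matrix(2, 5, 5) + diag(5)
  expect_equal(ggEpsilon(cs), 1)
  # sample estimate at n = 200 sits just below 1 (the estimator's known
  # negative bias under sphericity)
  set.seed(5)
  n <- 200; k <- 5
  subj <- rnorm(n, sd = 2)
  y <- matrix(subj, n, k) + matrix(rnorm(n * k), n, k)
  expect_gt(rmAnovaGG(y)@epsilon, 0.95)
})

test_that("the battery dispatches to the reference tests", {
  res <- statBattery("paired_t", x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(res@statistic, 0)
  expect_equal(res@pValue, 1)
  res <- statBattery("kruskal_wallis", x = rep(c(1, 2, 3), 3),
                     groups = rep(1:3, each = 3))
  expect_lt(abs(res@statistic), 1e-12)
  expect_error(statBattery("mann_whitney", x = 1:3), "arg")
  set.seed(6)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20); g <- rep(1:4, each = 5)
    expect_equal(statBattery("paired_t", x = x, y = y)@pValue,
                 stats::t.test(x, y, paired = TRUE)$p.value, tolerance = 1e-8)
    expect_equal(statBattery("one_sample_t", x = x, mu = 0.2)@pValue,
                 stats::t.test(x, mu = 0.2)$p.value, tolerance = 1e-8)
    expect_equal(statBattery("oneway_anova_bonferroni", x = x,
                             groups = g)@pValue,
                 summary(stats::aov(x ~ factor(g)))[[1]][["Pr(>F)"]][1],
                 tolerance = 1e-8)
    expect_equal(statBattery("kruskal_wallis", x = x, groups = g)@pValue,
                 stats::kruskal.test(x, factor(g))$p.value, tolerance = 1e-8)
    expect_equal(statBattery("spearman", x = x, y = y)@pValue,
                 stats::cor.test(x, y, method = "spearman",
                                 exact = FALSE)$p.value, tolerance = 1e-8)
  }
  # Bonferroni pairwise p-values are capped at 1
  res <- statBattery("oneway_anova_bonferroni", x = rnorm(40),
                     groups = rep(1:4, each = 10))
  expect_true(all(res@details$pairwise <= 1, na.rm = TRUE))
})

test_that("small-sample Spearman uses exact permutation", {
  # n = 5, perfect monotone sequence: exact two-sided p = 2/5! = 1/60
  res <- statBattery("spearman", x = 1:5, y = c(2, 4, 6, 8, 10))
  expect_equal(res@statistic, 1)
  expect_equal(res@pValue, 2 / 120)
})

test_that("chance levels match their closed forms", {
  cfg2 <- phasePreset("phase2")
  set.seed(7)
  tm <- chanceLevel(cfg2, "type_match", nSim = 1e5)
  # closed form: p_l/4 + p_r/4 + p_d/2 + p_vs/2 on the configured mix
  mix <- changeMix(cfg2)
  expect_equal(tm$analytic,
               sum(mix * c(0.25, 0.25, 0.5, 0.5)[match(names(mix),
                 c("l-IR", "r-IR", "d-IR", "VS"))]))
  expect_lt(abs(tm$estimate - tm$analytic), 3 * tm$se)
  # degenerate mix: all changes on one side -> 1/4
  oneSided <- studyConfig(changeMix = c("l-IR" = 1, "r-IR" = 0,
                                        "d-IR" = 0, "VS" = 0))
  expect_equal(chanceLevel(oneSided, "type_match", nSim = 1e4)$analytic, 0.25)
  # joint timing-and-type reading: (changes/engagements) / 4
  jt <- chanceLevel(cfg2, "joint_timing_type", nSim = 5e4,
                    engagementsPerDay = 25)
  expect_equal(jt$analytic, 0.05)
  expect_lt(abs(jt$estimate - jt$analytic), 3 * jt$se)
  expect_error(chanceLevel(cfg2, "type_match", nSim = 100), "1e4")
})

test_that("Monte-Carlo chance estimates track the closed form over seeds", {
  cfg2 <- phasePreset("phase2")
  for (interp in c("type_match", "joint_timing_type")) {
    ok <- 0L
    for (s in 1:20) {
      set.seed(200 + s)
      cl <- chanceLevel(cfg2, interp, nSim = 1e4)
      ok <- ok + (abs(cl$estimate - cl$analytic) < 3 * cl$se)
    }
    expect_gte(ok, 19L)
  }
})
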