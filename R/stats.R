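#' Greenhouse-Geisser epsilon
#'
#' The sphericity-violation correction factor computed from a k x k sample
#' covariance matrix of within-subject scores: with \eqn{S^* = C S C} the
#' double-centred covariance (\eqn{C = I - J/k}),
#' \deqn{\hat\epsilon = \frac{\mathrm{tr}(S^*)^2}{(k-1)\,
#'   \mathrm{tr}(S^{*2})},}
#' clamped to its theoretical range \eqn{[1/(k-1), 1]}. Under compound
#' symmetry (sphericity) epsilon equals 1; for k = 2 the bounds coincide.
#'
#' @param covariance symmetric positive semidefinite matrix.
#' @return epsilon in [1/(k-1), 1].
#' @examples
#' ggEpsilon(diag(5))   # 1
#' @export
ggEpsilon <- function(covariance) {
  if (!is.matrix(covariance) || nrow(covariance) != ncol(covariance) ||
      !isSymmetric(unname(covariance), tol = 1e-8))
    stop("covariance must be a symmetric matrix", call. = FALSE)
  k <- ncol(covariance)
  if (k < 2L) stop("need at least 2 within-subject levels", call. = FALSE)
  C <- diag(k) - 1 / k
  S <- C %*% covariance %*% C
  eps <- sum(diag(S))^2 / ((k - 1) * sum(S * S))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test for a subjects x conditions score matrix (e.g. per
#' participant accuracy in the five ITI bins), with degrees of freedom
#' corrected by the Greenhouse-Geisser epsilon estimated from the sample
#' covariance of the condition scores. Subjects with any missing cell are
#' dropped listwise with a warning.
#'
#' @param scores numeric matrix, rows = subjects, columns = conditions.
#' @return a [StatsResult-class]; `details` holds the uncorrected df and
#'   p-value and the subject count used.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(50), 10, 5)
#' rmAnovaGG(y)
#' @export
rmAnovaGG <- function(scores) {
  scores <- as.matrix(scores)
  ok <- stats::complete.cases(scores)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) with missing cells dropped")
    scores <- scores[ok, , drop = FALSE]
  }
  n <- nrow(scores); k <- ncol(scores)
  if (n < 3L) stop("need at least 3 complete subjects", call. = FALSE)
  grand <- mean(scores)
  colM <- colMeans(scores)
  rowM <- rowMeans(scores)
  ssTreat <- n * sum((colM - grand)^2)
  resid <- scores - outer(rowM, colM, "+") + grand
  ssRes <- sum(resid^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fstat <- (ssTreat / df1) / (ssRes / df2)
  eps <- ggEpsilon(stats::cov(scores))
  p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  new("StatsResult", testName = "repeated-measures ANOVA",
      statistic = Fstat, df = c(eps * df1, eps * df2), pValue = p,
      correction = "greenhouse-geisser", epsilon = eps,
      details = list(df_uncorrected = c(df1, df2),
                     p_uncorrected = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                     n_subjects = n))
}

#' Statistical test battery
#'
#' Uniform dispatcher over the tests used throughout the analysis pipeline.
#' Designs: `paired_t` (x vs y), `one_sample_t` (x vs `mu`),
#' `oneway_anova_bonferroni` (omnibus one-way ANOVA of `x` over `groups`,
#' with Bonferroni-adjusted pairwise t p-values in `details$pairwise`),
#' `kruskal_wallis` (x over groups) and `spearman` (x vs y, with the
#' package's tie and small-n permutation policy, see [practiceEffect()]).
#' All tests delegate to base \pkg{stats} implementations.
#'
#' @param design one of the designs above.
#' @param x numeric values.
#' @param y second sample (paired_t) or covariate (spearman).
#' @param groups factor-like group labels.
#' @param mu null value for one_sample_t.
#' @return a [StatsResult-class].
#' @examples
#' statBattery("paired_t", x = rnorm(10), y = rnorm(10))
#' @export
statBattery <- function(design = c("paired_t", "one_sample_t",
                                   "oneway_anova_bonferroni",
                                   "kruskal_wallis", "spearman"),
                        x, y = NULL, groups = NULL, mu = 0) {
  design <- match.arg(design)
  switch(design,
    paired_t = {
      d <- x - y
      tt <- .safeT(d, 0, "paired t-test")
      tt@details <- list(mean_difference = mean(d))
      tt
    },
    one_sample_t = {
      tt <- .safeT(x, mu, "one-sample t-test")
      tt@details <- list(mean = mean(x), mu = mu)
      tt
    },
    oneway_anova_bonferroni = {
      g <- factor(groups)
      fit <- stats::aov(x ~ g)
      s <- summary(fit)[[1]]
      pw <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni")
      new("StatsResult", testName = "one-way ANOVA",
          statistic = s[["F value"]][1], df = s[["Df"]],
          pValue = s[["Pr(>F)"]][1], correction = "bonferroni",
          epsilon = NA_real_,
          details = list(pairwise = pw$p.value))
    },
    kruskal_wallis = {
      kt <- stats::kruskal.test(x, factor(groups))
      new("StatsResult", testName = "Kruskal-Wallis H test",
          statistic = unname(kt$statistic), df = unname(kt$parameter),
          pValue = kt$p.value, correction = "none", epsilon = NA_real_,
          details = list())
    },
    spearman = {
      st <- .spearmanTest(x, y)
      new("StatsResult", testName = "Spearman rank correlation",
          statistic = st$rho, df = length(x) - 2, pValue = st$p,
          correction = "none", epsilon = NA_real_,
          details = list(rho = st$rho))
    })
}

# One-sample t on x against mu, with the degenerate zero-variance case
# defined by continuity: no variance and no effect gives t = 0, p = 1.
.safeT <- function(x, mu, label) {
  n <- length(x)
  if (stats::sd(x) == 0) {
    tstat <- if (mean(x) == mu) 0 else Inf * sign(mean(x) - mu)
    p <- if (tstat == 0) 1 else 0
    return(new("StatsResult", testName = label, statistic = tstat,
               df = n - 1, pValue = p, correction = "none",
               epsilon = NA_real_, details = list()))
  }
  tt <- stats::t.test(x, mu = mu)
  new("StatsResult", testName = label, statistic = unname(tt$statistic),
      df = unname(tt$parameter), pValue = tt$p.value, correction = "none",
      epsilon = NA_real_, details = list())
}

#' Chance level of the image tasks
#'
#' Probability that a participant who guesses blindly scores a correct
#' image-task response, assuming a guess is a uniform pick among the four
#' visual tasks (l-IR, r-IR, d-IR, VS). Two readings are implemented:
#' \describe{
#'   \item{type_match}{per change event: the uniformly guessed task maps to
#'     exactly the correct button set. d-IR and VS collide on both buttons,
#'     so the closed form is
#'     \eqn{p_{l} / 4 + p_{r} / 4 + p_{d} / 2 + p_{VS} / 2}.}
#'   \item{joint_timing_type}{per engagement: a change must also be pending
#'     at the engagement the guess falls on; closed form
#'     \eqn{\min(r_c / r_e, 1) / 4} with \eqn{r_c} changes/day and
#'     \eqn{r_e} engagements/day (the guessed task must name the change's
#'     own type).}
#' }
#' Both readings return the analytic value alongside a Monte-Carlo estimate
#' with its standard error.
#'
#' @param config a [StudyConfig-class] (supplies the change mix and rate).
#' @param interpretation "type_match" or "joint_timing_type".
#' @param nSim number of simulated change events / engagements (>= 1e4).
#' @param engagementsPerDay engagement rate for the joint reading.
#' @return list with `analytic`, `estimate`, `se`, `nSim`,
#'   `interpretation`.
#' @examples
#' chanceLevel(phasePreset("phase2"), "type_match", nSim = 1e4)$analytic
#' @export
chanceLevel <- function(config,
                        interpretation = c("type_match", "joint_timing_type"),
                        nSim = 1e5, engagementsPerDay = 25) {
  interpretation <- match.arg(interpretation)
  if (nSim < 1e4) stop("nSim must be at least 1e4", call. = FALSE)
  mix <- config@changeMix
  if (interpretation == "type_match") {
    match1 <- c("l-IR" = 0.25, "r-IR" = 0.25, "d-IR" = 0.5, "VS" = 0.5)
    analytic <- sum(mix * match1[names(mix)])
    types <- sample(CHANGE_TYPES, nSim, replace = TRUE, prob = mix)
    guesses <- sample(CHANGE_TYPES, nSim, replace = TRUE)
    hit <- expectedButtons(guesses) == expectedButtons(types)
    est <- mean(hit)
    se <- sqrt(est * (1 - est) / nSim)
  } else {
    analytic <- min(config@changeRate / engagementsPerDay, 1) / 4
    nDays <- ceiling(nSim / engagementsPerDay)
    perDay <- as.integer(engagementsPerDay)
    changes <- stats::rpois(nDays, config@changeRate)
    guesses <- matrix(sample(CHANGE_TYPES, nDays * perDay, replace = TRUE),
                      nDays, perDay)
    counts <- numeric(nDays * perDay)
    for (d in seq_len(nDays)) {
      if (changes[d] == 0) next
      at <- sample.int(perDay, changes[d], replace = TRUE)
      ty <- sample(CHANGE_TYPES, changes[d], replace = TRUE, prob = mix)
      ok <- guesses[d, at] == ty
      idx <- (d - 1L) * perDay + at
      for (j in which(ok)) counts[idx[j]] <- counts[idx[j]] + 1
    }
    est <- mean(counts)
    se <- stats::sd(counts) / sqrt(length(counts))
  }
  list(analytic = analytic, estimate = est, se = se, nSim = nSim,
       interpretation = interpretation)
}
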