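#' Fit the lapse-mixed logistic forgetting model
#'
#' Maximum-likelihood fit of the alternation response model of
#' [alternationAccuracy()] to scored trial-level records: accuracy
#' \eqn{p = \lambda/2 + (1-\lambda)\,\mathrm{logit}^{-1}(a - \beta
#' \ln(\mathrm{ITI}/1'') - \gamma[\mathrm{shift}] + \delta d
#' [\mathrm{stay}])}. The win-shift deficit \eqn{\gamma} and the win-stay
#' drift \eqn{\delta} are only estimated when the data contain both stay
#' and shift trials (under the single-alternation rule every classified
#' trial is a shift, so neither is identified); otherwise they are fixed at
#' 0. Trials without a defined ITI are dropped.
#'
#' @param records scored engagement records or a [LogBundle-class]; pooled
#'   across participants (a common-parameter fit).
#' @param fitPractice logical; force (TRUE) or suppress (FALSE) estimation
#'   of gamma and delta. NULL (default) decides from the data.
#' @return list: `estimates` (named vector a, beta, lambda, gamma, delta),
#'   `logLik`, `n`, `convergence` (0 = success).
#' @examples
#' b <- simulateCohort(c(older = 3), phasePreset("phase1"), seed = 2,
#'                     heterogeneity = 0)
#' fitForgettingModel(b)$estimates
#' @export
fitForgettingModel <- function(records, fitPractice = NULL) {
  records <- .asRecords(records)
  records <- records[!is.na(records$iti) & records$iti > 0, , drop = FALSE]
  if (!nrow(records)) stop("no scored trials with a defined ITI", call. = FALSE)
  y <- as.numeric(records$alternation_correct)
  lx <- log(records$iti / 60)
  isShift <- records$stay_shift_label == "shift"
  isStay <- records$stay_shift_label == "stay"
  day0 <- dayIndex(records$engagement_time) - 1L
  if (is.null(fitPractice)) fitPractice <- any(isStay) && any(isShift)

  nll <- function(par) {
    a <- par[1]; beta <- par[2]; lambda <- par[3]
    gamma <- if (fitPractice) par[4] else 0
    delta <- if (fitPractice) par[5] else 0
    eta <- a - beta * lx - gamma * isShift + delta * day0 * isStay
    p <- lambda / 2 + (1 - lambda) * stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  start <- c(a = 2, beta = 0.3, lambda = 0.05)
  lower <- c(-10, 0, 0)
  upper <- c(10, 10, 0.999)
  if (fitPractice) {
    start <- c(start, gamma = 0.2, delta = 0)
    lower <- c(lower, 0, -1)
    upper <- c(upper, 10, 1)
  }
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500))
  est <- c(fit$par, if (!fitPractice) c(gamma = 0, delta = 0))
  list(estimates = est[c("a", "beta", "lambda", "gamma", "delta")],
       logLik = -fit$value, n = length(y), convergence = fit$convergence)
}

#' Detection power for a win-stay practice drift
#'
#' Monte-Carlo power of the daily-mean Spearman trend test
#' ([practiceEffect()]) against a win-stay practice drift, under a
#' streamlined cohort model: each participant contributes Poisson-many
#' engagements per day, half of which are win-stay trials, with ITIs from
#' the activation sampler and correctness from [alternationAccuracy()].
#' Each replicate pools the cohort's daily win-stay accuracy over the
#' window and tests day-vs-accuracy at level `alpha`.
#'
#' @param drift win-stay drift, logit per day.
#' @param engagementsPerDay per-participant daily engagement rate.
#' @param nParticipants cohort size per replicate.
#' @param windowDays length of the analysis window, days.
#' @param nReplicates number of Monte-Carlo replicates.
#' @param profile base [ParticipantProfile-class]; its `stayDrift` is
#'   replaced by `drift`.
#' @param config a [StudyConfig-class] (supplies the ITI sampler).
#' @param alpha test level.
#' @return detection rate (fraction of replicates with p < alpha).
#' @export
practiceEffectPower <- function(drift = 0.01, engagementsPerDay = 21,
                                nParticipants = 600, windowDays = 14,
                                nReplicates = 100,
                                profile = presetProfile("older", "phase2"),
                                config = phasePreset("phase2"),
                                alpha = 0.05) {
  profile@stayDrift <- drift
  hits <- logical(nReplicates)
  for (r in seq_len(nReplicates)) {
    nStay <- stats::rbinom(windowDays, stats::rpois(windowDays,
                           nParticipants * engagementsPerDay), 0.5)
    daily <- numeric(windowDays)
    for (d in seq_len(windowDays)) {
      iti <- sampleActivationInterval(config, nStay[d])
      p <- alternationAccuracy(profile, iti, day = d - 1L, label = "stay")
      daily[d] <- mean(stats::runif(nStay[d]) < p)
    }
    st <- .spearmanTest(seq_len(windowDays), daily)
    hits[r] <- !is.na(st$p) && st$p < alpha
  }
  mean(hits)
}
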