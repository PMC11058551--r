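#' Confounder model: prevalence of a binary baseline confounder
#'
#' Describes the marginal distribution of the binary confounder `z`
#' (in the worked example, an indicator of age above 80 years).
#'
#' @param prevalence Probability in `[0, 1]` that `z = 1`.
#' @return An object of class `confounder_model`.
#' @examples
#' confounder_model(0.6)
#' @export
confounder_model <- function(prevalence) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L)
  if (is.na(prevalence) || prevalence < 0 || prevalence > 1) {
    stop("`prevalence` must be a probability in [0, 1]", call. = FALSE)
  }
  structure(list(prevalence = as.numeric(prevalence)),
            class = "confounder_model")
}

#' Exposure model: logistic dependence of a binary exposure on the confounder
#'
#' The exposure `x` (in the worked example, being physically active) is
#' Bernoulli with success probability
#' `plogis(qlogis(baseline_prob) + log_odds_ratio * z)`.
#'
#' @param baseline_prob Probability in `(0, 1)` that `x = 1` when `z = 0`.
#' @param log_odds_ratio Change in the log-odds of exposure per unit of `z`;
#'   must be finite.
#' @return An object of class `exposure_model`.
#' @examples
#' exposure_model(0.5, log(1 / 3))
#' @export
exposure_model <- function(baseline_prob, log_odds_ratio) {
  stopifnot(is.numeric(baseline_prob), length(baseline_prob) == 1L,
            is.numeric(log_odds_ratio), length(log_odds_ratio) == 1L)
  if (is.na(baseline_prob) || baseline_prob <= 0 || baseline_prob >= 1) {
    stop("`baseline_prob` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(log_odds_ratio)) {
    stop("`log_odds_ratio` must be finite", call. = FALSE)
  }
  structure(list(baseline_prob = as.numeric(baseline_prob),
                 log_odds_ratio = as.numeric(log_odds_ratio)),
            class = "exposure_model")
}

#' Weibull proportional-hazards outcome model
#'
#' Hazard convention: `h(t | x, z) = gamma * t^(gamma - 1) *
#' exp(beta0 + beta1 * x + beta2 * z)`, so that with `gamma = 1` the model
#' reduces to a constant-rate exponential model with baseline rate
#' `exp(beta0)` per time unit (year).
#'
#' @param beta0 Log baseline event rate per year among `x = 0, z = 0`.
#' @param beta1 Log hazard ratio for the exposure `x`.
#' @param beta2 Log hazard ratio for the confounder `z`.
#' @param gamma Weibull shape, strictly positive; `gamma > 1` means the
#'   hazard increases over follow-up in every covariate pattern.
#' @return An object of class `weibull_outcome`.
#' @examples
#' weibull_outcome(log(7 / 1000), log(0.8), log(4), 1.1)
#' @export
weibull_outcome <- function(beta0, beta1, beta2, gamma) {
  vals <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, gamma = gamma)
  stopifnot(is.numeric(vals), length(vals) == 4L)
  if (any(!is.finite(vals))) {
    stop("all Weibull outcome parameters must be finite", call. = FALSE)
  }
  if (gamma <= 0) stop("`gamma` must be strictly positive", call. = FALSE)
  structure(list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
                 beta2 = as.numeric(beta2), gamma = as.numeric(gamma)),
            class = "weibull_outcome")
}

#' Follow-up design: administrative censoring time
#'
#' All subjects enter at time 0 and are administratively censored at `tau`
#' years; that is the only censoring mechanism supported.
#'
#' @param tau Positive follow-up length in years.
#' @return An object of class `followup_design`.
#' @export
followup_design <- function(tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0) {
    stop("`tau` must be a positive, finite follow-up time", call. = FALSE)
  }
  structure(list(tau = as.numeric(tau)), class = "followup_design")
}

#' Study scenario: full description of a simulated cohort design
#'
#' Bundles the data-generating mechanism (confounder, exposure, outcome,
#' follow-up) with the cohort size and the two-sided significance level of
#' the planned Wald test.
#'
#' @param confounder A [confounder_model()].
#' @param exposure An [exposure_model()].
#' @param outcome A [weibull_outcome()].
#' @param followup A [followup_design()].
#' @param n Cohort size, integer `>= 2`.
#' @param alpha Two-sided significance level in `(0, 1)`.
#' @return An object of class `scenario`.
#' @seealso [activity_mortality_scenario()] for the packaged worked example.
#' @export
scenario <- function(confounder, exposure, outcome, followup, n,
                     alpha = 0.05) {
  stopifnot(inherits(confounder, "confounder_model"),
            inherits(exposure, "exposure_model"),
            inherits(outcome, "weibull_outcome"),
            inherits(followup, "followup_design"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2 ||
      n != round(n)) {
    stop("`n` must be a whole number >= 2", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(confounder = confounder, exposure = exposure,
                 outcome = outcome, followup = followup,
                 n = as.integer(n), alpha = as.numeric(alpha)),
            class = "scenario")
}

#' The packaged worked-example scenario
#'
#' An observational cohort of older people in which physical activity
#' (`x`, at least 3.5 h/week of moderate-to-vigorous activity) may lower
#' 10-year mortality, confounded by age group (`z`, older than 80 years):
#' about 60% are older than 80; younger subjects are active with
#' probability 50% while older subjects have 1/3 the odds of being active;
#' mortality follows a Weibull proportional-hazards model with baseline
#' rate 7 deaths per 1000 person-years (`beta0 = log(7/1000)`), exposure
#' hazard ratio 0.8, age hazard ratio 4, and shape 1.1; follow-up is 10
#' years, the cohort size 5000, and the test level 5% two-sided.
#'
#' All parameters are stored at full precision (as `log()` expressions),
#' not at their printed roundings.
#'
#' @param n Cohort size; default 5000.
#' @param alpha Two-sided significance level; default 0.05.
#' @return A [scenario()] object.
#' @examples
#' sc <- activity_mortality_scenario()
#' expected_events(sc)  # about 1005 deaths over 10 years
#' @export
activity_mortality_scenario <- function(n = 5000, alpha = 0.05) {
  scenario(
    confounder = confounder_model(0.6),
    exposure   = exposure_model(0.5, log(1 / 3)),
    outcome    = weibull_outcome(log(7 / 1000), log(0.8), log(4), 1.1),
    followup   = followup_design(10),
    n = n, alpha = alpha
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("Simulated cohort study scenario\n")
  cat(sprintf("  confounder: P(z=1) = %g\n", x$confounder$prevalence))
  cat(sprintf("  exposure:   P(x=1|z=0) = %g, log OR per z = %.4f\n",
              x$exposure$baseline_prob, x$exposure$log_odds_ratio))
  cat(sprintf("  outcome:    beta0 = %.4f, beta1 = %.4f, beta2 = %.4f, gamma = %g\n",
              x$outcome$beta0, x$outcome$beta1, x$outcome$beta2,
              x$outcome$gamma))
  cat(sprintf("  follow-up:  tau = %g years (administrative censoring)\n",
              x$followup$tau))
  cat(sprintf("  design:     n = %d, alpha = %g (two-sided)\n",
              x$n, x$alpha))
  invisible(x)
}
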