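# Data-generating mechanism: confounder -> exposure -> Weibull survival,
# administratively censored at tau. One uniform stream per variable
# (z, x, then the survival draw) in a fixed order, so a cohort is fully
# reproducible given (scenario, seed).

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses (and advances) the current
# stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed) || seed < 0) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw the binary confounder
#'
#' Independent Bernoulli draws of the confounder `z` with the model's
#' prevalence.
#'
#' @param model A [confounder_model()].
#' @param n Number of subjects, `>= 1`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of 0/1 of length `n`.
#' @export
sample_confounder <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "confounder_model"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  with_seed(seed, as.integer(runif(n) < model$prevalence))
}

#' Draw the binary exposure given the confounder
#'
#' Element `i` is Bernoulli with success probability
#' `plogis(qlogis(baseline_prob) + log_odds_ratio * z[i])`.
#'
#' @param model An [exposure_model()].
#' @param z Binary (0/1) confounder vector.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector the length of `z`.
#' @export
sample_exposure <- function(model, z, seed = NULL) {
  stopifnot(inherits(model, "exposure_model"))
  if (length(z) < 1L || !all(z %in% c(0, 1))) {
    stop("`z` must be a non-empty binary (0/1) vector", call. = FALSE)
  }
  p <- plogis(qlogis(model$baseline_prob) + model$log_odds_ratio * z)
  with_seed(seed, as.integer(runif(length(z)) < p))
}

#' Invert the Weibull survival function
#'
#' Given a survival probability `u`, returns the unique time `t` solving
#' `S(t) = exp(-exp(linear_predictor) * t^gamma) = u`, i.e.
#' `t = (-log(u) / exp(linear_predictor))^(1/gamma)`. This is the
#' inverse-transform step that turns one uniform draw per subject into a
#' latent time-to-event. Strictly decreasing in `u`.
#'
#' @param u Survival probabilities, each strictly inside `(0, 1)`.
#' @param linear_predictor Log rate scale `beta0 + beta1*x + beta2*z`;
#'   recycled against `u`.
#' @param gamma Weibull shape, `> 0`.
#' @return Event times in years, same length as the recycled inputs.
#' @examples
#' invert_survival(exp(-1), 0, 2)          # exactly 1
#' invert_survival(0.5, log(0.5), 1)       # exponential: log(2)/0.5
#' @export
invert_survival <- function(u, linear_predictor, gamma) {
  if (!is.numeric(u) || any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    stop("`gamma` must be a positive number", call. = FALSE)
  }
  if (any(!is.finite(linear_predictor))) {
    stop("`linear_predictor` must be finite", call. = FALSE)
  }
  (-log(u) / exp(linear_predictor))^(1 / gamma)
}

#' Generate one synthetic cohort from a scenario
#'
#' Draws `z`, then `x` given `z`, then a latent time-to-event by
#' [invert_survival()] with linear predictor
#' `beta0 + beta1*x + beta2*z`; the observed time is `min(latent, tau)`
#' and the event indicator is 1 exactly when the latent time falls inside
#' the follow-up window. Administrative censoring at `tau` is the only
#' censoring mechanism, so `event == 0` if and only if `time == tau`.
#'
#' @param scenario A [scenario()].
#' @param seed Optional integer seed; identical `(scenario, seed)` pairs
#'   give identical cohorts.
#' @return A `cohort`: a data frame with columns `id`, `z`, `x`, `time`
#'   (years), `event` (1 = death observed, 0 = censored) and attribute
#'   `tau`.
#' @examples
#' co <- generate_cohort(activity_mortality_scenario(), seed = 20230413)
#' sum(co$event)
#' @export
generate_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  n <- scenario$n
  with_seed(seed, {
    z <- sample_confounder(scenario$confounder, n)
    x <- sample_exposure(scenario$exposure, z)
    u <- runif(n)
    lp <- scenario$outcome$beta0 + scenario$outcome$beta1 * x +
      scenario$outcome$beta2 * z
    latent <- invert_survival(u, lp, scenario$outcome$gamma)
    tau <- scenario$followup$tau
    co <- data.frame(id = seq_len(n), z = z, x = x,
                     time = pmin(latent, tau),
                     event = as.integer(latent < tau))
    attr(co, "tau") <- tau
    class(co) <- c("cohort", "data.frame")
    co
  })
}

#' Write / read a cohort as CSV
#'
#' Plain CSV with header `id,z,x,time,event`; times are written with 10
#' significant digits.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `cohort` data frame (with `tau` taken
#'   as the maximum censored time present, or `max(time)` if none).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort),
            all(c("id", "z", "x", "time", "event") %in% names(cohort)))
  out <- cohort[, c("id", "z", "x", "time", "event")]
  out$time <- formatC(out$time, digits = 10, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  co <- utils::read.csv(path, colClasses = c(id = "integer", z = "integer",
                                             x = "integer", time = "numeric",
                                             event = "integer"))
  if (!identical(names(co), c("id", "z", "x", "time", "event"))) {
    stop("cohort CSV must have header id,z,x,time,event", call. = FALSE)
  }
  cens <- co$time[co$event == 0]
  attr(co, "tau") <- if (length(cens)) max(cens) else max(co$time)
  class(co) <- c("cohort", "data.frame")
  co
}

# Minimal structural validation shared by the fitting code.
check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("z", "x", "time", "event")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns z, x, time, event", call. = FALSE)
  }
  if (nrow(cohort) < 1L) stop("cohort is empty", call. = FALSE)
  if (any(cohort$time <= 0)) {
    stop("all observed times must be strictly positive", call. = FALSE)
  }
  if (!all(cohort$event %in% c(0, 1)) || !all(cohort$z %in% c(0, 1)) ||
      !all(cohort$x %in% c(0, 1))) {
    stop("z, x and event must be binary 0/1", call. = FALSE)
  }
  invisible(cohort)
}
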