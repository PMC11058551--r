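# Maximum-likelihood fitting of the Weibull proportional-hazards model
# h(t | x, z) = gamma * t^(gamma-1) * exp(beta0 + beta1*x + beta2*z)
# for right-censored cohorts. The shape is optimized on the log scale
# (s = log gamma) so positivity is structural; gradient and Hessian are
# analytic and Newton steps use step-halving.

#' Weibull proportional-hazards log-likelihood
#'
#' For subject `i` with event indicator `d_i`, time `t_i` and linear
#' predictor `lp_i = beta0 + beta1*x_i + beta2*z_i`, the contribution is
#' `d_i * (log(gamma) + (gamma - 1) * log(t_i) + lp_i) -
#' exp(lp_i) * t_i^gamma`; the function returns the sum over subjects.
#'
#' @param coefficients Numeric length-3 vector `(beta0, beta1, beta2)`.
#' @param log_gamma Log of the Weibull shape.
#' @param cohort Cohort data frame with columns `z`, `x`, `time`, `event`.
#' @return The log-likelihood, a single finite number for finite inputs.
#' @export
weibull_ph_loglik <- function(coefficients, log_gamma, cohort) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 3L,
            is.numeric(log_gamma), length(log_gamma) == 1L)
  check_cohort(cohort)
  g <- exp(log_gamma)
  w <- log(cohort$time)
  lp <- coefficients[1] + coefficients[2] * cohort$x +
    coefficients[3] * cohort$z
  sum(cohort$event * (log_gamma + (g - 1) * w + lp)) - sum(exp(lp + g * w))
}

# Log-likelihood, gradient and Hessian at theta = (beta0, beta1, beta2, s),
# s = log gamma, from precomputed design pieces. mu_i = exp(lp_i + g*w_i)
# is the subject's cumulative hazard at its observed time.
wph_derivs <- function(theta, X, d, w) {
  g <- exp(theta[4L])
  lp <- drop(X %*% theta[1:3])
  mu <- exp(lp + g * w)
  ll <- sum(d * (theta[4L] + (g - 1) * w + lp)) - sum(mu)
  grad <- c(crossprod(X, d - mu),
            sum(d * (1 + g * w)) - g * sum(mu * w))
  Hbb <- -crossprod(X, X * mu)
  Hbs <- -crossprod(X, mu * g * w)
  Hss <- g * sum(d * w) - g * sum(mu * w) - g^2 * sum(mu * w^2)
  H <- rbind(cbind(Hbb, Hbs), c(Hbs, Hss))
  list(ll = ll, grad = grad, H = H)
}

#' Fit the Weibull proportional-hazards model to a right-censored cohort
#'
#' Maximizes [weibull_ph_loglik()] over `(beta0, beta1, beta2, log(gamma))`
#' by Newton-Raphson with analytic gradient and Hessian and step-halving.
#' Initialization is the exponential moment estimate
#' `beta0 = log(total events / total person-time)`, `beta1 = beta2 = 0`,
#' `log(gamma) = 0`. Convergence requires gradient max-norm below
#' `1e-8` or a relative log-likelihood change below `1e-12` within 200
#' iterations; a fit that does not meet either is returned with
#' `converged = FALSE`, never silently. The covariance is the inverse of
#' the observed information at the optimum, on the `(beta, log gamma)`
#' scale.
#'
#' @param cohort Cohort data frame (columns `z`, `x`, `time`, `event`)
#'   with at least one event and both covariates non-constant.
#' @param level Confidence level used by downstream summaries, in
#'   `(0, 1)`; default 0.95.
#' @param fix_gamma Optional positive value at which to hold the shape
#'   fixed (e.g. `1` for the exponential sub-model); `NULL` (default)
#'   estimates it.
#' @return An object of class `weibull_fit` with elements `coefficients`
#'   (named `intercept`, `exposure`, `confounder`), `log_gamma`, `gamma`,
#'   `covariance` (4 x 4 over `(beta, log gamma)`; the shape row/column is
#'   zero when `fix_gamma` is used), `loglik`, `converged`, `iterations`,
#'   `n_events`, `n_subjects`, `level`.
#' @examples
#' co <- generate_cohort(activity_mortality_scenario(), seed = 20230413)
#' fit <- fit_weibull_ph(co)
#' wald_hr_test(fit, "exposure")
#' @export
fit_weibull_ph <- function(cohort, level = 0.95, fix_gamma = NULL) {
  check_cohort(cohort)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  d <- as.numeric(cohort$event)
  if (sum(d) == 0) stop("no events in cohort: model is not identifiable",
                        call. = FALSE)
  if (length(unique(cohort$x)) < 2L || length(unique(cohort$z)) < 2L) {
    stop("both covariates must be non-constant", call. = FALSE)
  }
  X <- cbind(1, as.numeric(cohort$x), as.numeric(cohort$z))
  w <- log(cohort$time)
  free <- if (is.null(fix_gamma)) 1:4 else 1:3
  if (!is.null(fix_gamma)) {
    stopifnot(is.numeric(fix_gamma), length(fix_gamma) == 1L, fix_gamma > 0)
  }
  theta <- c(log(sum(d) / sum(cohort$time)), 0, 0,
             if (is.null(fix_gamma)) 0 else log(fix_gamma))

  de <- wph_derivs(theta, X, d, w)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(200L)) {
    if (max(abs(de$grad[free])) < 1e-8) { converged <- TRUE; break }
    step <- rep(0, 4L)
    step[free] <- tryCatch(
      solve(de$H[free, free, drop = FALSE], de$grad[free]),
      error = function(e) stop("singular information matrix: ",
                               conditionMessage(e), call. = FALSE))
    cand_de <- NULL
    for (h in seq_len(40L)) {
      cand <- theta - step
      cd <- wph_derivs(cand, X, d, w)
      if (is.finite(cd$ll) && cd$ll >= de$ll - 1e-12) { cand_de <- cd; break }
      step <- step / 2
    }
    if (is.null(cand_de)) break  # line search failed
    rel_change <- abs(cand_de$ll - de$ll) / (abs(de$ll) + 1)
    theta <- cand
    de <- cand_de
    if (rel_change < 1e-12) {
      converged <- max(abs(de$grad[free])) < 1e-6
      break
    }
  }
  if (max(abs(de$grad[free])) < 1e-8) converged <- TRUE

  V <- matrix(0, 4L, 4L)
  V[free, free] <- tryCatch(solve(-de$H[free, free, drop = FALSE]),
                            error = function(e) {
                              converged <<- FALSE
                              matrix(NA_real_, length(free), length(free))
                            })
  nm <- c("intercept", "exposure", "confounder", "log_gamma")
  dimnames(V) <- list(nm, nm)
  structure(list(
    coefficients = stats::setNames(theta[1:3], nm[1:3]),
    log_gamma = theta[4L],
    gamma = exp(theta[4L]),
    covariance = V,
    loglik = de$ll,
    converged = converged,
    iterations = iter,
    n_events = as.integer(sum(d)),
    n_subjects = nrow(cohort),
    level = level,
    gamma_fixed = !is.null(fix_gamma)
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull proportional-hazards fit: %d subjects, %d events\n",
              x$n_subjects, x$n_events))
  se <- sqrt(diag(x$covariance))[1:3]
  tab <- data.frame(coef = x$coefficients, se = se,
                    hr = exp(x$coefficients), row.names = names(x$coefficients))
  print(round(tab, 4))
  cat(sprintf("shape gamma = %.4f%s, loglik = %.3f, %s (%d iterations)\n",
              x$gamma, if (x$gamma_fixed) " (fixed)" else "",
              x$loglik,
              if (x$converged) "converged" else "NOT CONVERGED",
              x$iterations))
  invisible(x)
}

#' Wald summary from an estimate and its standard error
#'
#' Computes `z = estimate / se`, the two-sided normal p-value
#' `2 * (1 - pnorm(|z|))`, and the confidence interval
#' `exp(estimate +/- qnorm(1 - (1 - level)/2) * se)` on the hazard-ratio
#' scale. The exact normal quantile is used (1.959964 at 95%), not 1.96.
#'
#' @param estimate Log hazard-ratio estimate.
#' @param se Positive standard error.
#' @param level Confidence level in `(0, 1)`.
#' @param term Optional label for printing.
#' @return An object of class `wald_summary` with fields `estimate`, `se`,
#'   `z`, `p_two_sided`, `hr`, `ci_low`, `ci_high`, `level`, `term`.
#' @examples
#' wald_summary(log(0.89), 0.0766)   # z = -1.52, p = 0.13
#' @export
wald_summary <- function(estimate, se, level = 0.95, term = "exposure") {
  stopifnot(is.numeric(estimate), length(estimate) == 1L,
            is.numeric(se), length(se) == 1L, se > 0,
            level > 0, level < 1)
  z <- estimate / se
  crit <- qnorm(1 - (1 - level) / 2)
  structure(list(estimate = estimate, se = se, z = z,
                 p_two_sided = 2 * (1 - pnorm(abs(z))),
                 hr = exp(estimate),
                 ci_low = exp(estimate - crit * se),
                 ci_high = exp(estimate + crit * se),
                 level = level, term = term),
            class = "wald_summary")
}

#' Wald test for one coefficient of a fitted model, on the hazard-ratio scale
#'
#' @param fit A converged [fit_weibull_ph()] result.
#' @param coefficient Which coefficient: an index in 1..3 or one of
#'   `"intercept"`, `"exposure"`, `"confounder"`.
#' @param level Confidence level; defaults to the fit's.
#' @return A `wald_summary`.
#' @export
wald_hr_test <- function(fit, coefficient = "exposure", level = fit$level) {
  stopifnot(inherits(fit, "weibull_fit"))
  if (!isTRUE(fit$converged)) {
    stop("fit did not converge; refusing to compute Wald statistics ",
         "(iterations = ", fit$iterations, ")", call. = FALSE)
  }
  idx <- if (is.character(coefficient)) {
    match(coefficient, names(fit$coefficients))
  } else as.integer(coefficient)
  if (is.na(idx) || idx < 1L || idx > 3L) {
    stop("`coefficient` must name or index one of the three coefficients",
         call. = FALSE)
  }
  wald_summary(unname(fit$coefficients[idx]),
               sqrt(fit$covariance[idx, idx]),
               level = level, term = names(fit$coefficients)[idx])
}

#' @export
print.wald_summary <- function(x, ...) {
  cat(sprintf(
    "Wald test (%s): HR = %.4f, %d%% CI %.4f-%.4f, z = %.2f, p = %.4g\n",
    x$term, x$hr, round(100 * x$level), x$ci_low, x$ci_high, x$z,
    x$p_two_sided))
  invisible(x)
}

#' Predicted survival curve for one covariate pattern
#'
#' `S(t) = exp(-exp(lp) * t^gamma)` with
#' `lp = beta0 + beta1*x + beta2*z`, evaluated either at the true
#' generating parameters (a [weibull_outcome()]) or at fitted ones
#' (a `weibull_fit`). Non-increasing in `t`, with `S(0) = 1`.
#'
#' @param object A `weibull_outcome` or `weibull_fit`.
#' @param times Non-negative times in years.
#' @param x,z Binary covariate values defining the pattern.
#' @return Vector of survival probabilities along `times`.
#' @examples
#' out <- activity_mortality_scenario()$outcome
#' predict_survival(out, 10, x = 0, z = 0)  # about 0.9157
#' @export
predict_survival <- function(object, times, x, z) {
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0)) {
    stop("`times` must be non-negative and finite", call. = FALSE)
  }
  stopifnot(length(x) == 1L, length(z) == 1L,
            x %in% c(0, 1), z %in% c(0, 1))
  if (inherits(object, "weibull_outcome")) {
    lp <- object$beta0 + object$beta1 * x + object$beta2 * z
    g <- object$gamma
  } else if (inherits(object, "weibull_fit")) {
    b <- object$coefficients
    lp <- b[["intercept"]] + b[["exposure"]] * x + b[["confounder"]] * z
    g <- object$gamma
  } else {
    stop("`object` must be a weibull_outcome or weibull_fit", call. = FALSE)
  }
  exp(-exp(lp) * times^g)
}

#' Plain-text and machine-readable fit report
#'
#' @param fit A `weibull_fit`.
#' @return A character vector of `key=value` lines (coefficients, SEs,
#'   hazard ratios, CIs, z, p, shape, log-likelihood, convergence).
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  lines <- c(sprintf("n_subjects=%d", fit$n_subjects),
             sprintf("n_events=%d", fit$n_events),
             sprintf("converged=%s", tolower(as.character(fit$converged))),
             sprintf("loglik=%.10g", fit$loglik),
             sprintf("gamma=%.10g", fit$gamma))
  for (term in names(fit$coefficients)) {
    if (fit$converged) {
      ws <- wald_hr_test(fit, term)
      lines <- c(lines, sprintf(
        "%s.coef=%.10g", term, ws$estimate),
        sprintf("%s.se=%.10g", term, ws$se),
        sprintf("%s.hr=%.10g", term, ws$hr),
        sprintf("%s.ci_low=%.10g", term, ws$ci_low),
        sprintf("%s.ci_high=%.10g", term, ws$ci_high),
        sprintf("%s.z=%.10g", term, ws$z),
        sprintf("%s.p=%.10g", term, ws$p_two_sided))
    } else {
      lines <- c(lines, sprintf("%s.coef=%.10g", term,
                                fit$coefficients[[term]]))
    }
  }
  lines
}
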