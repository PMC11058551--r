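# A slow, transparently-written per-subject loop used as the independent
# likelihood oracle.
loglik_loop <- function(beta, log_gamma, cohort) {
  g <- exp(log_gamma)
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    lp <- beta[1] + beta[2] * cohort$x[i] + beta[3] * cohort$z[i]
    t <- cohort$time[i]
    if (cohort$event[i] == 1) {
      total <- total + log_gamma + (g - 1) * log(t) + lp
    }
    total <- total - exp(lp) * t^g
  }
  total
}

test_that("weibull_ph_loglik matches hand-computed single-subject values", {
  one <- function(d, t, x = 0, z = 0) {
    data.frame(id = 1L, z = z, x = x, time = t, event = d)
  }
  # d=1, t=1, lp=0, gamma=1: log(1) + 0 + 0 - 1
  expect_equal(weibull_ph_loglik(c(0, 0, 0), 0, one(1, 1)), -1)
  # censored at t=10 with rate 0.007: -0.07
  expect_equal(weibull_ph_loglik(c(log(0.007), 0, 0), 0, one(0, 10)), -0.07)
  expect_error(weibull_ph_loglik(c(0, 0, 0), 0, one(1, -1)), "positive")
})

test_that("vectorized log-likelihood equals the naive loop oracle", {
  set.seed(21)
  for (i in 1:5) {
    sc <- high_rate_scenario(n = 80)
    co <- generate_cohort(sc)
    beta <- rnorm(3, sd = 0.8)
    lg <- rnorm(1, sd = 0.3)
    expect_equal(weibull_ph_loglik(beta, lg, co),
                 loglik_loop(beta, lg, co), tolerance = 1e-10)
  }
})

test_that("analytic gradient matches finite differences", {
  sc <- small_scenario(n = 300)
  co <- generate_cohort(sc, seed = 31)
  X <- cbind(1, co$x, co$z)
  theta <- c(-4.5, -0.1, 1.2, 0.05)
  de <- cohortpower:::wph_derivs(theta, X, co$event, log(co$time))
  eps <- 1e-6
  for (j in 1:4) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    fd <- (cohortpower:::wph_derivs(up, X, co$event, log(co$time))$ll -
             cohortpower:::wph_derivs(dn, X, co$event, log(co$time))$ll) /
      (2 * eps)
    expect_equal(de$grad[j], fd, tolerance = 1e-5)
  }
})

test_that("fit recovers the generating parameters at n = 200,000", {
  sc <- activity_mortality_scenario(n = 200000)
  co <- generate_cohort(sc, seed = 424242)
  fit <- fit_weibull_ph(co)
  expect_true(fit$converged)
  # tolerances ~ 3 asymptotic SE at this n
  expect_lt(abs(fit$coefficients[["exposure"]] - log(0.8)), 0.02)
  expect_lt(abs(fit$gamma - 1.1), 0.03)
  expect_lt(abs(fit$coefficients[["confounder"]] - log(4)), 0.04)
})

test_that("fit agrees with survival::survreg on the same cohort", {
  skip_if_not_installed("survival")
  sc <- activity_mortality_scenario()
  co <- generate_cohort(sc, seed = 99)
  fit <- fit_weibull_ph(co)
  sr <- survival::survreg(survival::Surv(time, event) ~ x + z,
                          data = co, dist = "weibull")
  # AFT -> PH mapping: gamma = 1/scale, beta_PH = -beta_AFT / scale
  expect_equal(fit$gamma, 1 / sr$scale, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients),
               unname(-coef(sr) / sr$scale), tolerance = 1e-6)
  # SE of the exposure log-HR via the delta method is not pulled from
  # survreg; instead check the log-likelihoods coincide at the optimum
  expect_equal(fit$loglik,
               weibull_ph_loglik(fit$coefficients, fit$log_gamma, co),
               tolerance = 1e-10)
})

test_that("gamma = 1 fits match the Poisson GLM oracle to 1e-3", {
  sc <- exponential_scenario(n = 20000)
  co <- generate_cohort(sc, seed = 77)
  fit <- fit_weibull_ph(co, fix_gamma = 1)
  expect_true(fit$converged)
  oracle <- exponential_glm_oracle(co)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-3)
  # free-shape fit on the same data lands near gamma = 1
  free <- fit_weibull_ph(co)
  expect_lt(abs(free$gamma - 1), 3 * sqrt(free$covariance[4, 4]) + 0.02)
})

test_that("fit refuses degenerate cohorts and flags them loudly", {
  sc <- small_scenario(n = 100)
  co <- generate_cohort(sc, seed = 8)
  no_events <- co; no_events$event <- 0L
  expect_error(fit_weibull_ph(no_events), "no events")
  const_x <- co; const_x$x <- 1L
  expect_error(fit_weibull_ph(const_x), "non-constant")
})

test_that("fit is invariant to subject order", {
  sc <- small_scenario(n = 800)
  co <- generate_cohort(sc, seed = 15)
  fit1 <- fit_weibull_ph(co)
  set.seed(16)
  fit2 <- fit_weibull_ph(co[sample(nrow(co)), ])
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$log_gamma, fit2$log_gamma, tolerance = 1e-8)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("loglik at the MLE dominates the truth in every simulated fit", {
  sc <- small_scenario(n = 400)
  out <- sc$outcome
  set.seed(23)
  for (i in 1:20) {
    co <- generate_cohort(sc)
    fit <- fit_weibull_ph(co)
    ll_truth <- weibull_ph_loglik(c(out$beta0, out$beta1, out$beta2),
                                  log(out$gamma), co)
    expect_gte(fit$loglik, ll_truth)
  }
})

test_that("beta1-hat is consistent across replicated studies at n = 5000", {
  rr <- run_replications(activity_mortality_scenario(), 2000,
                         mode = "alternative", master_seed = 5150)
  b <- rr$estimates[rr$converged]
  # mean of the estimates within 3 MC SE of the generating ln(0.8)
  expect_lt(abs(mean(b) - log(0.8)), 3 * sd(b) / sqrt(length(b)))
})

test_that("permuting the exposure kills its effect (null z-statistics)", {
  sc <- activity_mortality_scenario(n = 2000)
  co <- generate_cohort(sc, seed = 55)
  set.seed(56)
  zs <- replicate(200, {
    perm <- co
    perm$x <- sample(perm$x)
    fit <- fit_weibull_ph(perm)
    fit$coefficients[["exposure"]] / sqrt(fit$covariance[2, 2])
  })
  # under the permutation null ~95% of |z| fall below 1.96; allow 93%
  expect_gte(mean(abs(zs) < qnorm(0.975)), 0.93)
})

test_that("wald_summary reproduces hand-computed and degenerate cases", {
  # the printed worked-example statistics: estimate ln(0.89), SE
  # back-derived from z = -1.52
  ws <- wald_summary(log(0.89), log(0.89) / -1.52)
  expect_equal(ws$z, -1.52, tolerance = 1e-10)
  expect_equal(round(ws$p_two_sided, 2), 0.13)
  expect_equal(round(ws$hr, 2), 0.89)
  expect_lt(ws$ci_low, ws$hr)
  expect_gt(ws$ci_high, ws$hr)
  # rounded-input variant: same printed statistics after display rounding
  ws2 <- wald_summary(-0.1165, 0.0766)
  expect_identical(round(ws2$z, 2), -1.52)
  expect_identical(round(ws2$p_two_sided, 2), 0.13)

  # null point estimate
  ws0 <- wald_summary(0, 0.3)
  expect_equal(ws0$z, 0)
  expect_equal(ws0$p_two_sided, 1)
  expect_equal(ws0$ci_low * ws0$ci_high, 1, tolerance = 1e-12)

  # se -> 0 limit collapses the CI onto the estimate
  tiny <- wald_summary(log(2), 1e-10)
  expect_equal(tiny$ci_high - tiny$ci_low, 0, tolerance = 1e-8)

  # exact normal quantile, not 1.96
  ws95 <- wald_summary(0, 1)
  expect_equal(log(ws95$ci_high), qnorm(0.975), tolerance = 1e-12)
})

test_that("wald_hr_test works off a fit and refuses non-converged ones", {
  co <- generate_cohort(small_scenario(n = 1500), seed = 12)
  fit <- fit_weibull_ph(co)
  ws <- wald_hr_test(fit, "exposure")
  expect_equal(ws$hr, exp(fit$coefficients[["exposure"]]))
  expect_equal(ws$z, ws$estimate / ws$se)
  expect_error(wald_hr_test(fit, "shape"), "coefficient")
  broken <- fit; broken$converged <- FALSE
  expect_error(wald_hr_test(broken), "converge")
})

test_that("predict_survival matches frozen integration-oracle values", {
  out <- activity_mortality_scenario()$outcome
  # frozen from numeric integration of the hazard over (0, 10]
  expect_equal(predict_survival(out, 10, x = 0, z = 0), 0.915647,
               tolerance = 1e-6)
  expect_equal(predict_survival(out, 10, x = 1, z = 0), 0.931928,
               tolerance = 1e-6)
  expect_equal(predict_survival(out, 0, x = 1, z = 1), 1)
  tt <- seq(0.1, 10, by = 0.1)
  s <- predict_survival(out, tt, x = 0, z = 1)
  expect_true(all(diff(s) < 0))
  expect_error(predict_survival(out, -1, x = 0, z = 0), "non-negative")
})

test_that("fit_report is a parseable key/value summary", {
  co <- generate_cohort(small_scenario(n = 1000), seed = 44)
  fit <- fit_weibull_ph(co)
  rep <- fit_report(fit)
  kv <- strsplit(rep, "=", fixed = TRUE)
  expect_true(all(lengths(kv) == 2L))
  keys <- vapply(kv, `[`, "", 1L)
  expect_true(all(c("n_events", "gamma", "exposure.hr", "exposure.p",
                    "converged") %in% keys))
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), keys)
  expect_equal(as.numeric(vals[["gamma"]]), fit$gamma, tolerance = 1e-9)
})
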