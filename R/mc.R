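# Monte Carlo replication engine: generate -> fit -> test, many times.
# A master seed deterministically spawns one substream seed per replicate
# up front, so results do not depend on execution order and identical
# (scenario, n_reps, mode, master_seed) always reproduce bit-identically.

# Derive n per-replicate seeds from a master seed without disturbing the
# caller's RNG stream. Sampling without replacement keeps substreams
# distinct.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n, replace = FALSE))
}

#' Replicate the generate-fit-test cycle to estimate power or type-I error
#'
#' Each replicate generates a fresh cohort from the scenario (in `"null"`
#' mode the exposure log hazard-ratio `beta1` is forced to 0 in the
#' generator; nothing else changes), fits the Weibull proportional-hazards
#' model, and rejects when the two-sided Wald p-value for the exposure
#' coefficient is below the scenario's `alpha`. Non-converged replicates
#' are excluded from the power denominator and counted, never silently
#' dropped.
#'
#' @param scenario A [scenario()].
#' @param n_reps Number of replicates, `>= 1`.
#' @param mode `"alternative"` (generate under the scenario as given) or
#'   `"null"` (generate with `beta1 = 0`).
#' @param master_seed Integer master seed for the replicate substreams.
#' @return An object of class `replication_result`: vectors `estimates`
#'   (beta1-hat), `ses`, `zs`, `ps`, `rejections`, `converged`,
#'   `n_events`, `seeds` (one entry per requested replicate, `NA` where
#'   the fit failed), and scalars `n_requested`, `n_converged`, `power`,
#'   `mc_se`, `mean_events`, `mode`, `alpha`, `seed`.
#' @examples
#' sc <- activity_mortality_scenario(n = 500)
#' run_replications(sc, n_reps = 20, mode = "null", master_seed = 1)
#' @export
run_replications <- function(scenario, n_reps,
                             mode = c("alternative", "null"),
                             master_seed) {
  stopifnot(inherits(scenario, "scenario"))
  mode <- match.arg(mode)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps)) {
    stop("`n_reps` must be a positive count", call. = FALSE)
  }
  n_reps <- as.integer(n_reps)
  gen_scenario <- scenario
  if (mode == "null") {
    gen_scenario$outcome$beta1 <- 0
  }
  seeds <- derive_seeds(master_seed, n_reps)
  est <- se <- zs <- ps <- nev <- rep(NA_real_, n_reps)
  conv <- logical(n_reps)
  crit_idx <- 2L  # exposure coefficient
  for (i in seq_len(n_reps)) {
    co <- generate_cohort(gen_scenario, seed = seeds[i])
    fit <- tryCatch(fit_weibull_ph(co, level = 1 - scenario$alpha),
                    error = function(e) NULL)
    nev[i] <- sum(co$event)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    conv[i] <- TRUE
    est[i] <- unname(fit$coefficients[crit_idx])
    se[i] <- sqrt(fit$covariance[crit_idx, crit_idx])
    zs[i] <- est[i] / se[i]
    ps[i] <- 2 * (1 - pnorm(abs(zs[i])))
  }
  rej <- ifelse(conv, as.integer(ps < scenario$alpha), NA_integer_)
  n_conv <- sum(conv)
  power <- sum(rej[conv]) / n_conv
  structure(list(
    n_requested = n_reps,
    n_converged = n_conv,
    estimates = est, ses = se, zs = zs, ps = ps,
    rejections = rej, converged = conv, n_events = nev, seeds = seeds,
    power = power,
    mc_se = sqrt(power * (1 - power) / n_conv),
    mean_events = mean(nev),
    mode = mode, alpha = scenario$alpha, seed = master_seed,
    n = scenario$n
  ), class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  what <- if (x$mode == "null") "type-I error" else "power"
  cat(sprintf("Monte Carlo replication run (%s mode, n = %d, alpha = %g)\n",
              x$mode, x$n, x$alpha))
  cat(sprintf("  replicates: %d requested, %d converged\n",
              x$n_requested, x$n_converged))
  cat(sprintf("  %s = %.4f (MC SE %.4f)\n", what, x$power, x$mc_se))
  cat(sprintf("  mean events per study = %.1f\n", x$mean_events))
  invisible(x)
}

#' Summarize the sampling distribution of the estimated hazard ratio
#'
#' @param result A [run_replications()] result with at least 2 converged
#'   replicates.
#' @param probs Percentile probabilities for the HR-scale quantiles.
#' @return An object of class `sampling_summary`: `geometric_mean_hr`
#'   (`exp(mean(beta1_hat))`), `percentiles` (monotone, HR scale),
#'   `histogram` (a `hist()` object over the estimated HRs), and
#'   `n_converged`.
#' @export
summarize_sampling_distribution <- function(result,
                                            probs = c(0.01, 0.025, 0.05,
                                                      0.1, 0.25, 0.5, 0.75,
                                                      0.9, 0.95, 0.975,
                                                      0.99)) {
  stopifnot(inherits(result, "replication_result"))
  b <- result$estimates[result$converged]
  if (length(b) < 2L) {
    stop("need at least 2 converged replicates to summarize", call. = FALSE)
  }
  hr <- exp(b)
  structure(list(
    geometric_mean_hr = exp(mean(b)),
    percentiles = stats::quantile(hr, probs = probs, names = TRUE),
    histogram = graphics::hist(hr, breaks = 40, plot = FALSE),
    n_converged = length(b),
    mode = result$mode
  ), class = "sampling_summary")
}

#' @export
print.sampling_summary <- function(x, ...) {
  cat(sprintf("Sampling distribution of the estimated HR (%s mode, %d fits)\n",
              x$mode, x$n_converged))
  cat(sprintf("  geometric mean HR = %.4f\n", x$geometric_mean_hr))
  print(round(x$percentiles, 4))
  invisible(x)
}

#' Histogram of the hazard-ratio sampling distribution
#'
#' @param x A `replication_result`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.replication_result <- function(x, ...) {
  hr <- exp(x$estimates[x$converged])
  graphics::hist(hr, breaks = 40,
                 main = sprintf("Estimated HR over %d replicates (%s mode)",
                                x$n_converged, x$mode),
                 xlab = "hazard ratio", ...)
  graphics::abline(v = 1, lty = 2)
  invisible(x)
}

#' Calibrate the sample size against a target power
#'
#' Estimates power by [run_replications()] at each candidate cohort size
#' and reports the smallest candidate whose estimated power reaches the
#' target, or an explicit "none sufficient" outcome.
#'
#' @param scenario Base [scenario()]; its `n` is replaced by each
#'   candidate in turn.
#' @param target_power Desired power in `(0, 1)`.
#' @param candidate_ns Increasing vector of candidate cohort sizes.
#' @param n_reps Replicates per candidate.
#' @param master_seed Integer master seed; each candidate gets its own
#'   derived substream.
#' @return An object of class `sample_size_table`: data frame `table`
#'   with columns `n`, `power`, `mc_se`; `selected_n` (`NA` when no
#'   candidate suffices); `target_power`.
#' @export
calibrate_sample_size <- function(scenario, target_power, candidate_ns,
                                  n_reps, master_seed) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= 0 || target_power >= 1) {
    stop("`target_power` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (length(candidate_ns) < 1L || is.unsorted(candidate_ns, strictly = TRUE)) {
    stop("`candidate_ns` must be a non-empty strictly increasing vector",
         call. = FALSE)
  }
  sub_seeds <- derive_seeds(master_seed, length(candidate_ns))
  rows <- lapply(seq_along(candidate_ns), function(i) {
    sc <- scenario
    sc$n <- as.integer(candidate_ns[i])
    rr <- run_replications(sc, n_reps, mode = "alternative",
                           master_seed = sub_seeds[i])
    data.frame(n = sc$n, power = rr$power, mc_se = rr$mc_se)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$power >= target_power)
  structure(list(table = tab,
                 selected_n = if (length(ok)) tab$n[min(ok)] else NA_integer_,
                 target_power = target_power,
                 n_reps = n_reps, seed = master_seed),
            class = "sample_size_table")
}

#' @export
print.sample_size_table <- function(x, ...) {
  cat(sprintf("Sample-size calibration (target power %.2f, %d reps per n)\n",
              x$target_power, x$n_reps))
  print(transform(x$table, power = round(power, 4), mc_se = round(mc_se, 4)),
        row.names = FALSE)
  if (is.na(x$selected_n)) {
    cat("  no candidate reaches the target power\n")
  } else {
    cat(sprintf("  smallest sufficient n = %d\n", x$selected_n))
  }
  invisible(x)
}

#' Ensemble of estimated survival curves across replicated studies
#'
#' Each replicate generates a cohort, fits the model, and evaluates
#' [predict_survival()] for the requested covariate pattern over the time
#' grid; the true curve comes from the generating outcome model and is
#' independent of `n_reps` and the seed. Illustrates the sampling
#' variability of an estimated survival curve around the truth.
#'
#' @param scenario A [scenario()].
#' @param n_reps Number of replicated studies, `>= 2`.
#' @param pattern Length-2 vector `c(x, z)` of binary covariate values.
#' @param time_grid Non-empty vector of non-negative times (years).
#' @param master_seed Integer master seed.
#' @return An object of class `curve_ensemble`: `curves` (matrix,
#'   replicates x times), `true_curve`, `envelope` (pointwise min,
#'   median, max), `time_grid`, `pattern`, `n_converged`.
#' @export
survival_curve_ensemble <- function(scenario, n_reps = 900,
                                    pattern = c(x = 1, z = 0),
                                    time_grid = seq(0.25, 10, by = 0.25),
                                    master_seed = 1) {
  stopifnot(inherits(scenario, "scenario"))
  if (n_reps < 2) stop("`n_reps` must be at least 2", call. = FALSE)
  if (length(time_grid) < 1L) stop("`time_grid` must be non-empty",
                                   call. = FALSE)
  x <- unname(pattern[1]); z <- unname(pattern[2])
  seeds <- derive_seeds(master_seed, n_reps)
  curves <- matrix(NA_real_, n_reps, length(time_grid))
  for (i in seq_len(n_reps)) {
    co <- generate_cohort(scenario, seed = seeds[i])
    fit <- tryCatch(fit_weibull_ph(co), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    curves[i, ] <- predict_survival(fit, time_grid, x = x, z = z)
  }
  ok <- stats::complete.cases(curves)
  env <- apply(curves[ok, , drop = FALSE], 2, function(col)
    c(min = min(col), median = stats::median(col), max = max(col)))
  structure(list(curves = curves[ok, , drop = FALSE],
                 true_curve = predict_survival(scenario$outcome, time_grid,
                                               x = x, z = z),
                 envelope = env, time_grid = time_grid,
                 pattern = c(x = x, z = z),
                 n_converged = sum(ok)),
            class = "curve_ensemble")
}

#' @export
print.curve_ensemble <- function(x, ...) {
  cat(sprintf(
    "Survival-curve ensemble: %d fitted studies, pattern (x=%d, z=%d)\n",
    x$n_converged, x$pattern[["x"]], x$pattern[["z"]]))
  tmax <- which.max(x$time_grid)
  cat(sprintf("  S(%g): true %.4f, estimated median %.4f, range %.4f-%.4f\n",
              x$time_grid[tmax], x$true_curve[tmax],
              x$envelope["median", tmax], x$envelope["min", tmax],
              x$envelope["max", tmax]))
  invisible(x)
}

#' Plot the ensemble of estimated survival curves with the truth overlaid
#'
#' @param x A `curve_ensemble`.
#' @param max_curves Spaghetti lines to draw (subsampled for legibility).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.curve_ensemble <- function(x, max_curves = 200, ...) {
  graphics::plot(range(x$time_grid), c(min(x$envelope["min", ]), 1),
                 type = "n", xlab = "years", ylab = "survival probability",
                 main = "Sampling variability of estimated survival", ...)
  idx <- seq_len(nrow(x$curves))
  if (length(idx) > max_curves) idx <- idx[seq(1, length(idx),
                                               length.out = max_curves)]
  for (i in idx) graphics::lines(x$time_grid, x$curves[i, ],
                                 col = grDevices::adjustcolor("grey", 0.4))
  graphics::lines(x$time_grid, x$true_curve, lwd = 3, lty = 2)
  invisible(x)
}

#' Write per-replicate results as CSV
#'
#' One row per requested replicate:
#' `rep,seed,beta1_hat,se,z,p,reject,converged,n_events`.
#'
#' @param result A `replication_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replication_csv <- function(result, path) {
  stopifnot(inherits(result, "replication_result"))
  df <- data.frame(rep = seq_len(result$n_requested),
                   seed = result$seeds,
                   beta1_hat = result$estimates,
                   se = result$ses, z = result$zs, p = result$ps,
                   reject = result$rejections,
                   converged = as.integer(result$converged),
                   n_events = result$n_events)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
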