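#' Simulation scenario configuration
#'
#' Describes one cell of the frequentist evaluation grid for the one-way
#' random-intercept model on the log scale: balanced groups of size `n_g`,
#' `m` groups, variance ratio `phi` \eqn{= \tau^2/\sigma^2}, residual variance
#' `sigma2`, and global log-scale mean `mu`.
#'
#' @param n_g group size.
#' @param m number of groups.
#' @param phi variance ratio \eqn{\tau^2/\sigma^2}.
#' @param sigma2 residual variance on the log scale.
#' @param mu global mean on the log scale (default 0).
#' @param B number of Monte Carlo replicates (default 2000).
#' @param n_iter,burn_in MCMC budget per replicate (defaults 5000 / 1000).
#' @param seed base seed; per-replicate seeds are derived deterministically.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(n_g, m, phi, sigma2, mu = 0, B = 2000,
                            n_iter = 5000, burn_in = 1000, seed = 1L) {
  stopifnot(n_g >= 1, m >= 2, phi >= 0, sigma2 >= 0, B >= 1,
            n_iter > burn_in, burn_in >= 0)
  structure(list(n_g = as.integer(n_g), m = as.integer(m), phi = phi,
                 sigma2 = sigma2, tau2 = phi * sigma2, mu = mu,
                 B = as.integer(B), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario: n_g = %d, m = %d, phi = %g, sigma2 = %g (tau2 = %g), mu = %g, B = %d, MCMC %d/%d\n",
              x$n_g, x$m, x$phi, x$sigma2, x$tau2, x$mu, x$B, x$n_iter, x$burn_in))
  invisible(x)
}

scenario_salt <- function(config) {
  as.integer(round(
    (config$n_g * 131 + config$m * 1009 + config$phi * 7919 +
       config$sigma2 * 104729 + config$mu * 611) %% 1000003))
}

#' Generate one replicate dataset from the random-intercept model
#'
#' Draws \eqn{w_{ij} = \mu + v_j + \varepsilon_{ij}} with
#' \eqn{v_j \sim N(0, \tau^2 = \phi\sigma^2)},
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)}, and returns the positive
#' responses \eqn{y = \exp(w)}.  Deterministic given `(config$seed,
#' replicate)`.
#'
#' @param config a [scenario_config()].
#' @param replicate replicate index (>= 1).
#' @return A tibble with columns `group`, `y`, `w`; the drawn group effects
#'   are attached as attribute `"v"` and the per-group true conditional
#'   expectations \eqn{\exp\{\mu + v_j + \sigma^2/2\}} as attribute
#'   `"theta_c_true"`.
#' @export
simulate_scenario_data <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"), replicate >= 1)
  rs <- derive_seed(config$seed, replicate, scenario_salt(config))
  with_seed(rs, {
    v <- rnorm(config$m, 0, sqrt(config$tau2))
    eps <- rnorm(config$m * config$n_g, 0, sqrt(config$sigma2))
    w <- config$mu + rep(v, each = config$n_g) + eps
    out <- tibble(group = factor(rep(seq_len(config$m), each = config$n_g)),
                  y = exp(w), w = w)
    attr(out, "v") <- v
    attr(out, "theta_c_true") <- exp(config$mu + v + config$sigma2 / 2)
    attr(out, "theta_m_true") <- exp(config$mu + (config$sigma2 + config$tau2) / 2)
    out
  })
}

arm_priors <- function(arm, design) {
  switch(arm,
    GIG = elicit_priors(design, r = 2, c = 1, epsilon = 0.01),
    IG_1_1 = prior_spec(gig_params(-1, sqrt(2), 0),
                        gig_params(-1, sqrt(2), 0), q = design$q),
    IG_small = prior_spec(gig_params(-0.001, sqrt(0.002), 0),
                          gig_params(-0.001, sqrt(0.002), 0), q = design$q),
    abort(sprintf("unknown arm '%s'", arm), class = "gigmm_usage_error"))
}

rmse_se <- function(err2, rmse, B) {
  if (rmse == 0) return(0)
  sd(err2) / sqrt(B) / (2 * rmse)
}

#' Frequentist metrics from replicate-level estimates
#'
#' Computes the evaluation metrics of the simulation study.  For the marginal
#' expectation: Bias, RMSE, frequentist coverage (Cov) and average width (Wid)
#' of the 95% intervals.  For the group-specific expectations (arguments
#' `group_*`, replicate-by-group matrices): relative absolute bias (RABias,
#' with the absolute value taken after averaging over replicates and before
#' averaging over groups), relative RMSE (RRMSE), average coverage (ACo) and
#' average width (AWi).  Monte Carlo standard errors accompany every metric
#' (delta-method for RMSE-type metrics; replicate-level for the averaged
#' group metrics).
#'
#' @param est replicate estimates of the marginal expectation (length B).
#' @param truth true marginal expectation (scalar or length B).
#' @param lower,upper interval bounds (length B), or `NULL`.
#' @param group_est,group_truth,group_lower,group_upper B x J matrices for the
#'   group expectations, or `NULL`.
#' @return Tibble with columns `functional`, `metric`, `value`, `mc_se`.
#' @export
metrics_from_estimates <- function(est = NULL, truth = NULL,
                                   lower = NULL, upper = NULL,
                                   group_est = NULL, group_truth = NULL,
                                   group_lower = NULL, group_upper = NULL) {
  out <- list()
  if (!is.null(est)) {
    B <- length(est)
    if (!length(truth) %in% c(1L, B))
      abort("truth must be scalar or length B", class = "gigmm_usage_error")
    err <- est - truth
    rmse <- sqrt(mean(err^2))
    rows <- tibble(functional = "theta_m",
                   metric = c("Bias", "RMSE"),
                   value = c(mean(err), rmse),
                   mc_se = c(sd(err) / sqrt(B), rmse_se(err^2, rmse, B)))
    if (!is.null(lower)) {
      stopifnot(length(lower) == B, length(upper) == B)
      cov <- mean(truth >= lower & truth <= upper)
      wid <- upper - lower
      rows <- dplyr::bind_rows(rows, tibble(
        functional = "theta_m", metric = c("Cov", "Wid"),
        value = c(cov, mean(wid)),
        mc_se = c(sqrt(cov * (1 - cov) / B), sd(wid) / sqrt(B))))
    }
    out <- c(out, list(rows))
  }
  if (!is.null(group_est)) {
    group_est <- as.matrix(group_est); group_truth <- as.matrix(group_truth)
    if (!all(dim(group_est) == dim(group_truth)))
      abort("group estimate/truth dimensions differ", class = "gigmm_usage_error")
    B <- nrow(group_est); J <- ncol(group_est)
    rel <- (group_est - group_truth) / group_truth
    rab_j <- abs(colMeans(rel))
    rrmse_j <- sqrt(colMeans(rel^2))
    rab_se <- sqrt(sum(apply(rel, 2, var) / B)) / J
    rrmse_se <- sqrt(sum(vapply(seq_len(J), function(j)
      rmse_se(rel[, j]^2, rrmse_j[j], B)^2, numeric(1)))) / J
    rows <- tibble(functional = "theta_c",
                   metric = c("RABias", "RRMSE"),
                   value = c(mean(rab_j), mean(rrmse_j)),
                   mc_se = c(rab_se, rrmse_se))
    if (!is.null(group_lower)) {
      group_lower <- as.matrix(group_lower); group_upper <- as.matrix(group_upper)
      covmat <- group_truth >= group_lower & group_truth <= group_upper
      cov_k <- rowMeans(covmat)
      wid_k <- rowMeans(group_upper - group_lower)
      rows <- dplyr::bind_rows(rows, tibble(
        functional = "theta_c", metric = c("ACo", "AWi"),
        value = c(mean(cov_k), mean(wid_k)),
        mc_se = c(sd(cov_k) / sqrt(B), sd(wid_k) / sqrt(B))))
    }
    out <- c(out, list(rows))
  }
  dplyr::bind_rows(out)
}

#' Run one simulation scenario
#'
#' Frequentist evaluation of the estimators of the marginal expectation
#' \eqn{\theta_m} and the group expectations \eqn{\theta_c(v_j)} over `B`
#' paired replicates (the same datasets are used by every arm).  MCMC arms
#' (`"GIG"`, `"IG_1_1"`, `"IG_small"`) report posterior means and 0.025/0.975
#' interval endpoints; the `"conditional"` arm evaluates the closed-form
#' benchmark estimators with the variances treated as known.  The tibble also
#' carries a `MaxEst` row per arm (the largest replicate-level \eqn{\theta_m}
#' estimate), the numerical sentinel for non-existing posterior moments.
#'
#' @param config a [scenario_config()].
#' @param arms subset of `c("GIG", "IG_1_1", "IG_small", "conditional")`.
#' @param fast if `TRUE`, divide `B` and the MCMC budget by 4 (Monte Carlo
#'   standard errors are always reported).
#' @param verbose print per-arm progress.
#' @return Tibble with columns `arm`, `functional`, `metric`, `value`,
#'   `mc_se`; the configuration is attached as attribute `"config"` and the
#'   replicate-level \eqn{\theta_m} estimates as attribute `"estimates"`.
#' @export
run_scenario <- function(config, arms = c("GIG", "conditional"),
                         fast = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  arms <- match.arg(arms, c("GIG", "IG_1_1", "IG_small", "conditional"),
                    several.ok = TRUE)
  B <- if (fast) max(2L, config$B %/% 4L) else config$B
  n_iter <- if (fast) max(40L, config$n_iter %/% 4L) else config$n_iter
  burn_in <- if (fast) config$burn_in %/% 4L else config$burn_in

  # design structure is replicate-invariant (balanced layout); build once
  d1 <- simulate_scenario_data(config, 1L)
  design <- mixed_design(d1, "y", groups = "group")
  theta_m_true <- attr(d1, "theta_m_true")
  J <- config$m

  mcmc_arms <- setdiff(arms, "conditional")
  priors <- lapply(setNames(mcmc_arms, mcmc_arms), arm_priors, design = design)

  res <- list()
  for (arm in arms)
    res[[arm]] <- list(est = numeric(B), lower = numeric(B), upper = numeric(B),
                       gest = matrix(NA_real_, B, J),
                       glower = matrix(NA_real_, B, J),
                       gupper = matrix(NA_real_, B, J))
  gtruth <- matrix(NA_real_, B, J)
  failures <- 0L

  for (k in seq_len(B)) {
    dk <- simulate_scenario_data(config, k)
    design$w <- dk$w
    gtruth[k, ] <- attr(dk, "theta_c_true")
    for (arm in arms) {
      if (arm == "conditional") {
        be <- benchmark_estimators(dk$w, dk$group, config$sigma2, config$tau2)
        res[[arm]]$est[k] <- be$value[be$estimator == "theta_m"]
        res[[arm]]$gest[k, ] <- be$value[be$estimator == "theta_c"]
        res[[arm]]$lower[k] <- NA_real_; res[[arm]]$upper[k] <- NA_real_
        next
      }
      fit_seed <- derive_seed(config$seed, k, scenario_salt(config) +
                                match(arm, c("GIG", "IG_1_1", "IG_small")) * 7L)
      draws <- tryCatch(
        run_gibbs(design, priors[[arm]], n_iter = n_iter, burn_in = burn_in,
                  seed = fit_seed),
        error = function(e) NULL)
      if (is.null(draws)) {  # re-seed once and count the failure
        failures <- failures + 1L
        draws <- run_gibbs(design, priors[[arm]], n_iter = n_iter,
                           burn_in = burn_in, seed = fit_seed + 1L)
      }
      thm <- exp(draws$beta[, 1] + 0.5 * (draws$sigma2 + draws$tau2[, 1]))
      res[[arm]]$est[k] <- mean(thm)
      qs <- quantile(thm, c(0.025, 0.975), names = FALSE)
      res[[arm]]$lower[k] <- qs[1]; res[[arm]]$upper[k] <- qs[2]
      lin <- draws$beta[, 1] + 0.5 * draws$sigma2
      thc <- exp(sweep(draws$u, 1, lin, `+`))
      res[[arm]]$gest[k, ] <- colMeans(thc)
      gq <- apply(thc, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
      res[[arm]]$glower[k, ] <- gq[1, ]; res[[arm]]$gupper[k, ] <- gq[2, ]
    }
    if (verbose && k %% 200 == 0)
      message(sprintf("  replicate %d / %d", k, B))
  }

  metrics <- dplyr::bind_rows(lapply(arms, function(arm) {
    r <- res[[arm]]
    has_int <- arm != "conditional"
    m <- metrics_from_estimates(
      est = r$est, truth = theta_m_true,
      lower = if (has_int) r$lower, upper = if (has_int) r$upper,
      group_est = r$gest, group_truth = gtruth,
      group_lower = if (has_int) r$glower,
      group_upper = if (has_int) r$gupper)
    dplyr::bind_rows(m, tibble(functional = "theta_m", metric = "MaxEst",
                               value = max(r$est), mc_se = NA_real_)) |>
      dplyr::mutate(arm = arm, .before = 1)
  }))
  attr(metrics, "config") <- config
  attr(metrics, "B") <- B
  attr(metrics, "failures") <- failures
  attr(metrics, "estimates") <- lapply(res, `[[`, "est")
  metrics
}
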