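oneway_data <- function(m = 10, n_g = 2, sigma2 = 0.05, tau2 = 0.025,
                        mu = 0, seed = 1) {
  set.seed(seed)
  v <- rnorm(m, 0, sqrt(tau2))
  w <- mu + rep(v, each = n_g) + rnorm(m * n_g, 0, sqrt(sigma2))
  tibble::tibble(y = exp(w), group = factor(rep(seq_len(m), each = n_g)))
}

test_that("chains are bitwise reproducible given the seed", {
  d <- oneway_data(seed = 3)
  des <- mixed_design(d, "y", groups = "group")
  pr <- elicit_priors(des)
  a <- run_gibbs(des, pr, n_iter = 300, burn_in = 50, seed = 9)
  b <- run_gibbs(des, pr, n_iter = 300, burn_in = 50, seed = 9)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sigma2, b$sigma2)
  expect_identical(a$u, b$u)
  c <- run_gibbs(des, pr, n_iter = 300, burn_in = 50, seed = 10)
  expect_false(identical(a$sigma2, c$sigma2))
  expect_identical(length(a$sigma2), 250L)
  expect_true(all(a$sigma2 > 0) && all(a$tau2 > 0))
})

test_that("with clamped variances the beta draws match the closed-form posterior", {
  set.seed(11)
  g <- rep(1:6, each = 5)
  X <- cbind(1, rnorm(30))
  des <- build_design(rnorm(30, sd = 0.6), X,
                      list(g = stats::model.matrix(~ factor(g) - 1)))
  sigma2 <- 0.3; tau2 <- 0.2
  want <- beta_conditional_posterior(des, sigma2, tau2)
  pr <- elicit_priors(des)
  dr <- run_gibbs(des, pr, n_iter = 22000, burn_in = 2000, seed = 5,
                  init = list(sigma2 = sigma2, tau2 = tau2),
                  fix_variances = TRUE)
  expect_true(all(dr$sigma2 == sigma2))
  dg <- mcmc_diagnostics(dr)
  for (j in 1:2) {
    ess <- dg$ess[j]
    se <- sd(dr$beta[, j]) / sqrt(ess)
    expect_lt(abs(mean(dr$beta[, j]) - want$mean[j]), 4 * se)
    expect_equal(var(dr$beta[, j]), want$cov[j, j], tolerance = 0.1)
  }
  emp_cor <- cor(dr$beta[, 1], dr$beta[, 2])
  want_cor <- want$cov[1, 2] / sqrt(want$cov[1, 1] * want$cov[2, 2])
  expect_lt(abs(emp_cor - want_cor), 0.05)
})

test_that("the residual-variance full conditional is the conjugate GIG", {
  d <- oneway_data(m = 10, n_g = 2, seed = 21)
  des <- mixed_design(d, "y", groups = "group")
  pr <- elicit_priors(des)
  # fixed state: beta at OLS, u = 0 (the sampler's initial state)
  beta_ols <- mean(des$w)
  rss <- sum((des$w - beta_ols)^2)
  cond <- gig_params(pr$sigma2$lambda - des$n / 2,
                     sqrt(rss + pr$sigma2$delta^2), pr$sigma2$gamma)
  draws <- rgig(1e5, cond, seed = 31)
  cdf <- gig_quad_cdf(cond, min(draws) * 0.9, max(draws) * 1.1)
  expect_ks_pass(draws, cdf, label = "sigma2 full conditional")
  # the sampler's own first-iteration draw follows the same law
  first <- vapply(1:2000, function(i)
    run_gibbs(des, pr, n_iter = 1, burn_in = 0, seed = i)$sigma2, numeric(1))
  expect_ks_pass(first, cdf, label = "sampler one-step sigma2")
})

test_that("inverse-gamma priors reproduce the normal-inverse-gamma update", {
  d <- oneway_data(m = 10, n_g = 2, seed = 22)
  des <- mixed_design(d, "y", groups = "group")
  # IG(1, 1) prior encoded on the gamma = 0 boundary
  beta_ols <- mean(des$w)
  rss <- sum((des$w - beta_ols)^2)
  cond <- gig_params(-1 - des$n / 2, sqrt(rss + 2), 0)
  draws <- rgig(5e4, cond, seed = 33)
  # 1/sigma2 | state ~ Gamma(1 + n/2, rate = (rss + 2)/2)
  expect_ks_pass(1 / draws, function(x)
    stats::pgamma(x, shape = 1 + des$n / 2, rate = (rss + 2) / 2),
    label = "IG boundary conditional")
})

test_that("the sampler recovers the generating variance components", {
  cfg <- scenario_config(n_g = 20, m = 50, phi = 1, sigma2 = 0.25, seed = 77)
  d <- simulate_scenario_data(cfg, 1)
  des <- mixed_design(d, "y", groups = "group")
  pr <- elicit_priors(des)
  dr <- run_gibbs(des, pr, n_iter = 5000, burn_in = 1000, seed = 13)
  expect_lt(abs(mean(dr$sigma2) - 0.25) / 0.25, 0.15)
  expect_lt(abs(mean(dr$tau2[, 1]) - 0.25) / 0.25, 0.30)
})

test_that("effective sample size and split-PSRF behave on reference chains", {
  set.seed(41)
  # i.i.d. chain: ESS close to the chain length
  x <- rnorm(4000)
  expect_lt(abs(gigmm:::ess_one(x) - 4000) / 4000, 0.1)
  # AR(1) with coefficient 0.9: ESS ~ n (1 - phi) / (1 + phi)
  n <- 40000; phi <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n))
  want <- n * (1 - phi) / (1 + phi)
  expect_lt(abs(gigmm:::ess_one(ar) - want) / want, 0.25)
  # two halves of one stationary chain: PSRF near 1
  expect_lt(gigmm:::rhat_split(rnorm(4000), rep(1L, 4000)), 1.05)
})

test_that("diagnostics table flags and errors as documented", {
  d <- oneway_data(seed = 5)
  des <- mixed_design(d, "y", groups = "group")
  pr <- elicit_priors(des)
  dr <- run_gibbs(des, pr, n_iter = 1200, burn_in = 200, seed = 2)
  dg <- mcmc_diagnostics(dr)
  expect_true(all(c("(Intercept)", "sigma2", "tau2_group") %in% dg$parameter))
  expect_true(all(dg$ess > 0))
  expect_true(all(is.finite(dg$psrf)))
  short <- run_gibbs(des, pr, n_iter = 60, burn_in = 10, seed = 2)
  expect_error(mcmc_diagnostics(short), class = "gigmm_usage_error")
})

test_that("multiple chains derive distinct deterministic seeds", {
  d <- oneway_data(seed = 6)
  des <- mixed_design(d, "y", groups = "group")
  pr <- elicit_priors(des)
  dr <- run_gibbs(des, pr, n_iter = 400, burn_in = 100, seed = 3, chains = 2L)
  expect_identical(length(dr$sigma2), 600L)
  expect_identical(sort(unique(dr$chain)), 1:2)
  expect_false(identical(dr$sigma2[1:300], dr$sigma2[301:600]))
  dr2 <- run_gibbs(des, pr, n_iter = 400, burn_in = 100, seed = 3, chains = 2L)
  expect_identical(dr$sigma2, dr2$sigma2)
})
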