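test_that("marginal expectation draws evaluate exp{x'b + (sigma2 + sum tau2)/2}", {
  dr <- make_draws(beta = 0, u = 0, sigma2 = 0.05, tau2 = 0.025)
  expect_equal(theta_m_draws(dr)$value, exp(0.0375))
  expect_equal(round(theta_m_draws(dr)$value, 3), 1.038)
  dr2 <- make_draws(beta = 0, u = 0, sigma2 = 0.75, tau2 = 1.5)
  expect_equal(round(theta_m_draws(dr2)$value, 2), 3.08)
  # degenerate point mass
  dr0 <- make_draws(beta = 0, u = 0, sigma2 = 0, tau2 = 0)
  expect_equal(theta_m_draws(dr0)$value, 1)
  # covariate point enters through the linear predictor
  drb <- make_draws(beta = cbind(1, 2), u = 0, sigma2 = 0, tau2 = 0)
  expect_equal(theta_m_draws(drb, c(1, 0.5))$value, exp(2))
  expect_error(theta_m_draws(drb, c(1, 0, 0)), class = "gigmm_dimension_error")
})

test_that("conditional expectation draws support full and partial conditioning", {
  dr <- make_draws(beta = 0, u = cbind(0.1, -0.2), sigma2 = 0.05,
                   tau2 = 0.025)
  colnames(dr$u) <- c("g:1", "g:2")
  # conditioning on group 1
  got <- theta_c_draws(dr, z_point = c(g = "1"))
  expect_equal(got$value, exp(0.1 + 0.025))
  # integrating out everything reproduces theta_m
  all_out <- theta_c_draws(dr, z_point = rep(0, 2), condition_on = character())
  expect_equal(all_out$value, theta_m_draws(dr)$value)
  expect_error(theta_c_draws(dr, z_point = c(g = "7")),
               class = "gigmm_config_error")
})

test_that("partial conditioning adds tau2/2 for each integrated-out factor", {
  # two-factor reading-time style functional: condition on the item effect
  # v_k, integrate out the subject effect: exp{b0 + x b1 + v_k + (tau_u^2 + sigma^2)/2}
  beta <- cbind(6, -0.05); u <- cbind(0.3, -0.1, 0.2)  # v1, v2, u1
  colnames(u) <- c("v:1", "v:2", "u:1")
  tau2 <- cbind(0.04, 0.07); colnames(tau2) <- c("v", "u")
  dr <- make_draws(beta, u, sigma2 = 0.27, tau2 = tau2)
  got <- theta_c_draws(dr, x_point = c(1, 1), z_point = c(1, 0, 0),
                       condition_on = "v")
  expect_equal(got$value, exp(6 - 0.05 + 0.3 + (0.07 + 0.27) / 2))
})

test_that("predictive draws obey the log-normal mean and median identities", {
  B <- 2e5
  dr <- make_draws(beta = matrix(0.2, B, 1), u = matrix(0, B, 1),
                   sigma2 = rep(0.3, B), tau2 = matrix(0.1, B, 1))
  pd <- predictive_draws(dr, mode = "new-group", seed = 8)
  want_mean <- exp(0.2 + (0.3 + 0.1) / 2)
  se <- sd(pd$value) / sqrt(B)
  expect_lt(abs(mean(pd$value) - want_mean), 4 * se)
  expect_equal(unname(stats::median(pd$value)), exp(0.2), tolerance = 0.01)
  # noiseless limit degenerates to exp{x'beta}
  dr0 <- make_draws(beta = matrix(0.2, 10, 1), u = matrix(0, 10, 1),
                    sigma2 = rep(0, 10) + 1e-30, tau2 = matrix(1e-30, 10, 1))
  pd0 <- predictive_draws(dr0, mode = "new-group", seed = 1)
  expect_equal(pd0$value, rep(exp(0.2), 10), tolerance = 1e-6)
  # observed-group mode uses the sampled effect
  dr1 <- make_draws(beta = 0, u = cbind(`g:1` = 0.4), sigma2 = 1e-30,
                    tau2 = cbind(g = 0.5))
  pd1 <- predictive_draws(dr1, z_point = c(g = "1"), mode = "observed-group",
                          seed = 2)
  expect_equal(pd1$value, exp(0.4), tolerance = 1e-6)
})

test_that("summaries report mean, sd, median and equal-tailed quantiles", {
  f <- gigmm:::new_functional(rep(2.5, 40), "theta_m", list())
  s <- summarize_functional(f)
  expect_equal(s$mean, 2.5); expect_equal(s$sd, 0)
  expect_equal(c(s$lower, s$upper), c(2.5, 2.5))
  set.seed(9)
  x <- exp(rnorm(2e5))
  f2 <- gigmm:::new_functional(x, "theta_m", list())
  s2 <- summarize_functional(f2)
  expect_lt(abs(s2$mean - exp(0.5)), 4 * sd(x) / sqrt(length(x)))
  expect_equal(c(s2$lower, s2$upper),
               unname(quantile(x, c(0.025, 0.975))))
  expect_equal(tidy(f2), s2)
})

test_that("benchmark estimators evaluate their closed forms", {
  # w identically zero: group and global means vanish
  w <- rep(0, 20); g <- rep(1:10, each = 2)
  be <- benchmark_estimators(w, g, sigma2 = 0.05, tau2 = 0.025)
  expect_equal(be$value[be$estimator == "theta_m"],
               exp(0.0375 - 3 * (0.05 + 2 * 0.025) / 40))
  shr <- 0.05 / (0.05 + 2 * 0.025)
  want_c <- exp(0.05 / 2 - 1.5 * shr * (0.025 + 0.05 / 20))
  expect_equal(unique(be$value[be$estimator == "theta_c"]), want_c)
  # tau2 = 0 keeps the formulas finite; vanishing variances give 1
  be0 <- benchmark_estimators(w, g, sigma2 = 1e-12, tau2 = 0)
  expect_equal(be0$value, rep(1, 11), tolerance = 1e-10)
  expect_error(benchmark_estimators(rnorm(5), c(1, 1, 2, 2, 2), 0.1, 0.1),
               class = "gigmm_unsupported_design_error")
})

test_that("the marginal benchmark minimises MSE in the class k exp(wbar)", {
  # balanced one-way layout, variances known: simulate wbar directly
  m <- 10; n_g <- 2; sigma2 <- 0.25; tau2 <- 0.25; n <- m * n_g
  set.seed(12)
  B <- 40000
  wbar <- rnorm(B, 0, sqrt((sigma2 + n_g * tau2) / n))
  theta <- exp((sigma2 + tau2) / 2)
  k_star <- exp((sigma2 + tau2) / 2 - 3 * (sigma2 + n_g * tau2) / (2 * n))
  ks <- k_star * seq(0.7, 1.3, by = 0.05)
  mse <- vapply(ks, function(k) mean((k * exp(wbar) - theta)^2), numeric(1))
  expect_equal(which.min(mse), which.min(abs(ks - k_star)))
})

test_that("averaging conditional draws over fresh random effects recovers theta_m", {
  # one posterior state (beta = 0, sigma2 = 0.3, tau2 = 0.4) replicated with
  # fresh u ~ N(0, tau2): the Monte Carlo average of theta_c equals theta_m
  B <- 2e5; sigma2 <- 0.3; tau2 <- 0.4
  set.seed(31)
  u <- matrix(rnorm(B, 0, sqrt(tau2)))
  dr <- make_draws(beta = matrix(0, B, 1), u = u,
                   sigma2 = rep(sigma2, B), tau2 = matrix(tau2, B, 1))
  tc <- theta_c_draws(dr, z_point = 1, condition_on = "g")
  tm <- theta_m_draws(dr)$value[1]
  se <- sd(tc$value) / sqrt(B)
  expect_lt(abs(mean(tc$value) - tm), 4 * se)
})
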