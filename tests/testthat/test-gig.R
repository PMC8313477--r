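test_that("parameter validation accepts the permissible region and rejects the rest", {
  expect_s3_class(gig_params(1, 0.5, 2), "gig_params")
  expect_s3_class(gig_params(-1, sqrt(2), 0), "gig_params")   # inverse gamma
  expect_s3_class(gig_params(0, 1, 1), "gig_params")
  expect_s3_class(gig_params(2, 0, 1), "gig_params")          # Gamma
  bad <- list(c(0, 1, 0),       # lambda = 0 needs gamma > 0
              c(1, 1, 0),       # lambda > 0 needs gamma > 0
              c(-1, 0, 1),      # delta = 0 needs lambda > 0
              c(0, 0, 1),
              c(1, -1, 1),      # negative delta
              c(1, 1, -1))      # negative gamma
  for (b in bad)
    expect_error(gig_params(b[1], b[2], b[3]), class = "gigmm_parameter_error")
  expect_error(dgig(-1, gig_params(1, 1, 1)), class = "gigmm_domain_error")
})

test_that("log-density matches closed-form special cases", {
  # Gamma limit with shape 1, rate 1: Exponential(1)
  expect_equal(gig_logpdf(1, gig_params(1, 0, sqrt(2))), -1)
  # lambda = -1/2 is the inverse Gaussian(mu = delta/gamma, shape = delta^2)
  v <- c(0.2, 0.7, 1, 1.9, 4.2)
  dig <- function(v, mu, lam) sqrt(lam / (2 * pi * v^3)) *
    exp(-lam * (v - mu)^2 / (2 * mu^2 * v))
  expect_equal(dgig(v, gig_params(-0.5, 1, 1)), dig(v, 1, 1), tolerance = 1e-12)
  expect_equal(dgig(v, gig_params(-0.5, 2, 0.8)), dig(v, 2.5, 4), tolerance = 1e-12)
  # gamma = 0 boundary is the exact inverse-gamma density
  expect_equal(dgig(v, gig_params(-1, sqrt(2), 0)),
               1 / v^2 * exp(-1 / v), tolerance = 1e-12)
})

test_that("density normalises to one across the parameter grid", {
  grid <- list(gig_params(1, 0.01, 1.975), gig_params(-3.5, 2, 1.975),
               gig_params(0, 1, 1), gig_params(2.5, 0.3, 4),
               gig_params(-0.5, 1, 1), gig_params(-9, 3, 0),
               gig_params(3, 0, 2), gig_params(0.3, 0.2, 0.1))
  for (p in grid)
    expect_equal(gig_quad_mass(p), 1, tolerance = 1e-8)
})

test_that("interior density is continuous into the Gamma and inverse-gamma limits", {
  v <- c(0.1, 0.5, 1, 2, 5)
  near_gamma <- dgig(v, gig_params(1.5, 1e-6, 2))
  expect_equal(near_gamma, dgamma(v, 1.5, rate = 2), tolerance = 1e-4)
  near_ig <- dgig(v, gig_params(-2, 1.5, 1e-6))
  expect_equal(near_ig, dgig(v, gig_params(-2, 1.5, 0)), tolerance = 1e-4)
})

test_that("duality identity holds: p(v; l,d,g) = p(1/v; -l,g,d) / v^2", {
  vs <- c(0.05, 0.3, 1, 2.4, 11)
  for (par in list(c(1, 0.4, 2), c(-2.5, 1.3, 0.7), c(0, 1, 1))) {
    lhs <- gig_logpdf(vs, gig_params(par[1], par[2], par[3]))
    rhs <- gig_logpdf(1 / vs, gig_params(-par[1], par[3], par[2])) - 2 * log(vs)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("moments match quadrature and flag non-existence", {
  expect_equal(gig_moment(1, gig_params(1, 0, sqrt(2))), 1)
  expect_equal(gig_moment(1, gig_params(0, 1, 1)),
               besselK(1, 1) / besselK(1, 0))
  expect_equal(gig_moment(1, gig_params(0, 1, 1)),
               gig_quad_moment(1, gig_params(0, 1, 1)), tolerance = 1e-8)
  # IG(1, 1) has no finite second moment
  expect_identical(gig_moment(2, gig_params(-1, sqrt(2), 0)), Inf)
  expect_identical(gig_moment(1, gig_params(-1, sqrt(2), 0)), Inf)
  expect_equal(gig_moment(0.5, gig_params(-1, sqrt(2), 0)),
               gig_quad_moment(0.5, gig_params(-1, sqrt(2), 0)), tolerance = 1e-6)
  # Gamma boundary: negative moments below -lambda do not exist
  expect_identical(gig_moment(-2, gig_params(1.5, 0, 1)), Inf)
  for (p in list(gig_params(-3.5, 2, 1.975), gig_params(2.5, 0.3, 4)))
    for (r in c(-1, 1, 2))
      expect_equal(gig_moment(r, p), gig_quad_moment(r, p), tolerance = 1e-7)
})

test_that("variates are reproducible and hit all generator regions correctly", {
  p <- gig_params(1, 0, sqrt(2))
  expect_identical(rgig(10, p, seed = 42), rgig(10, p, seed = 42))
  expect_false(all(rgig(10, p, seed = 1) == rgig(10, p, seed = 2)))

  # Exponential(1) boundary: mean within 4 MC standard errors
  x <- rgig(1e5, p, seed = 1)
  expect_lt(abs(mean(x) - 1), 4 * sd(x) / sqrt(length(x)))

  # inverse-Gaussian case: mean against the Bessel moment identity
  pig <- gig_params(-0.5, 1, 1)
  x <- rgig(1e5, pig, seed = 3)
  expect_lt(abs(mean(x) - gig_moment(1, pig)), 4 * sd(x) / sqrt(length(x)))

  # KS against the quadrature CDF, one parameter point per sampler region
  regions <- list(
    shift = gig_params(-3.5, 2, 1.975),       # strongly negative order (duality)
    shift2 = gig_params(4, 0.5, 3),           # large positive order
    noshift = gig_params(0.5, 1, 0.8),        # central region
    twopiece = gig_params(0.3, 0.1, 0.5),     # small omega, lambda < 1
    zero_lam = gig_params(0, 0.3, 0.3))       # lambda = 0, small omega
  ns <- c(shift = 1e5, shift2 = 3e4, noshift = 3e4, twopiece = 3e4,
          zero_lam = 3e4)
  for (nm in names(regions)) {
    prm <- regions[[nm]]
    x <- rgig(ns[[nm]], prm, seed = 7)
    cdf <- gig_quad_cdf(prm, min(x) * 0.9, max(x) * 1.1)
    expect_ks_pass(x, cdf, label = nm)
  }
})

test_that("sample moments agree with the moment identity where moments exist", {
  for (prm in list(gig_params(1, 0.01, 1.975), gig_params(-3.5, 2, 1.975),
                   gig_params(2, 1, 1))) {
    x <- rgig(5e4, prm, seed = 5)
    for (r in c(1, 2)) {
      mom <- gig_moment(r, prm)
      se <- sd(x^r) / sqrt(length(x))
      expect_lt(abs(mean(x^r) - mom), 4 * se)
    }
  }
})
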