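# Independent numerical oracles used across the suite.

# normalisation integral of the GIG density by adaptive quadrature
gig_quad_mass <- function(params) {
  stats::integrate(function(v) dgig(v, params), 0, Inf,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# r-th moment by quadrature
gig_quad_moment <- function(r, params) {
  stats::integrate(function(v) v^r * dgig(v, params), 0, Inf,
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# vectorised CDF by cumulative trapezoid integration on a log-spaced grid,
# anchored by adaptive quadrature below the grid
gig_quad_cdf <- function(params, lo, hi, n_grid = 20001L) {
  xs <- exp(seq(log(lo), log(hi), length.out = n_grid))
  fx <- dgig(xs, params)
  cum <- c(0, cumsum(diff(xs) * (head(fx, -1) + fx[-1]) / 2))
  head_mass <- stats::integrate(function(v) dgig(v, params), 0, lo,
                                rel.tol = 1e-10)$value
  cdf <- stats::approxfun(xs, pmin(head_mass + cum, 1), yleft = 0, yright = 1)
  cdf
}

# two-sided KS check of a sample against a numeric CDF at alpha = 0.01
expect_ks_pass <- function(sample, cdf, label = "sample") {
  n <- length(sample)
  d <- suppressWarnings(stats::ks.test(sample, cdf)$statistic)
  crit <- 1.628 / sqrt(n)  # asymptotic critical value at alpha = 0.01
  expect_lt(d, crit, label = sprintf("KS statistic for %s", label))
}

# dense-covariance GLS oracle for the conditional posterior of beta
gls_beta_oracle <- function(design, sigma2, tau2) {
  V <- diag(design$n) * sigma2
  for (s in seq_len(design$q)) {
    Zs <- design$Z_blocks[[s]]
    V <- V + tau2[s] * tcrossprod(Zs)
  }
  Vi <- solve(V)
  cov <- solve(crossprod(design$X, Vi %*% design$X))
  mean <- drop(cov %*% crossprod(design$X, Vi %*% design$w))
  list(mean = mean, cov = cov)
}

# random small mixed design (unbalanced grouping) for property tests
random_design <- function(seed, n = 24, p = 2, q = 1, intercept = TRUE) {
  set.seed(seed)
  X <- if (intercept) cbind(1, matrix(rnorm(n * (p - 1)), n)) else
    matrix(rnorm(n * p), n)
  Z_blocks <- lapply(seq_len(q), function(s) {
    m <- sample(3:6, 1)
    g <- factor(sample(seq_len(m), n, replace = TRUE))
    while (nlevels(droplevels(g)) < m) g <- factor(sample(seq_len(m), n, replace = TRUE))
    stats::model.matrix(~ g - 1)
  })
  w <- rnorm(n)
  build_design(w, X, Z_blocks)
}

# hand-made draws container for exact functional evaluations
make_draws <- function(beta, u, sigma2, tau2) {
  beta <- as.matrix(beta); u <- as.matrix(u); tau2 <- as.matrix(tau2)
  if (is.null(colnames(beta))) colnames(beta) <- paste0("b", seq_len(ncol(beta)))
  if (is.null(colnames(u))) colnames(u) <- paste0("g:", seq_len(ncol(u)))
  if (is.null(colnames(tau2))) colnames(tau2) <- "g"
  structure(list(beta = beta, u = u, sigma2 = sigma2, tau2 = tau2,
                 chain = rep(1L, length(sigma2)),
                 meta = list(seed = NA, n_iter = length(sigma2),
                             burn_in = 0L, chains = 1L)),
            class = "lnmm_draws")
}
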