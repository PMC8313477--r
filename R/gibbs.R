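# deterministic sub-seed derivation (chains, simulation replicates)
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 69621 +
                as.double(salt) * 40692) %% 2147483399) + 1L
}

#' Gibbs sampler for the log-normal mixed model
#'
#' Direct Gibbs sampler for \eqn{w = X\beta + Zu + \varepsilon} under the flat
#' improper prior on \eqn{\beta} and GIG priors on the variance components,
#' exploiting normal-GIG conjugacy: the residual variance is drawn from
#' GIG\eqn{(\lambda_\sigma - n/2, \sqrt{RSS + \delta_\sigma^2}, \gamma_\sigma)},
#' each \eqn{\tau_s^2} from
#' GIG\eqn{(\lambda_{\tau,s} - m_s/2, \sqrt{u_s^Tu_s + \delta_{\tau,s}^2}, \gamma_{\tau,s})},
#' and \eqn{u}, \eqn{\beta} from their Gaussian full conditionals.  The sweep
#' order is \eqn{\sigma^2 \to \tau^2 \to u \to \beta} (any fixed order is a
#' valid Gibbs scheme).  Inverse-gamma priors are the \eqn{\gamma = 0} boundary
#' of the same code path.  Chains are bitwise reproducible given `seed`.
#'
#' @param design a [mixed_design()].
#' @param priors a `gig_priors` object ([elicit_priors()] or [prior_spec()]).
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations (`n_iter > burn_in >= 0`).
#' @param seed integer seed (optional but recommended).
#' @param chains number of independent chains; per-chain seeds are derived
#'   deterministically from `seed`.
#' @param init optional named list overriding the default initial state
#'   (`beta` at OLS, `u = 0`, `sigma2` at the OLS residual variance,
#'   `tau2 = sigma2 / q`); elements `beta`, `u`, `sigma2`, `tau2`.
#' @param fix_variances if `TRUE`, \eqn{\sigma^2} and \eqn{\tau^2} stay clamped
#'   at their initial values (used to cross-check the closed-form conditional
#'   posterior of \eqn{\beta}).
#' @param overdispersed if `TRUE`, scatter the initial state (for convergence
#'   diagnostics with multiple chains).
#' @return An object of class `lnmm_draws`: list with matrices `beta`
#'   (draws x p), `u` (draws x m), `tau2` (draws x q), vector `sigma2`,
#'   integer vector `chain`, and `meta` (seed, n_iter, burn_in, chains).
#' @export
run_gibbs <- function(design, priors, n_iter = 5000, burn_in = 1000,
                      seed = NULL, chains = 1L, init = NULL,
                      fix_variances = FALSE, overdispersed = FALSE) {
  stopifnot(inherits(design, "mixed_design"), inherits(priors, "gig_priors"))
  if (!(n_iter > burn_in && burn_in >= 0))
    abort("need n_iter > burn_in >= 0", class = "gigmm_usage_error")
  if (length(priors$tau2) == 1L && design$q > 1L)
    priors$tau2 <- rep(priors$tau2, design$q)
  if (length(priors$tau2) != design$q)
    abort("one tau2 prior per random factor is required", class = "gigmm_config_error")
  X <- design$X; Z <- design$Z; w <- design$w

  beta0 <- drop(solve(crossprod(X), crossprod(X, w)))
  res0 <- w - X %*% beta0
  sig0 <- max(drop(crossprod(res0)) / max(design$n - design$p, 1), 1e-8)
  state <- list(beta = beta0, u = rep(0, design$m), sigma2 = sig0,
                tau2 = rep(sig0 / design$q, design$q))
  if (!is.null(init)) state[names(init)] <- init

  lam_t <- vapply(priors$tau2, `[[`, numeric(1), "lambda")
  del_t <- vapply(priors$tau2, `[[`, numeric(1), "delta")
  gam_t <- vapply(priors$tau2, `[[`, numeric(1), "gamma")

  run_one <- function(chain_seed, jitter) {
    with_seed(chain_seed, {
      st <- state
      if (jitter) {
        st$beta <- st$beta + rnorm(design$p, 0, 2 * sqrt(st$sigma2))
        st$sigma2 <- st$sigma2 * exp(rnorm(1, 0, 1))
        st$tau2 <- st$tau2 * exp(rnorm(design$q, 0, 1))
      }
      gibbs_lmm_cpp(w, X, Z, design$m_s,
                    priors$sigma2$lambda, priors$sigma2$delta, priors$sigma2$gamma,
                    lam_t, del_t, gam_t,
                    as.integer(n_iter), as.integer(burn_in),
                    st$beta, st$u, st$sigma2, st$tau2,
                    isTRUE(fix_variances))
    })
  }

  seeds <- if (is.null(seed)) rep(list(NULL), chains)
           else lapply(seq_len(chains), function(i)
                       if (chains == 1L) seed else derive_seed(seed, i))
  res <- lapply(seq_len(chains), function(i)
                run_one(seeds[[i]], overdispersed && i > 1L))

  keep <- n_iter - burn_in
  out <- list(
    beta = do.call(rbind, lapply(res, `[[`, "beta")),
    u = do.call(rbind, lapply(res, `[[`, "u")),
    sigma2 = unlist(lapply(res, `[[`, "sigma2")),
    tau2 = do.call(rbind, lapply(res, `[[`, "tau2")),
    chain = rep(seq_len(chains), each = keep),
    meta = list(seed = seed, n_iter = n_iter, burn_in = burn_in,
                chains = chains, fix_variances = isTRUE(fix_variances)))
  colnames(out$beta) <- colnames(design$X)
  colnames(out$u) <- colnames(design$Z)
  colnames(out$tau2) <- names(design$Z_blocks)
  class(out) <- "lnmm_draws"
  out
}

#' @export
print.lnmm_draws <- function(x, ...) {
  cat(sprintf("posterior draws: %d retained (%d chain%s, %d iterations, %d burn-in)\n",
              length(x$sigma2), x$meta$chains, if (x$meta$chains > 1) "s" else "",
              x$meta$n_iter, x$meta$burn_in))
  invisible(x)
}

#' Fit a Bayesian log-normal mixed model
#'
#' One-call interface: builds the design from a data frame, elicits the
#' default weakly informative GIG priors (unless explicit priors are given),
#' and runs the Gibbs sampler.
#'
#' @inheritParams mixed_design
#' @inheritParams run_gibbs
#' @param priors optional `gig_priors`; by default elicited via
#'   [elicit_priors()] with the settings below.
#' @param r,c,epsilon,targets elicitation settings passed to [elicit_priors()].
#' @return An object of class `lnmm_fit`: list with `design`, `priors`,
#'   `draws` (an `lnmm_draws`), and `response`.
#' @examples
#' d <- simulate_scenario_data(scenario_config(n_g = 5, m = 10, phi = 1,
#'                                             sigma2 = 0.25, seed = 7), 1)
#' fit <- fit_lnmm(d, "y", groups = "group", n_iter = 600, burn_in = 100, seed = 1)
#' tidy(fit)
#' @export
fit_lnmm <- function(data, response, fixed = character(), groups,
                     intercept = TRUE, priors = NULL,
                     r = 2, c = 1, epsilon = 0.01, targets = "marginal",
                     n_iter = 5000, burn_in = 1000, seed = NULL, chains = 1L,
                     ...) {
  design <- mixed_design(data, response, fixed, groups, intercept)
  if (is.null(priors))
    priors <- elicit_priors(design, r = r, c = c, epsilon = epsilon,
                            targets = targets)
  draws <- run_gibbs(design, priors, n_iter = n_iter, burn_in = burn_in,
                     seed = seed, chains = chains, ...)
  structure(list(design = design, priors = priors, draws = draws,
                 response = response), class = "lnmm_fit")
}

#' @export
print.lnmm_fit <- function(x, ...) {
  print(x$design)
  print(x$draws)
  invisible(x)
}

draw_matrix <- function(draws, include_u = TRUE) {
  stopifnot(inherits(draws, "lnmm_draws"))
  tau2 <- draws$tau2
  colnames(tau2) <- paste0("tau2_", colnames(draws$tau2))
  parts <- list(draws$beta,
                matrix(draws$sigma2, ncol = 1,
                       dimnames = list(NULL, "sigma2")),
                tau2)
  if (include_u) {
    u <- draws$u
    colnames(u) <- paste0("u[", colnames(draws$u), "]")
    parts <- c(parts, list(u))
  }
  do.call(cbind, parts)
}

ess_one <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  lag_max <- min(n - 2L, 2000L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE)$acf)
  # Geyer initial positive sequence on pair sums rho_{2k} + rho_{2k+1}
  k <- floor((length(rho) - 1) / 2)
  if (k < 1) return(n)
  pair <- rho[2 * seq_len(k) - 1] + rho[2 * seq_len(k)]
  cut <- which(pair <= 0)[1]
  if (is.na(cut)) cut <- k + 1L
  tau <- -1 + 2 * sum(pair[seq_len(cut - 1)])
  min(n, n / max(tau, 1e-8))
}

rhat_split <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(ch) {
    h <- length(ch) %/% 2
    list(ch[seq_len(h)], ch[h + seq_len(h)])
  }), recursive = FALSE)
  nc <- length(halves); nn <- length(halves[[1]])
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, var, numeric(1))
  W <- mean(vrs)
  B <- nn * var(mns)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' MCMC convergence diagnostics
#'
#' Effective sample size (initial-positive-sequence autocorrelation
#' truncation) and split-chain potential scale reduction factor for every
#' model parameter.
#'
#' @param draws an `lnmm_draws` or `lnmm_fit`.
#' @param include_u include the individual random effects.
#' @param psrf_warn threshold above which a parameter is flagged.
#' @return A tibble with columns `parameter`, `ess`, `psrf`, `flagged`.
#' @export
mcmc_diagnostics <- function(draws, include_u = FALSE, psrf_warn = 1.01) {
  if (inherits(draws, "lnmm_fit")) draws <- draws$draws
  M <- draw_matrix(draws, include_u = include_u)
  if (nrow(M) < 100)
    abort("at least 100 retained draws are required for diagnostics",
          class = "gigmm_usage_error")
  tibble(
    parameter = colnames(M),
    ess = apply(M, 2, ess_one),
    psrf = apply(M, 2, rhat_split, chain = draws$chain)
  ) |>
    dplyr::mutate(flagged = .data$psrf > psrf_warn)
}

#' @export
tidy.lnmm_fit <- function(x, level = 0.95, include_u = FALSE, ...) {
  M <- draw_matrix(x$draws, include_u = include_u)
  a <- (1 - level) / 2
  tibble(
    term = colnames(M),
    estimate = colMeans(M),
    std.error = apply(M, 2, sd),
    conf.low = apply(M, 2, quantile, probs = a),
    conf.high = apply(M, 2, quantile, probs = 1 - a)
  )
}

#' @export
glance.lnmm_fit <- function(x, ...) {
  dg <- mcmc_diagnostics(x$draws)
  tibble(n = x$design$n, p = x$design$p, q = x$design$q,
         m = x$design$m, rank_deficiency = x$design$l,
         n_draws = length(x$draws$sigma2), chains = x$draws$meta$chains,
         min_ess = min(dg$ess), max_psrf = max(dg$psrf))
}

#' @export
autoplot.lnmm_fit <- function(object, parameters = NULL, ...) {
  M <- draw_matrix(object$draws, include_u = FALSE)
  df <- as_tibble(M) |>
    dplyr::mutate(.iteration = dplyr::row_number(),
                  .chain = factor(object$draws$chain)) |>
    tidyr::pivot_longer(cols = -c(".iteration", ".chain"),
                        names_to = "parameter", values_to = "value")
  if (!is.null(parameters)) df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.iteration, y = .data$value,
                                   colour = .data$.chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
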