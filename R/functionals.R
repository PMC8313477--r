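new_functional <- function(values, kind, point) {
  if (any(!is.finite(values) | values <= 0))
    abort("functional draws must be strictly positive and finite",
          class = "gigmm_numerical_error")
  structure(tibble(draw = seq_along(values), value = values),
            kind = kind, point = point,
            class = c("lnmm_functional", class(tibble())))
}

get_draws <- function(x) if (inherits(x, "lnmm_fit")) x$draws else x

#' Posterior draws of the marginal expectation on the data scale
#'
#' For each retained draw, evaluates
#' \eqn{\theta_m(\tilde x) = \exp\{\tilde x^T\beta + (\sigma^2 + \sum_s \tau_s^2)/2\}},
#' the expectation of the positive response at covariate point \eqn{\tilde x}
#' with every random effect integrated out.
#'
#' @param fit an `lnmm_fit` or `lnmm_draws`.
#' @param x_point fixed-effect covariate point (length p, original column
#'   order); defaults to the intercept-only point.
#' @return An `lnmm_functional`: tibble of positive draws with columns `draw`,
#'   `value`.
#' @export
theta_m_draws <- function(fit, x_point = NULL) {
  draws <- get_draws(fit)
  p <- ncol(draws$beta)
  if (is.null(x_point)) x_point <- c(1, rep(0, p - 1))
  if (length(x_point) != p)
    abort(sprintf("x_point must have length %d", p), class = "gigmm_dimension_error")
  lin <- drop(draws$beta %*% x_point)
  vals <- exp(lin + 0.5 * (draws$sigma2 + rowSums(draws$tau2)))
  new_functional(vals, "theta_m", list(x = x_point))
}

#' Posterior draws of group-conditional expectations
#'
#' For each retained draw, evaluates
#' \eqn{\theta_c(\tilde x, \tilde z) = \exp\{\tilde x^T\beta + \tilde z^Tu + \sigma^2/2\}},
#' the expectation conditional on the random effects selected by
#' \eqn{\tilde z}.  Partial conditioning is supported: factors not named in
#' `condition_on` are integrated out and contribute \eqn{\tau_s^2/2} to the
#' exponent instead of their \eqn{\tilde z^Tu_s} term.  Conditioning on no
#' factor reproduces [theta_m_draws()].
#'
#' @inheritParams theta_m_draws
#' @param z_point numeric selector of length m over the stacked random
#'   effects (original block order), or a named character/numeric vector
#'   `c(factor = level)` selecting one level per conditioned factor.
#' @param condition_on names of the factors conditioned on; defaults to the
#'   factors with a nonzero entry in `z_point` (all factors named by a level
#'   selector).
#' @return An `lnmm_functional`.
#' @export
theta_c_draws <- function(fit, x_point = NULL, z_point = NULL,
                          condition_on = NULL) {
  draws <- get_draws(fit)
  p <- ncol(draws$beta); m <- ncol(draws$u)
  q <- ncol(draws$tau2)
  factors <- colnames(draws$tau2)
  block_cols <- lapply(factors, function(f)
    which(sub(":.*$", "", colnames(draws$u)) == f))
  names(block_cols) <- factors
  if (is.null(x_point)) x_point <- c(1, rep(0, p - 1))
  if (length(x_point) != p)
    abort(sprintf("x_point must have length %d", p), class = "gigmm_dimension_error")

  is_selector <- !is.null(z_point) && !is.null(names(z_point)) &&
    (is.character(z_point) || length(z_point) != m)
  if (is_selector) {
    # level selector: c(group = "3") picks the u column "group:3"
    z <- rep(0, m)
    for (f in names(z_point)) {
      col <- paste(f, z_point[[f]], sep = ":")
      j <- match(col, colnames(draws$u))
      if (is.na(j))
        abort(sprintf("unknown random-effect level '%s'", col),
              class = "gigmm_config_error")
      z[j] <- 1
    }
    if (is.null(condition_on)) condition_on <- names(z_point)
    z_point <- z
  }
  if (is.null(z_point)) z_point <- rep(0, m)
  if (length(z_point) != m)
    abort(sprintf("z_point must have length %d", m), class = "gigmm_dimension_error")
  if (is.null(condition_on))
    condition_on <- factors[vapply(block_cols, function(j)
      any(z_point[j] != 0), logical(1))]
  if (!all(condition_on %in% factors))
    abort("condition_on names unknown factors", class = "gigmm_config_error")

  lin <- drop(draws$beta %*% x_point) + 0.5 * draws$sigma2
  for (f in factors) {
    if (f %in% condition_on) {
      j <- block_cols[[f]]
      lin <- lin + drop(draws$u[, j, drop = FALSE] %*% as.numeric(z_point[j]))
    } else {
      lin <- lin + 0.5 * as.numeric(draws$tau2[, f])
    }
  }
  new_functional(exp(lin), "theta_c",
                 list(x = x_point, z = z_point, condition_on = condition_on))
}

#' Posterior predictive draws on the data scale
#'
#' Composition sampling of \eqn{\tilde y = \exp\{\tilde x^T\beta + \tilde z^Tu^*
#' + \sigma\varepsilon^*\}}, \eqn{\varepsilon^* \sim N(0,1)}, one predictive
#' draw per retained posterior draw.  In `"observed-group"` mode \eqn{u^*} is
#' the sampled random effect selected by `z_point`; in `"new-group"` mode a
#' fresh \eqn{N(0, \tau_s^2)} effect is drawn per factor and draw.
#'
#' @inheritParams theta_c_draws
#' @param mode `"new-group"` or `"observed-group"`.
#' @param seed optional seed for the predictive noise.
#' @return An `lnmm_functional`.
#' @export
predictive_draws <- function(fit, x_point = NULL, z_point = NULL,
                             mode = c("new-group", "observed-group"),
                             seed = NULL) {
  mode <- match.arg(mode)
  draws <- get_draws(fit)
  p <- ncol(draws$beta)
  if (is.null(x_point)) x_point <- c(1, rep(0, p - 1))
  B <- length(draws$sigma2)
  with_seed(seed, {
    lin <- drop(draws$beta %*% x_point)
    if (mode == "observed-group") {
      tc <- theta_c_draws(fit, x_point, z_point,
                          condition_on = colnames(draws$tau2))
      lin <- log(tc$value) - 0.5 * draws$sigma2
    } else {
      for (f in colnames(draws$tau2))
        lin <- lin + rnorm(B, 0, sqrt(draws$tau2[, f]))
    }
    vals <- exp(lin + sqrt(draws$sigma2) * rnorm(B))
    new_functional(vals, "predictive", list(x = x_point, mode = mode))
  })
}

#' Summarise functional draws
#'
#' Posterior mean (the default point estimate), standard deviation, median,
#' and the equal-tailed credible interval.
#'
#' @param fdraws an `lnmm_functional`.
#' @param level interval level (default 0.95, i.e. the 0.025 and 0.975
#'   posterior quantiles).
#' @return One-row tibble with `kind`, `mean`, `sd`, `median`, `lower`,
#'   `upper`, `level`.
#' @export
summarize_functional <- function(fdraws, level = 0.95) {
  stopifnot(inherits(fdraws, "lnmm_functional"), nrow(fdraws) > 0)
  a <- (1 - level) / 2
  qs <- quantile(fdraws$value, c(a, 1 - a), names = FALSE)
  tibble(kind = attr(fdraws, "kind"),
         mean = mean(fdraws$value), sd = sd(fdraws$value),
         median = stats::median(fdraws$value),
         lower = qs[1], upper = qs[2], level = level)
}

#' @export
tidy.lnmm_functional <- function(x, level = 0.95, ...) summarize_functional(x, level)

#' @export
autoplot.lnmm_functional <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(x = attr(object, "kind"), y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Closed-form conditional benchmark estimators
#'
#' Minimum-MSE style benchmark predictors for the balanced one-way layout with
#' the variance components treated as known: the marginal-expectation
#' predictor
#' \deqn{\hat\theta_m^c = \exp\{\bar w + (\sigma^2+\tau^2)/2 - 3(\sigma^2 + n_g\tau^2)/(2n)\}}
#' (minimum frequentist MSE in the class \eqn{k\exp\{\bar w\}}) and the
#' group-expectation predictor derived as the Bayes estimator under relative
#' quadratic loss,
#' \deqn{\hat\theta_c^c(v_j) = \exp\{\tfrac{\sigma^2}{\sigma^2+n_g\tau^2}
#'   (\tfrac{\tau^2 n_g}{\sigma^2}\bar w_{.j} - \bar w) + \tfrac{\sigma^2}{2}
#'   - \tfrac{3}{2}\tfrac{\sigma^2}{\sigma^2+n_g\tau^2}(\tau^2 + \tfrac{\sigma^2}{n})\}.}
#'
#' @param w vector of log responses.
#' @param group group labels aligned with `w`; the design must be balanced.
#' @param sigma2,tau2 known variance components.
#' @return A tibble with columns `estimator` (`"theta_m"` / `"theta_c"`),
#'   `group` (`NA` for the marginal row), `value`.
#' @export
benchmark_estimators <- function(w, group, sigma2, tau2) {
  group <- factor(group, levels = unique(as.character(group)))
  counts <- table(group)
  if (length(unique(as.integer(counts))) != 1L)
    abort("benchmark estimators require a balanced one-way layout",
          class = "gigmm_unsupported_design_error")
  n_g <- as.integer(counts[1]); m <- length(counts); n <- n_g * m
  wbar <- mean(w)
  wbar_j <- tapply(w, group, mean)
  th_m <- exp(wbar + (sigma2 + tau2) / 2 - 3 * (sigma2 + n_g * tau2) / (2 * n))
  shr <- sigma2 / (sigma2 + n_g * tau2)
  th_c <- exp(shr * ((tau2 * n_g / sigma2) * wbar_j - wbar) + sigma2 / 2 -
                1.5 * shr * (tau2 + sigma2 / n))
  dplyr::bind_rows(
    tibble(estimator = "theta_m", group = NA_character_, value = th_m),
    tibble(estimator = "theta_c", group = names(wbar_j), value = as.numeric(th_c)))
}
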