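#' Generalized inverse Gaussian parameter triple
#'
#' Validates and stores the parameters \eqn{(\lambda, \delta, \gamma)} of the
#' generalized inverse Gaussian (GIG) distribution with density proportional to
#' \eqn{v^{\lambda-1} \exp\{-(\delta^2 v^{-1} + \gamma^2 v)/2\}} on \eqn{v > 0}.
#' The boundary \eqn{\delta = 0} (with \eqn{\lambda > 0}, \eqn{\gamma > 0}) is
#' the Gamma\eqn{(\lambda, \gamma^2/2)} distribution; \eqn{\gamma = 0} (with
#' \eqn{\lambda < 0}, \eqn{\delta > 0}) is the inverse gamma
#' IG\eqn{(-\lambda, \delta^2/2)}; \eqn{\lambda = -1/2} gives the inverse
#' Gaussian.  Boundaries are expressed by literal zeros, never by a small
#' epsilon.
#'
#' @param lambda real shape parameter \eqn{\lambda}.
#' @param delta  small-values parameter \eqn{\delta \ge 0}.
#' @param gamma  tail parameter \eqn{\gamma \ge 0}.
#'
#' @return An object of class `gig_params`: a named list with elements
#'   `lambda`, `delta`, `gamma`.
#'
#' @examples
#' gig_params(1, 0.01, sqrt(3.9))   # default weakly informative variance prior
#' gig_params(-1, sqrt(2), 0)       # the IG(1, 1) boundary
#' @export
gig_params <- function(lambda, delta, gamma) {
  stopifnot(is.numeric(lambda), is.numeric(delta), is.numeric(gamma),
            length(lambda) == 1L, length(delta) == 1L, length(gamma) == 1L)
  if (!all(is.finite(c(lambda, delta, gamma))))
    abort("GIG parameters must be finite", class = "gigmm_parameter_error")
  if (delta < 0 || gamma < 0)
    abort("delta and gamma must be non-negative", class = "gigmm_parameter_error")
  ok <- if (delta > 0) {
    (lambda < 0 && gamma >= 0) || (lambda == 0 && gamma > 0) ||
      (lambda > 0 && gamma > 0)
  } else {
    lambda > 0 && gamma > 0
  }
  if (!ok)
    abort(
      sprintf("invalid GIG parameter combination (lambda = %g, delta = %g, gamma = %g)",
              lambda, delta, gamma),
      class = "gigmm_parameter_error")
  structure(list(lambda = lambda, delta = delta, gamma = gamma),
            class = "gig_params")
}

#' @export
print.gig_params <- function(x, ...) {
  kind <- if (x$delta == 0) "Gamma boundary"
    else if (x$gamma == 0) "inverse-gamma boundary"
    else "interior"
  cat(sprintf("GIG(lambda = %g, delta = %g, gamma = %g)  [%s]\n",
              x$lambda, x$delta, x$gamma, kind))
  invisible(x)
}

as_gig_params <- function(x) {
  if (inherits(x, "gig_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(gig_params(x[1], x[2], x[3]))
  abort("expected a gig_params object or a numeric triple",
        class = "gigmm_parameter_error")
}

# log K_nu(x) for real nu, x > 0, stable for large order and argument.
# besselK overflows (even exponentially scaled) for large |nu|; the uniform
# asymptotic (Debye) expansion takes over there.
lbesselK <- function(nu, x) {
  nu <- abs(nu)  # K_{-nu} = K_nu
  b <- suppressWarnings(besselK(x, nu, expon.scaled = TRUE))
  out <- ifelse(is.finite(b) & b > 0, log(b) - x, NA_real_)
  bad <- which(is.na(out))
  if (length(bad)) {
    nu_b <- rep_len(nu, length(out))[bad]
    x_b <- rep_len(x, length(out))[bad]
    z <- x_b / nu_b
    s <- sqrt(1 + z^2)
    eta <- s + log(z / (1 + s))
    out[bad] <- 0.5 * log(pi / (2 * nu_b)) - nu_b * eta - 0.25 * log1p(z^2)
  }
  out
}

#' GIG log-density
#'
#' Density of the generalized inverse Gaussian distribution, evaluated in log
#' space with exponentially scaled Bessel functions.  The Gamma
#' (\eqn{\delta = 0}) and inverse-gamma (\eqn{\gamma = 0}) boundaries return
#' the exact limiting densities.
#'
#' @param v vector of positive evaluation points.
#' @param params a [gig_params()] object (or numeric triple).
#' @param log if `TRUE` (default for `gig_logpdf`) return the log-density.
#'
#' @return Numeric vector of (log-)density values.
#' @examples
#' gig_logpdf(1, gig_params(1, 0, sqrt(2)))   # Exponential(1) at 1: -1
#' @export
gig_logpdf <- function(v, params) dgig(v, params, log = TRUE)

#' @rdname gig_logpdf
#' @export
dgig <- function(v, params, log = FALSE) {
  p <- as_gig_params(params)
  if (any(!is.finite(v) | v <= 0))
    abort("GIG density requires strictly positive v", class = "gigmm_domain_error")
  ld <- if (p$delta == 0) {
    dgamma(v, shape = p$lambda, rate = p$gamma^2 / 2, log = TRUE)
  } else if (p$gamma == 0) {
    a <- -p$lambda; b <- p$delta^2 / 2
    a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
  } else {
    p$lambda * log(p$gamma / p$delta) - log(2) -
      lbesselK(p$lambda, p$delta * p$gamma) +
      (p$lambda - 1) * log(v) - 0.5 * (p$delta^2 / v + p$gamma^2 * v)
  }
  if (log) ld else exp(ld)
}

#' GIG moments
#'
#' Fractional moment \eqn{E[V^r]} of the GIG distribution, using
#' \eqn{E[V^r] = (\delta/\gamma)^r K_{\lambda+r}(\delta\gamma) / K_\lambda(\delta\gamma)}
#' in the interior and the Gamma / inverse-gamma moment formulas on the
#' boundaries.  Returns `Inf` when the moment does not exist (for example the
#' variance of an IG(1, 1) variable) rather than a spurious finite number.
#'
#' @param r moment order (any real).
#' @inheritParams gig_logpdf
#' @return The moment, or `Inf` if it is not finite.
#' @examples
#' gig_moment(1, gig_params(1, 0, sqrt(2)))     # Exponential(1) mean: 1
#' gig_moment(2, gig_params(-1, sqrt(2), 0))    # IG(1,1) second moment: Inf
#' @export
gig_moment <- function(r, params) {
  p <- as_gig_params(params)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (p$delta == 0) {
    if (p$lambda + r <= 0) return(Inf)
    return(exp(lgamma(p$lambda + r) - lgamma(p$lambda) - r * log(p$gamma^2 / 2)))
  }
  if (p$gamma == 0) {
    if (r >= -p$lambda) return(Inf)
    return(exp(r * log(p$delta^2 / 2) + lgamma(-p$lambda - r) - lgamma(-p$lambda)))
  }
  exp(r * log(p$delta / p$gamma) +
        lbesselK(p$lambda + r, p$delta * p$gamma) -
        lbesselK(p$lambda, p$delta * p$gamma))
}

#' GIG random variates
#'
#' Draws i.i.d. GIG variates via a three-region rejection sampler
#' (mode-shifted ratio-of-uniforms for concentrated shapes, plain
#' ratio-of-uniforms in the central region, and a two-piece hat for
#' \eqn{0 < \lambda < 1} with small \eqn{\delta\gamma}); negative \eqn{\lambda}
#' is handled through the duality \eqn{1/V \sim GIG(-\lambda, \gamma, \delta)},
#' and the \eqn{\delta = 0} / \eqn{\gamma = 0} boundaries dispatch to Gamma and
#' inverse-gamma generators.  Draws consume R's RNG stream.
#'
#' @param n number of draws.
#' @inheritParams gig_logpdf
#' @param seed optional integer; if supplied, draws are generated under this
#'   seed and the caller's RNG state is restored afterwards.
#' @return Numeric vector of `n` positive draws.
#' @examples
#' mean(rgig(1e4, gig_params(1, 0, sqrt(2)), seed = 1))   # about 1
#' @export
rgig <- function(n, params, seed = NULL) {
  p <- as_gig_params(params)
  stopifnot(length(n) == 1L, n >= 1)
  with_seed(seed, rgig_cpp(as.integer(n), p$lambda, p$delta, p$gamma))
}
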