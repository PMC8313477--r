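#' Build the mixed-model design from a data frame
#'
#' Constructs the design objects of the log-normal linear mixed model
#' \eqn{w = X\beta + Zu + \varepsilon}, \eqn{w = \log y}, from a tabular
#' dataset: the fixed-effect matrix `X` (intercept plus the named covariate
#' columns), and one 0/1 incidence block `Z_s` per grouping factor, with levels
#' ordered by first appearance.  All design-derived quantities entering the
#' posterior-moment existence conditions are computed: the projector `P_Z` on
#' the random-effect span, the rank deficiency `l` of \eqn{X^T(I - P_Z)X}, the
#' column reordering placing the `l` fixed-effect columns lying in the span of
#' `Z` first, and the `L_s` matrices whose leading \eqn{l \times l} block is
#' the inverse of the corresponding block of
#' \eqn{X_o^T Z (Z^TZ)^- C_s (Z^TZ)^- Z^T X_o}.
#'
#' @param data a data frame with the response, covariates and grouping columns.
#' @param response name of the strictly positive response column `y`.
#' @param fixed character vector of fixed-effect covariate column names
#'   (possibly empty: intercept-only model).
#' @param groups character vector of grouping-factor column names (one random
#'   intercept block per factor).
#' @param intercept include a fixed intercept column (default `TRUE`).
#' @return A `mixed_design` object; see [build_design()] for its fields.
#' @examples
#' d <- simulate_scenario_data(scenario_config(n_g = 2, m = 10, phi = 0.5,
#'                                             sigma2 = 0.25, seed = 1), 1)
#' mixed_design(d, response = "y", groups = "group")
#' @export
mixed_design <- function(data, response, fixed = character(), groups,
                         intercept = TRUE) {
  data <- validate_table(data, response)
  w <- log(data[[response]])
  n <- length(w)
  X <- matrix(numeric(0), n, 0)
  nms <- character(0)
  if (intercept) { X <- cbind(X, rep(1, n)); nms <- "(Intercept)" }
  for (f in fixed) {
    if (!f %in% names(data))
      abort(sprintf("fixed-effect column '%s' not found", f),
            class = "gigmm_config_error")
    X <- cbind(X, as.numeric(data[[f]]))
    nms <- c(nms, f)
  }
  colnames(X) <- nms
  if (length(groups) == 0L)
    abort("at least one grouping factor is required", class = "gigmm_config_error")
  Z_blocks <- list()
  for (g in groups) {
    if (!g %in% names(data))
      abort(sprintf("grouping column '%s' not found", g),
            class = "gigmm_config_error")
    fac <- factor(data[[g]], levels = unique(as.character(data[[g]])))
    Zs <- stats::model.matrix(~ fac - 1)
    colnames(Zs) <- paste(g, levels(fac), sep = ":")
    Z_blocks[[g]] <- Zs
  }
  build_design(w, X, Z_blocks)
}

#' Low-level design constructor
#'
#' @param w numeric vector of log responses.
#' @param X full-column-rank fixed-effect matrix (`n x p`).
#' @param Z_blocks list of `q` random-effect design blocks `Z_s` (`n x m_s`).
#' @return An object of class `mixed_design` with fields `w`, `X`, `Z`
#'   (column-bound blocks), `Z_blocks`, `m_s`, `q`, `P_Z`, `l`, `col_order`
#'   (permutation defining `X_o`), `X_o`, and `L_s` (list of `p x p` matrices).
#' @rdname mixed_design
#' @export
build_design <- function(w, X, Z_blocks) {
  X <- as.matrix(X)
  n <- length(w); p <- ncol(X)
  if (!all(is.finite(w)))
    abort("non-finite log-response", class = "gigmm_data_error")
  if (nrow(X) != n)
    abort("X and w dimensions do not conform", class = "gigmm_dimension_error")
  if (n < p + 1)
    abort("need n >= p + 1 observations", class = "gigmm_model_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  Z_blocks <- lapply(Z_blocks, as.matrix)
  q <- length(Z_blocks)
  if (q == 0L) abort("at least one random-effect block is required",
                     class = "gigmm_config_error")
  for (Zs in Z_blocks) {
    if (nrow(Zs) != n)
      abort("Z block and w dimensions do not conform", class = "gigmm_dimension_error")
    if (all(Zs == 0)) abort("all-zero Z block", class = "gigmm_model_error")
  }
  if (is.null(names(Z_blocks))) names(Z_blocks) <- paste0("g", seq_len(q))
  Z <- do.call(cbind, Z_blocks)
  m_s <- vapply(Z_blocks, ncol, integer(1))
  m <- sum(m_s)

  # numerical rank; `scale` anchors the tolerance, so that a matrix that is
  # zero up to rounding (X'(I-P_Z)X with X fully inside span(Z)) is not
  # mistaken for a full-rank one
  tol_rank <- function(M, scale = 0) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (!length(d)) return(0L)
    sum(d > max(dim(M)) * .Machine$double.eps * max(d[1], scale))
  }
  sX1 <- svd(X, nu = 0, nv = 0)$d[1]
  if (tol_rank(X) < p)
    abort("fixed-effect design X is rank deficient", class = "gigmm_model_error")

  ZtZ_pinv <- MASS::ginv(crossprod(Z))
  P_Z <- Z %*% ZtZ_pinv %*% t(Z)
  RX <- (diag(n) - P_Z) %*% X
  # l = p (every fixed-effect column in span(Z), e.g. the intercept-only
  # one-way layout) is legitimate: the zero-mean random-effect prior keeps
  # the conditional posterior of beta proper.  The rank deficiency of
  # X'(I-P_Z)X equals that of (I-P_Z)X; ranking the latter on the linear
  # scale uses the same 1e-8 relative-residual rule as the column-in-span
  # detection below and sits far above the projector's rounding noise.
  dR <- svd(RX, nu = 0, nv = 0)$d
  l <- p - sum(dR > 1e-8 * sX1)

  # columns of X lying in span(Z): relative residual norm under the projector
  res_norm <- sqrt(colSums(((diag(n) - P_Z) %*% X)^2)) / sqrt(colSums(X^2))
  in_span <- res_norm <= 1e-8
  if (sum(in_span) != l)
    abort(sprintf(
      "rank deficiency l = %d but %d individual columns of X lie in span(Z); shared directions must be whole columns",
      l, sum(in_span)), class = "gigmm_model_error")
  col_order <- unname(c(which(in_span), which(!in_span)))
  X_o <- X[, col_order, drop = FALSE]

  L_s <- vector("list", q)
  names(L_s) <- names(Z_blocks)
  if (l > 0) {
    offs <- cumsum(c(0, m_s))
    for (s in seq_len(q)) {
      Cs <- matrix(0, m, m)
      idx <- (offs[s] + 1):(offs[s] + m_s[s])
      Cs[cbind(idx, idx)] <- 1
      Ts <- crossprod(X_o, Z %*% ZtZ_pinv %*% Cs %*% ZtZ_pinv %*% t(Z) %*% X_o)
      Ls <- matrix(0, p, p)
      Ls[1:l, 1:l] <- solve(Ts[1:l, 1:l, drop = FALSE])
      L_s[[s]] <- Ls
    }
  } else {
    for (s in seq_len(q)) L_s[[s]] <- matrix(0, p, p)
  }

  structure(list(w = w, X = X, Z = Z, Z_blocks = Z_blocks, m_s = m_s, q = q,
                 n = n, p = p, m = m, P_Z = P_Z, l = l,
                 col_order = col_order, X_o = X_o, L_s = L_s),
            class = "mixed_design")
}

#' @export
print.mixed_design <- function(x, ...) {
  cat(sprintf("log-normal mixed-model design: n = %d, p = %d, %d random factor%s (m = %s), rank deficiency l = %d\n",
              x$n, x$p, x$q, if (x$q > 1) "s" else "",
              paste(x$m_s, collapse = "+"), x$l))
  invisible(x)
}

as_point_matrix <- function(points, p) {
  if (is.null(points) || length(points) == 0L)
    abort("points must be nonempty", class = "gigmm_usage_error")
  if (is.numeric(points) && is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  if (ncol(points) != p)
    abort(sprintf("prediction points must have %d columns", p),
          class = "gigmm_dimension_error")
  points
}

#' Maximum leverage over a set of prediction points
#'
#' Computes \eqn{h_m = \max_i \tilde{x}_i^T (X^TX)^{-1} \tilde{x}_i}, the
#' design leverage entering the residual-variance existence threshold, together
#' with the analogous per-factor quantities
#' \eqn{l_{m,s} = \max_i \tilde{x}_{o,i}^T L_s \tilde{x}_{o,i}} for the
#' random-effect variances.  Points are given in the original column order of
#' `X`; the recorded reordering to `X_o` is applied internally.
#'
#' @param design a `mixed_design`.
#' @param points matrix (rows are points) or single p-vector; defaults to the
#'   observed design rows.
#' @return A list with `h` (scalar) and `l` (named numeric of length `q`).
#' @export
design_leverage <- function(design, points = NULL) {
  if (is.null(points)) points <- design$X
  pts <- as_point_matrix(points, design$p)
  XtX_inv <- solve(crossprod(design$X))
  h <- max(rowSums((pts %*% XtX_inv) * pts))
  pts_o <- pts[, design$col_order, drop = FALSE]
  lm <- vapply(design$L_s,
               function(L) max(rowSums((pts_o %*% L) * pts_o)),
               numeric(1))
  list(h = h, l = lm)
}

#' @rdname design_leverage
#' @export
max_leverage <- function(design, points = NULL) design_leverage(design, points)$h

#' Conditional posterior of the fixed effects given the variance components
#'
#' Closed-form Gaussian posterior \eqn{\beta | \sigma^2, \tau^2, w} under the
#' flat improper prior on \eqn{\beta}: mean \eqn{\bar\beta} and covariance
#' \eqn{V_\beta} built from the projector on the random-effect span, with the
#' GLS-type intermediates returned for inspection.
#'
#' @param design a `mixed_design`.
#' @param sigma2 residual variance (> 0).
#' @param tau2 vector of `q` random-effect variances (> 0).
#' @return A list with `mean`, `cov`, and intermediates `M`, `V_Z_inv`,
#'   `beta_ols`, `beta_gls`.
#' @export
beta_conditional_posterior <- function(design, sigma2, tau2) {
  stopifnot(sigma2 > 0, length(tau2) == design$q, all(tau2 > 0))
  X <- design$X; Z <- design$Z; w <- design$w; n <- design$n
  Dinv <- diag(rep(1 / tau2, design$m_s), design$m)
  # Woodbury form of the marginal precision (sigma2 I + Z D Z')^{-1}:
  # I/sigma2 + M with M = -Z (Z'Z + sigma2 D^{-1})^{-1} Z' / sigma2.
  # Exact for any Z, including rank-deficient crossed designs, where the
  # pseudo-inverse shortcut through (Z'Z)^- misstates the shared direction.
  V_Z_inv <- design$P_Z - Z %*% solve(crossprod(Z) + sigma2 * Dinv, t(Z))
  M <- (V_Z_inv - design$P_Z) / sigma2
  XtX <- crossprod(X)
  A <- XtX / sigma2 + crossprod(X, M %*% X)
  kappa <- kappa(A, exact = FALSE)
  if (!all(is.finite(A)) || kappa > 1e12)
    abort(sprintf("ill-conditioned posterior precision (condition number %.3g)", kappa),
          class = "gigmm_numerical_error")
  V_beta <- solve(A)
  V_beta <- (V_beta + t(V_beta)) / 2
  beta_ols <- solve(XtX, crossprod(X, w))
  XtMw <- crossprod(X, M %*% w)
  XtMX <- crossprod(X, M %*% X)
  beta_gls <- tryCatch(drop(solve(XtMX, XtMw)),
                       error = function(e) drop(MASS::ginv(XtMX) %*% XtMw))
  mean <- drop(V_beta %*% (XtX %*% beta_ols / sigma2 + XtMw))
  list(mean = mean, cov = V_beta, M = M, V_Z_inv = V_Z_inv,
       beta_ols = drop(beta_ols), beta_gls = beta_gls)
}
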