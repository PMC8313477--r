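---
title: "GIG priors for log-normal mixed models: model, elicitation, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GIG priors for log-normal mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gigmm)
```

## The model and why the prior matters

`gigmm` fits the hierarchical model

$$
\mathbf w \mid \mathbf u, \beta, \sigma^2 \sim
  \mathcal N_n(\mathbf X\beta + \mathbf Z\mathbf u,\ \sigma^2 \mathbf I),
\qquad
\mathbf u_s \mid \tau^2_s \sim \mathcal N_{m_s}(\mathbf 0,\ \tau^2_s\mathbf I),
\qquad
\mathbf w = \log \mathbf y,
$$

with a flat improper prior on the fixed effects $\beta$ and generalized
inverse Gaussian (GIG) priors on every variance component.  The GIG density
with parameters $(\lambda, \delta, \gamma)$ is

$$
p(v) = \Big(\frac{\gamma}{\delta}\Big)^{\lambda}
       \frac{1}{2K_\lambda(\delta\gamma)}\,
       v^{\lambda-1}
       \exp\!\Big\{-\tfrac12\big(\delta^2 v^{-1} + \gamma^2 v\big)\Big\},
       \qquad v > 0,
$$

which contains the Gamma$(\lambda, \gamma^2/2)$ ($\delta \to 0$), the inverse
gamma IG$(-\lambda, \delta^2/2)$ ($\gamma \to 0$, $\lambda < 0$) and the
inverse Gaussian ($\lambda = -1/2$) as boundary cases.  In the package these
boundaries are expressed by *literal zeros* in `gig_params()` and dispatch to
the exact limiting densities and generators — no silent epsilon stands in for
a limit.

Scientific interest is usually on the original scale of $y$: the marginal
expectation $\theta_m(\tilde{\mathbf x}) = \exp\{\tilde{\mathbf x}^\top\beta +
(\sigma^2 + \sum_s \tau^2_s)/2\}$, group-conditional expectations
$\theta_c(\tilde{\mathbf x}, \tilde{\mathbf z}) = \exp\{\tilde{\mathbf
x}^\top\beta + \tilde{\mathbf z}^\top\mathbf u + \sigma^2/2\}$, and posterior
predictive draws of $y$ itself.  These are exponential functions of the
variance components, so the existence of their posterior moments is governed
by the *tail* of the variance priors.  A prior without a
$\exp\{-\gamma^2 v\}$ factor (inverse gamma, half-$t$, uniform) yields
posterior distributions for $\theta_m$, $\theta_c$ and $\tilde y$ with **no
finite moments**: posterior means and standard deviations computed from MCMC
output estimate divergent integrals.  The GIG tail parameter $\gamma$ makes
the required exponential decay explicit and tunable.

## Existence thresholds and the default elicitation

For a requested moment order $r > 0$ the thresholds implemented in
`existence_threshold()` are, with $h = \tilde{\mathbf x}^\top(\mathbf
X^\top\mathbf X)^{-1}\tilde{\mathbf x}$ the leverage of the prediction point:

| target | condition |
|---|---|
| $\theta_c$ | $\gamma_\sigma^2 > r + r^2 h$ |
| $\theta_m$ | additionally $\gamma_{\tau,s}^2 > r + r^2\, \tilde{\mathbf x}_o^\top \mathbf L_s \tilde{\mathbf x}_o$ for every factor $s$ |
| predictive | $\gamma_\sigma^2 > r^2 + r^2 h$ |

$\mathbf L_s$ is a design quantity tied to the rank deficiency
$l = p - \operatorname{rank}\{\mathbf X^\top(\mathbf I - \mathbf P_Z)\mathbf
X\}$: its only nonzero block is the inverse of the leading $l \times l$ block
of $\mathbf X_o^\top \mathbf Z (\mathbf Z^\top\mathbf Z)^- \mathbf C_s
(\mathbf Z^\top\mathbf Z)^- \mathbf Z^\top \mathbf X_o$, where $\mathbf X_o$
reorders the fixed-effect columns that lie inside the random-effect span
first.  For a random-intercept factor with $m$ groups this reduces to
$\mathbf L_{s;1,1} = 1/m$ for *any* group-size pattern, so the $\tau$
condition is simply $\gamma^2_\tau > r + r^2/m$ — a property the test suite
verifies by brute force on random unbalanced designs.

`elicit_priors()` implements the automatic weakly informative strategy:

* $\gamma_\sigma = \sqrt{(r+c) + (r+c)^2 h_m}$ and
  $\gamma_{\tau,s} = \sqrt{(r+c) + (r+c)^2 l_{m,s}}$, the thresholds at order
  $r + c$ with leverages maximised over the prediction points (defaulting to
  the observed design rows, i.e. moments exist wherever the model will be
  evaluated); with a predictive target the first term becomes $(r+c)^2$;
* by default one *common* $\gamma$, the largest (most restrictive) of these;
* $\lambda = 1$ and $\delta = \varepsilon = 0.01$ for every variance prior.

Defaults and their rationale:

* **`r = 2`** — two finite posterior moments, so the reported posterior mean
  and standard deviation are estimates of finite quantities.
* **`c = 1`** — a safety margin above the bare threshold: integrals that are
  finite but barely so are numerically unstable. Margins below 0.5 trigger a
  warning.
* **`epsilon = 0.01`** — with $\lambda = 1$ and $\delta$ near zero each
  variance prior is approximately an Exponential$(\gamma^2/2)$, and the
  implied prior on each intraclass correlation
  $\rho_s = \tau_s^2/(\sigma^2+\tau_s^2)$ is approximately Uniform(0, 1) —
  the uniform-shrinkage prior.  `rho_prior_density()` evaluates the implied
  density; the suite confirms by simulation that $\rho$ under the default
  spec passes a Kolmogorov–Smirnov test against the uniform at $n = 10^5$.

On the density of $\rho$: for $\sigma^2, \tau^2$ i.i.d.
GIG$(\lambda,\delta,\gamma)$ the package evaluates

$$
p(\rho) = \frac{K_{2\lambda}\!\big(\gamma\delta/\sqrt{\rho(1-\rho)}\big)}
               {2\,K_\lambda(\gamma\delta)^2\;\rho(1-\rho)},
$$

a normalized-GIG density re-derived from the ratio construction; its
small-$\delta\gamma$ limit is the Beta-type kernel
$\Gamma(2|\lambda|)/\Gamma(|\lambda|)^2\,[\rho(1-\rho)]^{|\lambda|-1}$, which
at $\lambda = 1$ is exactly uniform.  (The derivation is reproduced in code
because published statements of this density are easy to mistranscribe; the
implemented form is validated by quadrature normalisation and by simulation.)
The implied prior on $\phi = \tau^2/\sigma^2$ from a uniform $\rho$ is
$p(\phi) = (1+\phi)^{-2}$; the package tests the uniform-$\rho$ property,
which is the operational design goal.

## The Gibbs sampler

Normal–GIG conditional conjugacy gives closed-form full conditionals:

$$
\sigma^2 \mid \cdot \sim \mathrm{GIG}\Big(\lambda_\sigma - \tfrac n2,\
  \sqrt{\mathrm{RSS} + \delta_\sigma^2},\ \gamma_\sigma\Big),
\qquad
\tau^2_s \mid \cdot \sim \mathrm{GIG}\Big(\lambda_{\tau,s} - \tfrac{m_s}2,\
  \sqrt{\mathbf u_s^\top \mathbf u_s + \delta_{\tau,s}^2},\ \gamma_{\tau,s}\Big),
$$

$\mathbf u \mid \cdot \sim \mathcal N(\mathbf V_u \mathbf Z^\top(\mathbf w -
\mathbf X\beta),\ \sigma^2\mathbf V_u)$ with $\mathbf V_u = (\mathbf
Z^\top\mathbf Z + \sigma^2\mathbf D^{-1})^{-1}$, and $\beta \mid \cdot \sim
\mathcal N((\mathbf X^\top\mathbf X)^{-1}\mathbf X^\top(\mathbf w - \mathbf
Z\mathbf u),\ \sigma^2(\mathbf X^\top\mathbf X)^{-1})$.

Design choices:

* **Sweep order** $\sigma^2 \to \tau^2 \to \mathbf u \to \beta$. The order is
  not dictated by the theory; any fixed order is a valid Gibbs scheme, and
  fixing one makes runs bitwise reproducible.
* **Initialisation**: $\beta$ at OLS of $w$ on $X$, $\mathbf u = 0$,
  $\sigma^2$ at the OLS residual variance, $\tau^2_s = \sigma^2/q$.  An
  overdispersed-start option scatters secondary chains for convergence
  diagnostics.
* **Budget**: 5000 iterations with 1000 discarded as burn-in by default —
  the full conditionals mix quickly in the designs targeted here (the
  smallest effective sample sizes in the worked examples are in the
  hundreds per 4000 retained draws).
* **Linear algebra**: $\mathbf V_u$ is refactorised by Cholesky every
  iteration; with the small-to-moderate $m$ this model family targets,
  correctness is cheaper than caching.  The sweep is implemented in C++
  (RcppArmadillo) and consumes R's RNG stream, so `set.seed()` governs the
  whole chain.
* **Inverse-gamma arms**: IG$(a,b)$ enters as GIG$(-a, \sqrt{2b}, 0)$, so the
  comparison arms of the simulation study run through the *same* code path
  with a boundary parameter, not through a second sampler.

GIG random variates use a three-region rejection scheme: mode-shifted
ratio-of-uniforms for concentrated cases ($|\lambda| > 2$ or
$\omega = \delta\gamma > 3$), plain ratio-of-uniforms in the central region,
and a two-piece hat (power law near 0, exponential tail) for
$0 < \lambda < 1$ with small $\omega$, where the density is unbounded near
the origin in practice.  Negative $\lambda$ uses the duality
$1/V \sim \mathrm{GIG}(-\lambda, \gamma, \delta)$.  All quasi-density
evaluations happen in log space; the Bessel function $K_\lambda$ is only
needed for densities and moments, where it is evaluated exponentially scaled
with a uniform asymptotic fallback for very large order (the full
conditionals produce orders like $\lambda - n/2$).

One numerical subtlety surfaced while validating the closed-form conditional
posterior of $\beta$ (used as an oracle for the sampler): the textbook
pseudo-inverse expression for the marginal precision of $\mathbf w$ is exact
only when $\mathbf Z$ has full column rank.  With crossed intercept factors
$\mathbf Z$ is rank-deficient (each block's columns sum to the intercept),
and the package instead evaluates the marginal precision through the Woodbury
identity $(\sigma^2\mathbf I + \mathbf Z\mathbf D\mathbf Z^\top)^{-1} =
\sigma^{-2}[\mathbf I - \mathbf Z(\mathbf Z^\top\mathbf Z +
\sigma^2\mathbf D^{-1})^{-1}\mathbf Z^\top]$, which is exact for any
$\mathbf Z$, agrees with a dense-inversion oracle in all tested cases, and is
exactly what the Gibbs conditionals marginalise to.

Numerical rank decisions (the rank deficiency $l$, detection of fixed-effect
columns inside the random-effect span) use a relative singular-value cut-off
of $10^{-8}$ on $(\mathbf I - \mathbf P_Z)\mathbf X$, far above the
projector's rounding noise and far below genuine non-degenerate directions.
A column *partially* aligned with the span (between those scales) is
rejected with an explicit error rather than silently classified.  The
degenerate case $l = p$ — every fixed-effect column inside the span, e.g.
the intercept-only one-way layout — is accepted: the zero-mean random-effect
prior keeps the conditional posterior of $\beta$ proper, and this is in fact
the central use case of the simulation study.

## Functionals

`theta_m_draws()`, `theta_c_draws()` and `predictive_draws()` transform
retained draws.  Partial conditioning is supported: factors named in
`condition_on` contribute their sampled $\tilde{\mathbf z}^\top\mathbf u_s$;
every other factor is integrated out and contributes $\tau^2_s/2$ to the
exponent.  This covers functionals such as "the expected response for item
$k$, averaged over subjects", which neither the fully marginal nor the fully
conditional expectation expresses.  Predictive draws are composed one per
retained draw; `"new-group"` mode draws a fresh $N(0, \tau^2_s)$ effect per
factor and draw, `"observed-group"` reuses the sampled effects.  Summaries
report the posterior mean as the point estimate — meaningful precisely
because the elicitation guarantees its existence — with the median available
for comparisons against arms whose posterior mean does not exist.

`benchmark_estimators()` implements the closed-form conditional benchmarks
for the balanced one-way layout with known variances: the minimum-MSE
predictor of $\theta_m$ in the class $k\exp\{\bar w\}$,
$\hat\theta_m^c = \exp\{\bar w + (\sigma^2+\tau^2)/2 - 3(\sigma^2 +
n_g\tau^2)/(2n)\}$, and the relative-quadratic-loss Bayes estimator of the
group expectations.  These are evaluation baselines, not estimators the
package recommends (they assume the variances known).

## The simulation harness and what it does (not) show

`simulate_scenario_data()` draws from the generating model itself:
$w_{ij} = \mu + v_j + \varepsilon_{ij}$ with $v_j \sim N(0, \tau^2 =
\phi\sigma^2)$, $\varepsilon_{ij} \sim N(0,\sigma^2)$, $y = e^w$, balanced
groups.  Scenario defaults — $n_g \in \{2, 5\}$, $m = 10$, $\phi \in \{0.5,
1, 2\}$, $\sigma^2 \in \{0.05, \dots, 0.75\}$, $\mu = 0$, $B = 2000$
replicates, 5000/1000 MCMC iterations — are the study conditions this
package's evaluation is defined under: small samples, where prior influence
is at its strongest, and log-scale variances spanning the range common in
applications.

`run_scenario()` evaluates, over $B$ *paired* replicates (identical data
across arms, variance-reducing for contrasts), the GIG arm with the default
elicitation, the IG(1,1) and IG(0.001, 0.001) boundary arms, and the
conditional benchmarks, reporting Bias/RMSE/coverage/width for $\theta_m$
and the relative group-level metrics (RABias, RRMSE, average coverage and
width), each with a Monte Carlo standard error (delta method for the
RMSE-type metrics, replicate-level for the averaged group metrics).  Group
truths $\theta_c^{(k)}(v_j) = \exp\{\mu + v_j + \sigma^2/2\}$ are recomputed
per replicate from the drawn effects.  A `MaxEst` row per arm records the
largest replicate-level $\theta_m$ estimate — the numerical sentinel for
non-existing moments: under IG priors this quantity is effectively unbounded
in $B$ (single replicates in the thousands and beyond), while the GIG arm
stays within an order of magnitude of the truth.  Per-replicate seeds derive
deterministically from (seed, scenario, replicate), so every cell is exactly
reproducible.  `fast = TRUE` divides $B$ and the MCMC budget by 4 for quick
passes; the reported MC standard errors quantify the loss.

What the generator deliberately does *not* emulate: non-normal log-scale
errors, unbalanced or informative group sizes, covariate effects, or
correlated random slopes/intercepts within a factor.  Passing tests
therefore certify the estimators under the model's own assumptions — the
frequentist operating characteristics of a correctly specified Bayesian
model — not robustness to misspecification.  Correlated random effects with
free correlation parameters are out of scope altogether: their full
conditionals are no longer GIG/Gaussian, so the direct Gibbs sampler does
not apply.

## Known limitations

* Only random intercepts (or known-correlation reparameterisations that
  reduce to them); no free correlation parameters between random effects.
* A proper normal prior on $\beta$ is not offered; the theory is developed
  under the flat improper prior.
* The existence thresholds bound *moments*; quantile-based summaries are
  well defined under any of the priors, and intervals under IG priors in the
  simulations are wide but not invalid.
* Problem sizes: the test suite and the acceptance script run the first
  evaluation scenario and the sentinel scenario at the full $B = 2000$; the
  remaining 22 grid cells are exercised through the same code path at small
  $B$ only.
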