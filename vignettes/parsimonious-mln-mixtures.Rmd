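---
title: "Parsimonious mixtures of multivariate leptokurtic-normal distributions: models, algorithms, and numerical choices"
author: "mlnmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimonious MLN mixtures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnmix)
```

## The model

The multivariate leptokurtic-normal (MLN) distribution multiplies the
normal density by a kurtosis-controlled polynomial factor:

$$f(x \mid \mu, \Sigma, \beta)
  = \{1 + \beta\, g(r)\}\, \phi(x \mid \mu, \Sigma), \qquad
  r = (x-\mu)^\top \Sigma^{-1} (x-\mu),$$

with

$$g(r) = \frac{r^2 - 2(d+2)r + d(d+2)}{8d(d+2)}, \qquad
  \beta \in \Big[0,\ \frac{4d(d+2)}{d+4}\Big].$$

It arises from a multivariate Gram–Charlier expansion of the normal, and its
three parameters are exactly the moments a practitioner wants per cluster:
mean, covariance, and (Mardia-type) excess kurtosis.  The upper limit of the
admissible $\beta$ range guarantees positivity — on that range
$1 + \beta g(r) \ge 2/(d+4) > 0$ because $g$ is bounded below by $-1/(4d)$ —
and unimodality.  A $k$-component mixture
$p(x) = \sum_j \pi_j f(x \mid \mu_j, \Sigma_j, \beta_j)$ provides robust
model-based clustering when the component tails are heavier than normal.

Parsimony comes from the familiar eigendecomposition of each component
covariance,

$$\Sigma_j = \lambda_j\, \Gamma_j\, \Psi_j\, \Gamma_j^\top,$$

with volume $\lambda_j = |\Sigma_j|^{1/d}$, orthogonal orientation
$\Gamma_j$, and diagonal shape $\Psi_j$ with $|\Psi_j| = 1$.  (The volume is
defined from $|\Sigma_j|$; defining it from $|\Psi_j|$ would contradict the
side condition $|\Psi_j| = 1$, so the standard convention is used.)  Each
factor may be **E**qual across components, **V**arying, or the **I**dentity
(shape/orientation only), giving 14 covariance structures; a spherical shape
leaves no orientation to estimate, so shape `I` forces orientation `I`.
Crossed with an **E**qual or **V**arying excess kurtosis this yields the 28
models named by four letters, e.g. `EEVV`: shared volume and shape, varying
orientation and kurtosis.  Free-parameter counts follow the letters
(`count_free_params()`); the BIC used throughout is $2\ell - m\log n$, so
that — like the log-likelihood — it is maximized.

## Two fitting algorithms

Both algorithms are EM at the top level: the E-step computes
responsibilities $w_{ij}$ (log-sum-exp stabilized), the weights update as
$\pi_j = n_j/n$, and the kurtosis update is shared (below).  They differ in
the $(\mu_j, \Sigma_j)$ M-step.

### The quadratic minorizer and the MM algorithm

Written in the standardized coordinate $z = \Sigma^{-1/2}(x-\mu)$, the
log-density has radial derivative
$u'(r) = \beta g'/(1+\beta g) - \tfrac12$ and a Hessian (in $z$) whose
eigenvalues are $4r\,u''(r) + 2u'(r)$ along $z$ and $2u'(r)$ across it.  The
directional coefficient $c(r) = 4r\,u'' + 2u'$ is bounded below; its
stationary points in $r$ solve a depressed quartic whose coefficients are
polynomial in $(\beta, d)$ (derived symbolically in this package and checked
against a grid-scan oracle; see *Numerical choices*).  With

$$M = \Big|\min\big\{c(0),\ c(r_1), \ldots, c(r_4)\big\}\Big|$$

over the nonnegative stationary points (beyond the largest one $c$ increases
monotonically to $-1$, so no tail candidate is needed; $M = 1$ exactly at
$\beta = 0$), the log-density admits the quadratic minorizer

$$\log f(z^\top z) \ \ge\ C_0 + [2u'(r_0) + M]\, z_0^\top z
  - \tfrac{M}{2}\, z^\top z,$$

touching at the expansion point $z_0$.  Summing over observations gives a
surrogate that is, in the covariance parameters,

$$\sum_j \Big[ -\tfrac{n_j}{2}\log|\Sigma_j|
  + \mathrm{Tr}(\Sigma_j^{-1/2} A_j)
  - \tfrac12 \mathrm{Tr}(\Sigma_j^{-1} B_j) \Big],$$

maximized under each model's structural constraints by
`mm_cov_update()`.  Because every step maximizes a touching minorizer, the
observed log-likelihood is **monotone by construction** — the test suite
hard-asserts that no MM trace ever decreases.

### The damped fixed-point algorithm

A cheaper first-order surrogate expands $\log f$ linearly in $r$, which
yields weighted-mean updates with weights
$\kappa_i = 1 - 2\beta g'(r_i)/(1+\beta g(r_i))$ (strictly positive on the
admissible range; its interior minimum sits at $r = d+4$ when
$\beta = \beta_{\max}$).  Using the resulting $\kappa$-weighted scatter
$R_j$ directly can make the log-likelihood oscillate, so the update is
damped:

$$S_j = (1-a)\,\Sigma_j^{(q)} + a\,R_j, \qquad
  a = \frac{1}{1 + \beta\,\tfrac{d+4}{4d(d+2)}},$$

chosen so that $a = 1$ at $\beta = 0$ (the classical covariance update) and
$a = \tfrac12$ at $\beta = \beta_{\max}$ (a half step).  The `fp_weight`
argument overrides $a$ with a fixed value for users who want to explore the
damping.  The damped step is not a guaranteed minorizer; the fitter logs
every log-likelihood decrease (`n_drops`, `max_drop`) rather than silently
ignoring it, and on the package's simulation designs the traces are
empirically monotone.

### Updating the excess kurtosis

The weighted log-likelihood term $\sum_i w_i \log\{1 + \beta g(r_i)\}$ is
concave in $\beta$ (each summand has negative second derivative), so the
update iterates a guarded Newton-type step
$\beta^+ = \beta + \sum w\gamma / \sum w\gamma^2$ with
$\gamma_i = \beta g(r_i)/(1+\beta g(r_i))$, clamped to
$[0, \beta_{\max}(d)]$, accepting a step only if the objective increases; if
the step stalls (including the $\beta = 0$ start, where $\gamma \equiv 0$),
a bracketed golden-section search over the admissible interval finishes the
job.  Correctness therefore never depends on the step formula.  The shared-
kurtosis variants pool the sums over components.  Three-letter model names
(`"VVV"`) fit with $\beta$ held at a user-supplied `fixed_beta`.

### Stopping

Aitken acceleration on the log-likelihood sequence: with ratio
$a_q = (\ell_{q+1}-\ell_q)/(\ell_q-\ell_{q-1})$ and extrapolated limit
$\ell_\infty = \ell_q + (\ell_{q+1}-\ell_q)/(1-a_q)$, the fit stops when
$0 \le \ell_\infty - \ell_{q+1} < \mathrm{tol}$ (default $10^{-6}$); a ratio
$\ge 1$ is never converged.  Default cap: 1000 iterations.

## Numerical choices

* **Quartic roots.** `polyroot` (Jenkins–Traub) followed by a short Newton
  polish of the real roots on the monic quartic, so residuals are below
  $10^{-8}$; imaginary parts under $10^{-7}$ relative are truncated.  The
  quartic's coefficients were derived symbolically from $h'(r) = 0$ and are
  validated in the tests against sign changes of a finite-difference
  derivative on a dense grid — the grid oracle, not the algebra, is the
  correctness contract.
* **Unconstrained MM covariance update.** The stationary condition in
  $\Xi_j = \Sigma_j^{-1/2}$ is a Riccati-type matrix equation; since the
  surrogate is strictly concave in $\Xi_j$ (log-determinant plus a concave
  quadratic), the package solves it with a damped Newton iteration on
  $\mathrm{vec}(\Xi)$ (Kronecker Hessian, step-halving line search, PD
  safeguard), which converges globally to the unique SPD solution.  A
  numerical fallback over the Cholesky factor handles pathological inputs,
  with a warning.
* **Structured MM updates.** Blockwise coordinate ascent: the volume update
  is the closed-form positive root of a quadratic in $\lambda^{-1/2}$; the
  shape update is a guarded BFGS on $\log\psi$ with the unit-determinant
  constraint enforced by centering; orientation updates use the linear
  majorization of the quadratic trace objective, solved by a polar (SVD)
  factor, which cannot decrease the objective.  Every block is accepted only
  if the surrogate does not decrease, and the update returns the incumbent
  when a proposal would decrease it — so MM monotonicity survives inexact
  inner solves.  Inner loops cap at 100 sweeps with relative tolerance
  $10^{-8}$.
* **Fixed-point constrained updates.** Classical closed forms for the
  diagonal/unconstrained/shared structures; volume–shape flip-flops for
  `VEI`/`VEV`/`VEE` (warm-started from the previous EM iterate); shared-
  orientation models (`EVE`, `VVE`) alternate the same majorized orthogonal
  step with closed-form shape/volume solves.
* **Decomposition conventions.** Eigenvalues sorted decreasing; each
  eigenvector column is signed so its largest-magnitude entry is positive;
  exact ties are ordered by the row index of that entry, so the identity
  decomposes to $\Gamma = I$ and results are reproducible.
* **Degenerate fits.** A component whose effective count drops below
  $d + 1$, or a scatter that loses positive definiteness, aborts that start;
  the fitter retries with a fresh random start (up to 5 times) and the
  search grid records the failure reason instead of aborting.
* **Random starts.** Each start draws $k$ observations as centroids,
  hard-assigns every observation to its nearest centroid, and takes one
  normal-theory M-step with $\beta = 0$.  Soft near-uniform random
  responsibilities were evaluated and rejected: they start all components at
  nearly identical parameters (the label-permutation saddle), from which the
  strictly ascending MM algorithm can be funneled into a wrong-axis local
  optimum on every such start, while hard centroid starts break the symmetry
  spatially and reach the dominant mode reliably.  All randomness flows from
  the user seed; search grids derive one seed per (model, k) cell so results
  are independent of evaluation order.

## Exact samplers

The squared Mahalanobis radius of an MLN vector follows a signed mixture of
chi-square laws,
$F(r) = (1+\tfrac{\beta}{8}) F_{\chi^2_d}(r)
      - \tfrac{\beta}{4} F_{\chi^2_{d+2}}(r)
      + \tfrac{\beta}{8} F_{\chi^2_{d+4}}(r)$,
whose weights sum to one and whose second moment gives
$E[r^2] = d(d+2) + \beta$ — the moment identity the tests check.  `rmln()`
inverts this monotone CDF by vectorized bisection on a guaranteed bracket
(tolerance below $10^{-12}$) and multiplies by a uniform direction on the
sphere: an exact sampler, no approximation beyond root-finding tolerance.

The misspecification generators are likewise exact: the multivariate-t by
the normal/chi-square representation, and the generalized-hyperbolic (GHD)
by a normal mean–variance mixture $x = \mu + w\alpha + \sqrt{w}z$ with GIG
mixing weight.  GIG variates use ratio-of-uniforms with a closed-form
bounding rectangle (both suprema are GIG modes) and log-scale acceptance, so
no overflow is possible; the tests verify $E[w]$ and $E[1/w]$ against
Bessel-function ratios.

## The simulation designs

`mln_design(k, d, delta, lambda, rho, n, seed)` encodes the package's
standard data-generating setups: equal weights, means at
$\pm\delta\mathbf 1_d$ (two components), $\{-\delta, 0, \delta\}\mathbf 1_d$
(three), or the four sign-block corners (four components; the two stacked
blocks have length $d/2$, so this design requires even $d$), covariances
$\lambda^{e_j}\,\Xi_d(\rho)$ with $\Xi_d(\rho) = (1-\rho)I + \rho J$ and
volume exponents $(1,-1)$, $(-1,0,1)$, $(-1,0,0,1)$, and all component
kurtoses at the admissible maximum $4d(d+2)/(d+4)$.  The
$(\lambda, \rho)$ pairs $(1,0), (2,0), (1,0.5), (2,0.5)$ generate `EIIE`,
`VIIE`, `EEEE` and `VEEE` structural truths, verified in the tests by
decomposing the built covariances.

What these designs emulate — well-controlled elliptical clusters with
maximal excess kurtosis, varying separation, volume and correlation — is
deliberately idealized.  They do not contain outliers, skewness (except via
the GHD generator), unequal weights, or non-elliptical structure, so passing
the simulation checks demonstrates correctness of the estimators under the
model and graceful behavior under the two misspecifications studied, not
robustness to arbitrary real data.

## Study protocol and problem sizes

The packaged studies (`study_*`) use the Aitken rule at $10^{-6}$ with a
300-iteration cap, and the following sizes, chosen as a desk-scale protocol
the package commits to:

* algorithm agreement: 20 replications, $d = 2$, $n = 500$, 4 random starts
  (this experiment compares the two algorithms *at the maximum-likelihood
  solution*, so enough starts are used to reach the global optimum on every
  replication), $\beta$ fixed at its maximum so the algorithms differ only
  in the $(\mu, \Sigma)$ steps;
* selection of $k$ (model fixed, $k_{\max} = 8$): 60–100 replications at
  $n = 300$, one random start per grid cell (start-to-start variation is
  absorbed by the binomial bands of the selection counts);
* model selection at fixed $k$ over all 28 models: 20 replications at
  $n = 100$, one start per cell;
* GHD misspecification: 25 replications at $n = 500$ over a reduced grid of
  three models and $k \le 4$ (the models and component counts that dominate
  the full-grid selections), one start per cell.

Replication counts enter the checks through exact binomial/Monte-Carlo
bands, so smaller runs widen — never bias — the comparison.

One check needs a boundary-aware formulation: the recovery study generates
data with $\beta$ exactly at $\beta_{\max}(d)$, the edge of the admissible
range.  The ML estimator is clamped there, its deviations are one-sided,
and the usual symmetric 3-standard-error band around the truth is
miscalibrated *by construction* (the folded-normal mean deficit is about
$0.68$ clamped-SDs regardless of $n$).  Interior parameters use the
standard band; $\beta$ is checked against the folded prediction
$E[\hat\beta] \approx \beta_{\max} - 0.683\,\mathrm{sd}(\hat\beta)$ with the
same band width.

## Known limitations

* Platykurtic extensions ($\beta < 0$) are out of scope; the admissible
  range is enforced, never extrapolated.
* The FP algorithm's monotonicity is empirical, not proven; decreases are
  logged and surfaced, and the MM algorithm is the guaranteed-monotone
  alternative at extra cost per iteration.
* Standard errors (e.g. parametric bootstrap) are not provided.
* Model-based clustering with $k$ large relative to $n$ routinely produces
  degenerate starts; the retry/record machinery makes grids complete, but
  sparse cells should be interpreted with care.
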