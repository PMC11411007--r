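# mlnmix

Model-based clustering with **parsimonious mixtures of multivariate
leptokurtic-normal (MLN) distributions**, for data whose clusters have
heavier-than-normal tails — a common situation in biometric and
epidemiological measurements, where a few extreme observations per group
would otherwise distort normal-mixture fits.

The MLN density is a multivariate normal times a kurtosis-controlled
polynomial factor,

    f(x | mu, Sigma, beta) = {1 + beta * g(r)} * phi(x | mu, Sigma),
    g(r) = (r^2 - 2(d+2) r + d(d+2)) / (8 d (d+2)),
    r    = (x - mu)' Sigma^{-1} (x - mu),
    beta in [0, 4d(d+2)/(d+4)],

so each cluster is parameterized by exactly its mean, covariance, and excess
kurtosis `beta`.  Parsimony comes from the eigendecomposition
`Sigma_j = lambda_j Gamma_j Psi_j Gamma_j'` with each factor equal (E),
varying (V), or identity (I) across clusters, crossed with an equal or
varying `beta` — the 28 four-letter models (`"EIIE"`, `"EEVV"`, `"VVVV"`,
...).  Maximum likelihood uses either

* **MM** — an EM whose M-step maximizes a quadratic minorizer built from a
  provable curvature bound on the log-density; the log-likelihood is
  monotone by construction; or
* **FP** — a faster damped fixed-point EM whose covariance step blends the
  weighted scatter with the current covariance
  (`a = 1` at `beta = 0`, `a = 1/2` at the kurtosis maximum).

Model choice is by BIC in the maximization convention `2*loglik - m*log(n)`;
clustering quality by the adjusted Rand index.  Exact simulators for MLN,
multivariate-t, and generalized-hyperbolic mixtures make every result
reproducible without external data.  See the vignette
(`vignettes/parsimonious-mln-mixtures.Rmd`) for the full methods account.

## Worked example

Simulate two correlated, unequal-volume, maximally leptokurtic clusters and
recover the generating structure:

```r
library(mlnmix)
sim <- sample_design(mln_design(k = 2, d = 2, delta = 3, lambda = 2,
                                rho = 0.5, n = 400, seed = 7))
fit <- mln_fit(sim$x, "VEEE", k = 2, seed = 1)
fit
#> Parsimonious MLN mixture: model VEEE, k = 2 (FP algorithm)
#>   log-likelihood -1296.194  BIC -2652.303  (10 free parameters, n = 400)
#>   16 iterations, converged
#>   mixing weights: 0.484 0.516
#>   excess kurtosis: 5.333 5.333
adjusted_rand_index(fit$labels, sim$labels)
#> [1] 0.9701503
```

The mixing weights sit at the generating 1/2–1/2, and the shared excess
kurtosis is estimated at the generating maximum `beta_max(2) = 5.333`.  A
BIC search separates the true model from both a too-simple and a too-rich
alternative:

```r
sr <- mln_search(sim$x, models = c("EIIE", "VEEE", "VVVV"), k_values = 1:3,
                 seed = 1, n_starts = 2)
sr
#> MLN model search: 9 cells (9 fitted, 0 failed)
#> Best by BIC: model VEEE, k = 2 (BIC -2652.303)
```

`VVVV` at `k = 2` reaches a slightly higher log-likelihood (-1295.36 vs
-1296.19) but pays for its 3 extra parameters in BIC (-2668.61 vs
-2652.30): the parsimonious truth wins.

A thin command-line driver wraps the same functions:

```sh
inst/cli/mln simulate --k 2 --d 2 --delta 3 --n 500 --seed 1 --out sim/
inst/cli/mln fit --input sim/data.csv --model VEEE --k 2 --out fit/
inst/cli/mln search --input sim/data.csv --models all --kmin 1 --kmax 3 --out grid/
```

Every output directory contains the resolved configuration and per-iteration
log-likelihoods, so any run can be reproduced and audited for monotonicity.

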