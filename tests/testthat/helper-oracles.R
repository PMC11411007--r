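# Shared test fixtures and independent numerical oracles.

rspd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d, d)
  scale * (crossprod(A) + 0.5 * diag(d))
}

# --- independent brute-force oracle for the constrained covariance M-steps ---
#
# Parameterizes each model family directly (log-volumes, sum-zero log-shapes,
# Cayley-transform orientations) and maximizes the surrogate with multi-start
# BFGS plus alternating Nelder-Mead polish rounds.  Entirely independent of
# the closed-form / coordinate-ascent code paths it checks.

cayley_orth <- function(theta, d) {
  S <- matrix(0, d, d)
  S[lower.tri(S)] <- theta
  S <- S - t(S)
  (diag(d) - S) %*% solve(diag(d) + S)
}

oracle_build_sigma <- function(model, par, d, k) {
  m <- validate_model_name(model)
  i <- 0
  lam <- if (m$volume == "V") exp(par[i + (1:k)]) else rep(exp(par[i + 1]), k)
  i <- i + if (m$volume == "V") k else 1
  getpsi <- function() {
    v <- par[i + seq_len(d - 1)]; i <<- i + d - 1
    exp(c(v, -sum(v)))
  }
  psi <- switch(m$shape,
    I = rep(list(rep(1, d)), k),
    E = { p <- getpsi(); rep(list(p), k) },
    V = lapply(seq_len(k), function(j) getpsi()))
  ngam <- d * (d - 1) / 2
  getgam <- function() {
    g <- cayley_orth(par[i + seq_len(ngam)], d); i <<- i + ngam; g
  }
  gam <- switch(m$orientation,
    I = rep(list(diag(d)), k),
    E = { g <- getgam(); rep(list(g), k) },
    V = lapply(seq_len(k), function(j) getgam()))
  lapply(seq_len(k), function(j)
    lam[j] * (gam[[j]] %*% (psi[[j]] * t(gam[[j]]))))
}

oracle_n_par <- function(model, d, k) {
  m <- validate_model_name(model)
  (if (m$volume == "V") k else 1) +
    switch(m$shape, I = 0, E = d - 1, V = k * (d - 1)) +
    switch(m$orientation, I = 0, E = d * (d - 1) / 2, V = k * d * (d - 1) / 2)
}

# Maximize `objective(sigma_list)` over the model family; returns sigma list.
cov_oracle <- function(model, objective, d, k, n_restarts = 6, rounds = 4) {
  np <- oracle_n_par(model, d, k)
  neg <- function(p) {
    val <- tryCatch(objective(oracle_build_sigma(model, p, d, k)),
                    error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }
  best <- NULL
  for (s in seq_len(n_restarts)) {
    p0 <- rnorm(np, 0, if (s == 1) 1e-8 else 0.7)
    ft <- suppressWarnings(
      optim(p0, neg, method = "BFGS",
            control = list(maxit = 800, reltol = 1e-15)))
    if (is.null(best) || ft$value < best$value) best <- ft
  }
  for (rd in seq_len(rounds)) {
    if (np > 1)
      best <- suppressWarnings(
        optim(best$par, neg, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-15)))
    best <- suppressWarnings(
      optim(best$par, neg, method = "BFGS",
            control = list(maxit = 800, reltol = 1e-15)))
  }
  # derivative-based finishing stage: the trace objectives can be very flat
  # near the optimum, where simplex methods stall early
  neg_safe <- function(p) {
    if (any(!is.finite(p))) return(1e10)
    min(neg(p), 1e10)
  }
  fin <- tryCatch(
    suppressWarnings(nlm(neg_safe, best$par, gradtol = 1e-13,
                         steptol = 1e-14, iterlim = 500)),
    error = function(e) NULL)
  if (!is.null(fin) && fin$minimum <= best$value)
    best <- list(par = fin$estimate, value = fin$minimum)
  oracle_build_sigma(model, best$par, d, k)
}

max_frobenius_gap <- function(sig_a, sig_b) {
  max(mapply(function(a, b) sqrt(sum((a - b)^2)), sig_a, sig_b))
}

# Expected complete-data log-likelihood (up to the additive constant):
# sum_ij w_ij { log pi_j - r_ij/2 + log[1 + beta_j g(r_ij)] }.
expected_complete_ll <- function(x, W, pi, mu, sigma, beta) {
  d <- ncol(x)
  tot <- 0
  for (j in seq_len(ncol(W))) {
    R <- chol(sigma[[j]])
    z <- backsolve(R, t(x) - mu[, j], transpose = TRUE)
    r <- colSums(z^2)
    tot <- tot + sum(W[, j] * (log(pi[j]) - sum(log(diag(R))) - r / 2 +
                                 log1p(beta[j] * g_poly(r, d))))
  }
  tot
}
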