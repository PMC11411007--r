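test_that("E-step handles the degenerate symmetric configurations exactly", {
  set.seed(21)
  x <- matrix(rnorm(40), 20, 2)
  # k = 1: all responsibilities one
  es <- e_step(x, 1, matrix(0, 2, 1), list(diag(2)), 0)
  expect_equal(es$W, matrix(1, 20, 1))
  # two identical components: all 0.5
  es2 <- e_step(x, c(0.5, 0.5), matrix(0, 2, 2), list(diag(2), diag(2)),
                c(1, 1))
  expect_equal(es2$W, matrix(0.5, 20, 2))
  # a point equidistant from two mirrored components
  es3 <- e_step(matrix(c(0, 0), 1, 2), c(0.5, 0.5),
                cbind(c(-2, 0), c(2, 0)), list(diag(2), diag(2)), c(2, 2))
  expect_equal(as.vector(es3$W), c(0.5, 0.5))
  # log-sum-exp stabilization: likelihood identical with shifted data scale
  far <- x + 1e3
  es4 <- e_step(far, c(0.4, 0.6), cbind(rep(1e3, 2), rep(1e3, 2) + 1),
                list(diag(2), 2 * diag(2)), c(0, 3))
  es5 <- e_step(x, c(0.4, 0.6), cbind(rep(0, 2), rep(0, 2) + 1),
                list(diag(2), 2 * diag(2)), c(0, 3))
  expect_equal(es4$loglik, es5$loglik, tolerance = 1e-10)
  expect_equal(es4$W, es5$W, tolerance = 1e-10)
})

test_that("mixing-weight update is the responsibility column mean", {
  expect_equal(update_pi(matrix(1, 30, 1)), 1)
  expect_equal(update_pi(rbind(c(1, 0), c(0, 1))), c(0.5, 0.5))
  W <- cbind(rep(0.3, 100), rep(0.7, 100))
  expect_equal(update_pi(W), c(0.3, 0.7))
  expect_warning(update_pi(cbind(rep(0.99, 50), rep(0.01, 50)), d = 3),
                 "degenerate")
})

test_that("kurtosis update matches a dense 1-D maximization oracle", {
  set.seed(22)
  d <- 2
  bmax <- beta_max(d)
  for (i in 1:10) {
    r <- matrix(rchisq(200, d) * runif(1, 0.7, 2.5), ncol = 1)
    W <- matrix(runif(200, 0.2, 1), ncol = 1)
    obj <- function(b) sum(W * log1p(b * g_poly(r, d)))
    # golden-section oracle refined from a dense grid
    grid <- seq(0, bmax, length.out = 2001)
    i0 <- which.max(vapply(grid, obj, 0))
    lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
    oracle <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
    for (b_start in c(0, 1.7, bmax)) {
      got <- update_beta(r, W, b_start, shared = FALSE, d = d)
      expect_lt(abs(obj(got) - obj(oracle)), 1e-7 * (abs(obj(oracle)) + 1))
      expect_true(got >= 0 && got <= bmax)
    }
  }
  # beta = 0 start engages the fallback search (gamma = 0/0 guard)
  r0 <- matrix(rchisq(300, 2) * 2, ncol = 1)  # overdispersed: wants beta > 0
  got0 <- update_beta(r0, matrix(1, 300, 1), 0, shared = FALSE, d = 2)
  expect_gt(got0, 0)
  # shared update pools components and stays clamped
  r2 <- cbind(rchisq(150, 2) * 3, rchisq(150, 2) * 3)
  W2 <- matrix(0.5, 150, 2)
  gs <- update_beta(r2, W2, c(1, 1), shared = TRUE, d = 2)
  expect_equal(gs[1], gs[2])
  expect_lte(gs[1], beta_max(2))
})

test_that("Aitken acceleration stops on geometric traces and rejects divergence", {
  l <- 10 - 2 * 0.5^(0:30)
  # the extrapolated limit is exactly 10; converged once within tolerance
  hits <- vapply(3:31, function(q) aitken_converged(l[1:q], tol = 1e-6), NA)
  expect_true(any(hits))
  first <- which(hits)[1] + 2
  gap_prev <- 10 - l[first - 1]
  expect_gt(gap_prev, 1e-7)           # did not stop absurdly early
  expect_true(aitken_converged(c(5, 5, 5), tol = 1e-6))       # flat trace
  expect_false(aitken_converged(c(1, 2, 4), tol = 1e-6))      # a >= 1
  expect_false(aitken_converged(c(1, 2, 2.9), tol = 1e-6))    # far from limit
})

test_that("MM M-step reduces to the normal-theory step at beta = 0", {
  set.seed(23)
  x <- matrix(rnorm(120), 60, 2)
  W <- matrix(runif(120, 0.1, 1), 60, 2)
  W <- W / rowSums(W)
  state <- list(pi = colMeans(W), mu = cbind(c(0.2, 0), c(-0.2, 0.1)),
                sigma = list(diag(2), diag(2)), beta = c(0, 0))
  es <- list(W = W, r = sapply(1:2, function(j)
    rowSums(sweep(x, 2, state$mu[, j])^2)))
  ms <- mlnmix:::mm_m_step(x, es, state, validate_model_name("VVV"))
  nj <- colSums(W)
  for (j in 1:2) {
    xbar <- colSums(W[, j] * x) / nj[j]
    expect_equal(ms$mu[, j], xbar, tolerance = 1e-12)
    U <- t(x) - xbar
    expect_equal(ms$sigma[[j]], (U %*% (W[, j] * t(U))) / nj[j],
                 tolerance = 1e-8)
  }
})

test_that("the MM step never decreases the expected complete log-likelihood", {
  set.seed(24)
  d <- 2; k <- 2
  worst <- Inf
  for (rep in 1:50) {
    n <- 80
    x <- rbind(rmln(n / 2, rnorm(d, -1), rspd(d), runif(1, 0, beta_max(d))),
               rmln(n / 2, rnorm(d, 1), rspd(d), runif(1, 0, beta_max(d))))
    mu <- cbind(rnorm(d, -1), rnorm(d, 1))
    sigma <- list(rspd(d), rspd(d))
    beta <- runif(k, 0, beta_max(d))
    pi <- as.vector(rexp(k)); pi <- pi / sum(pi)
    es <- e_step(x, pi, mu, sigma, beta)
    state <- list(pi = pi, mu = mu, sigma = sigma, beta = beta)
    before <- expected_complete_ll(x, es$W, pi, mu, sigma, beta)
    ms <- mlnmix:::mm_m_step(x, es, state, validate_model_name("VVV"))
    after <- expected_complete_ll(x, es$W, pi, ms$mu, ms$sigma, beta)
    worst <- min(worst, after - before)
  }
  expect_gte(worst, -1e-8)
})

test_that("MM mean update coefficients vanish at beta = 0 (A_j = 0)", {
  set.seed(25)
  x <- matrix(rnorm(60), 30, 2)
  state <- list(pi = 1, mu = matrix(c(0, 0), 2, 1), sigma = list(diag(2)),
                beta = 0)
  es <- list(W = matrix(1, 30, 1), r = matrix(rowSums(x^2), ncol = 1))
  # 2u'(r) + M = 0 identically when beta = 0, M = 1
  expect_equal(2 * u_prime(es$r[, 1], 0, 2) + bound_M(0, 2)$M,
               rep(0, 30))
})

test_that("FP step reduces to the classical update at beta = 0 and damps at beta_max", {
  set.seed(26)
  x <- matrix(rnorm(100), 50, 2)
  W <- matrix(1, 50, 1)
  state <- list(pi = 1, mu = matrix(colMeans(x) + 0.3, 2, 1),
                sigma = list(diag(2)), beta = 0)
  es <- list(W = W, r = matrix(rowSums(sweep(x, 2, state$mu[, 1])^2), ncol = 1))
  ms <- mlnmix:::fp_m_step(x, es, state, validate_model_name("VVV"))
  expect_equal(ms$mu[, 1], colMeans(x), tolerance = 1e-12)
  U <- t(x) - colMeans(x)
  expect_equal(ms$sigma[[1]], (U %*% t(U)) / 50, tolerance = 1e-10)
  # damping weight: a = 1 at beta = 0, a = 1/2 at beta_max
  a_of <- function(b, d) 1 / (1 + b * (d + 4) / (4 * d * (d + 2)))
  expect_equal(a_of(0, 3), 1)
  for (d in 1:6) expect_equal(a_of(beta_max(d), d), 0.5)
})

test_that("kappa weights are strictly positive over the admissible range", {
  for (d in c(2, 5)) {
    b <- beta_max(d)
    r <- seq(0, 200, length.out = 20001)
    kap <- 1 - 2 * b * g_poly_d1(r, d) / (1 + b * g_poly(r, d))
    expect_gt(min(kap), 0)
    # at beta = beta_max the stationary condition g''(1+beta g) = beta g'^2
    # reduces to r = (d+2) +/- 2, so the interior minimum sits at r = d + 4
    expect_equal(r[which.min(kap)], d + 4, tolerance = 0.05)
  }
})

test_that("fitting a single normal component recovers the closed-form MLE", {
  set.seed(27)
  x <- matrix(rnorm(300), 150, 2)
  f <- mln_fit(x, "EII", k = 1, n_starts = 1, seed = 1, fixed_beta = 0)
  expect_equal(as.vector(f$mu), colMeans(x), tolerance = 1e-6)
  S <- crossprod(sweep(x, 2, colMeans(x))) / 150
  expect_equal(f$sigma[[1]], mean(diag(S)) * diag(2), tolerance = 1e-6)
})

test_that("component relabeling leaves the likelihood invariant", {
  sim <- sample_design(mln_design(k = 2, d = 2, delta = 3, n = 200, seed = 31))
  f1 <- mln_fit(sim$x, "VVVE", k = 2, n_starts = 2, seed = 11)
  perm <- c(2, 1)
  ll_perm <- mln_loglik(sim$x, f1$pi[perm], f1$mu[, perm],
                        f1$sigma[perm], f1$beta[perm])
  expect_equal(ll_perm, f1$loglik, tolerance = 1e-10)
})

test_that("fit validates model/kurtosis configuration", {
  x <- matrix(rnorm(100), 50, 2)
  expect_error(mln_fit(x, "VVV", k = 1, seed = 1), "fixed_beta")
  expect_error(mln_fit(x, "VVVE", k = 1, seed = 1, fixed_beta = 1),
               "3-letter")
  expect_error(mln_fit(cbind(x, NA), "VVVE", k = 1, seed = 1), "finite")
})
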