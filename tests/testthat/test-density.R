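test_that("radial polynomial g and its derivatives have the closed-form values", {
  expect_equal(g_poly(0, 2), 1 / 8)
  expect_equal(g_poly(4, 2), -1 / (4 * 2))  # minimum -1/(4d) at r = d+2
  # zeros at (d+2) +/- sqrt(2(d+2)), checked numerically from the quadratic
  zeros <- (2 + 2) + c(-1, 1) * sqrt(2 * (2 + 2))
  expect_equal(g_poly(zeros, 2), c(0, 0), tolerance = 1e-12)
  expect_equal(zeros, c(1.171573, 6.828427), tolerance = 1e-6)
  # derivatives match central finite differences
  for (d in c(1, 3, 7)) {
    r <- c(0.3, 2, 11.5)
    fd <- (g_poly(r + 1e-6, d) - g_poly(r - 1e-6, d)) / 2e-6
    expect_equal(g_poly_d1(r, d), fd, tolerance = 1e-8)
  }
  expect_error(g_poly(1, 0), "positive integer")
})

test_that("the admissible kurtosis range is 4d(d+2)/(d+4), increasing in d", {
  expect_equal(beta_max(2), 32 / 6)
  expect_equal(beta_max(4), 12)
  expect_true(all(diff(vapply(1:30, beta_max, 0)) > 0))
})

test_that("log-density matches the normal-times-polynomial form", {
  # beta = 0 at the mode: exactly the MN log-density
  expect_equal(dmln(c(0, 0), c(0, 0), diag(2), 0, log = TRUE), -log(2 * pi))
  # at the mode for general beta: -(d/2)log(2pi) + log(1 + beta/8)
  for (d in c(1, 3, 5)) {
    b <- 0.7 * beta_max(d)
    expect_equal(dmln(rep(0, d), rep(0, d), diag(d), b, log = TRUE),
                 -(d / 2) * log(2 * pi) + log(1 + b / 8))
  }
  # beta = 0 equals dnorm-based MN density on random inputs
  set.seed(42)
  mu <- rnorm(3); Sg <- rspd(3)
  x <- matrix(rnorm(30), 10, 3)
  ld <- dmln(x, mu, Sg, 0, log = TRUE)
  R <- chol(Sg)
  z <- backsolve(R, t(x) - mu, transpose = TRUE)
  ld_mn <- -1.5 * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
  expect_equal(ld, ld_mn, tolerance = 1e-14)
})

test_that("the univariate MLN density integrates to one", {
  f <- function(x) dmln(matrix(x, ncol = 1), 0, matrix(1, 1, 1), 2.4)
  expect_equal(integrate(Vectorize(f), -Inf, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
})

test_that("u' matches finite differences of the radial log-density", {
  expect_equal(u_prime(c(0, 1, 10), 0, 2), rep(-0.5, 3))
  expect_equal(u_prime(2 + 2, 4.1, 2), -0.5)  # g' vanishes at r = d+2
  set.seed(7)
  for (i in 1:20) {
    d <- sample(1:6, 1)
    b <- runif(1, 0.1, beta_max(d))
    r <- runif(1, 0.01, 30)
    fd <- (mlnmix:::radial_logf(r + 1e-6, b, d) -
             mlnmix:::radial_logf(r - 1e-6, b, d)) / 2e-6
    expect_equal(u_prime(r, b, d), fd, tolerance = 1e-6)
  }
})

test_that("h collects the beta-dependent curvature terms; full coefficient is h - 1", {
  expect_equal(h_func(c(0, 3, 50), 0, 2), rep(0, 3))
  expect_equal(curvature_coeff(c(0, 3, 50), 0, 2), rep(-1, 3))
  # h vanishes at infinity
  expect_lt(abs(h_func(1e6, beta_max(2), 2)), 1e-4)
  # curvature_coeff = 4r u'' + 2u' via finite differences of u'
  set.seed(8)
  for (i in 1:15) {
    d <- sample(2:6, 1)
    b <- runif(1, 0.1, beta_max(d))
    r <- runif(1, 0.05, 25)
    upp <- (u_prime(r + 1e-5, b, d) - u_prime(r - 1e-5, b, d)) / 2e-5
    expect_equal(curvature_coeff(r, b, d), 4 * r * upp + 2 * u_prime(r, b, d),
                 tolerance = 1e-6)
  }
})

test_that("quartic roots are true stationary points of h", {
  for (cfg in list(c(2, beta_max(2)), c(5, beta_max(5)), c(3, 1.2))) {
    d <- cfg[1]; b <- cfg[2]
    roots <- quartic_stationary_points(b, d)
    expect_lte(length(roots), 4)
    # monic quartic residuals below 1e-8
    p0 <- -3 * d * (d + 2)^2 * (b + 8) * (b * d + 4 * b - 8 * d) / b^2
    p1 <- 8 * b * (d + 2)^2 * (b * d - b + 12 * d) / b^2
    p2 <- -6 * b * (d + 2) * (b * d - 2 * b + 16 * d) / b^2
    res <- ((roots^2 + p2) * roots + p1) * roots + p0
    expect_lt(max(abs(res)), 1e-8)
    # roots coincide with sign changes of a finite-difference derivative of h
    grid <- seq(-10, 50, by = 1e-3)
    dh <- diff(h_func(grid, b, d))
    sc <- grid[which(diff(sign(dh)) != 0) + 1]
    inside <- roots[roots > -10 & roots < 50]
    expect_equal(length(inside), length(sc))
    expect_equal(sort(inside), sort(sc), tolerance = 1e-2)
  }
  expect_error(quartic_stationary_points(0, 2), "degenerates")
})

test_that("bound M equals the dense-grid infimum of the curvature coefficient", {
  expect_equal(bound_M(0, 2)$M, 1)
  expect_equal(bound_M(0, 7)$M, 1)
  for (cfg in list(c(2, beta_max(2)), c(5, beta_max(5)))) {
    d <- cfg[1]; b <- cfg[2]
    grid <- seq(0, 1000, by = 1e-3)
    expect_equal(bound_M(b, d)$M, abs(min(curvature_coeff(grid, b, d))),
                 tolerance = 1e-6)
  }
})

test_that("the quadratic surrogate minorizes the log-density and touches at z0", {
  set.seed(9)
  d <- 2; b <- beta_max(2)
  for (i in 1:200) {
    z0 <- rnorm(d, sd = 2); z <- rnorm(d, sd = 2)
    gap <- mlnmix:::radial_logf(sum(z^2), b, d) -
      mlnmix:::quad_minorizer(z, z0, b, d)
    expect_gte(gap, -1e-10)
    touch <- mlnmix:::radial_logf(sum(z0^2), b, d) -
      mlnmix:::quad_minorizer(z0, z0, b, d)
    expect_lt(abs(touch), 1e-10)
  }
  # first-order surrogate agrees with log f and its derivative at z0
  set.seed(10)
  for (i in 1:20) {
    d <- sample(1:4, 1); b <- runif(1, 0.2, beta_max(d))
    r0 <- runif(1, 0.1, 15)
    sur <- function(r) mlnmix:::radial_logf(r0, b, d) +
      u_prime(r0, b, d) * (r - r0)
    expect_equal(sur(r0), mlnmix:::radial_logf(r0, b, d))
    fd_sur <- (sur(r0 + 1e-6) - sur(r0 - 1e-6)) / 2e-6
    fd_log <- (mlnmix:::radial_logf(r0 + 1e-6, b, d) -
                 mlnmix:::radial_logf(r0 - 1e-6, b, d)) / 2e-6
    expect_equal(fd_sur, fd_log, tolerance = 1e-6)
  }
})

test_that("density positivity: 1 + beta g(r) >= 2/(d+4) over the admissible range", {
  for (d in 1:8) {
    b <- beta_max(d)
    r <- seq(0, 500, length.out = 2000)
    expect_gte(min(1 + b * g_poly(r, d)), 2 / (d + 4) - 1e-12)
  }
})

test_that("radial CDF is a proper, nondecreasing distribution function", {
  for (cfg in list(c(2, beta_max(2)), c(4, 3), c(1, 1.5))) {
    d <- cfg[1]; b <- cfg[2]
    # signed weights sum to one
    expect_equal((1 + b / 8) - b / 4 + b / 8, 1)
    r <- seq(0, 80, length.out = 500)
    Fv <- mln_radial_cdf(r, b, d)
    expect_true(all(diff(Fv) >= -1e-12))
    expect_equal(mln_radial_cdf(0, b, d), 0)
    expect_gt(mln_radial_cdf(200, b, d), 1 - 1e-10)
    # quantile inverts the CDF
    p <- c(0.05, 0.3, 0.7, 0.99)
    q <- mln_radial_quantile(p, b, d)
    expect_equal(mln_radial_cdf(q, b, d), p, tolerance = 1e-9)
  }
})

test_that("MLN sampling reproduces the moment identities", {
  d <- 2; b <- beta_max(2)
  mu <- c(1, 2); Sg <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  X <- rmln(1e5, mu, Sg, b, seed = 42)
  # mean and covariance within 3 standard errors
  se_mu <- sqrt(diag(Sg) / 1e5)
  expect_true(all(abs(colMeans(X) - mu) < 3 * se_mu))
  expect_lt(max(abs(cov(X) - Sg)), 0.03)
  # E[r^2] = d(d+2) + beta
  z <- backsolve(chol(Sg), t(X) - mu, transpose = TRUE)
  r2 <- colSums(z^2)^2
  expect_lt(abs(mean(r2) - (d * (d + 2) + b)) / (sd(r2) / sqrt(1e5)), 3.5)
  # beta = 0 reduces to the multivariate normal: radial KS test against chi^2_d
  X0 <- rmln(1e4, rep(0, 3), diag(3), 0, seed = 7)
  r0 <- rowSums(X0^2)
  expect_gt(suppressWarnings(ks.test(r0, pchisq, df = 3))$p.value, 0.01)
  # reproducibility
  expect_identical(rmln(50, mu, Sg, b, seed = 5), rmln(50, mu, Sg, b, seed = 5))
  expect_error(rmln(10, mu, Sg, beta_max(2) + 1), "beta")
})
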