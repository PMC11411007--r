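#' The multivariate leptokurtic-normal (MLN) distribution
#'
#' The MLN density is the multivariate normal density multiplied by the
#' polynomial factor \eqn{1 + \beta g(r)}, where \eqn{r} is the squared
#' Mahalanobis distance and \eqn{\beta \ge 0} is exactly the excess kurtosis.
#' It arises from a multivariate Gram-Charlier expansion of the normal and is
#' elliptical, unimodal and nonnegative for
#' \eqn{\beta \in [0, 4d(d+2)/(d+4)]}.
#'
#' @name mln-distribution
#' @keywords internal
NULL

#' Radial polynomial of the MLN density
#'
#' \code{g_poly} evaluates \eqn{g(r) = [r^2 - 2(d+2)r + d(d+2)] / [8d(d+2)]},
#' the quadratic that multiplies the excess kurtosis in the MLN density.
#' \code{g_poly_d1} is its first derivative \eqn{(r - (d+2))/(4d(d+2))} and
#' \code{g_poly_d2} the constant second derivative \eqn{1/(4d(d+2))}.
#'
#' @param r Nonnegative squared Mahalanobis distance(s).
#' @param d Dimension (positive integer).
#' @return Numeric vector of the same length as \code{r}.
#' @examples
#' g_poly(0, d = 2)       # 1/8
#' g_poly(4, d = 2)       # -1/(4*2), the minimum
#' @export
g_poly <- function(r, d) {
  check_dim(d)
  (r^2 - 2 * (d + 2) * r + d * (d + 2)) / (8 * d * (d + 2))
}

#' @rdname g_poly
#' @export
g_poly_d1 <- function(r, d) {
  check_dim(d)
  (r - (d + 2)) / (4 * d * (d + 2))
}

#' @rdname g_poly
#' @export
g_poly_d2 <- function(d) {
  check_dim(d)
  1 / (4 * d * (d + 2))
}

#' Largest admissible excess kurtosis
#'
#' The MLN density is nonnegative and unimodal for
#' \eqn{\beta \in [0, 4d(d+2)/(d+4)]}; this returns the upper endpoint.
#'
#' @param d Dimension (positive integer).
#' @return The bound \eqn{4d(d+2)/(d+4)}.
#' @examples
#' beta_max(2)  # 16/3
#' beta_max(4)  # 12
#' @export
beta_max <- function(d) {
  check_dim(d)
  4 * d * (d + 2) / (d + 4)
}

# unchecked fast paths for EM hot loops
g_fast <- function(r, d) (r^2 - 2 * (d + 2) * r + d * (d + 2)) / (8 * d * (d + 2))
g1_fast <- function(r, d) (r - (d + 2)) / (4 * d * (d + 2))

check_dim <- function(d) {
  if (length(d) != 1L || !is.finite(d) || d < 1 || d != round(d))
    stop("'d' must be a positive integer dimension", call. = FALSE)
  invisible(d)
}

check_beta <- function(beta, d) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > beta_max(d) + 1e-10)
    stop(sprintf("'beta' must lie in [0, %.6f] for d = %d", beta_max(d), d),
         call. = FALSE)
  invisible(beta)
}

#' MLN (log-)density
#'
#' Evaluates the density of the multivariate leptokurtic-normal distribution,
#' \eqn{f(x) = \{1 + \beta g(r)\}\,\phi(x \mid \mu, \Sigma)} with
#' \eqn{r = (x-\mu)^\top \Sigma^{-1} (x-\mu)}.
#'
#' @param x Numeric vector of length \code{d}, or an \code{n x d} matrix of
#'   observations in rows.
#' @param mu Mean vector (length \code{d}).
#' @param sigma Symmetric positive-definite covariance matrix (\code{d x d}).
#' @param beta Excess kurtosis, in \code{[0, beta_max(d)]}.
#' @param log Logical; return the log-density?
#' @return Numeric vector of length \code{n}.
#' @export
dmln <- function(x, mu, sigma, beta = 0, log = FALSE) {
  x <- as_row_matrix(x, length(mu))
  d <- length(mu)
  check_beta(beta, d)
  R <- chol_pd(sigma)
  z <- backsolve(R, t(x) - mu, transpose = TRUE)  # R^T z = (x - mu)^T
  r <- colSums(z^2)
  ld <- -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * r +
    log1p(beta * g_poly(r, d))
  if (log) ld else exp(ld)
}

as_row_matrix <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop("length(x) must equal length(mu)", call. = FALSE)
    matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d) stop("ncol(x) must equal length(mu)", call. = FALSE)
    x
  }
}

# Cholesky factor with an informative failure for non-PD input.
chol_pd <- function(sigma, context = "covariance matrix") {
  out <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(out))
    stop(sprintf("%s is not symmetric positive definite", context), call. = FALSE)
  out
}

#' First derivative of the radial log-density
#'
#' Returns \eqn{u'(r) = \beta g'(r)/[1 + \beta g(r)] - 1/2}, the derivative of
#' the MLN log-density with respect to the squared Mahalanobis distance.
#'
#' @inheritParams g_poly
#' @param beta Excess kurtosis.
#' @export
u_prime <- function(r, beta, d) {
  check_beta(beta, d)
  beta * g_poly_d1(r, d) / (1 + beta * g_poly(r, d)) - 0.5
}

#' Curvature trace function of the radial log-density
#'
#' \code{h_func} is the three-term function
#' \eqn{h(r) = 4r\,\beta g''/(1+\beta g) - 4r\,[\beta g'/(1+\beta g)]^2 +
#' 2\beta g'/(1+\beta g)}, which collects the \eqn{\beta}-dependent part of the
#' directional-curvature coefficient of the log-density along the radial
#' direction. \code{curvature_coeff} is the full coefficient
#' \eqn{4r\,u''(r) + 2u'(r) = h(r) - 1}; its infimum over \eqn{r \ge 0} sets
#' the quadratic-minorizer bound (see \code{\link{bound_M}}).
#'
#' @inheritParams u_prime
#' @export
h_func <- function(r, beta, d) {
  check_beta(beta, d)
  q <- 1 + beta * g_poly(r, d)
  gp <- beta * g_poly_d1(r, d) / q
  gpp <- beta * g_poly_d2(d) / q
  4 * r * gpp - 4 * r * gp^2 + 2 * gp
}

#' @rdname h_func
#' @export
curvature_coeff <- function(r, beta, d) {
  h_func(r, beta, d) - 1
}

#' Stationary points of the curvature trace function
#'
#' The stationary points of \code{\link{h_func}} (equivalently of
#' \code{\link{curvature_coeff}}) in \eqn{r} are the real roots of a depressed
#' quartic in \eqn{r}; this solves that quartic.  Roots are found with
#' \code{\link[base]{polyroot}} and polished by Newton iteration so that the
#' monic quartic residual is below \code{1e-8}; complex-pair roots are
#' discarded.
#'
#' @param beta Excess kurtosis, strictly positive (the quartic degenerates at
#'   \code{beta = 0}; callers must special-case it).
#' @param d Dimension.
#' @return Sorted numeric vector of real roots (possibly empty, at most 4).
#' @export
quartic_stationary_points <- function(beta, d) {
  check_dim(d)
  if (!is.finite(beta) || beta <= 0)
    stop("the stationary-point quartic degenerates at beta = 0", call. = FALSE)
  c0 <- -3 * d * (d + 2)^2 * (beta + 8) * (beta * d + 4 * beta - 8 * d)
  c1 <- 8 * beta * (d + 2)^2 * (beta * d - beta + 12 * d)
  c2 <- -6 * beta * (d + 2) * (beta * d - 2 * beta + 16 * d)
  c4 <- beta^2
  # monic form: r^4 + p2 r^2 + p1 r + p0
  p0 <- c0 / c4; p1 <- c1 / c4; p2 <- c2 / c4
  rts <- polyroot(c(p0, p1, p2, 0, 1))
  keep <- abs(Im(rts)) < 1e-7 * (1 + abs(Re(rts)))
  x <- Re(rts[keep])
  # Newton polish on the monic quartic
  for (i in seq_len(6)) {
    fx <- ((x^2 + p2) * x + p1) * x + p0
    dfx <- (4 * x^2 + 2 * p2) * x + p1
    step <- ifelse(abs(dfx) > 0, fx / dfx, 0)
    x <- x - step
  }
  sort(unique(x))
}

#' Quadratic-minorizer curvature bound M
#'
#' The MLN log-density, viewed as a function of the standardized residual
#' \eqn{z}, has Hessian bounded below by \eqn{-M I_d}, where \eqn{M} is the
#' absolute value of the infimum of the curvature coefficient
#' \eqn{4r\,u''(r) + 2u'(r)} over \eqn{r \ge 0}.  The infimum is attained
#' either at \eqn{r = 0} or at a nonnegative stationary point (a real root of
#' the depressed quartic); beyond the largest root the coefficient increases
#' monotonically to \eqn{-1}.  At \code{beta = 0} the coefficient is the
#' constant \eqn{-1} and \code{M = 1}.
#'
#' @inheritParams quartic_stationary_points
#' @param beta Excess kurtosis in \code{[0, beta_max(d)]}.
#' @return A list with components \code{roots} (real stationary points) and
#'   \code{M} (the nonnegative bound).
#' @export
bound_M <- function(beta, d) {
  check_beta(beta, d)
  if (beta == 0)
    return(list(roots = numeric(0), M = 1))
  roots <- quartic_stationary_points(beta, d)
  cand <- c(0, roots[roots >= 0])
  list(roots = roots, M = abs(min(curvature_coeff(cand, beta, d))))
}

# Unnormalized radial log-density log{1 + beta g(r)} - r/2 (constants dropped);
# shared by the minorizer/surrogate helpers and their tests.
radial_logf <- function(r, beta, d) {
  log1p(beta * g_poly(r, d)) - r / 2
}

#' Quadratic minorizer of the MLN log-density
#'
#' Evaluates the quadratic minorizer of \eqn{\log f(z^\top z)} (normalizing
#' constants dropped) built from the curvature bound \code{M}, expanded at
#' \code{z0}:
#' \deqn{C_0 + [2u'(r_0) + M]\, z_0^\top z - (M/2)\, z^\top z,}
#' with \eqn{C_0 = \log f(r_0) - 2u'(r_0) r_0 - (M/2) r_0}.  The minorizer
#' touches the log-density at \code{z = z0} and lies below it everywhere.
#'
#' @param z,z0 Standardized residual vectors of length \code{d}.
#' @param beta Excess kurtosis.
#' @param d Dimension.
#' @return Scalar value of the minorizer (same constant offset as
#'   \code{radial} log-density with constants dropped).
#' @keywords internal
quad_minorizer <- function(z, z0, beta, d) {
  r0 <- sum(z0^2)
  M <- bound_M(beta, d)$M
  up0 <- u_prime(r0, beta, d)
  C0 <- radial_logf(r0, beta, d) - 2 * up0 * r0 - (M / 2) * r0
  C0 + (2 * up0 + M) * sum(z0 * z) - (M / 2) * sum(z^2)
}

#' Sample from the MLN distribution
#'
#' Exact sampling via the stochastic representation of elliptical laws:
#' the squared radius \eqn{r} follows the signed chi-square mixture with CDF
#' \deqn{F(r) = (1+\beta/8) F_{\chi^2_d}(r) - (\beta/4) F_{\chi^2_{d+2}}(r) +
#'   (\beta/8) F_{\chi^2_{d+4}}(r),}
#' inverted numerically (vectorized bisection to tolerance below 1e-12);
#' the direction is uniform on the unit sphere; then
#' \eqn{x = \mu + \sqrt{r}\, \Sigma^{1/2} u}.
#'
#' @param n Number of draws.
#' @param mu Mean vector.
#' @param sigma Covariance matrix.
#' @param beta Excess kurtosis in \code{[0, beta_max(d)]}.
#' @param seed Optional integer seed set before drawing (for convenience;
#'   otherwise the generator respects the global RNG state).
#' @return An \code{n x d} matrix of draws.
#' @export
rmln <- function(n, mu, sigma, beta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(mu)
  check_beta(beta, d)
  R <- chol_pd(sigma)
  u <- runif(n)
  r <- mln_radial_quantile(u, beta, d)
  z <- matrix(rnorm(n * d), n, d)
  z <- z / sqrt(rowSums(z^2))
  sweep(sqrt(r) * (z %*% R), 2, mu, `+`)
}

#' Radial CDF and quantile of the MLN squared radius
#'
#' \code{mln_radial_cdf} evaluates the signed chi-square mixture CDF of the
#' squared Mahalanobis radius; \code{mln_radial_quantile} inverts it by
#' monotone bisection on a guaranteed bracket.
#'
#' @param r,p Evaluation points (radii / probabilities).
#' @inheritParams u_prime
#' @export
mln_radial_cdf <- function(r, beta, d) {
  check_beta(beta, d)
  (1 + beta / 8) * pchisq(r, d) - (beta / 4) * pchisq(r, d + 2) +
    (beta / 8) * pchisq(r, d + 4)
}

#' @rdname mln_radial_cdf
#' @export
mln_radial_quantile <- function(p, beta, d) {
  check_beta(beta, d)
  hi0 <- qchisq(1 - 1e-13, d + 4)
  while (mln_radial_cdf(hi0, beta, d) < max(p)) hi0 <- hi0 * 2
  lo <- rep(0, length(p))
  hi <- rep(hi0, length(p))
  for (i in seq_len(70)) {
    mid <- (lo + hi) / 2
    below <- mln_radial_cdf(mid, beta, d) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}
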