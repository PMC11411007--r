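#' Equicorrelation scale matrix
#'
#' \eqn{\Xi_d(\rho) = (1-\rho) I_d + \rho J_d}, SPD for
#' \eqn{\rho \in [0, 1)}; eigenvalues \eqn{1 + (d-1)\rho} (once) and
#' \eqn{1-\rho} (\eqn{d-1} times).
#'
#' @param rho Equicorrelation in \code{[0, 1)}.
#' @param d Dimension.
#' @export
xi_matrix <- function(rho, d) {
  check_dim(d)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  (1 - rho) * diag(d) + rho * matrix(1, d, d)
}

#' Simulation design for MLN mixture experiments
#'
#' Describes a \eqn{k}-component MLN mixture data-generating setup indexed by
#' the separation \eqn{\delta}, volume factor \eqn{\lambda}, equicorrelation
#' \eqn{\rho}, dimension \eqn{d} and sample size \eqn{n}; all component
#' excess kurtoses are fixed at the maximum \eqn{4d(d+2)/(d+4)}.  The
#' \eqn{(\lambda, \rho)} pairs (1,0), (2,0), (1,0.5), (2,0.5) generate,
#' respectively, EIIE, VIIE, EEEE and VEEE structural truths.  The
#' four-component design places means at the corners
#' \eqn{\delta(\pm 1, \pm 1)} built from two stacked sign blocks of length
#' \eqn{d/2}, so it requires even \eqn{d}.
#'
#' @param k Number of components (2, 3, or 4).
#' @param d Dimension (even when \code{k = 4}).
#' @param delta Separation between component means.
#' @param lambda Volume factor (> 0).
#' @param rho Equicorrelation in \code{[0, 1)}.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return An object of class \code{"mln_design"}.
#' @export
mln_design <- function(k, d, delta, lambda = 1, rho = 0, n = 500, seed = 1L) {
  if (!k %in% 2:4) stop("'k' must be 2, 3, or 4", call. = FALSE)
  check_dim(d)
  if (k == 4 && d %% 2 != 0)
    stop("the four-component design requires even 'd'", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive")
  xi_matrix(rho, d)  # validates rho
  structure(list(k = k, d = d, delta = delta, lambda = lambda, rho = rho,
                 n = n, seed = as.integer(seed)),
            class = "mln_design")
}

#' Build the mixture parameters of a simulation design
#'
#' Expands an \code{\link{mln_design}} into explicit mixture parameters:
#' equal weights; means \eqn{(3-2j)\delta 1_d} (k = 2), \eqn{(j-2)\delta 1_d}
#' (k = 3) or stacked sign blocks (k = 4); covariances
#' \eqn{\lambda^{e_j}\,\Xi_d(\rho)} with volume exponents (1, -1), (-1, 0, 1)
#' and (-1, 0, 0, 1); excess kurtoses at \code{beta_max(d)}.
#'
#' @param design An \code{"mln_design"}.
#' @return List with \code{pi}, \code{mu} (\code{d x k}), \code{sigma}
#'   (list), \code{beta}.
#' @export
build_theta <- function(design) {
  stopifnot(inherits(design, "mln_design"))
  k <- design$k; d <- design$d
  Xi <- xi_matrix(design$rho, d)
  ones <- rep(1, d)
  mu <- switch(as.character(k),
    "2" = sapply(1:2, function(j) (3 - 2 * j) * design$delta * ones),
    "3" = sapply(1:3, function(j) (j - 2) * design$delta * ones),
    "4" = sapply(1:4, function(j) {
      half <- rep(1, d / 2)
      design$delta * c((-1)^j * half, (-1)^floor((j + 1) / 2) * half)
    }))
  expo <- switch(as.character(k),
    "2" = c(1, -1),                 # lambda^{3-2j}
    "3" = (1:3) - 2,                # lambda^{j-2}
    "4" = floor((1:4) / 2 - 1))     # lambda^{floor(j/2-1)}
  sigma <- lapply(expo, function(e) design$lambda^e * Xi)
  list(pi = rep(1 / k, k), mu = matrix(mu, nrow = d), sigma = sigma,
       beta = rep(beta_max(d), k))
}

#' Sample a dataset from an MLN simulation design
#'
#' Component labels are multinomial with the design's weights; observations
#' are exact MLN draws (\code{\link{rmln}}).  A pure function of
#' (design, seed): identical seeds give identical output.
#'
#' @param design An \code{"mln_design"}.
#' @return List with \code{x} (\code{n x d} matrix), \code{labels} (integer
#'   vector), and \code{theta} (the generating parameters).
#' @export
sample_design <- function(design) {
  theta <- build_theta(design)
  set.seed(design$seed)
  lab <- sample.int(design$k, design$n, replace = TRUE, prob = theta$pi)
  x <- matrix(0, design$n, design$d)
  for (j in seq_len(design$k)) {
    idx <- which(lab == j)
    if (length(idx))
      x[idx, ] <- rmln(length(idx), theta$mu[, j], theta$sigma[[j]],
                       theta$beta[j])
  }
  list(x = x, labels = lab, theta = theta)
}

#' Sample from a two-component multivariate-t mixture
#'
#' Misspecification generator: equal weights, means \eqn{\mp 3 \cdot 1_d},
#' identity scale matrices, common degrees of freedom \eqn{\nu}.  Uses the
#' standard construction \eqn{x = \mu + z / \sqrt{w/\nu}},
#' \eqn{w \sim \chi^2_\nu}.
#'
#' @param nu Degrees of freedom (> 0).
#' @param d Dimension.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return List with \code{x} and \code{labels}.
#' @export
sample_t_mixture <- function(nu, d, n, seed = 1L) {
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive", call. = FALSE)
  check_dim(d)
  set.seed(seed)
  lab <- sample.int(2L, n, replace = TRUE)
  mu <- cbind(rep(-3, d), rep(3, d))
  z <- matrix(rnorm(n * d), n, d)
  w <- rchisq(n, nu)
  x <- t(mu[, lab]) + z / sqrt(w / nu)
  list(x = x, labels = lab)
}

#' Generalized inverse Gaussian variates
#'
#' Samples from the GIG law with density proportional to
#' \eqn{w^{\lambda-1} \exp\{-\omega (w + 1/w)/2\}} on \eqn{(0, \infty)}
#' (symmetric \eqn{\chi = \psi = \omega} parameterization), by the
#' ratio-of-uniforms method: the bounding rectangle is computed in closed
#' form from the modes of \eqn{f} and \eqn{x^2 f(x)} (both GIG modes), and
#' acceptance is tested on the log scale so no overflow can occur.
#'
#' @param n Number of draws.
#' @param lambda GIG index (tail parameter; any real).
#' @param omega Concentration (> 0).
#' @param max_rounds Rejection-round cap; exceeding it raises an error.
#' @return Numeric vector of positive draws.
#' @export
rgig <- function(n, lambda, omega = 1, max_rounds = 1000L) {
  if (!is.finite(omega) || omega <= 0) stop("'omega' must be positive")
  logf <- function(x) (lambda - 1) * log(x) - omega * (x + 1 / x) / 2
  gig_mode <- function(l) ((l - 1) + sqrt((l - 1)^2 + omega^2)) / omega
  m  <- gig_mode(lambda)        # mode of f
  m2 <- gig_mode(lambda + 2)    # mode of x^2 f(x)
  log_umax <- logf(m) / 2
  log_vmax <- log(m2) + logf(m2) / 2
  out <- numeric(0)
  for (round in seq_len(max_rounds)) {
    need <- n - length(out)
    if (need <= 0) break
    nb <- max(2L * need, 100L)
    u <- runif(nb); v <- runif(nb)
    x <- exp(log_vmax + log(v) - log_umax - log(u))
    acc <- 2 * (log_umax + log(u)) <= logf(x)
    out <- c(out, x[acc])
  }
  if (length(out) < n)
    stop("GIG rejection sampler exceeded its round cap", call. = FALSE)
  out[seq_len(n)]
}

#' Sample from a two-component generalized-hyperbolic mixture
#'
#' Misspecification generator: equal weights, means \eqn{\mp 3 \cdot 1_d},
#' identity scale, GIG index \eqn{\lambda} shared, concentration
#' \eqn{\omega = 1}, and skewness vectors
#' \eqn{(\alpha_1, \alpha_2) = \alpha(-1_d, 0_d)} — component 1 is skewed,
#' component 2 is elliptically symmetric.  Draws use the normal
#' mean-variance mixture representation
#' \eqn{x = \mu + w\,\alpha + \sqrt{w}\, z}, \eqn{w \sim} GIG.
#'
#' @param lambda GIG index (tail behavior).
#' @param alpha Skewness scalar.
#' @param d Dimension.
#' @param n Sample size.
#' @param omega GIG concentration (default 1).
#' @param seed Integer seed.
#' @return List with \code{x} and \code{labels}.
#' @export
sample_ghd_mixture <- function(lambda, alpha, d, n, omega = 1, seed = 1L) {
  check_dim(d)
  set.seed(seed)
  lab <- sample.int(2L, n, replace = TRUE)
  mu <- cbind(rep(-3, d), rep(3, d))
  skew <- cbind(rep(-alpha, d), rep(0, d))
  w <- rgig(n, lambda, omega)
  z <- matrix(rnorm(n * d), n, d)
  x <- t(mu[, lab]) + w * t(skew[, lab]) + sqrt(w) * z
  list(x = x, labels = lab)
}
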