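#' @section EM engine:
#' Maximum-likelihood fitting alternates an exact E-step (posterior
#' responsibilities) with M-steps for the weights, the excess kurtosis
#' (guarded Newton with a 1-D fallback), and the means/covariances via either
#' the MM minorizer (monotone by construction) or the damped fixed-point
#' surrogate.  Aitken acceleration on the log-likelihood sequence is the
#' stopping rule.
#' @name em-engine
#' @keywords internal
NULL

# Per-component Mahalanobis distances and log-densities for all observations.
component_stats <- function(x, mu, sigma, beta) {
  n <- nrow(x); d <- ncol(x); k <- ncol(mu)
  tx <- t(x)
  r <- matrix(0, n, k); ld <- matrix(0, n, k)
  for (j in seq_len(k)) {
    R <- chol_pd(sigma[[j]], context = sprintf("component %d covariance", j))
    z <- backsolve(R, tx - mu[, j], transpose = TRUE)
    r[, j] <- colSums(z^2)
    ld[, j] <- -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * r[, j] +
      log1p(beta[j] * g_fast(r[, j], d))
  }
  list(r = r, ld = ld)
}

#' E-step: responsibilities and observed log-likelihood
#'
#' Computes \eqn{w_{ij} \propto \pi_j f(x_i \mid \mu_j, \Sigma_j, \beta_j)}
#' with rows normalized, using log-sum-exp stabilization, together with the
#' observed log-likelihood \eqn{\sum_i \log \sum_j \pi_j f(x_i \mid \cdot)}.
#'
#' @param x Data matrix (\code{n x d}).
#' @param pi Mixing weights (length \code{k}).
#' @param mu Matrix of component means (\code{d x k}).
#' @param sigma List of \code{k} SPD covariance matrices.
#' @param beta Vector of \code{k} excess kurtoses.
#' @return List with \code{W} (\code{n x k} responsibilities),
#'   \code{loglik}, and the per-component squared Mahalanobis distances
#'   \code{r} (reused by the M-step).
#' @export
e_step <- function(x, pi, mu, sigma, beta) {
  cs <- component_stats(x, mu, sigma, beta)
  L <- sweep(cs$ld, 2, log(pi), `+`)
  mrow <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  bad <- !is.finite(mrow)
  if (any(bad))
    stop(sprintf("density underflow for observation(s) %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  lse <- mrow + log(rowSums(exp(L - mrow)))
  list(W = exp(L - lse), loglik = sum(lse), r = cs$r)
}

#' Mixing-weight update
#'
#' \eqn{\pi_j = n_j / n} with \eqn{n_j = \sum_i w_{ij}}.  A component whose
#' effective count falls below \eqn{d + 1} is flagged with a warning (the
#' fitting loop treats it as a degenerate start).
#'
#' @param W Responsibility matrix.
#' @param d Dimension (for the degeneracy warning threshold); optional.
#' @return Vector of mixing weights.
#' @export
update_pi <- function(W, d = NULL) {
  nj <- colSums(W)
  if (!is.null(d) && any(nj < d + 1))
    warning("degenerate component: effective count below d + 1", call. = FALSE)
  nj / nrow(W)
}

#' Excess-kurtosis update
#'
#' Updates \eqn{\beta_j} (per component, or a single shared \eqn{\beta}) by
#' the self-concordance-motivated Newton-type step
#' \eqn{\beta^+ = \beta + \sum w\gamma / \sum w\gamma^2} with
#' \eqn{\gamma_i = \beta g(r_i)/[1+\beta g(r_i)]}, clamped to
#' \eqn{[0, \beta_{\max}(d)]}.  The step is accepted only if it increases the
#' weighted log-likelihood term \eqn{\sum_i w_i \log[1+\beta g(r_i)]}
#' (which is concave in \eqn{\beta}); otherwise — including the degenerate
#' \eqn{\beta = 0} start where \eqn{\gamma \equiv 0} — a bracketed 1-D
#' maximization over the admissible range is used.
#'
#' @param r Matrix of squared Mahalanobis distances (\code{n x k}).
#' @param W Responsibility matrix (\code{n x k}).
#' @param beta Current kurtosis vector (length \code{k}).
#' @param shared Logical: single \eqn{\beta} across components?
#' @param d Dimension.
#' @return Updated kurtosis vector (length \code{k}; identical entries when
#'   \code{shared}).
#' @export
update_beta <- function(r, W, beta, shared, d) {
  bmax <- beta_max(d)
  g <- g_fast(r, d)
  obj <- function(b, cols) sum(W[, cols, drop = FALSE] *
                                 log1p(b * g[, cols, drop = FALSE]))
  newton_or_search <- function(b0, cols) {
    b <- b0
    for (it in seq_len(50L)) {
      gmat <- g[, cols, drop = FALSE]
      gam <- b * gmat / (1 + b * gmat)
      num <- sum(W[, cols, drop = FALSE] * gam)
      den <- sum(W[, cols, drop = FALSE] * gam^2)
      if (den <= 0) break                       # gamma = 0/0 guard (beta = 0)
      prop <- min(max(b + num / den, 0), bmax)
      if (obj(prop, cols) < obj(b, cols)) break # ascent guard tripped
      moved <- abs(prop - b)
      b <- prop
      if (moved < 1e-9 * (1 + b)) return(b)
    }
    cand <- optimize(function(bb) obj(bb, cols), c(0, bmax),
                     maximum = TRUE, tol = 1e-8)$maximum
    cand <- c(cand, 0, bmax, b, b0)
    cand[which.max(vapply(cand, obj, 0, cols = cols))]
  }
  k <- ncol(r)
  if (shared) {
    rep(newton_or_search(beta[1], seq_len(k)), k)
  } else {
    vapply(seq_len(k), function(j) newton_or_search(beta[j], j), 0)
  }
}

#' Aitken-accelerated convergence check
#'
#' From the last three log-likelihoods computes the Aitken ratio
#' \eqn{a = (l_{q+1}-l_q)/(l_q-l_{q-1})} and the extrapolated limit
#' \eqn{l_\infty = l_q + (l_{q+1}-l_q)/(1-a)}; convergence is declared when
#' \eqn{0 \le l_\infty - l_{q+1} < tol}.  A ratio \eqn{a \ge 1} (diverging
#' gaps) is never converged; a zero denominator (flat trace) falls back to
#' the successive-change criterion.
#'
#' @param trace Numeric vector; the last three entries are used.
#' @param tol Tolerance (default \code{1e-6}).
#' @return Logical.
#' @export
aitken_converged <- function(trace, tol = 1e-6) {
  stopifnot(length(trace) >= 3)
  l <- utils::tail(trace, 3)
  den <- l[2] - l[1]
  if (den == 0) return(abs(l[3] - l[2]) < tol)
  a <- (l[3] - l[2]) / den
  if (!is.finite(a) || a >= 1) return(FALSE)
  linf <- l[2] + (l[3] - l[2]) / (1 - a)
  gap <- linf - l[3]
  (gap >= 0) && (gap < tol)
}

# ---- M-steps --------------------------------------------------------------

# MM minorizer M-step for (mu_j, Sigma_j).  `es` is the E-step output.
mm_m_step <- function(x, es, state, m, fp_weight = NULL) {
  W <- es$W; r <- es$r
  n <- nrow(x); d <- ncol(x); k <- ncol(W)
  tx <- t(x)
  nj <- colSums(W)
  A <- vector("list", k); B <- vector("list", k)
  mu_new <- state$mu
  M <- vapply(state$beta, function(b) bound_M(b, d)$M, 0)
  for (j in seq_len(k)) {
    w <- W[, j]
    cij <- 2 * u_prime(r[, j], state$beta[j], d) + M[j]    # 0 when beta = 0
    V <- tx - state$mu[, j]                                # d x n, old mean
    xbar <- colSums(w * x) / nj[j]
    mu_new[, j] <- xbar - (V %*% (w * cij)) / (M[j] * nj[j])
    U <- tx - mu_new[, j]                                  # d x n, new mean
    e <- eigen((state$sigma[[j]] + t(state$sigma[[j]])) / 2, symmetric = TRUE)
    isq <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    # A_j = sum_i w c (x_i - mu^+) z_i',  z_i = Sigma^{-1/2} (x_i - mu_old)
    A[[j]] <- (U %*% (w * cij * t(V))) %*% isq
    B[[j]] <- M[j] * (U %*% (w * t(U)))
  }
  sigma_new <- mm_cov_update(m, nj, A, B, sigma0 = state$sigma)
  list(mu = mu_new, sigma = sigma_new)
}

# Damped fixed-point M-step for (mu_j, Sigma_j).
fp_m_step <- function(x, es, state, m, fp_weight = NULL) {
  W <- es$W; r <- es$r
  d <- ncol(x); k <- ncol(W)
  tx <- t(x)
  nj <- colSums(W)
  mu_new <- state$mu
  S <- vector("list", k)
  for (j in seq_len(k)) {
    b <- state$beta[j]
    kap <- 1 - 2 * b * g1_fast(r[, j], d) / (1 + b * g_fast(r[, j], d))
    wk <- W[, j] * kap
    den <- sum(wk)
    if (den <= 0)
      stop("nonpositive kappa-weight total; kappa must be positive",
           call. = FALSE)
    mu_new[, j] <- colSums(wk * x) / den
    U <- tx - mu_new[, j]
    Rj <- (U %*% (wk * t(U))) / nj[j]
    a <- if (is.null(fp_weight)) 1 / (1 + b * (d + 4) / (4 * d * (d + 2)))
         else fp_weight
    S[[j]] <- (1 - a) * state$sigma[[j]] + a * Rj
  }
  sigma_new <- fp_cov_update(m, S, nj, sigma_init = state$sigma)
  list(mu = mu_new, sigma = sigma_new)
}

# ---- fitting --------------------------------------------------------------

degenerate <- function(msg) {
  structure(class = c("mln_degenerate", "condition"),
            list(message = msg, call = NULL))
}

run_em <- function(x, m, k, W0, algorithm, max_iter, tol,
                   fixed_beta, fp_weight) {
  n <- nrow(x); d <- ncol(x)
  shared_beta <- identical(m$kurtosis, "E")
  nj <- colSums(W0)
  if (any(nj < d + 1)) stop(degenerate("initial component too small"))
  mu <- sapply(seq_len(k), function(j) colSums(W0[, j] * x) / nj[j])
  mu <- matrix(mu, nrow = d)
  S0 <- lapply(seq_len(k), function(j) {
    U <- t(x) - mu[, j]
    (U %*% (W0[, j] * t(U))) / nj[j]
  })
  sigma <- fp_cov_update(m, S0, nj)
  beta <- rep(if (is.null(fixed_beta)) 0 else fixed_beta, k)
  pi <- nj / n
  state <- list(pi = pi, mu = mu, sigma = sigma, beta = beta)
  m_step_fun <- if (algorithm == "mm") mm_m_step else fp_m_step

  trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (q in seq_len(max_iter)) {
    es <- tryCatch(
      e_step(x, state$pi, state$mu, state$sigma, state$beta),
      error = function(e) stop(degenerate(conditionMessage(e))))
    trace <- c(trace, es$loglik)
    if (length(trace) >= 3 && aitken_converged(trace, tol)) {
      converged <- TRUE
      break
    }
    nj <- colSums(es$W)
    if (any(nj < d + 1) || any(!is.finite(nj)))
      stop(degenerate("component collapsed during EM"))
    state$pi <- nj / n
    if (is.null(fixed_beta))
      state$beta <- update_beta(es$r, es$W, state$beta, shared_beta, d)
    ms <- tryCatch(m_step_fun(x, es, state, m, fp_weight),
                   error = function(e) stop(degenerate(conditionMessage(e))))
    state$mu <- ms$mu
    state$sigma <- ms$sigma
  }
  drops <- diff(trace)
  viol <- drops < -1e-8 * (abs(trace[-1]) + 1)
  list(state = state, W = es$W, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged,
       n_drops = sum(viol),
       max_drop = if (any(viol)) max(-drops[viol]) else 0)
}

#' Fit a parsimonious MLN mixture
#'
#' Fits a finite mixture of multivariate leptokurtic-normal distributions
#' under one of the 28 parsimonious covariance/kurtosis structures, by
#' maximum likelihood with either the MM (quadratic-minorizer, monotone) or
#' the damped fixed-point (FP) algorithm.  Each random start draws k
#' observations as centroids, hard-assigns every observation to its nearest
#' centroid, takes one normal-theory M-step, and then alternates the E-step
#' with the chosen M-step until Aitken-accelerated convergence.  Starts that degenerate
#' (a component's effective count below \eqn{d+1}, or a singular scatter)
#' are retried with a fresh seed up to 5 times.
#'
#' @param x Numeric data matrix (\code{n x d}).
#' @param model 4-letter model name (e.g. \code{"EEVV"}), or a 3-letter name
#'   with \code{fixed_beta} supplied.
#' @param k Number of components.
#' @param algorithm \code{"fp"} (default, faster) or \code{"mm"} (monotone
#'   log-likelihood guaranteed).
#' @param n_starts Number of random starts.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Aitken tolerance on the log-likelihood limit.
#' @param seed Integer seed controlling all randomness of the fit.
#' @param fixed_beta Optional known excess kurtosis: hold \eqn{\beta_j} fixed
#'   at this value (requires a 3-letter model name).
#' @param fp_weight Optional fixed damping weight \eqn{a \in (0, 1]} for the
#'   FP covariance step, overriding the default
#'   \eqn{a = 1/[1 + \beta(d+4)/(4d(d+2))]}.
#' @return An object of class \code{"mln_fit"}: converged parameters
#'   (\code{pi}, \code{mu}, \code{sigma}, \code{beta}), \code{loglik} and its
#'   full \code{trace}, \code{bic}, posterior matrix \code{W}, hard
#'   \code{labels}, iteration diagnostics and monotonicity audit
#'   (\code{n_drops}, \code{max_drop}).
#' @examples
#' sim <- sample_design(mln_design(k = 2, d = 2, delta = 3, n = 200, seed = 1))
#' fit <- mln_fit(sim$x, "EIIE", k = 2, seed = 1, n_starts = 2)
#' fit
#' @export
mln_fit <- function(x, model, k, algorithm = c("fp", "mm"),
                    n_starts = 4L, max_iter = 1000L, tol = 1e-6,
                    seed = NULL, fixed_beta = NULL, fp_weight = NULL) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("data matrix contains non-finite values")
  m <- validate_model_name(model)
  d <- ncol(x); n <- nrow(x)
  if (is.na(m$kurtosis) && is.null(fixed_beta))
    stop("3-letter models require 'fixed_beta'", call. = FALSE)
  if (!is.na(m$kurtosis) && !is.null(fixed_beta))
    stop("'fixed_beta' requires a 3-letter model name", call. = FALSE)
  if (!is.null(fixed_beta)) check_beta(fixed_beta, d)
  if (!is.null(seed)) set.seed(seed)
  start_seeds <- sample.int(2147483646L, n_starts * 6L)
  tx0 <- t(x)

  best <- NULL
  failures <- character(0)
  si <- 0L
  for (s in seq_len(n_starts)) {
    run <- NULL
    for (attempt in seq_len(6L)) {
      si <- si + 1L
      set.seed(start_seeds[si])
      # random-centroid hard start: k distinct observations seed the
      # components; nearest-centroid labels give the initial partition
      cent <- x[sample.int(n, k), , drop = FALSE]
      dmat <- vapply(seq_len(k), function(j)
        colSums((tx0 - cent[j, ])^2), numeric(n))
      lab0 <- max.col(-dmat, ties.method = "first")
      W0 <- matrix(0, n, k)
      W0[cbind(seq_len(n), lab0)] <- 1
      run <- withCallingHandlers(
        tryCatch(
          run_em(x, m, k, W0, algorithm, max_iter, tol, fixed_beta, fp_weight),
          mln_degenerate = function(e) {
            failures <<- c(failures, conditionMessage(e)); NULL
          }),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(run)) break
    }
    if (!is.null(run) && (is.null(best) || run$loglik > best$loglik))
      best <- run
  }
  if (is.null(best))
    stop(sprintf("all %d starts degenerated (%s)", n_starts,
                 paste(unique(failures), collapse = "; ")), call. = FALSE)

  n_params <- count_free_params(m, d, k)
  structure(list(
    model = m$name, k = k, algorithm = algorithm,
    pi = best$state$pi, mu = best$state$mu, sigma = best$state$sigma,
    beta = best$state$beta, fixed_beta = fixed_beta,
    loglik = best$loglik, trace = best$trace,
    n_params = n_params, bic = bic_value(best$loglik, n_params, n),
    W = best$W, labels = max.col(best$W),
    n_iter = best$n_iter, converged = best$converged,
    n_drops = best$n_drops, max_drop = best$max_drop,
    n = n, d = d, seed = seed), class = "mln_fit")
}

#' @export
print.mln_fit <- function(x, ...) {
  cat(sprintf("Parsimonious MLN mixture: model %s, k = %d (%s algorithm)\n",
              x$model, x$k, toupper(x$algorithm)))
  cat(sprintf("  log-likelihood %.3f  BIC %.3f  (%d free parameters, n = %d)\n",
              x$loglik, x$bic, x$n_params, x$n))
  cat(sprintf("  %d iterations, %sconverged\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  cat("  mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("  excess kurtosis:", paste(sprintf("%.3f", x$beta), collapse = " "), "\n")
  if (x$n_drops > 0)
    cat(sprintf("  NOTE: %d log-likelihood decrease(s), max %.3g\n",
                x$n_drops, x$max_drop))
  invisible(x)
}

#' Observed log-likelihood of an MLN mixture
#'
#' @param x Data matrix.
#' @param pi,mu,sigma,beta Mixture parameters as in \code{\link{e_step}}.
#' @return Scalar log-likelihood.
#' @export
mln_loglik <- function(x, pi, mu, sigma, beta) {
  e_step(as.matrix(x), pi, mu, sigma, beta)$loglik
}
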