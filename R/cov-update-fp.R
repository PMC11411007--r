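#' Constrained covariance M-step for the fixed-point surrogate
#'
#' Given per-component scatter matrices \eqn{S_j} and effective counts
#' \eqn{n_j}, returns the covariance matrices minimizing
#' \deqn{\sum_j n_j \left[\log|\Sigma_j| +
#'   \mathrm{Tr}(\Sigma_j^{-1} S_j)\right]}
#' under the structural constraints of the requested model — the classical
#' normal-theory constrained M-step.  Closed forms are used wherever they
#' exist; the VEI/VEV/VEE models use the usual volume/shape flip-flop, and the
#' shared-orientation models (EVE, VVE) alternate a majorized orthogonal
#' update (see \code{\link{orth_procrustes_max}}) with closed-form
#' volume/shape steps.
#'
#' @param name Model identifier (3- or 4-letter; only the covariance triple
#'   is used).
#' @param S List of \code{k} symmetric PSD scatter matrices \eqn{S_j}.
#' @param nj Numeric vector of effective counts \eqn{n_j}.
#' @param max_inner,tol_inner Cap and relative tolerance for the inner
#'   flip-flop iterations.
#' @param sigma_init Optional list of covariance matrices used to warm-start
#'   the iterative (flip-flop) structures; closed-form structures ignore it.
#' @return List of \code{k} SPD matrices \eqn{\Sigma_j}.
#' @export
fp_cov_update <- function(name, S, nj, max_inner = 100L, tol_inner = 1e-8,
                          sigma_init = NULL) {
  m <- if (inherits(name, "mln_model")) name else validate_model_name(name)
  k <- length(S)
  d <- nrow(S[[1]])
  n <- sum(nj)
  W <- Map(function(s, w) w * s, S, nj)   # scatter matrices n_j * S_j
  triple <- paste0(m$volume, m$shape, m$orientation)

  sig <- switch(triple,
    EII = {
      lam <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
      rep(list(lam * diag(d)), k)
    },
    VII = {
      lapply(seq_len(k), function(j)
        (sum(diag(W[[j]])) / (nj[j] * d)) * diag(d))
    },
    EEI = {
      D <- Reduce(`+`, lapply(W, function(w) diag(w, names = FALSE)))
      rep(list(diag(D / n, d)), k)
    },
    VVI = {
      lapply(seq_len(k), function(j) diag(diag(W[[j]]) / nj[j], d))
    },
    EVI = {
      Dj <- lapply(W, function(w) diag(w, names = FALSE))
      gj <- vapply(Dj, function(dd) exp(mean(log(dd))), 0)  # |diag W_j|^{1/d}
      lam <- sum(gj) / n
      lapply(seq_len(k), function(j) diag(lam * Dj[[j]] / gj[j], d))
    },
    VEI = fp_vei(W, nj, d, k, max_inner, tol_inner, sigma_init),
    EEE = {
      rep(list(Reduce(`+`, W) / n), k)
    },
    VVV = lapply(seq_len(k), function(j) W[[j]] / nj[j]),
    EVV = {
      detj <- vapply(W, function(w) exp(mean(log(eigen(w, symmetric = TRUE,
                                                       only.values = TRUE)$values))), 0)
      lam <- sum(detj) / n
      lapply(seq_len(k), function(j) lam * W[[j]] / detj[j])
    },
    EEV = {
      eg <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
      A <- Reduce(`+`, lapply(eg, `[[`, "values"))
      lapply(seq_len(k), function(j)
        eg[[j]]$vectors %*% ((A / n) * t(eg[[j]]$vectors)))
    },
    VEV = fp_vev(W, nj, d, k, max_inner, tol_inner, sigma_init),
    VEE = fp_vee(W, nj, d, k, max_inner, tol_inner, sigma_init),
    EVE = fp_orient_shared(W, nj, d, k, vary_volume = FALSE, max_inner, tol_inner),
    VVE = fp_orient_shared(W, nj, d, k, vary_volume = TRUE, max_inner, tol_inner),
    stop("unhandled covariance structure ", triple)
  )
  sig
}

# objective minimized by fp_cov_update (used for monotonicity guards/tests)
fp_cov_objective <- function(sigma, S, nj) {
  sum(vapply(seq_along(S), function(j) {
    R <- chol_pd(sigma[[j]])
    nj[j] * (2 * sum(log(diag(R))) +
               sum(diag(chol2inv(R) %*% S[[j]])))
  }, 0))
}

init_lam <- function(sigma_init, k) {
  if (is.null(sigma_init)) return(NULL)
  vapply(sigma_init, function(s) prod(diag(s))^(1 / nrow(s)), 0)
}

# VEI: Sigma_j = lam_j * Psi (diagonal), |Psi| = 1
fp_vei <- function(W, nj, d, k, max_inner, tol_inner, sigma_init = NULL) {
  Dj <- lapply(W, function(w) diag(w, names = FALSE))
  lam <- init_lam(sigma_init, k)
  if (is.null(lam))
    lam <- vapply(seq_len(k), function(j) sum(Dj[[j]]) / (nj[j] * d), 0)
  obj_old <- Inf
  for (it in seq_len(max_inner)) {
    B <- Reduce(`+`, Map(function(dd, l) dd / l, Dj, as.list(lam)))
    psi <- B / exp(mean(log(B)))
    lam <- vapply(seq_len(k), function(j) sum(Dj[[j]] / psi) / (nj[j] * d), 0)
    obj <- sum(vapply(seq_len(k), function(j)
      nj[j] * d * log(lam[j]) + sum(Dj[[j]] / (lam[j] * psi)), 0))
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol_inner * (abs(obj) + 1)) break
    obj_old <- obj
  }
  lapply(seq_len(k), function(j) diag(lam[j] * psi, d))
}

# VEV: Sigma_j = lam_j * Gamma_j Psi Gamma_j', Gamma_j from eigen(W_j)
fp_vev <- function(W, nj, d, k, max_inner, tol_inner, sigma_init = NULL) {
  eg <- lapply(W, function(w) eigen((w + t(w)) / 2, symmetric = TRUE))
  Om <- lapply(eg, `[[`, "values")
  lam <- init_lam(sigma_init, k)
  if (is.null(lam))
    lam <- vapply(seq_len(k), function(j) sum(Om[[j]]) / (nj[j] * d), 0)
  obj_old <- Inf
  for (it in seq_len(max_inner)) {
    B <- Reduce(`+`, Map(function(o, l) o / l, Om, as.list(lam)))
    psi <- B / exp(mean(log(B)))
    lam <- vapply(seq_len(k), function(j) sum(Om[[j]] / psi) / (nj[j] * d), 0)
    obj <- sum(vapply(seq_len(k), function(j)
      nj[j] * d * log(lam[j]) + sum(Om[[j]] / (lam[j] * psi)), 0))
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol_inner * (abs(obj) + 1)) break
    obj_old <- obj
  }
  lapply(seq_len(k), function(j)
    eg[[j]]$vectors %*% ((lam[j] * psi) * t(eg[[j]]$vectors)))
}

# VEE: Sigma_j = lam_j * C, C SPD with |C| = 1
fp_vee <- function(W, nj, d, k, max_inner, tol_inner, sigma_init = NULL) {
  lam <- init_lam(sigma_init, k)
  if (is.null(lam))
    lam <- vapply(seq_len(k), function(j) sum(diag(W[[j]])) / (nj[j] * d), 0)
  obj_old <- Inf
  C <- diag(d)
  trCW <- numeric(k)
  for (it in seq_len(max_inner)) {
    B <- W[[1]] / lam[1]
    for (j in seq_len(k)[-1]) B <- B + W[[j]] / lam[j]
    C <- B / det(B)^(1 / d)
    Cinv <- solve(C)
    for (j in seq_len(k)) {
      trCW[j] <- sum(Cinv * W[[j]])   # Tr(Cinv W_j), both symmetric
      lam[j] <- trCW[j] / (nj[j] * d)
    }
    obj <- sum(nj * d * log(lam) + trCW / lam)
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol_inner * (abs(obj) + 1)) break
    obj_old <- obj
  }
  lapply(seq_len(k), function(j) lam[j] * C)
}

# EVE / VVE: shared orientation Gamma, per-component shape Psi_j, volume
# shared (EVE) or varying (VVE).  Alternates the majorized orthogonal update
# with closed-form shape/volume steps.
fp_orient_shared <- function(W, nj, d, k, vary_volume, max_inner, tol_inner) {
  n <- sum(nj)
  Gam <- eigen(Reduce(`+`, W) / n, symmetric = TRUE)$vectors
  obj_old <- Inf
  lam <- rep(1, k); Psi <- vector("list", k)
  for (it in seq_len(max_inner)) {
    Dj <- lapply(W, function(w) diag(crossprod(Gam, w %*% Gam), names = FALSE))
    gj <- vapply(Dj, function(dd) exp(mean(log(dd))), 0)
    if (vary_volume) {
      lam <- gj / nj
      Psi <- lapply(seq_len(k), function(j) Dj[[j]] / gj[j])
    } else {
      lam <- rep(sum(gj) / n, k)
      Psi <- lapply(seq_len(k), function(j) Dj[[j]] / gj[j])
    }
    # orientation: maximize sum_j Tr(Gam D_m Gam' C_m), C_m = -W_j/lam_j, D_m = 1/Psi_j
    Gam <- orth_procrustes_max(
      Cs = lapply(seq_len(k), function(j) -W[[j]] / lam[j]),
      Ds = lapply(Psi, function(p) 1 / p),
      gamma0 = Gam)
    obj <- sum(vapply(seq_len(k), function(j)
      nj[j] * d * log(lam[j]) +
        sum(diag(crossprod(Gam, W[[j]] %*% Gam)) / (lam[j] * Psi[[j]])), 0))
    if (is.finite(obj_old) && abs(obj_old - obj) <= tol_inner * (abs(obj) + 1)) break
    obj_old <- obj
  }
  lapply(seq_len(k), function(j) compose_covariance(lam[j], Gam, Psi[[j]]))
}

#' Majorized orthogonal-matrix ascent step
#'
#' Maximizes \eqn{f(\Gamma) = \sum_m \mathrm{Tr}(\Gamma D_m \Gamma^\top C_m)}
#' over orthogonal \eqn{\Gamma}, with \eqn{C_m} symmetric and \eqn{D_m}
#' positive diagonal (given as vectors), by iterating the linear majorization
#' of Kiers: the quadratic is bounded by its tangent plus a Lipschitz
#' curvature term, and the linearized problem
#' \eqn{\max_\Gamma \mathrm{Tr}(F^\top \Gamma)} is solved by the polar factor
#' (SVD) of \eqn{F = \nabla f(\Gamma_0) + L\,\Gamma_0}.  Each sweep cannot
#' decrease \eqn{f}.
#'
#' @param Cs List of symmetric matrices (sign carries the direction of
#'   optimization).
#' @param Ds List of positive weight vectors (diagonal matrices).
#' @param gamma0 Starting orthogonal matrix.
#' @param max_iter,tol Iteration cap and relative objective tolerance.
#' @return Orthogonal matrix.
#' @export
orth_procrustes_max <- function(Cs, Ds, gamma0, max_iter = 100L, tol = 1e-10) {
  f <- function(G) sum(vapply(seq_along(Cs), function(m)
    sum(diag((G %*% (Ds[[m]] * t(G))) %*% Cs[[m]])), 0))
  L <- 2 * sum(vapply(seq_along(Cs), function(m)
    max(abs(eigen(Cs[[m]], symmetric = TRUE, only.values = TRUE)$values)) *
      max(Ds[[m]]), 0))
  if (L == 0) return(gamma0)
  G <- gamma0
  fv <- f(G)
  for (it in seq_len(max_iter)) {
    grad <- Reduce(`+`, lapply(seq_along(Cs), function(m)
      2 * Cs[[m]] %*% sweep(G, 2, Ds[[m]], `*`)))
    sv <- svd(grad + L * G)
    Gn <- sv$u %*% t(sv$v)
    fn <- f(Gn)
    if (fn < fv) break          # numerically flat; keep current
    done <- (fn - fv) <= tol * (abs(fv) + 1)
    G <- Gn; fv <- fn
    if (done) break
  }
  G
}
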