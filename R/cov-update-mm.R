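#' Constrained covariance M-step for the quadratic-minorizer (MM) surrogate
#'
#' Maximizes the minorizer of the expected complete log-likelihood in the
#' covariance parameters,
#' \deqn{\sum_j \left[-\frac{n_j}{2}\log|\Sigma_j|
#'   + \mathrm{Tr}(\Sigma_j^{-1/2} A_j)
#'   - \frac{1}{2}\mathrm{Tr}(\Sigma_j^{-1} B_j)\right],}
#' under the structural constraints of the requested model.  For the
#' unconstrained (VVV) and fully shared (EEE) structures the stationary
#' condition in \eqn{\Xi_j = \Sigma_j^{-1/2}} is solved exactly by a damped
#' Newton iteration on the strictly concave surrogate (the Riccati-type
#' stationary equation has a unique SPD solution); all other structures use
#' blockwise coordinate ascent over volume (closed form), shape (guarded
#' quasi-Newton on the log scale), and orientation (majorized orthogonal
#' step, \code{\link{orth_procrustes_max}}).  Every block is accepted only if
#' it does not decrease the surrogate, so the update is monotone by
#' construction.
#'
#' @param name Model identifier (covariance triple used).
#' @param nj Effective counts \eqn{n_j}.
#' @param A List of \code{d x d} matrices \eqn{A_j} (need not be symmetric;
#'   only the symmetric part enters the objective).
#' @param B List of symmetric PSD matrices \eqn{B_j}.
#' @param sigma0 Optional list of current covariance matrices; the returned
#'   update never has a lower surrogate value than \code{sigma0}.
#' @param max_inner,tol_inner Coordinate-ascent cap and relative tolerance.
#' @return List of \code{k} SPD matrices.
#' @export
mm_cov_update <- function(name, nj, A, B, sigma0 = NULL,
                          max_inner = 100L, tol_inner = 1e-8) {
  m <- if (inherits(name, "mln_model")) name else validate_model_name(name)
  k <- length(B)
  d <- nrow(B[[1]])
  As <- lapply(A, function(a) (a + t(a)) / 2)
  triple <- paste0(m$volume, m$shape, m$orientation)

  sig <- if (triple == "VVV") {
    lapply(seq_len(k), function(j) mm_solve_free(As[[j]], B[[j]], nj[j]))
  } else if (triple == "EEE") {
    rep(list(mm_solve_free(Reduce(`+`, As), Reduce(`+`, B), sum(nj))), k)
  } else {
    mm_coordinate_ascent(m, nj, As, B, max_inner, tol_inner)
  }
  if (!is.null(sigma0) &&
      mm_cov_objective(sig, nj, As, B) < mm_cov_objective(sigma0, nj, As, B))
    sig <- sigma0
  sig
}

#' MM covariance surrogate value
#'
#' Evaluates the surrogate objective maximized by \code{\link{mm_cov_update}}
#' at a given set of covariance matrices.
#'
#' @inheritParams mm_cov_update
#' @param sigma List of SPD matrices.
#' @export
mm_cov_objective <- function(sigma, nj, A, B) {
  sum(vapply(seq_along(sigma), function(j) {
    e <- eigen((sigma[[j]] + t(sigma[[j]])) / 2, symmetric = TRUE)
    if (any(e$values <= 0)) return(-Inf)
    ihalf <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
    Asym <- (A[[j]] + t(A[[j]])) / 2
    -0.5 * nj[j] * sum(log(e$values)) + sum(ihalf * Asym) -
      0.5 * sum((ihalf %*% ihalf) * B[[j]])
  }, 0))
}

# Exact maximizer of n log|Xi| + Tr(Xi A) - (1/2) Tr(Xi B Xi) over SPD Xi,
# returned as Sigma = Xi^{-2}.  Damped Newton on the strictly concave
# objective; falls back to optim over the Cholesky factor of Sigma if the
# Newton iteration stalls.
mm_solve_free <- function(A, B, n) {
  d <- nrow(B)
  eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- pmax(eB$values, max(eB$values) * 1e-12)
  Xi <- eB$vectors %*% (sqrt(n / vals) * t(eB$vectors))  # exact when A = 0
  phi <- function(X) {
    e <- eigen(X, symmetric = TRUE, only.values = TRUE)$values
    if (any(e <= 0)) return(-Inf)
    n * sum(log(e)) + sum(X * A) - 0.5 * sum((X %*% B) * X)
  }
  Id <- diag(d)
  f0 <- phi(Xi)
  scale_ref <- n + sum(abs(A)) + sum(abs(B))
  ok <- FALSE
  for (it in seq_len(60L)) {
    Xinv <- solve(Xi)
    G <- n * Xinv + A - 0.5 * (B %*% Xi + Xi %*% B)
    G <- (G + t(G)) / 2
    if (sqrt(sum(G^2)) < 1e-11 * scale_ref) { ok <- TRUE; break }
    H <- -n * kronecker(Xinv, Xinv) -
      0.5 * (kronecker(Id, B) + kronecker(B, Id))
    step <- tryCatch(matrix(solve(H, -as.vector(G)), d, d),
                     error = function(e) NULL)
    if (is.null(step)) break
    step <- (step + t(step)) / 2
    alpha <- 1
    improved <- FALSE
    for (ls in seq_len(40L)) {
      Xn <- Xi + alpha * step
      fn <- phi(Xn)
      if (is.finite(fn) && fn >= f0) { Xi <- Xn; f0 <- fn; improved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!improved) break
  }
  if (!ok && !mm_newton_near_stationary(Xi, A, B, n, scale_ref))
    return(mm_solve_free_fallback(A, B, n, Xi))
  e <- eigen(Xi, symmetric = TRUE)
  e$vectors %*% ((1 / e$values^2) * t(e$vectors))
}

mm_newton_near_stationary <- function(Xi, A, B, n, scale_ref) {
  Xinv <- solve(Xi)
  G <- n * Xinv + A - 0.5 * (B %*% Xi + Xi %*% B)
  sqrt(sum(G^2)) < 1e-7 * scale_ref
}

# Fallback: numerical maximization over the Cholesky factor of Sigma.
mm_solve_free_fallback <- function(A, B, n, Xi_start) {
  warning("MM covariance Newton solve stalled; falling back to numerical ",
          "maximization over the Cholesky factor", call. = FALSE)
  d <- nrow(B)
  e <- eigen(Xi_start, symmetric = TRUE)
  sig0 <- e$vectors %*% ((1 / e$values^2) * t(e$vectors))
  L0 <- t(chol(sig0))
  par0 <- c(log(diag(L0)), L0[lower.tri(L0)])
  unpack <- function(p) {
    L <- diag(exp(p[seq_len(d)]), d)
    L[lower.tri(L)] <- p[-seq_len(d)]
    tcrossprod(L)
  }
  obj <- function(p) -mm_cov_objective(list(unpack(p)), n, list(A), list(B))
  fit <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  unpack(fit$par)
}

# Coordinate ascent for structured MM updates.  State: lam (length k), psi
# (list of k positive vectors, each with product 1), Gam (list of k
# orthogonal matrices), with sharing/identity enforced per the model letters.
mm_coordinate_ascent <- function(m, nj, As, B, max_inner, tol_inner) {
  k <- length(B); d <- nrow(B[[1]]); n <- sum(nj)

  # ---- structural initialization from the normal-theory solution on B ----
  Gam <- switch(m$orientation,
    I = rep(list(diag(d)), k),
    E = rep(list(eigen(Reduce(`+`, B) / n, symmetric = TRUE)$vectors), k),
    V = lapply(B, function(b) eigen((b + t(b)) / 2, symmetric = TRUE)$vectors))
  diagB <- function(j) pmax(diag(crossprod(Gam[[j]], B[[j]] %*% Gam[[j]])),
                            1e-300)
  psi <- switch(m$shape,
    I = rep(list(rep(1, d)), k),
    E = {
      pool <- Reduce(`+`, lapply(seq_len(k), diagB))
      rep(list(pool / exp(mean(log(pool)))), k)
    },
    V = lapply(seq_len(k), function(j) {
      dj <- diagB(j); dj / exp(mean(log(dj)))
    }))
  lam_of <- function(j) sum(diagB(j) / psi[[j]]) / (nj[j] * d)
  lam <- if (m$volume == "V") vapply(seq_len(k), lam_of, 0) else
    rep(sum(vapply(seq_len(k), function(j) sum(diagB(j) / psi[[j]]), 0)) / (n * d), k)

  build <- function() lapply(seq_len(k), function(j)
    compose_covariance(lam[j], Gam[[j]], psi[[j]]))
  obj <- function() mm_cov_objective(build(), nj, As, B)

  # per-component quadratic coefficients at the current (psi, Gam)
  coefs <- function(j) {
    P <- Gam[[j]] %*% (psi[[j]]^(-0.5) * t(Gam[[j]]))
    Q <- Gam[[j]] %*% ((1 / psi[[j]]) * t(Gam[[j]]))
    c(c1 = sum(P * As[[j]]), c2 = sum(Q * B[[j]]))
  }

  f_old <- obj()
  for (it in seq_len(max_inner)) {
    ## volume: closed-form root of c2 t^2 - c1 t - N d = 0 in t = lam^{-1/2}
    cc <- vapply(seq_len(k), coefs, c(0, 0))
    if (m$volume == "V") {
      for (j in seq_len(k)) {
        if (cc["c2", j] <= 0) next
        t_j <- (cc["c1", j] + sqrt(cc["c1", j]^2 +
                                     4 * cc["c2", j] * nj[j] * d)) /
          (2 * cc["c2", j])
        lam[j] <- t_j^(-2)
      }
    } else {
      c1 <- sum(cc["c1", ]); c2 <- sum(cc["c2", ])
      if (c2 > 0) {
        t_ <- (c1 + sqrt(c1^2 + 4 * c2 * n * d)) / (2 * c2)
        lam <- rep(t_^(-2), k)
      }
    }

    ## shape: guarded BFGS on log psi (sum-zero enforced by centering)
    if (m$shape != "I") {
      if (m$shape == "V") {
        for (j in seq_len(k)) {
          psi[[j]] <- mm_shape_step(list(j), psi[[j]], lam, Gam, As, B)
        }
      } else {
        ps <- mm_shape_step(seq_len(k), psi[[1]], lam, Gam, As, B)
        psi <- rep(list(ps), k)
      }
    }

    ## orientation: majorized orthogonal step
    if (m$orientation != "I") {
      mk_terms <- function(js) {
        Cs <- list(); Ds <- list()
        for (j in js) {
          Cs <- c(Cs, list(lam[j]^(-0.5) * As[[j]]),
                  list(-B[[j]] / (2 * lam[j])))
          Ds <- c(Ds, list(psi[[j]]^(-0.5)), list(1 / psi[[j]]))
        }
        list(Cs = Cs, Ds = Ds)
      }
      if (m$orientation == "V") {
        for (j in seq_len(k)) {
          tm <- mk_terms(j)
          Gam[[j]] <- orth_procrustes_max(tm$Cs, tm$Ds, Gam[[j]])
        }
      } else {
        tm <- mk_terms(seq_len(k))
        G <- orth_procrustes_max(tm$Cs, tm$Ds, Gam[[1]])
        Gam <- rep(list(G), k)
      }
    }

    f_new <- obj()
    if (abs(f_new - f_old) <= tol_inner * (abs(f_old) + 1)) break
    f_old <- f_new
  }
  build()
}

# One guarded shape update: maximize over psi (product 1) the terms of the
# components in `js`, holding lam and Gam fixed.  Returns the new psi vector.
mm_shape_step <- function(js, psi_cur, lam, Gam, As, B) {
  d <- length(psi_cur)
  a <- lapply(js, function(j)
    lam[j]^(-0.5) * diag(crossprod(Gam[[j]], As[[j]] %*% Gam[[j]])))
  b <- lapply(js, function(j)
    (1 / lam[j]) * diag(crossprod(Gam[[j]], B[[j]] %*% Gam[[j]])))
  val <- function(ps) {
    s <- 0
    for (i in seq_along(js))
      s <- s + sum(a[[i]] / sqrt(ps)) - 0.5 * sum(b[[i]] / ps)
    s
  }
  fn <- function(phi) {
    ps <- exp(phi - mean(phi))
    -val(ps)
  }
  gr <- function(phi) {
    ps <- exp(phi - mean(phi))
    Gp <- rep(0, d)
    for (i in seq_along(js))
      Gp <- Gp - 0.5 * a[[i]] * ps^(-1.5) + 0.5 * b[[i]] * ps^(-2)
    gpsi <- Gp * ps
    -(gpsi - mean(gpsi))
  }
  fit <- tryCatch(
    optim(log(psi_cur), fn, gr, method = "BFGS",
          control = list(maxit = 100, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(psi_cur)
  ps_new <- exp(fit$par - mean(fit$par))
  if (val(ps_new) >= val(psi_cur)) ps_new else psi_cur
}
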