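#' BIC in the maximization convention
#'
#' Returns \eqn{2\ell - m \log n}: like the log-likelihood, larger is
#' better.  \eqn{m} is the free-parameter count of the model.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n Sample size.
#' @examples
#' bic_value(-2777.461, count_free_params("VVVV", 6, 2), 202)  # -5857.493
#' @export
bic_value <- function(loglik, n_params, n) {
  2 * loglik - n_params * log(n)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie), from
#' the pair-counting contingency table: 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  np <- ch2(length(a))
  expected <- sum_a * sum_b / np
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (mx - expected)
}

#' Exhaustive BIC search over models and numbers of components
#'
#' Fits every (model, k) cell of the grid and ranks the successful fits by
#' BIC (maximization convention).  Ties are broken toward fewer free
#' parameters, then lexicographic model name.  Degenerate cells are recorded
#' with their failure reason and excluded from the ranking, so large
#' simulation grids always complete.  Each cell's randomness is driven by a
#' seed derived deterministically from \code{(seed, model, k)}, making the
#' grid reproducible cell-by-cell and independent of evaluation order.
#'
#' @param x Data matrix.
#' @param models Character vector of model names (default: all 28).
#' @param k_values Integer vector of component counts.
#' @param seed Master seed.
#' @param ... Passed to \code{\link{mln_fit}} (e.g. \code{algorithm},
#'   \code{n_starts}, \code{tol}, \code{fixed_beta}).
#' @return An object of class \code{"mln_search"}: list with \code{results}
#'   (one row per cell: model, k, loglik, n_params, bic, n_iter, converged,
#'   error), \code{fits} (successful \code{mln_fit} objects, named
#'   "model:k"), and \code{best} (the top-ranked fit).
#' @export
mln_search <- function(x, models = mln_model_names(), k_values = 1:3,
                       seed = 1L, ...) {
  stopifnot(length(models) >= 1, length(k_values) >= 1)
  x <- as.matrix(x)
  grid <- expand.grid(model = models, k = k_values,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fits <- list()
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mod <- grid$model[i]; k <- grid$k[i]
    cell_seed <- cell_seed_for(seed, mod, k)
    fit <- tryCatch(mln_fit(x, mod, k, seed = cell_seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(model = mod, k = k, loglik = NA_real_,
                              n_params = count_free_params(mod, ncol(x), k),
                              bic = NA_real_, n_iter = NA_integer_,
                              converged = FALSE,
                              error = conditionMessage(fit),
                              stringsAsFactors = FALSE)
    } else {
      fits[[paste0(mod, ":", k)]] <- fit
      rows[[i]] <- data.frame(model = mod, k = k, loglik = fit$loglik,
                              n_params = fit$n_params, bic = fit$bic,
                              n_iter = fit$n_iter, converged = fit$converged,
                              error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  ok <- !is.na(results$bic)
  if (!any(ok))
    stop("every (model, k) cell failed to fit", call. = FALSE)
  ord <- order(-results$bic[ok], results$n_params[ok], results$model[ok])
  top <- which(ok)[ord[1]]
  structure(list(results = results,
                 fits = fits,
                 best = fits[[paste0(results$model[top], ":", results$k[top])]]),
            class = "mln_search")
}

# Deterministic per-cell seed from (master seed, model, k).
cell_seed_for <- function(seed, model, k) {
  h <- sum(utf8ToInt(model) * seq_len(nchar(model)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + k * 17) %% 2147483629 + 1)
}

#' @export
print.mln_search <- function(x, ...) {
  ok <- !is.na(x$results$bic)
  cat(sprintf("MLN model search: %d cells (%d fitted, %d failed)\n",
              nrow(x$results), sum(ok), sum(!ok)))
  cat(sprintf("Best by BIC: model %s, k = %d (BIC %.3f)\n",
              x$best$model, x$best$k, x$best$bic))
  invisible(x)
}

#' Combine two components with identical location and scale
#'
#' When two mixture components share the same mean and covariance the model
#' is identifiable only up to merging them; the merged component's excess
#' kurtosis is the weight-combined value \eqn{\beta^* = \pi_j\beta_j +
#' \pi_t\beta_t}.  Provided as a post-hoc utility for interpreting such
#' fits.
#'
#' @param pi Mixing-weight vector.
#' @param beta Kurtosis vector.
#' @param j,t Indices of the two components to combine.
#' @return The combined excess kurtosis (scalar).
#' @export
combine_kurtosis <- function(pi, beta, j, t) {
  stopifnot(length(pi) == length(beta), j != t,
            j %in% seq_along(pi), t %in% seq_along(pi))
  pi[j] * beta[j] + pi[t] * beta[t]
}
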