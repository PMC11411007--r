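#' Simulation studies for the parsimonious MLN mixture
#'
#' These functions regenerate, at configurable replication counts, the
#' package's standard simulation experiments: MM/FP solution agreement on
#' well-separated two-component data, BIC model selection with the number of
#' components fixed, BIC selection of the number of components with the
#' model fixed, and behavior under misspecified (multivariate-t or
#' generalized-hyperbolic) data.  All are pure functions of their seed.
#'
#' @name mln-studies
#' @keywords internal
NULL

rep_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 131071 + r * 7919) %% 2147483629 + 1)
}

#' MM/FP agreement experiment
#'
#' On replicated draws from the well-separated two-component design
#' (\eqn{\mu = \pm\delta 1_d}, \eqn{\Sigma_j = I_d}, \eqn{\beta_j} at its
#' maximum, held fixed during fitting so both algorithms differ only in
#' their \eqn{(\mu_j, \Sigma_j)} updates), fits the same covariance
#' structure with both algorithms and records final log-likelihoods, ARIs
#' against the generating labels, and any log-likelihood decreases.
#'
#' @param n_reps Number of replications.
#' @param d Dimension.
#' @param n Sample size per replication.
#' @param model 3-letter covariance structure to fit.
#' @param delta Separation (the reference design uses 5).
#' @param seed Master seed.
#' @param n_starts,tol Passed to \code{\link{mln_fit}}.
#' @return Data frame with one row per replication: \code{ll_fp},
#'   \code{ll_mm}, \code{ari_fp}, \code{ari_mm}, \code{drops_fp},
#'   \code{drops_mm}, \code{max_drop_fp}, \code{max_drop_mm}.
#' @export
study_algorithm_agreement <- function(n_reps = 20L, d = 2L, n = 500L,
                                      model = "VVV", delta = 5,
                                      seed = 1L, n_starts = 4L, tol = 1e-6) {
  bfix <- beta_max(d)
  out <- lapply(seq_len(n_reps), function(r) {
    sim <- sample_design(mln_design(k = 2, d = d, delta = delta, lambda = 1,
                                    rho = 0, n = n, seed = rep_seed(seed, r)))
    fit1 <- mln_fit(sim$x, model, k = 2, algorithm = "fp",
                    n_starts = n_starts, tol = tol,
                    seed = rep_seed(seed, r), fixed_beta = bfix)
    fit2 <- mln_fit(sim$x, model, k = 2, algorithm = "mm",
                    n_starts = n_starts, tol = tol,
                    seed = rep_seed(seed, r), fixed_beta = bfix)
    data.frame(rep = r,
               ll_fp = fit1$loglik, ll_mm = fit2$loglik,
               ari_fp = adjusted_rand_index(fit1$labels, sim$labels),
               ari_mm = adjusted_rand_index(fit2$labels, sim$labels),
               drops_fp = fit1$n_drops, drops_mm = fit2$n_drops,
               max_drop_fp = fit1$max_drop, max_drop_mm = fit2$max_drop)
  })
  do.call(rbind, out)
}

#' BIC selection of the number of components (model fixed)
#'
#' For each replication, draws a dataset from the requested
#' \eqn{\theta_k(\delta, \lambda, \rho, d)} design, fits the (correct) model
#' for \eqn{k = 1, \ldots, k_{\max}}, and records the BIC-selected \eqn{k}.
#'
#' @param model 4-letter model to fit.
#' @param k_true Generating number of components.
#' @param delta,lambda,rho,d,n Design parameters.
#' @param n_reps Number of replications.
#' @param k_max Largest number of components searched.
#' @param seed Master seed.
#' @param n_starts,max_iter Fitting protocol for each grid cell (study
#'   default: 1 random start, 300 EM iterations).
#' @param ... Passed to \code{\link{mln_fit}} via \code{\link{mln_search}}.
#' @return List with \code{counts} (named integer vector over
#'   \eqn{1..k_{\max}}) and \code{selected} (per-replication choices).
#' @export
study_k_selection <- function(model, k_true, delta, lambda, rho,
                              n, d = 2L, n_reps = 100L, k_max = 8L,
                              seed = 1L, n_starts = 1L, max_iter = 300L,
                              ...) {
  sel <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- sample_design(mln_design(k = k_true, d = d, delta = delta,
                                    lambda = lambda, rho = rho, n = n,
                                    seed = rep_seed(seed, r)))
    sr <- mln_search(sim$x, models = model, k_values = seq_len(k_max),
                     seed = rep_seed(seed, r), n_starts = n_starts,
                     max_iter = max_iter, ...)
    sel[r] <- sr$best$k
  }
  counts <- tabulate(sel, nbins = k_max)
  names(counts) <- seq_len(k_max)
  list(counts = counts, selected = sel)
}

#' BIC selection of the parsimonious model (k fixed)
#'
#' For each replication, draws a dataset from
#' \eqn{\theta_k(\delta, \lambda, \rho, d)}, fits all the requested models
#' at the correct \eqn{k}, and records the BIC-selected model.
#'
#' @param lambda,rho,delta,d,n,k_true Design parameters.
#' @param models Candidate model names (default: all 28).
#' @param n_reps Number of replications.
#' @param seed Master seed.
#' @param ... Passed to \code{\link{mln_fit}}.
#' @return List with \code{counts} (named integer vector over models) and
#'   \code{selected}.
#' @export
study_model_selection <- function(lambda, rho, n, k_true = 2L, d = 2L,
                                  delta = 3, models = mln_model_names(),
                                  n_reps = 20L, seed = 1L, n_starts = 1L,
                                  max_iter = 300L, ...) {
  sel <- character(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- sample_design(mln_design(k = k_true, d = d, delta = delta,
                                    lambda = lambda, rho = rho, n = n,
                                    seed = rep_seed(seed, r)))
    sr <- mln_search(sim$x, models = models, k_values = k_true,
                     seed = rep_seed(seed, r), n_starts = n_starts,
                     max_iter = max_iter, ...)
    sel[r] <- sr$best$model
  }
  counts <- table(factor(sel, levels = models))
  list(counts = counts, selected = sel)
}

#' Fitting MLN mixtures to misspecified data
#'
#' Generates data from a two-component multivariate-t or
#' generalized-hyperbolic mixture, runs the BIC search over the requested
#' MLN models and component numbers, and computes the ARI between the
#' selected fit's labels and the generating labels.
#'
#' @param generator \code{"ghd"} or \code{"t"}.
#' @param lambda,alpha GHD index and skewness (used when
#'   \code{generator = "ghd"}).
#' @param nu Degrees of freedom (used when \code{generator = "t"}).
#' @param d Dimension.
#' @param n Sample size.
#' @param models,k_values Search grid.
#' @param n_reps Number of replications.
#' @param seed Master seed.
#' @param ... Passed to \code{\link{mln_fit}}.
#' @return List with \code{ari} (per-replication), \code{mean_ari},
#'   \code{sd_ari}, \code{selected_k}, \code{selected_model}.
#' @export
study_misspecification <- function(generator = c("ghd", "t"),
                                   lambda = 1, alpha = 0, nu = 4,
                                   d = 2L, n = 500L,
                                   models = c("EIIE", "VIIE", "VIIV"),
                                   k_values = 1:4, n_reps = 25L,
                                   seed = 1L, n_starts = 1L, max_iter = 300L,
                                   ...) {
  generator <- match.arg(generator)
  ari <- numeric(n_reps)
  sel_k <- integer(n_reps)
  sel_m <- character(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- if (generator == "ghd")
      sample_ghd_mixture(lambda, alpha, d, n, seed = rep_seed(seed, r))
    else
      sample_t_mixture(nu, d, n, seed = rep_seed(seed, r))
    sr <- mln_search(sim$x, models = models, k_values = k_values,
                     seed = rep_seed(seed, r), n_starts = n_starts,
                     max_iter = max_iter, ...)
    ari[r] <- adjusted_rand_index(sr$best$labels, sim$labels)
    sel_k[r] <- sr$best$k
    sel_m[r] <- sr$best$model
  }
  list(ari = ari, mean_ari = mean(ari), sd_ari = sd(ari),
       selected_k = sel_k, selected_model = sel_m)
}

#' Joint BIC selection of model and number of components
#'
#' For each replication, draws a dataset from
#' \eqn{\theta_k(\delta, \lambda, \rho, d)} and lets the BIC pick both the
#' parsimonious model and \eqn{k} over the full search grid.
#'
#' @param lambda,rho,delta,d,n,k_true Design parameters.
#' @param models,k_values Search grid (defaults: all 28 models, k up to 8).
#' @param n_reps Number of replications.
#' @param seed Master seed.
#' @param n_starts,max_iter Fitting protocol per grid cell.
#' @param ... Passed to \code{\link{mln_fit}}.
#' @return List with \code{selected} (data frame of model, k per
#'   replication) and \code{counts} (table over the selected pairs).
#' @export
study_joint_selection <- function(lambda, rho, delta, n, k_true = 2L,
                                  d = 2L, models = mln_model_names(),
                                  k_values = 1:8, n_reps = 10L, seed = 1L,
                                  n_starts = 1L, max_iter = 300L, ...) {
  sel <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- sample_design(mln_design(k = k_true, d = d, delta = delta,
                                    lambda = lambda, rho = rho, n = n,
                                    seed = rep_seed(seed, r)))
    sr <- mln_search(sim$x, models = models, k_values = k_values,
                     seed = rep_seed(seed, r), n_starts = n_starts,
                     max_iter = max_iter, ...)
    sel[[r]] <- data.frame(model = sr$best$model, k = sr$best$k,
                           stringsAsFactors = FALSE)
  }
  sel <- do.call(rbind, sel)
  list(selected = sel, counts = table(paste(sel$model, sel$k, sep = ":")))
}
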