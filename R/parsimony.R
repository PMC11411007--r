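#' The parsimonious MLN model family
#'
#' Each component covariance is eigendecomposed as
#' \eqn{\Sigma_j = \lambda_j \Gamma_j \Psi_j \Gamma_j^\top} with volume
#' \eqn{\lambda_j = |\Sigma_j|^{1/d}}, orthogonal orientation \eqn{\Gamma_j}
#' and diagonal shape \eqn{\Psi_j} with \eqn{|\Psi_j| = 1}.  Constraining each
#' factor to be equal (E) across components, varying (V), or the identity (I,
#' for shape/orientation) gives the familiar fourteen covariance structures;
#' crossing them with an equal or varying excess kurtosis \eqn{\beta_j} gives
#' the twenty-eight four-letter models, e.g. \code{"EEVV"}.
#'
#' @name parsimonious-models
#' @keywords internal
NULL

# The 14 valid (volume, shape, orientation) triples, mclust ordering.
COV_STRUCTURES <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI",
                    "EEE", "VEE", "EVE", "VVE",
                    "EEV", "VEV", "EVV", "VVV")

#' Enumerate the parsimonious MLN model names
#'
#' @param kurtosis One of \code{"both"} (all 28 four-letter models),
#'   \code{"E"}, \code{"V"}, or \code{"none"} (the 14 three-letter covariance
#'   structures, excess kurtosis handled externally).
#' @return Character vector of model identifiers.
#' @examples
#' length(mln_model_names())        # 28
#' mln_model_names("none")          # the 14 covariance structures
#' @export
mln_model_names <- function(kurtosis = c("both", "E", "V", "none")) {
  kurtosis <- match.arg(kurtosis)
  switch(kurtosis,
    both = as.vector(t(outer(COV_STRUCTURES, c("E", "V"), paste0))),
    E    = paste0(COV_STRUCTURES, "E"),
    V    = paste0(COV_STRUCTURES, "V"),
    none = COV_STRUCTURES)
}

#' Parse and validate a parsimonious model identifier
#'
#' Accepts a 4-letter name (volume, shape, orientation, kurtosis) or a
#' 3-letter name (kurtosis fixed externally, e.g. when \eqn{\beta} is held at
#' a known value) and rejects combinations outside the family: volume must be
#' E/V, shape I/E/V, orientation I/E/V, kurtosis E/V, and shape I forces
#' orientation I (a spherical component has no orientation).
#'
#' @param name Model identifier string.
#' @return An object of class \code{"mln_model"}: a list with fields
#'   \code{name}, \code{volume}, \code{shape}, \code{orientation},
#'   \code{kurtosis} (\code{NA} for 3-letter names).
#' @examples
#' validate_model_name("EEVV")
#' validate_model_name("VVV")   # kurtosis fixed externally
#' @export
validate_model_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nchar(name) %in% c(3L, 4L))
    stop("model name must be a single 3- or 4-letter string", call. = FALSE)
  letters_ <- strsplit(toupper(name), "")[[1]]
  triple <- paste(letters_[1:3], collapse = "")
  if (!triple %in% COV_STRUCTURES)
    stop(sprintf("'%s' is not a valid covariance structure; valid: %s",
                 triple, paste(COV_STRUCTURES, collapse = ", ")), call. = FALSE)
  kurt <- if (nchar(name) == 4L) letters_[4] else NA_character_
  if (!is.na(kurt) && !kurt %in% c("E", "V"))
    stop(sprintf("kurtosis letter must be E or V, got '%s'", kurt), call. = FALSE)
  structure(list(name = toupper(name), volume = letters_[1],
                 shape = letters_[2], orientation = letters_[3],
                 kurtosis = kurt),
            class = "mln_model")
}

#' Number of free parameters of a parsimonious MLN mixture
#'
#' Counts \eqn{(k-1)} mixing weights, \eqn{kd} means, then volume (1 or
#' \eqn{k}), shape (0, \eqn{d-1}, or \eqn{k(d-1)}), orientation (0,
#' \eqn{d(d-1)/2}, or \eqn{k d(d-1)/2}) and kurtosis (1 or \eqn{k}; 0 for
#' 3-letter names with \eqn{\beta} fixed).
#'
#' @param name Model identifier (3 or 4 letters) or an \code{"mln_model"}.
#' @param d Dimension.
#' @param k Number of mixture components.
#' @return Integer parameter count.
#' @examples
#' count_free_params("VVVV", d = 6, k = 2)  # 57
#' count_free_params("EEVV", d = 6, k = 2)  # 51
#' @export
count_free_params <- function(name, d, k) {
  m <- if (inherits(name, "mln_model")) name else validate_model_name(name)
  check_dim(d)
  stopifnot(k >= 1)
  vol <- if (m$volume == "V") k else 1
  shp <- switch(m$shape, I = 0, E = d - 1, V = k * (d - 1))
  ori <- switch(m$orientation, I = 0, E = d * (d - 1) / 2, V = k * d * (d - 1) / 2)
  kur <- if (is.na(m$kurtosis)) 0 else if (m$kurtosis == "V") k else 1
  as.integer((k - 1) + k * d + vol + shp + ori + kur)
}

#' Volume/shape/orientation decomposition of a covariance matrix
#'
#' Decomposes an SPD matrix as \eqn{\Sigma = \lambda \Gamma \Psi \Gamma^\top}
#' with \eqn{\lambda = |\Sigma|^{1/d}}, \eqn{\Psi} the diagonal matrix of
#' eigenvalues divided by \eqn{\lambda} (so \eqn{|\Psi| = 1}), sorted in
#' decreasing order, and \eqn{\Gamma} the corresponding orthonormal
#' eigenvectors with the sign convention that the largest-magnitude entry of
#' each column is positive (ties broken by original index), making the
#' decomposition deterministic.
#'
#' @param sigma SPD matrix.
#' @return List with components \code{lam} (scalar volume), \code{gamma}
#'   (orthogonal matrix), \code{psi} (vector of scaled eigenvalues, product 1).
#' @export
decompose_covariance <- function(sigma) {
  sigma <- as.matrix(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("covariance matrix is not positive definite", call. = FALSE)
  d <- nrow(sigma)
  lam <- exp(mean(log(e$values)))
  psi <- e$values / lam
  gam <- e$vectors
  for (u in seq_len(d)) {
    i <- which.max(abs(gam[, u]))
    if (gam[i, u] < 0) gam[, u] <- -gam[, u]
  }
  # deterministic order: decreasing eigenvalue, ties broken by the row index
  # of each column's largest-magnitude entry (so I_d decomposes to Gamma = I)
  anchor <- apply(abs(gam), 2, which.max)
  ord <- order(-round(psi, 10), anchor)
  list(lam = lam, gamma = gam[, ord, drop = FALSE], psi = psi[ord])
}

# Rebuild Sigma from a decomposition (psi as vector).
compose_covariance <- function(lam, gamma, psi) {
  lam * (gamma %*% (psi * t(gamma)))
}
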