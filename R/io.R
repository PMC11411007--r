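#' Read a numeric data matrix from delimited text
#'
#' Reads CSV or TSV (separator chosen by extension unless given), with an
#' optional header row (auto-detected: a first line with any non-numeric
#' field is treated as a header).  Every cell must parse as a finite number;
#' offending rows/columns are reported by position.
#'
#' @param path File path (\code{.csv} implies comma, anything else tab,
#'   unless \code{sep} is given).
#' @param sep Optional field separator.
#' @return Numeric matrix with column names (generated as \code{x1..xd} when
#'   the file has no header).
#' @export
read_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE,
                          colClasses = NA, fill = FALSE)
  if (ncol(df) == 0L) stop("no columns parsed from ", path, call. = FALSE)
  mat <- suppressWarnings(
    vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
  mat <- matrix(mat, nrow = nrow(df))
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    off <- if (has_header) 1L else 0L
    stop(sprintf("non-numeric or missing value at row %d, column %d of %s",
                 bad[1, 1] + off, bad[1, 2], path), call. = FALSE)
  }
  colnames(mat) <- if (has_header) names(df) else paste0("x", seq_len(ncol(df)))
  mat
}

#' Serialize / restore fitted mixture parameters as JSON
#'
#' \code{fit_to_json} writes the fitted parameters (weights, means,
#' covariances as nested row-major arrays, kurtoses, model, log-likelihood,
#' BIC, iteration count) to a JSON file; \code{fit_from_json} restores them
#' into the parameter list accepted by \code{\link{mln_loglik}} and
#' \code{\link{e_step}}, so a reloaded fit reproduces its stored
#' log-likelihood.
#'
#' @param fit An \code{"mln_fit"}.
#' @param path Output JSON path.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "mln_fit"))
  obj <- list(model = fit$model, k = fit$k, algorithm = fit$algorithm,
              pi = fit$pi,
              mu = lapply(seq_len(fit$k), function(j) fit$mu[, j]),
              sigma = lapply(fit$sigma, function(s)
                lapply(seq_len(nrow(s)), function(i) s[i, ])),
              beta = fit$beta,
              loglik = fit$loglik, bic = fit$bic,
              n_params = fit$n_params, n_iter = fit$n_iter,
              converged = fit$converged, n = fit$n, d = fit$d)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_to_json
#' @export
fit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- obj$d
  list(model = obj$model, k = obj$k,
       pi = vapply(obj$pi, as.numeric, 0),
       mu = vapply(obj$mu, function(col) vapply(col, as.numeric, 0),
                   numeric(d)),
       sigma = lapply(obj$sigma, function(s)
         t(vapply(s, function(row) vapply(row, as.numeric, 0), numeric(d)))),
       beta = vapply(obj$beta, as.numeric, 0),
       loglik = obj$loglik, bic = obj$bic)
}

#' Write per-observation clustering output
#'
#' Writes a CSV with the hard labels and the posterior probabilities of a
#' fitted mixture, one row per observation.
#'
#' @param fit An \code{"mln_fit"}.
#' @param path Output CSV path.
#' @export
labels_to_csv <- function(fit, path) {
  stopifnot(inherits(fit, "mln_fit"))
  df <- data.frame(label = fit$labels)
  W <- fit$W
  colnames(W) <- paste0("posterior_", seq_len(ncol(W)))
  utils::write.csv(cbind(df, W), path, row.names = FALSE)
  invisible(path)
}

#' Write a model-search results grid
#'
#' @param search An \code{"mln_search"}.
#' @param path Output CSV path.
#' @export
search_to_csv <- function(search, path) {
  stopifnot(inherits(search, "mln_search"))
  utils::write.csv(search$results, path, row.names = FALSE)
  invisible(path)
}
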