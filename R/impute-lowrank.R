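# Metabolomics intensities are approximately log-normal, so the
# model-based imputers fit on the log scale by default. Returns the
# working-scale intensity_matrix plus the back-transform.
working_scale <- function(x, log_transform) {
  if (!log_transform) {
    return(list(x = x, back = identity))
  }
  v <- x$values
  if (any(v[!x$mask] <= 0, na.rm = TRUE)) {
    warning("non-positive observed intensities; fitting on the raw scale")
    return(list(x = x, back = identity))
  }
  lv <- v
  lv[!x$mask] <- log(v[!x$mask])
  list(x = intensity_matrix(lv, mask = x$mask, sample_ids = x$sample_ids,
                            metabolite_ids = x$metabolite_ids),
       back = exp)
}

# relative change of the imputed entries between iterations
imputed_change <- function(new, old, mask) {
  denom <- sqrt(sum(old[mask]^2))
  if (denom == 0) denom <- .Machine$double.eps
  sqrt(sum((new[mask] - old[mask])^2)) / denom
}

#' Iterative low-rank SVD imputation
#'
#' Alternating low-rank matrix completion: missing cells are initialized
#' with column means, then the column-centered completed matrix is
#' approximated by its rank-`rank` truncated SVD and the missing cells
#' are refilled from the reconstruction, until the relative change of
#' the imputed entries drops below `tol` or `max_iter` is reached.
#'
#' @param x an [intensity_matrix()].
#' @param rank positive integer, at most `min(dim(x)) - 1`.
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum number of refinement iterations.
#' @param log_transform fit on the log scale (default `TRUE`; intensities
#'   must then be positive).
#' @return an `"imputation_result"`; see [impute_constant()].
#' @export
impute_svd <- function(x, rank = 2L, tol = 1e-4, max_iter = 100L,
                       log_transform = TRUE) {
  stopifnot(is_intensity_matrix(x))
  if (rank < 1 || rank > min(dim(x)) - 1) {
    stop("`rank` must lie in [1, min(dim) - 1]", call. = FALSE)
  }
  require_observed(x, "svd")
  ws <- working_scale(x, log_transform)
  fit <- lowrank_loop(ws$x, ncomp = rank, regularization = 0, scale = FALSE,
                      tol = tol, max_iter = max_iter)
  new_imputation_result(x, ws$back(fit$completed), "svd",
                        converged = fit$converged,
                        n_iterations = fit$n_iterations)
}

#' Regularized iterative PCA (EM) imputation
#'
#' Expectation-maximization-style imputation on the column-standardized
#' matrix: missing cells start at the column means, each iteration takes
#' the leading `ncomp` principal components, shrinks the retained
#' singular values ridge-style toward the residual level (each retained
#' singular value `l` becomes `l * (l^2 - reg * s2) / l^2`, with `s2`
#' the mean of the discarded squared singular values, floored at zero)
#' and refills the missing cells from the shrunken reconstruction.
#' Shrinkage damps the overfitting that plain alternating SVD exhibits
#' at high missingness. `ncomp = 0` degenerates to column-mean
#' imputation, and `regularization = 0` to the unshrunken SVD fixed
#' point.
#'
#' @param x an [intensity_matrix()].
#' @param ncomp non-negative integer number of components, at most
#'   `min(dim(x)) - 1`.
#' @param regularization shrinkage intensity in `[0, 1]`.
#' @param scale standardize columns to unit variance before fitting
#'   (default `TRUE`).
#' @inheritParams impute_svd
#' @return an `"imputation_result"`; see [impute_constant()].
#' @export
impute_iterative_pca <- function(x, ncomp = 2L, regularization = 1,
                                 tol = 1e-4, max_iter = 100L, scale = TRUE,
                                 log_transform = TRUE) {
  stopifnot(is_intensity_matrix(x))
  if (ncomp < 0 || ncomp > min(dim(x)) - 1) {
    stop("`ncomp` must lie in [0, min(dim) - 1]", call. = FALSE)
  }
  if (regularization < 0 || regularization > 1) {
    stop("`regularization` must lie in [0, 1]", call. = FALSE)
  }
  require_observed(x, "iterative_pca")
  ws <- working_scale(x, log_transform)
  if (ncomp == 0L) {
    fit <- impute_constant(ws$x, "mean")
    return(new_imputation_result(x, ws$back(fit$completed), "iterative_pca"))
  }
  fit <- lowrank_loop(ws$x, ncomp = ncomp, regularization = regularization,
                      scale = scale, tol = tol, max_iter = max_iter)
  new_imputation_result(x, ws$back(fit$completed), "iterative_pca",
                        converged = fit$converged,
                        n_iterations = fit$n_iterations)
}

# shared alternating-SVD engine; works on the (already transformed)
# working scale, centering and optionally scaling columns each pass
lowrank_loop <- function(x, ncomp, regularization, scale, tol, max_iter) {
  v <- x$values
  mask <- x$mask
  completed <- v
  cm <- col_stats(x, mean)
  for (j in which(colSums(mask) > 0)) completed[mask[, j], j] <- cm[j]
  if (!any(mask)) {
    return(list(completed = completed, converged = TRUE, n_iterations = 0L))
  }

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- colMeans(completed)
    sdev <- if (scale) apply(completed, 2, stats::sd) else rep(1, ncol(completed))
    sdev[sdev == 0 | is.na(sdev)] <- 1
    z <- sweep(sweep(completed, 2, mu, "-"), 2, sdev, "/")
    sv <- svd(z, nu = ncomp, nv = ncomp)
    d <- sv$d[seq_len(ncomp)]
    rest <- sv$d[-seq_len(ncomp)]
    if (regularization > 0 && length(rest) > 0) {
      s2 <- mean(rest^2)
      d <- pmax(d - regularization * s2 / d, 0)
    }
    recon <- sv$u %*% (t(sv$v) * d)
    refit <- sweep(sweep(recon, 2, sdev, "*"), 2, mu, "+")
    new_completed <- completed
    new_completed[mask] <- refit[mask]
    delta <- imputed_change(new_completed, completed, mask)
    completed <- new_completed
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(completed = completed, converged = converged, n_iterations = iter)
}
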