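new_imputation_result <- function(x, completed, method, converged = TRUE,
                                  n_iterations = 0L, seed = NULL) {
  # uniform contract: observed cells are returned bit-identical
  out <- x$values
  out[x$mask] <- completed[x$mask]
  dimnames(out) <- dimnames(x$values)
  structure(
    list(completed = out,
         n_imputed = sum(x$mask),
         converged = converged,
         n_iterations = as.integer(n_iterations),
         method = method,
         seed = seed),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> method '%s': %d cells imputed, %s after %d iteration(s)\n",
              x$method, x$n_imputed,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

col_stats <- function(x, fun) {
  vapply(seq_len(ncol(x$values)), function(j) {
    v <- x$values[!x$mask[, j], j]
    if (length(v) == 0) NA_real_ else fun(v)
  }, numeric(1))
}

require_observed <- function(x, method) {
  empty <- colSums(!x$mask) == 0
  if (any(empty)) {
    stop(sprintf("method '%s' cannot impute metabolite(s) with no observed values: %s",
                 method, paste(x$metabolite_ids[empty], collapse = ", ")),
         call. = FALSE)
  }
}

#' Constant-value imputation strategies
#'
#' Replaces each missing cell of metabolite `j` by a per-column constant
#' computed from that column's observed cells: 0, the minimum, half the
#' minimum (the classical limit-of-detection heuristic), the mean, or
#' the median.
#'
#' @param x an [intensity_matrix()].
#' @param strategy one of `"zero"`, `"min"`, `"half_min"`, `"mean"`,
#'   `"median"`.
#' @return an object of class `"imputation_result"` with elements
#'   `completed` (complete numeric matrix), `n_imputed`, `converged`,
#'   `n_iterations`, `method` and `seed`. Observed cells are always
#'   returned unchanged, bit for bit.
#' @examples
#' m <- intensity_matrix(matrix(c(2, 4, NA, 1, 1, 1), nrow = 3))
#' impute_constant(m, "mean")$completed
#' @export
impute_constant <- function(x, strategy = c("zero", "min", "half_min",
                                            "mean", "median")) {
  stopifnot(is_intensity_matrix(x))
  strategy <- match.arg(strategy)
  if (strategy != "zero") require_observed(x, strategy)
  fill <- switch(strategy,
    zero = rep(0, ncol(x$values)),
    min = col_stats(x, min),
    half_min = col_stats(x, min) / 2,
    mean = col_stats(x, mean),
    median = col_stats(x, stats::median)
  )
  completed <- x$values
  for (j in which(colSums(x$mask) > 0)) {
    completed[x$mask[, j], j] <- fill[j]
  }
  new_imputation_result(x, completed, strategy)
}

#' Random-range baseline imputation
#'
#' The intentionally weak baseline: each missing cell of metabolite `j`
#' is drawn uniformly between that column's observed minimum and
#' maximum. Any method worth using should beat this.
#'
#' @param x an [intensity_matrix()].
#' @param seed integer seed; the result is a pure function of
#'   `(x, seed)`.
#' @return an `"imputation_result"`; see [impute_constant()].
#' @export
impute_random <- function(x, seed = 1L) {
  stopifnot(is_intensity_matrix(x))
  require_observed(x, "random")
  lo <- col_stats(x, min)
  hi <- col_stats(x, max)
  completed <- x$values
  withr::with_seed(seed, {
    for (j in which(colSums(x$mask) > 0)) {
      k <- sum(x$mask[, j])
      completed[x$mask[, j], j] <- stats::runif(k, lo[j], hi[j])
    }
  })
  new_imputation_result(x, completed, "random", seed = as.integer(seed))
}

#' K-nearest-neighbour imputation (sample-wise, Euclidean)
#'
#' For a sample `i` missing metabolite `j`, distances to all other
#' samples are computed over the metabolites observed in both
#' (pairwise-complete squared differences averaged over the shared
#' metabolites, then square-rooted), the `k` nearest samples that
#' observe metabolite `j` are selected (distance ties broken by sample
#' order), and the missing cell is filled with the unweighted mean of
#' their values on the working scale. Fewer than `k` eligible
#' neighbours: all available are used; none: the column's observed
#' mean.
#'
#' By default distances and neighbour means are taken on the log scale
#' (so the filled value is the neighbours' geometric mean): on raw
#' log-normal intensities, Euclidean distances are dominated by the few
#' highest-abundance metabolites and neighbour averages are badly
#' biased — raw-scale KNN fails to beat even column-mean imputation on
#' such data.
#'
#' @param x an [intensity_matrix()].
#' @param k positive integer number of neighbours.
#' @param log_transform compute distances and neighbour means on the
#'   log scale (default `TRUE`; intensities must then be positive).
#' @return an `"imputation_result"`; see [impute_constant()].
#' @export
impute_knn <- function(x, k = 5L, log_transform = TRUE) {
  stopifnot(is_intensity_matrix(x))
  if (k < 1) stop("`k` must be a positive integer", call. = FALSE)
  require_observed(x, "knn")
  ws <- working_scale(x, log_transform)
  x_work <- ws$x
  v <- x_work$values
  obs <- !x$mask
  n <- nrow(v)
  col_means <- col_stats(x_work, mean)

  # pairwise-complete mean-squared-difference distances between samples
  d2 <- matrix(Inf, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      shared <- obs[a, ] & obs[b, ]
      ns <- sum(shared)
      if (ns > 0) {
        d2[a, b] <- d2[b, a] <- sum((v[a, shared] - v[b, shared])^2) / ns
      }
    }
  }

  completed <- v
  for (j in which(colSums(x$mask) > 0)) {
    donors <- which(obs[, j])
    for (i in which(x$mask[, j])) {
      cand <- setdiff(donors, i)
      cand <- cand[is.finite(d2[i, cand])]
      if (length(cand) == 0) {
        completed[i, j] <- col_means[j]
        next
      }
      ord <- cand[order(d2[i, cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      completed[i, j] <- mean(v[nb, j])
    }
  }
  new_imputation_result(x, ws$back(completed), "knn")
}
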