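#' Iterative random-forest imputation
#'
#' missForest-style chained-equations imputation: missing cells start at
#' the column means; metabolites are then visited in order of increasing
#' missing fraction, each regressed on all other metabolites with a
#' random forest fitted on the samples that observe it, and its missing
#' cells replaced by the forest predictions. The sweep repeats until the
#' total normalized squared change of the imputed values increases
#' relative to the previous sweep — the previous sweep's matrix is then
#' returned — or `max_iter` is reached.
#'
#' @param x an [intensity_matrix()] with at least 2 metabolites.
#' @param n_trees trees per forest.
#' @param max_iter maximum number of sweeps over the metabolites.
#' @param seed integer seed; the result is a pure function of
#'   `(x, hyperparameters, seed)`.
#' @param log_transform fit on the log scale (default `TRUE`).
#' @param verbose print per-sweep progress.
#' @return an `"imputation_result"`; see [impute_constant()].
#'   `converged` is `TRUE` when the stopping rule fired before
#'   `max_iter`.
#' @export
impute_forest <- function(x, n_trees = 100L, max_iter = 10L, seed = 1L,
                          log_transform = TRUE, verbose = FALSE) {
  stopifnot(is_intensity_matrix(x))
  if (ncol(x$values) < 2L) {
    stop("random-forest imputation needs at least 2 metabolites", call. = FALSE)
  }
  require_observed(x, "forest")
  if (!any(x$mask)) {
    return(new_imputation_result(x, x$values, "forest",
                                 n_iterations = 0L, seed = as.integer(seed)))
  }
  ws <- working_scale(x, log_transform)
  v <- ws$x$values
  mask <- x$mask
  p <- ncol(v)

  completed <- v
  cm <- col_stats(ws$x, mean)
  for (j in which(colSums(mask) > 0)) completed[mask[, j], j] <- cm[j]

  visit <- order(colMeans(mask))
  visit <- visit[colSums(mask)[visit] > 0]

  df_names <- paste0("V", seq_len(p))
  prev <- completed
  prev_score <- Inf
  converged <- FALSE
  iter <- 0L

  withr::with_seed(as.integer(seed), {
    while (iter < max_iter) {
      iter <- iter + 1L
      before <- completed
      for (j in visit) {
        dat <- as.data.frame(completed)
        names(dat) <- df_names
        obs_j <- !mask[, j]
        fit <- ranger::ranger(
          x = dat[obs_j, -j, drop = FALSE], y = completed[obs_j, j],
          num.trees = n_trees, num.threads = 1L, verbose = FALSE,
          seed = sample.int(.Machine$integer.max, 1)
        )
        pred <- stats::predict(fit, dat[mask[, j], -j, drop = FALSE])
        completed[mask[, j], j] <- pred$predictions
      }
      # missForest stopping rule: stop when the change starts rising
      score <- sum(vapply(visit, function(j) {
        sum((completed[mask[, j], j] - before[mask[, j], j])^2) /
          max(sum(completed[mask[, j], j]^2), .Machine$double.eps)
      }, numeric(1)))
      if (verbose) {
        message(sprintf("forest sweep %d: change %.3g", iter, score))
      }
      if (score >= prev_score) {
        completed <- prev  # revert to the better previous sweep
        converged <- TRUE
        break
      }
      prev <- completed
      prev_score <- score
    }
  })
  new_imputation_result(x, ws$back(completed), "forest",
                        converged = converged, n_iterations = iter,
                        seed = as.integer(seed))
}

#' Quantile-based imputation of left-censored data (QRILC-style)
#'
#' Treats each metabolite's missing cells as values censored below the
#' detection limit. On the log scale, a Gaussian is fitted to the
#' observed (upper) part of each column by regressing the observed order
#' statistics on the standard-normal quantiles of their estimated
#' probability positions (which account for the censored share), and the
#' missing cells are drawn from that Gaussian truncated above at the
#' observed minimum. `tune_sigma` scales the sd of the fitted Gaussian;
#' values below 1 concentrate draws near the truncated distribution's
#' centre.
#'
#' @param x an [intensity_matrix()].
#' @param tune_sigma sd multiplier in `(0, 1]`.
#' @param seed integer seed.
#' @param log_transform fit and draw on the log scale (default `TRUE`).
#' @return an `"imputation_result"`; every imputed value is at most the
#'   column's observed minimum. Columns with fewer than 4 observed
#'   values fall back to half-minimum imputation with a warning.
#' @export
impute_qrilc <- function(x, tune_sigma = 1, seed = 1L, log_transform = TRUE) {
  stopifnot(is_intensity_matrix(x))
  if (tune_sigma <= 0 || tune_sigma > 1) {
    stop("`tune_sigma` must lie in (0, 1]", call. = FALSE)
  }
  require_observed(x, "qrilc")
  ws <- working_scale(x, log_transform)
  v <- ws$x$values
  mask <- x$mask
  n <- nrow(v)
  completed <- v

  withr::with_seed(as.integer(seed), {
    for (j in which(colSums(mask) > 0)) {
      obs <- v[!mask[, j], j]
      m <- sum(mask[, j])
      if (length(obs) < 4L) {
        warning(sprintf(
          "metabolite '%s' has fewer than 4 observed values; using half-minimum",
          x$metabolite_ids[j]))
        # half the raw-scale minimum, expressed on the working scale
        completed[mask[, j], j] <- if (identical(ws$back, exp)) {
          min(obs) - log(2)
        } else {
          min(obs) / 2
        }
        next
      }
      # Blom plotting positions shifted into the observed (upper)
      # probability range [m/n, 1]
      k <- length(obs)
      pp <- (m + seq_len(k) - 0.375) / (n + 0.25)
      q <- stats::qnorm(pp)
      fit <- stats::lm.fit(cbind(1, q), sort(obs))
      mu <- fit$coefficients[1]
      sigma <- max(fit$coefficients[2], .Machine$double.eps)
      sigma_draw <- sigma * tune_sigma
      upper <- min(obs)
      # inverse-CDF draw from N(mu, sigma_draw) truncated above at `upper`
      pu <- stats::pnorm((upper - mu) / sigma_draw)
      if (pu <= 0) {
        completed[mask[, j], j] <- upper
      } else {
        u <- stats::runif(m, 0, pu)
        completed[mask[, j], j] <- mu + sigma_draw * stats::qnorm(u)
      }
    }
  })
  completed[mask] <- pmin(completed[mask],
                          rep(col_stats(ws$x, min), each = n)[mask])
  new_imputation_result(x, ws$back(completed), "qrilc",
                        seed = as.integer(seed))
}
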