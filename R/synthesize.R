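#' Configuration for the synthetic intensity-matrix generator
#'
#' Describes a correlated log-normal feature table: on the log scale each
#' cell is `mean_log_intensity + signal + noise`, where the signal is a
#' low-rank factor product (rank `latent_rank`, factor strengths decaying
#' geometrically with ratio 1/2 and normalized so the expected latent
#' variance per cell equals `sd_log_intensity^2`) and the noise is iid
#' Gaussian with sd `noise_sd`. Intensities are the exponentials, hence
#' strictly positive and log-normal, with the dominant-first-component
#' correlation structure typical of LC-MS metabolomics.
#'
#' @param n_samples,n_metabolites positive integers, matrix shape.
#' @param latent_rank non-negative integer, number of latent factors;
#'   must not exceed `min(n_samples, n_metabolites)`. 0 gives iid noise.
#' @param noise_sd non-negative residual sd on the log scale.
#' @param mean_log_intensity grand mean of log intensities.
#' @param sd_log_intensity positive; total latent (structured) sd on the
#'   log scale.
#' @param seed integer seed driving all randomness of the generator.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples, n_metabolites, latent_rank = 3,
                              noise_sd = 0.3, mean_log_intensity = 7,
                              sd_log_intensity = 1, seed = 1L) {
  stopifnot(n_samples >= 1, n_metabolites >= 1,
            noise_sd >= 0, sd_log_intensity > 0)
  if (latent_rank < 0 || latent_rank > min(n_samples, n_metabolites)) {
    stop("`latent_rank` must lie in [0, min(n_samples, n_metabolites)]",
         call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_metabolites = as.integer(n_metabolites),
         latent_rank = as.integer(latent_rank),
         noise_sd = noise_sd,
         mean_log_intensity = mean_log_intensity,
         sd_log_intensity = sd_log_intensity,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a complete synthetic intensity matrix
#'
#' @param config a [simulation_config()].
#' @return a complete [intensity_matrix()] (mask all `FALSE`).
#' @examples
#' m <- generate_complete(simulation_config(20, 10, seed = 42))
#' range(m$values)  # strictly positive
#' @export
generate_complete <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  p <- config$n_metabolites
  r <- config$latent_rank
  withr::with_seed(config$seed, {
    logs <- matrix(config$mean_log_intensity, n, p)
    if (r > 0) {
      # factor strengths halve with each component; normalized so the
      # expected per-cell latent variance is sd_log_intensity^2
      w <- 0.5^(seq_len(r) - 1)
      s <- config$sd_log_intensity * w / sqrt(sum(w^2))
      u <- matrix(stats::rnorm(n * r), n, r)
      v <- matrix(stats::rnorm(p * r), p, r)
      logs <- logs + u %*% (t(v) * s)
    }
    if (config$noise_sd > 0) {
      logs <- logs + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    }
    intensity_matrix(exp(logs))
  })
}

#' Specify a missingness mechanism
#'
#' Bundles a mechanism (`"MCAR"`, `"MAR"`, `"MNAR_LOD"` or `"MIXTURE"`)
#' with its parameters for use with [ampute()] and scenario grids.
#'
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR_LOD"`, `"MIXTURE"`.
#' @param missing_fraction target overall missing fraction in `[0, 1]`.
#'   For pure `MNAR_LOD` it doubles as the default `lod_quantile`.
#' @param mar_driver index of the fully observed driver metabolite, or
#'   `"auto"` (the highest-variance column).
#' @param mar_strength non-negative slope of the logistic dependence of
#'   missingness on the (standardized) driver; 0 degenerates to MCAR.
#' @param lod_quantile per-metabolite censoring quantile in `(0, 1)`;
#'   defaults to `missing_fraction` for pure MNAR_LOD.
#' @param lod_mode `"deterministic"` (mask exactly the cells below the
#'   column threshold) or `"probabilistic"` (logistic decay around it).
#' @param mixture_weights named non-negative weights over mechanisms
#'   (names among MCAR/MAR/MNAR_LOD) summing to 1; required iff
#'   `mechanism = "MIXTURE"`.
#' @param seed optional integer seed (used when [ampute()] is not given
#'   one).
#' @return list of class `"amputation_pattern"`.
#' @export
amputation_pattern <- function(mechanism = c("MCAR", "MAR", "MNAR_LOD", "MIXTURE"),
                               missing_fraction = 0.2,
                               mar_driver = "auto", mar_strength = 1,
                               lod_quantile = NULL,
                               lod_mode = c("deterministic", "probabilistic"),
                               mixture_weights = NULL, seed = NULL) {
  mechanism <- match.arg(mechanism)
  lod_mode <- match.arg(lod_mode)
  stopifnot(missing_fraction >= 0, missing_fraction <= 1, mar_strength >= 0)
  if (mechanism == "MIXTURE") {
    if (is.null(mixture_weights)) {
      stop("`mixture_weights` is required for mechanism MIXTURE", call. = FALSE)
    }
    if (is.null(names(mixture_weights)) ||
        !all(names(mixture_weights) %in% c("MCAR", "MAR", "MNAR_LOD"))) {
      stop("`mixture_weights` must be named with MCAR/MAR/MNAR_LOD",
           call. = FALSE)
    }
    if (any(mixture_weights < 0) || abs(sum(mixture_weights) - 1) > 1e-8) {
      stop("`mixture_weights` must be non-negative and sum to 1", call. = FALSE)
    }
  } else if (!is.null(mixture_weights)) {
    stop("`mixture_weights` is only meaningful for mechanism MIXTURE",
         call. = FALSE)
  }
  if (mechanism == "MNAR_LOD" && is.null(lod_quantile)) {
    lod_quantile <- missing_fraction
  }
  if (!is.null(lod_quantile) &&
      (lod_quantile <= 0 || lod_quantile >= 1)) {
    stop("`lod_quantile` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(mechanism = mechanism, missing_fraction = missing_fraction,
         mar_driver = mar_driver, mar_strength = mar_strength,
         lod_quantile = lod_quantile, lod_mode = lod_mode,
         mixture_weights = mixture_weights,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "amputation_pattern"
  )
}

new_amputation_result <- function(truth, mask, mech_labels) {
  structure(
    list(amputed = intensity_matrix(truth, mask = mask,
                                    sample_ids = rownames(truth),
                                    metabolite_ids = colnames(truth)),
         truth = truth,
         mechanism_per_cell = mech_labels),
    class = "amputation_result"
  )
}

#' @export
print.amputation_result <- function(x, ...) {
  tab <- table(x$mechanism_per_cell[x$amputed$mask])
  cat(sprintf("<amputation_result> %d x %d, %d masked cells (%.1f%%)\n",
              nrow(x$truth), ncol(x$truth), sum(x$amputed$mask),
              100 * mean(x$amputed$mask)))
  if (length(tab)) print(tab)
  invisible(x)
}

#' Ampute completely at random (MCAR)
#'
#' Masks each cell independently with probability `missing_fraction`,
#' emulating missingness from stochastic acquisition failures that is
#' independent of all intensities.
#'
#' @param truth complete [intensity_matrix()] or numeric matrix.
#' @param missing_fraction per-cell masking probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list of class `"amputation_result"` with elements `amputed`
#'   (intensity_matrix), `truth` (complete matrix) and
#'   `mechanism_per_cell` (character matrix, `NA` where observed).
#' @export
ampute_mcar <- function(truth, missing_fraction, seed = 1L) {
  truth <- as_truth_matrix(truth)
  stopifnot(missing_fraction >= 0, missing_fraction <= 1)
  mask <- withr::with_seed(seed, {
    matrix(stats::runif(length(truth)) < missing_fraction,
           nrow(truth), ncol(truth))
  })
  labels <- matrix(NA_character_, nrow(truth), ncol(truth))
  labels[mask] <- "MCAR"
  new_amputation_result(truth, mask, labels)
}

# expected masking probability, logistic in the standardized driver
mar_probs <- function(intercept, strength, z) stats::plogis(intercept - strength * z)

# calibrate the logistic intercept so mean masking probability over the
# non-driver cells hits `target` (bisection, relative tolerance 0.5%)
mar_calibrate_intercept <- function(strength, z, target) {
  f <- function(a) mean(mar_probs(a, strength, z)) - target
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < 0.005 * max(target, 1e-12)) break
  }
  (lo + hi) / 2
}

#' Ampute at random given an observed driver (MAR)
#'
#' Missingness in every non-driver metabolite depends, through a logistic
#' link, on the standardized value of one fully observed driver
#' metabolite: samples with low driver values lose more cells. The
#' logistic intercept is calibrated numerically so the expected overall
#' missing fraction equals `missing_fraction`; the driver column itself
#' is never masked.
#'
#' @inheritParams ampute_mcar
#' @param mar_driver column index of the driver metabolite, or `"auto"`
#'   to pick the highest-variance column.
#' @param mar_strength non-negative logistic slope; 0 reduces to MCAR.
#' @return an `"amputation_result"`; see [ampute_mcar()].
#' @export
ampute_mar <- function(truth, missing_fraction, mar_driver = "auto",
                       mar_strength = 1, seed = 1L) {
  truth <- as_truth_matrix(truth)
  stopifnot(missing_fraction >= 0, missing_fraction <= 1, mar_strength >= 0)
  p <- ncol(truth)
  if (p < 2L) stop("MAR amputation needs at least 2 metabolites", call. = FALSE)
  if (identical(mar_driver, "auto")) {
    mar_driver <- which.max(apply(truth, 2, stats::var))
  }
  mar_driver <- as.integer(mar_driver)
  if (mar_driver < 1L || mar_driver > p) {
    stop("`mar_driver` index out of range", call. = FALSE)
  }
  z <- as.numeric(scale(log(pmax(truth[, mar_driver], .Machine$double.xmin))))
  if (anyNA(z)) z <- rep(0, nrow(truth))  # constant driver
  # target fraction over non-driver cells so the overall share matches
  target <- min(1, missing_fraction * p / (p - 1))
  a <- mar_calibrate_intercept(mar_strength, z, target)
  pr <- mar_probs(a, mar_strength, z)

  mask <- withr::with_seed(seed, {
    m <- matrix(stats::runif(length(truth)), nrow(truth), p) < pr
    m[, mar_driver] <- FALSE
    m
  })
  labels <- matrix(NA_character_, nrow(truth), p)
  labels[mask] <- "MAR"
  new_amputation_result(truth, mask, labels)
}

#' Ampute by limit-of-detection censoring (MNAR)
#'
#' Left-censors each metabolite at its own empirical detection limit,
#' the `lod_quantile` quantile of that column's true values.
#' Deterministic mode masks exactly the cells strictly below the
#' threshold; probabilistic mode masks cell `(i, j)` with probability
#' decreasing logistically in `truth[i, j] - t_j` (width 0.2 column sd),
#' so masking concentrates below, but is not confined to, the threshold.
#'
#' @inheritParams ampute_mcar
#' @param lod_quantile censoring quantile in `(0, 1)`.
#' @param lod_mode `"deterministic"` or `"probabilistic"`.
#' @return an `"amputation_result"`; see [ampute_mcar()].
#' @export
ampute_mnar_lod <- function(truth, lod_quantile = 0.2,
                            lod_mode = c("deterministic", "probabilistic"),
                            seed = 1L) {
  truth <- as_truth_matrix(truth)
  lod_mode <- match.arg(lod_mode)
  stopifnot(lod_quantile > 0, lod_quantile < 1)
  thresholds <- apply(truth, 2, stats::quantile, probs = lod_quantile,
                      names = FALSE)
  if (lod_mode == "deterministic") {
    mask <- sweep(truth, 2, thresholds, "<")
  } else {
    sds <- apply(truth, 2, stats::sd)
    const <- sds == 0 | is.na(sds)
    if (any(const)) {
      warning("constant column(s) in probabilistic LOD mode; ",
              "falling back to deterministic censoring there")
      sds[const] <- Inf  # plogis(0/Inf) handled below
    }
    pr <- stats::plogis(-sweep(sweep(truth, 2, thresholds, "-"), 2,
                               0.2 * sds, "/"))
    if (any(const)) pr[, const] <- (truth < rep(thresholds, each = nrow(truth)))[, const]
    mask <- withr::with_seed(seed, {
      matrix(stats::runif(length(truth)), nrow(truth), ncol(truth)) < pr
    })
  }
  labels <- matrix(NA_character_, nrow(truth), ncol(truth))
  labels[mask] <- "MNAR_LOD"
  new_amputation_result(truth, mask, labels)
}

#' Ampute under a mixture of mechanisms
#'
#' Splits the missing-cell budget (`missing_fraction` times the cell
#' count) across mechanisms by `mixture_weights` and applies them in the
#' fixed order MNAR_LOD, MAR, MCAR on still-observed cells, so that
#' detection-limit censoring acts on the genuinely small values before
#' the random mechanisms consume budget. For a deterministic LOD
#' component the censoring quantile is derived from its budget share.
#'
#' @inheritParams ampute_mcar
#' @param pattern an [amputation_pattern()] with `mechanism = "MIXTURE"`.
#' @param seed integer seed; overrides `pattern$seed` when given.
#' @return an `"amputation_result"` whose `mechanism_per_cell` records
#'   which mechanism masked each cell.
#' @export
ampute_mixture <- function(truth, pattern, seed = NULL) {
  truth <- as_truth_matrix(truth)
  stopifnot(inherits(pattern, "amputation_pattern"))
  if (pattern$mechanism != "MIXTURE") {
    stop("`pattern` must have mechanism MIXTURE", call. = FALSE)
  }
  seed <- as.integer(seed %||% pattern$seed %||% 1L)
  n_cells <- length(truth)
  w <- pattern$mixture_weights
  budget <- round(pattern$missing_fraction * n_cells * w)
  names(budget) <- names(w)

  mask <- matrix(FALSE, nrow(truth), ncol(truth))
  labels <- matrix(NA_character_, nrow(truth), ncol(truth))

  withr::with_seed(seed, {
    b <- budget["MNAR_LOD"]
    if (!is.na(b) && b > 0) {
      q <- min(0.999, max(1e-9, b / n_cells))
      sub <- ampute_mnar_lod(truth, lod_quantile = q,
                             lod_mode = pattern$lod_mode,
                             seed = stats::runif(1) * 1e9)
      mask <- sub$amputed$mask
      labels[mask] <- "MNAR_LOD"
    }
    b <- budget["MAR"]
    if (!is.na(b) && b > 0) {
      p <- ncol(truth)
      drv <- pattern$mar_driver
      if (identical(drv, "auto")) drv <- which.max(apply(truth, 2, stats::var))
      z <- as.numeric(scale(log(pmax(truth[, drv], .Machine$double.xmin))))
      if (anyNA(z)) z <- rep(0, nrow(truth))
      wcell <- matrix(rep(stats::plogis(-pattern$mar_strength * z), p),
                      ncol = p)
      wcell[, drv] <- 0
      avail <- which(!mask & wcell > 0)
      take <- sample(avail, size = min(b, length(avail)),
                     prob = wcell[avail])
      mask[take] <- TRUE
      labels[take] <- "MAR"
    }
    b <- budget["MCAR"]
    if (!is.na(b) && b > 0) {
      avail <- which(!mask)
      take <- sample(avail, size = min(b, length(avail)))
      mask[take] <- TRUE
      labels[take] <- "MCAR"
    }
  })
  new_amputation_result(truth, mask, labels)
}

#' Apply an amputation pattern
#'
#' Dispatches to [ampute_mcar()], [ampute_mar()], [ampute_mnar_lod()] or
#' [ampute_mixture()] according to `pattern$mechanism`.
#'
#' @inheritParams ampute_mixture
#' @param pattern an [amputation_pattern()].
#' @return an `"amputation_result"`.
#' @export
ampute <- function(truth, pattern, seed = NULL) {
  stopifnot(inherits(pattern, "amputation_pattern"))
  seed <- as.integer(seed %||% pattern$seed %||% 1L)
  switch(pattern$mechanism,
    MCAR = ampute_mcar(truth, pattern$missing_fraction, seed = seed),
    MAR = ampute_mar(truth, pattern$missing_fraction,
                     mar_driver = pattern$mar_driver,
                     mar_strength = pattern$mar_strength, seed = seed),
    MNAR_LOD = ampute_mnar_lod(truth,
                               lod_quantile = pattern$lod_quantile %||%
                                 pattern$missing_fraction,
                               lod_mode = pattern$lod_mode, seed = seed),
    MIXTURE = ampute_mixture(truth, pattern, seed = seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
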