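make_im <- function(values, mask = NULL) intensity_matrix(values, mask = mask)

test_that("constant strategies fill the forced per-column values", {
  v <- matrix(c(2, 4, NA, 1, 1, 1), nrow = 3)
  m <- make_im(v)
  expect_equal(impute_constant(m, "mean")$completed[3, 1], 3)
  expect_equal(impute_constant(m, "min")$completed[3, 1], 2)
  expect_equal(impute_constant(m, "half_min")$completed[3, 1], 1)
  expect_equal(impute_constant(m, "zero")$completed[3, 1], 0)

  med <- make_im(matrix(c(1, 3, 10, NA, 5, 5, 5, 5), nrow = 4))
  expect_equal(impute_constant(med, "median")$completed[4, 1], 3)

  # fully missing column is an error naming the column, except for zero
  v2 <- matrix(c(1, 2, NA, NA), nrow = 2,
               dimnames = list(NULL, c("keep", "gone")))
  expect_error(impute_constant(make_im(v2), "mean"), "gone")
  expect_equal(unname(impute_constant(make_im(v2), "zero")$completed[, 2]),
               c(0, 0))
})

test_that("random imputation stays in range and is seed-deterministic", {
  v <- matrix(c(5, 5, 5, NA, 2, 9, 1, 7), nrow = 4)
  m <- make_im(v)
  expect_equal(impute_random(m, seed = 1)$completed[4, 1], 5)

  big <- rand_im(30, 8, 0.3, seed = 2)
  r <- impute_random(big, seed = 3)
  lo <- apply(big$values, 2, min, na.rm = TRUE)
  hi <- apply(big$values, 2, max, na.rm = TRUE)
  for (j in seq_len(8)) {
    imp <- r$completed[big$mask[, j], j]
    expect_true(all(imp >= lo[j] & imp <= hi[j]))
  }
  expect_identical(impute_random(big, seed = 3)$completed, r$completed)
  expect_false(identical(impute_random(big, seed = 4)$completed, r$completed))

  # uniform-mean calibration: 10000 draws into a [0, 1] column
  v <- cbind(c(0, 1, rep(NA, 10000)), rlnorm(10002))
  mcal <- make_im(v)
  r <- impute_random(mcal, seed = 5)
  expect_gt(mean(r$completed[3:10002, 1]), 0.47)
  expect_lt(mean(r$completed[3:10002, 1]), 0.53)
})

test_that("knn uses shared-feature distances and nearest donors", {
  # a twin sample at distance zero forces its value
  v <- rbind(c(1, 2, 3, 4),
             c(1, 2, 3, NA),
             c(9, 9, 9, 9))
  r <- impute_knn(make_im(v), k = 1)
  expect_equal(r$completed[2, 4], 4)

  # k covering all donors reduces to the column mean over other samples
  v <- matrix(rlnorm(20), 5, 4)
  v[2, 3] <- NA
  r <- impute_knn(make_im(v), k = 10, log_transform = FALSE)
  expect_equal(r$completed[2, 3], mean(v[-2, 3]))

  # exhaustive oracle agreement on small random instances
  for (seed in 1:8) {
    m <- rand_im(5, 4, 0.15, seed = seed, min_obs = 2L)
    for (k in c(1, 2, 3)) {
      expect_equal(impute_knn(m, k = k, log_transform = FALSE)$completed,
                   knn_reference(m, k), tolerance = 1e-12)
    }
  }
  expect_error(impute_knn(rand_im(), k = 0), "positive")
})

test_that("svd completion recovers exact low-rank structure", {
  u <- c(1, 2, 3, 4, 5, 6)
  w <- c(2, 1, 4, 3)
  v <- outer(u, w)
  v_missing <- v
  v_missing[3, 2] <- NA
  r <- impute_svd(make_im(v_missing), rank = 1, tol = 1e-9, max_iter = 500)
  expect_lt(abs(r$completed[3, 2] - v[3, 2]) / v[3, 2], 1e-6)
  expect_true(r$converged)

  # huge tolerance stops after exactly one refinement of the mean fill
  r1 <- impute_svd(make_im(v_missing), rank = 1, tol = 1e9)
  expect_identical(r1$n_iterations, 1L)

  expect_error(impute_svd(rand_im(5, 4), rank = 4), "rank")
})

test_that("svd iterations settle monotonically on noisy low-rank data", {
  for (seed in 1:3) {
    cfg <- simulation_config(30, 12, latent_rank = 2, noise_sd = 0.05,
                             seed = seed)
    truth <- generate_complete(cfg)
    amp <- ampute_mcar(truth, 0.15, seed = seed + 50)
    fills <- lapply(3:6, function(k) {
      impute_svd(amp$amputed, rank = 2, tol = 0, max_iter = k)$completed
    })
    deltas <- sapply(1:3, function(i) {
      sqrt(sum((log(fills[[i + 1]][amp$amputed$mask]) -
                  log(fills[[i]][amp$amputed$mask]))^2))
    })
    expect_true(all(diff(deltas) <= 1e-8))
  }
})

test_that("iterative PCA degenerates, recovers and matches svd unshrunken", {
  m <- rand_im(12, 6, 0.2, seed = 20)
  deg <- impute_iterative_pca(m, ncomp = 0, log_transform = FALSE)
  expect_identical(deg$completed, impute_constant(m, "mean")$completed)

  # parameter recovery on near-noiseless rank-2 data
  rel_err <- sapply(1:10, function(seed) {
    cfg <- simulation_config(40, 15, latent_rank = 2, noise_sd = 0.01,
                             seed = 100 + seed)
    truth <- generate_complete(cfg)
    amp <- ampute_mcar(truth, 0.1, seed = 200 + seed)
    r <- impute_iterative_pca(amp$amputed, ncomp = 2, tol = 1e-6)
    mask <- amp$amputed$mask
    median(abs(r$completed[mask] - truth$values[mask]) / truth$values[mask])
  })
  expect_lt(median(rel_err), 0.05)

  # with shrinkage off and no scaling, the fixed point matches plain svd
  amp <- ampute_mcar(generate_complete(
    simulation_config(30, 10, latent_rank = 2, noise_sd = 0.05, seed = 7)),
    0.1, seed = 8)
  a <- impute_iterative_pca(amp$amputed, ncomp = 2, regularization = 0,
                            scale = FALSE, tol = 1e-8, max_iter = 500)
  b <- impute_svd(amp$amputed, rank = 2, tol = 1e-8, max_iter = 500)
  expect_equal(a$completed, b$completed, tolerance = 1e-4)

  expect_error(impute_iterative_pca(m, ncomp = 7), "ncomp")
  expect_error(impute_iterative_pca(m, regularization = 2), "regularization")
})

test_that("forest imputation exploits functional dependence deterministically", {
  withr::with_seed(30, {
    base <- rlnorm(200, 3, 0.5)
    v <- unname(cbind(base, base, rlnorm(200, 3, 0.5)))
    miss <- sample(200, 20)
    v[miss, 2] <- NA
  })
  m <- make_im(v)
  r <- impute_forest(m, n_trees = 100, seed = 31)
  rel <- abs(r$completed[miss, 2] - base[miss]) / base[miss]
  expect_lt(mean(rel), 0.1)

  expect_identical(impute_forest(m, n_trees = 50, seed = 5)$completed,
                   impute_forest(m, n_trees = 50, seed = 5)$completed)

  complete <- make_im(matrix(rlnorm(20), 5, 4))
  r0 <- impute_forest(complete, seed = 1)
  expect_identical(r0$n_iterations, 0L)
  expect_identical(r0$completed, complete$values)

  expect_error(impute_forest(make_im(matrix(c(1, NA, 3), 3, 1)), seed = 1),
               "2 metabolites")
})

test_that("qrilc draws below the detection limit on the log scale", {
  withr::with_seed(40, {
    full <- rlnorm(400)           # standard log-normal column
    cut <- quantile(full, 0.2)
    v <- cbind(full, rlnorm(400, 1, 0.3))
    v[full < cut, 1] <- NA
  })
  m <- make_im(v)
  r <- impute_qrilc(m, seed = 41)
  imp <- r$completed[m$mask[, 1], 1]
  obs <- v[!m$mask[, 1], 1]
  expect_true(all(imp <= min(obs) * (1 + 1e-12)))
  expect_lt(mean(log(imp)), mean(log(obs)))

  # shrinkage limit: tiny tune_sigma collapses the draws
  tight <- impute_qrilc(m, tune_sigma = 0.01, seed = 42)
  expect_lt(sd(log(tight$completed[m$mask[, 1], 1])),
            0.1 * sd(log(r$completed[m$mask[, 1], 1])))

  # sparse columns fall back to half-minimum with a warning
  v2 <- matrix(c(4, 6, 8, NA, NA, NA, rlnorm(6, 2)), ncol = 2)
  expect_warning(r2 <- impute_qrilc(make_im(v2), seed = 1), "half-minimum")
  expect_equal(unname(r2$completed[4:6, 1]), rep(2, 3))
})

test_that("the registry lists 11 runnable methods with stable metadata", {
  tab <- list_methods()
  builtin <- c("zero", "min", "half_min", "mean", "median", "random",
               "knn", "svd", "iterative_pca", "forest", "qrilc")
  expect_true(all(builtin %in% tab$name))
  expect_true(tab$stochastic[tab$name == "random"])
  expect_identical(tab$family[tab$name == "random"], "random")
  expect_identical(sum(tab$family == "constant"), 5L)

  fixture <- make_im(matrix(rlnorm(25, 3, 0.4), 5, 5))
  for (nm in builtin) {
    r <- impute(fixture, nm, seed = 1)
    expect_s3_class(r, "imputation_result")
    expect_false(anyNA(r$completed))
  }
})

test_that("dispatch overlays defaults, validates params and stays silent", {
  m <- rand_im(10, 5, 0.2, seed = 50)
  expect_identical(impute(m, "mean")$completed,
                   impute_constant(m, "mean")$completed)
  expect_error(impute(m, "foo"), "zero.*qrilc|unknown")
  expect_error(impute(m, "knn", params = list(bogus = 1)), "bogus")

  # stochastic methods without a seed derive and record one
  r <- impute(m, "random")
  expect_true(is.integer(r$seed) && r$seed > 0)

  # verbose = FALSE emits nothing on any channel
  out <- capture.output(
    msgs <- capture.output(r_silent <- impute(m, "forest", seed = 1),
                           type = "message")
  )
  expect_identical(out, character(0))
  expect_identical(msgs, character(0))
})

test_that("every method preserves observed cells bit-exactly", {
  methods <- c("zero", "min", "half_min", "mean", "median", "random",
               "knn", "svd", "iterative_pca", "forest", "qrilc")
  for (seed in 1:5) {
    m <- rand_im(12, 6, 0.2, seed = seed)
    off <- !m$mask
    for (nm in methods) {
      r <- impute(m, nm, seed = seed)
      expect_identical(r$completed[off], m$values[off])
      expect_identical(r$n_imputed, sum(m$mask))
    }
  }
})

test_that("constant and knn imputation are scale-equivariant", {
  m <- rand_im(10, 6, 0.25, seed = 60)
  c_pos <- 3.7
  scaled <- intensity_matrix(m$values * c_pos, mask = m$mask)
  for (nm in c("zero", "min", "half_min", "mean", "median", "knn")) {
    r1 <- impute(m, nm)
    r2 <- impute(scaled, nm)
    expect_equal(r2$completed, c_pos * r1$completed, tolerance = 1e-12)
  }
})
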