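test_that("generator honours degenerate configs and is deterministic", {
  cfg <- simulation_config(6, 4, latent_rank = 0, noise_sd = 0,
                           mean_log_intensity = 2, seed = 5)
  m <- generate_complete(cfg)
  expect_true(all(m$values == exp(2)))
  expect_false(any(m$mask))

  cfg <- simulation_config(30, 10, seed = 99)
  expect_identical(generate_complete(cfg)$values,
                   generate_complete(cfg)$values)

  expect_error(simulation_config(5, 4, latent_rank = 6), "latent_rank")
})

test_that("generated log-intensities are centred where configured", {
  cfg <- simulation_config(200, 10, latent_rank = 3, noise_sd = 0.3,
                           mean_log_intensity = 0, sd_log_intensity = 1,
                           seed = 123)
  m <- generate_complete(cfg)
  expect_true(all(m$values > 0))
  expect_lt(abs(mean(log(m$values))), 0.1)
})

test_that("MCAR masks the target share independently of values", {
  truth <- generate_complete(simulation_config(100, 100, seed = 1))
  expect_identical(sum(ampute_mcar(truth, 0, seed = 1)$amputed$mask), 0L)
  expect_identical(sum(ampute_mcar(truth, 1, seed = 1)$amputed$mask), 10000L)

  res <- ampute_mcar(truth, 0.3, seed = 7)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.3) / 10000
  share <- mean(res$amputed$mask)
  expect_gte(share, bounds[1])
  expect_lte(share, bounds[2])
  expect_true(all(res$mechanism_per_cell[res$amputed$mask] == "MCAR"))

  # masking indicator uncorrelated with the true values across replicates
  cors <- sapply(1:20, function(s) {
    r <- ampute_mcar(truth, 0.3, seed = s)
    cor(as.numeric(r$amputed$mask), as.numeric(truth$values))
  })
  expect_lt(abs(mean(cors)), 0.01)
})

test_that("MAR depends on the driver and hits the target fraction", {
  truth <- generate_complete(simulation_config(500, 20, seed = 2))
  strong <- ampute_mar(truth, 0.2, mar_driver = 1, mar_strength = 10,
                       seed = 3)
  expect_false(any(strong$amputed$mask[, 1]))  # driver stays observed
  drv <- truth$values[, 1]
  rate <- rowMeans(strong$amputed$mask[, -1])
  bottom <- rate[drv <= quantile(drv, 0.1)]
  top <- rate[drv >= quantile(drv, 0.9)]
  expect_gt(mean(bottom), mean(top))

  big <- generate_complete(simulation_config(200, 50, seed = 4))
  cal <- ampute_mar(big, 0.2, mar_driver = 1, mar_strength = 2, seed = 5)
  expect_lt(abs(mean(cal$amputed$mask) - 0.2), 0.03)

  expect_error(ampute_mar(truth, 0.2, mar_driver = 99), "out of range")
})

test_that("zero-strength MAR is indistinguishable from MCAR", {
  truth <- generate_complete(simulation_config(100, 20, seed = 6))
  drv <- truth$values[, 1]
  pvals <- sapply(1:50, function(s) {
    r <- ampute_mar(truth, 0.2, mar_driver = 1, mar_strength = 0, seed = s)
    cor.test(drv, rowSums(r$amputed$mask))$p.value
  })
  # at alpha = 0.01 we expect ~0.5 significant results over 50 replicates
  expect_lte(sum(pvals < 0.01), 4)
})

test_that("deterministic LOD censors exactly the sub-threshold cells", {
  col <- c(10, 3, 8, 1, 6, 9, 2, 7, 5, 4)
  truth <- cbind(col, rev(col) + 0.5)
  res <- ampute_mnar_lod(truth, lod_quantile = 0.2, lod_mode = "deterministic")
  expect_identical(unname(which(res$amputed$mask[, 1])), which(col <= 2))
  expect_identical(sum(res$amputed$mask), 4L)

  big <- generate_complete(simulation_config(50, 30, seed = 8))
  r2 <- ampute_mnar_lod(big, 0.25, "deterministic")
  th <- apply(big$values, 2, quantile, 0.25)
  for (j in seq_len(30)) {
    expect_identical(unname(r2$amputed$mask[, j]),
                     unname(big$values[, j] < th[j]))
  }
})

test_that("probabilistic LOD concentrates masking on low values", {
  truth <- generate_complete(simulation_config(500, 20, seed = 10))
  res <- ampute_mnar_lod(truth, 0.3, "probabilistic", seed = 11)
  masked_lower <- sapply(seq_len(20), function(j) {
    mj <- res$amputed$mask[, j]
    any(mj) && any(!mj) &&
      mean(truth$values[mj, j]) < mean(truth$values[!mj, j])
  })
  expect_true(all(masked_lower))
})

test_that("mixtures respect budgets and label every masked cell", {
  truth <- generate_complete(simulation_config(200, 100, seed = 12))
  pat <- amputation_pattern("MIXTURE", missing_fraction = 0.2,
                            mixture_weights = c(MNAR_LOD = 0.5, MCAR = 0.5))
  res <- ampute_mixture(truth, pat, seed = 13)
  n_cells <- length(truth$values)
  counts <- table(res$mechanism_per_cell[res$amputed$mask])
  expect_true(all(abs(counts - 0.1 * n_cells) <= 0.02 * n_cells))
  expect_lt(abs(mean(res$amputed$mask) - 0.2), 0.02)
  expect_false(anyNA(res$mechanism_per_cell[res$amputed$mask]))
  expect_true(all(is.na(res$mechanism_per_cell[!res$amputed$mask])))

  # degenerate single-component mixture behaves like plain MCAR
  deg <- ampute_mixture(truth, amputation_pattern(
    "MIXTURE", missing_fraction = 0.15, mixture_weights = c(MCAR = 1)),
    seed = 14)
  expect_true(all(deg$mechanism_per_cell[deg$amputed$mask] == "MCAR"))
  expect_lt(abs(mean(deg$amputed$mask) - 0.15), 0.02)

  expect_error(amputation_pattern("MIXTURE",
                                  mixture_weights = c(MCAR = 0.7, MAR = 0.7)),
               "sum to 1")
  expect_error(amputation_pattern("MCAR", mixture_weights = c(MCAR = 1)),
               "MIXTURE")
})

test_that("amputation never alters unmasked cells and is seed-deterministic", {
  truth <- generate_complete(simulation_config(40, 15, seed = 15))
  pats <- list(
    amputation_pattern("MCAR", 0.25),
    amputation_pattern("MAR", 0.25, mar_strength = 3),
    amputation_pattern("MNAR_LOD", 0.25),
    amputation_pattern("MIXTURE", 0.25,
                       mixture_weights = c(MCAR = 0.4, MAR = 0.3,
                                           MNAR_LOD = 0.3))
  )
  for (pat in pats) {
    a <- ampute(truth, pat, seed = 21)
    b <- ampute(truth, pat, seed = 21)
    expect_identical(a$amputed$mask, b$amputed$mask)
    off <- !a$amputed$mask
    expect_identical(a$amputed$values[off], truth$values[off])
    expect_identical(a$truth, truth$values)
  }
})

test_that("scenario grids are exact cross products with derived seeds", {
  expect_length(benchmark_grid(default_patterns()[1],
                               default_shapes()[1]), 1L)
  g <- benchmark_grid(default_patterns()[1:3], default_shapes()[1:4],
                      grid_seed = 2)
  expect_length(g, 12L)
  keys <- sapply(g, function(s) {
    paste(s$pattern$mechanism, s$pattern$missing_fraction,
          s$config$n_samples, s$config$n_metabolites)
  })
  expect_identical(anyDuplicated(keys), 0L)
  ids <- sapply(g, `[[`, "scenario_id")
  expect_identical(anyDuplicated(ids), 0L)

  g2 <- benchmark_grid(default_patterns()[1:3], default_shapes()[1:4],
                       grid_seed = 2)
  expect_identical(sapply(g2, `[[`, "seed"), sapply(g, `[[`, "seed"))
  seeds <- sapply(g, `[[`, "seed")
  expect_true(all(seeds > 0 & seeds < 2^31))
})
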