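# scenario grids -------------------------------------------------------

#' Expand a benchmark scenario grid
#'
#' Crosses amputation patterns with data shapes into the full list of
#' benchmark scenarios, each with a reproducible scenario id and a seed
#' derived from `grid_seed` by a counter-based scheme, so scenarios can
#' be regenerated independently (and in parallel) from their seed alone.
#'
#' @param patterns list of [amputation_pattern()] objects.
#' @param shapes list of [simulation_config()] objects.
#' @param grid_seed integer master seed.
#' @return list of class `"benchmark_grid"`; each element is a
#'   `"benchmark_scenario"` with `scenario_id`, `config`, `pattern`,
#'   `seed`.
#' @examples
#' g <- benchmark_grid(default_patterns(), default_shapes())
#' length(g)  # 230
#' @export
benchmark_grid <- function(patterns, shapes, grid_seed = 1L) {
  stopifnot(length(patterns) > 0, length(shapes) > 0)
  lapply(patterns, function(p) stopifnot(inherits(p, "amputation_pattern")))
  lapply(shapes, function(s) stopifnot(inherits(s, "simulation_config")))
  grid_seed <- as.integer(grid_seed)

  scenarios <- list()
  idx <- 0L
  for (si in seq_along(shapes)) {
    for (pi in seq_along(patterns)) {
      idx <- idx + 1L
      cfg <- shapes[[si]]
      pat <- patterns[[pi]]
      seed <- derive_seed(grid_seed, idx)
      cfg$seed <- derive_seed(seed, 1L)
      id <- sprintf("s%03d_%s_f%02.0f_%dx%d", idx, tolower(pat$mechanism),
                    100 * pat$missing_fraction, cfg$n_samples,
                    cfg$n_metabolites)
      scenarios[[idx]] <- structure(
        list(scenario_id = id, config = cfg, pattern = pat, seed = seed),
        class = "benchmark_scenario")
    }
  }
  structure(scenarios, class = c("benchmark_grid", "list"))
}

# counter-based derived seeds, kept inside the 32-bit integer range
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 1000003 + as.double(counter) * 7919) %%
               2147483563) + 1L
}

#' Default amputation patterns (10)
#'
#' Missing fractions 0.1/0.2/0.3 crossed with MCAR, MAR and
#' deterministic MNAR-LOD, plus one equal-weight three-way mixture at
#' fraction 0.2. These are this package's stand-in defaults for a
#' 10-pattern benchmark design.
#'
#' @return list of 10 [amputation_pattern()] objects.
#' @export
default_patterns <- function() {
  out <- list()
  for (f in c(0.1, 0.2, 0.3)) {
    out <- c(out, list(
      amputation_pattern("MCAR", missing_fraction = f),
      amputation_pattern("MAR", missing_fraction = f, mar_strength = 2),
      amputation_pattern("MNAR_LOD", missing_fraction = f)
    ))
  }
  c(out, list(amputation_pattern(
    "MIXTURE", missing_fraction = 0.2,
    mixture_weights = c(MCAR = 1 / 3, MAR = 1 / 3, MNAR_LOD = 1 / 3))))
}

#' Default dataset shapes (23)
#'
#' Shapes spanning 20-500 samples by 10-200 metabolites, emulating the
#' size range of published metabolomics feature tables.
#'
#' @param ... passed on to [simulation_config()] (e.g. `latent_rank`).
#' @return list of 23 [simulation_config()] objects.
#' @export
default_shapes <- function(...) {
  dims <- list(
    c(20, 10), c(20, 25), c(20, 50), c(20, 100),
    c(50, 10), c(50, 25), c(50, 50), c(50, 100), c(50, 200),
    c(100, 10), c(100, 25), c(100, 50), c(100, 100), c(100, 200),
    c(200, 10), c(200, 25), c(200, 50), c(200, 100), c(200, 200),
    c(500, 10), c(500, 25), c(500, 50), c(500, 100)
  )
  lapply(dims, function(d) simulation_config(d[1], d[2], ...))
}

#' The default benchmark grid (230 scenarios)
#'
#' @inheritParams benchmark_grid
#' @return a `"benchmark_grid"` of `10 * 23 = 230` scenarios.
#' @export
default_benchmark_grid <- function(grid_seed = 1L) {
  benchmark_grid(default_patterns(), default_shapes(), grid_seed = grid_seed)
}

# harness ---------------------------------------------------------------

# run fn() in a forked child that can be killed after `timeout_s`
# wall-clock seconds; returns list(status, value/message, wall_time_s)
run_with_timeout <- function(fn, timeout_s) {
  t0 <- proc.time()[["elapsed"]]
  if (.Platform$OS.type != "unix") {
    # no fork available: run inline, without hard timeout enforcement
    val <- tryCatch(fn(), error = function(e) e)
    wall <- proc.time()[["elapsed"]] - t0
    if (inherits(val, "error")) {
      return(list(status = "error", message = conditionMessage(val),
                  wall_time_s = wall))
    }
    return(list(status = "ok", value = val, wall_time_s = wall))
  }
  job <- parallel::mcparallel(tryCatch(fn(), error = function(e) {
    structure(list(message = conditionMessage(e)), class = "metimp_child_error")
  }), silent = TRUE)
  res <- parallel::mccollect(job, wait = FALSE, timeout = timeout_s)
  wall <- proc.time()[["elapsed"]] - t0
  if (is.null(res)) {
    tools::pskill(job$pid, tools::SIGKILL)
    parallel::mccollect(job, wait = FALSE)
    return(list(status = "timeout",
                message = sprintf("exceeded %gs budget", timeout_s),
                wall_time_s = wall))
  }
  val <- res[[1]]
  if (inherits(val, "metimp_child_error")) {
    return(list(status = "error", message = val$message, wall_time_s = wall))
  }
  if (inherits(val, "try-error")) {
    return(list(status = "error", message = as.character(val),
                wall_time_s = wall))
  }
  list(status = "ok", value = val, wall_time_s = wall)
}

#' Run one method on one benchmark scenario
#'
#' Regenerates the scenario's ground truth, amputes it under the
#' scenario pattern, then runs the method with its registry defaults in
#' a terminatable forked child under a per-attempt wall-clock budget.
#' Up to `attempts` tries are made, stopping at the first success; a
#' method failing all attempts is "not working" for the scenario.
#' Failures are captured as results, never propagated.
#'
#' @param method registered method name.
#' @param scenario a `"benchmark_scenario"` from [benchmark_grid()].
#' @param timeout_s wall-clock budget per attempt, seconds (default 120).
#' @param attempts maximum attempts (default 3).
#' @param params hyperparameter overrides forwarded to [impute()].
#' @return data frame with one row per attempt: `method`, `scenario_id`,
#'   `attempt`, `status` (`ok`/`error`/`timeout`), `nrmse` (`NA` unless
#'   ok), `wall_time_s`, `error_message`.
#' @export
run_scenario <- function(method, scenario, timeout_s = 120, attempts = 3L,
                         params = list()) {
  stopifnot(inherits(scenario, "benchmark_scenario"),
            timeout_s > 0, attempts >= 1)
  registry_get(method)  # fail fast on unknown methods
  truth_im <- generate_complete(scenario$config)
  amp <- ampute(truth_im, scenario$pattern, seed = derive_seed(scenario$seed, 2L))

  rows <- list()
  for (a in seq_len(attempts)) {
    attempt_seed <- derive_seed(scenario$seed, 10L + a)
    out <- run_with_timeout(function() {
      impute(amp$amputed, method, params = params, verbose = FALSE,
             seed = attempt_seed)
    }, timeout_s)
    score <- NA_real_
    msg <- NA_character_
    if (out$status == "ok") {
      score <- nrmse(amp$truth, out$value, amp$amputed$mask)$value
    } else {
      msg <- out$message
    }
    rows[[a]] <- data.frame(
      method = method, scenario_id = scenario$scenario_id, attempt = a,
      status = out$status, nrmse = score, wall_time_s = out$wall_time_s,
      error_message = msg, stringsAsFactors = FALSE)
    if (out$status == "ok") break
  }
  do.call(rbind, rows)
}

#' Run a full benchmark
#'
#' Executes every method on every scenario of a grid. Unknown method
#' names fail fast before anything runs; individual imputation failures
#' are captured per attempt and never abort the benchmark. Results are
#' reproducible from the grid seed: scenario data are regenerated from
#' derived seeds, not stored.
#'
#' @param methods character vector of registered method names.
#' @param grid a `"benchmark_grid"` (or list of scenarios).
#' @inheritParams run_scenario
#' @param verbose print one line per (method, scenario).
#' @return data frame of per-attempt results; see [run_scenario()].
#' @export
run_benchmark <- function(methods, grid, timeout_s = 120, attempts = 3L,
                          verbose = FALSE) {
  stopifnot(length(methods) > 0, length(grid) > 0)
  for (m in methods) registry_get(m)
  out <- list()
  for (m in methods) {
    for (sc in grid) {
      res <- run_scenario(m, sc, timeout_s = timeout_s, attempts = attempts)
      if (verbose) {
        message(sprintf("%s @ %s: %s", m, sc$scenario_id,
                        res$status[nrow(res)]))
      }
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}

#' Summarize benchmark results per method
#'
#' Collapses per-attempt results into one row per method: the success
#' rate (share of scenarios with at least one successful attempt), mean
#' NRMSE over successful scenarios (first successful attempt each),
#' per-mechanism mean NRMSE, maximum wall time over all attempts, and
#' the share of failed attempts attributable to timeouts versus errors.
#'
#' @param results per-attempt data frame from [run_benchmark()].
#' @param grid the grid the results were computed on.
#' @return data frame of class `"method_performance"` with columns
#'   `method`, `success_rate`, `mean_nrmse`, `nrmse_MCAR`, `nrmse_MAR`,
#'   `nrmse_MNAR_LOD`, `nrmse_MIXTURE`, `max_time_s`, `timeout_share`,
#'   `error_share`.
#' @export
summarize_benchmark <- function(results, grid) {
  mech <- vapply(grid, function(s) s$pattern$mechanism, character(1))
  names(mech) <- vapply(grid, `[[`, character(1), "scenario_id")
  n_scen <- length(grid)
  mechanisms <- c("MCAR", "MAR", "MNAR_LOD", "MIXTURE")

  rows <- lapply(split(results, results$method), function(r) {
    by_scen <- split(r, r$scenario_id)
    ok_first <- lapply(by_scen, function(s) {
      ok <- s[s$status == "ok", , drop = FALSE]
      if (nrow(ok) > 0) ok[1, , drop = FALSE] else NULL
    })
    ok_first <- do.call(rbind, ok_first)
    n_ok <- if (is.null(ok_first)) 0L else nrow(ok_first)
    per_mech <- vapply(mechanisms, function(mm) {
      if (is.null(ok_first)) return(NA_real_)
      v <- ok_first$nrmse[mech[ok_first$scenario_id] == mm]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    failed <- r[r$status != "ok", , drop = FALSE]
    data.frame(
      method = r$method[1],
      success_rate = n_ok / n_scen,
      mean_nrmse = if (n_ok > 0) mean(ok_first$nrmse) else NA_real_,
      nrmse_MCAR = per_mech[["MCAR"]],
      nrmse_MAR = per_mech[["MAR"]],
      nrmse_MNAR_LOD = per_mech[["MNAR_LOD"]],
      nrmse_MIXTURE = per_mech[["MIXTURE"]],
      max_time_s = max(r$wall_time_s),
      timeout_share = if (nrow(failed) > 0) {
        mean(failed$status == "timeout")
      } else NA_real_,
      error_share = if (nrow(failed) > 0) {
        mean(failed$status == "error")
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("method_performance", "data.frame")
  out
}

#' Rank methods by accuracy or speed
#'
#' Orders methods by per-mechanism (or overall) mean NRMSE, or by
#' maximum wall time. Methods whose success rate falls below
#' `success_floor` are demoted below all reliable methods regardless of
#' score — an unstable method is not a recommendation. Ties break
#' alphabetically.
#'
#' @param performance a `"method_performance"` data frame from
#'   [summarize_benchmark()].
#' @param criterion `"accuracy"` or `"speed"`.
#' @param mechanism `"MCAR"`, `"MAR"`, `"MNAR_LOD"`, `"MIXTURE"` or
#'   `"overall"`.
#' @param success_floor demotion threshold on the success rate
#'   (default 0.8).
#' @return character vector of method names, best first.
#' @export
rank_methods <- function(performance, criterion = c("accuracy", "speed"),
                         mechanism = "overall", success_floor = 0.8) {
  criterion <- match.arg(criterion)
  valid_mech <- c("overall", "MCAR", "MAR", "MNAR_LOD", "MIXTURE")
  if (!mechanism %in% valid_mech) {
    stop("unknown mechanism '", mechanism, "'; expected one of ",
         paste(valid_mech, collapse = ", "), call. = FALSE)
  }
  score <- if (criterion == "speed") {
    performance$max_time_s
  } else if (mechanism == "overall") {
    performance$mean_nrmse
  } else {
    performance[[paste0("nrmse_", mechanism)]]
  }
  demoted <- performance$success_rate < success_floor | is.na(score)
  score[is.na(score)] <- Inf
  performance$method[order(demoted, score, performance$method)]
}
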