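#' Recommend imputation methods for a missingness pattern
#'
#' Returns a ranked list of methods for a (mechanism, criterion) query.
#' Given a `performance` table from your own [run_benchmark()] run, the
#' ranking is a pure reordering of [rank_methods()] output on your data.
#' Without one, the shipped default table is returned: curated
#' per-mechanism rankings whose accuracy leaders map the per-pattern
#' winners reported in the metabolomics imputation literature onto this
#' package's native method families (MCAR: random forest, MAR:
#' regularized iterative PCA, MNAR from detection limits: minimum).
#' The recommendation is advisory only and is never auto-applied:
#' method choice should be made a priori from an understanding of the
#' missingness mechanism, not picked post hoc to favour a hypothesis.
#'
#' @param mechanism `"MCAR"`, `"MAR"`, `"MNAR_LOD"` or `"overall"`.
#' @param criterion `"accuracy"` or `"speed"`.
#' @param performance optional `"method_performance"` table from
#'   [summarize_benchmark()].
#' @param success_floor passed to [rank_methods()] when `performance`
#'   is given.
#' @return list of class `"recommendation"` with `query`,
#'   `ranked_methods`, `source` (`"shipped_defaults"` or
#'   `"user_benchmark"`) and `caveat`.
#' @examples
#' recommend_method("MNAR_LOD", "accuracy")$ranked_methods[1]  # "min"
#' @export
recommend_method <- function(mechanism = c("MCAR", "MAR", "MNAR_LOD", "overall"),
                             criterion = c("accuracy", "speed"),
                             performance = NULL, success_floor = 0.8) {
  mechanism <- match.arg(toupper(mechanism[1]),
                         c("MCAR", "MAR", "MNAR_LOD", "OVERALL"))
  if (mechanism == "OVERALL") mechanism <- "overall"
  criterion <- match.arg(criterion)

  if (!is.null(performance)) {
    ranked <- rank_methods(performance, criterion = criterion,
                           mechanism = mechanism,
                           success_floor = success_floor)
    return(structure(
      list(query = list(mechanism = mechanism, criterion = criterion),
           ranked_methods = ranked,
           source = "user_benchmark",
           caveat = "Ranking computed from the supplied benchmark results."),
      class = "recommendation"))
  }

  tab <- utils::read.csv(system.file("extdata", "recommended_methods.csv",
                                     package = "metimp"),
                         stringsAsFactors = FALSE)
  sel <- tab[tab$mechanism == mechanism & tab$criterion == criterion, ,
             drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no shipped ranking for (", mechanism, ", ", criterion, ")",
         call. = FALSE)
  }
  ranked <- sel$method[order(sel$rank)]
  known <- ranked %in% list_methods()$name
  if (!any(known)) {
    stop("shipped ranking contains no registered method", call. = FALSE)
  }
  structure(
    list(query = list(mechanism = mechanism, criterion = criterion),
         ranked_methods = ranked[known],
         source = "shipped_defaults",
         caveat = paste(
           "Shipped default ranking: per-mechanism winners reported for",
           "metabolomics imputation benchmarks, mapped onto this package's",
           "native method families and ordered by family suitability.",
           "It was not computed from your data; run run_benchmark() on",
           "scenarios resembling your data for a data-specific ranking.")),
    class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> %s / %s (%s)\n", x$query$mechanism,
              x$query$criterion, x$source))
  cat(paste(sprintf("%2d. %s", seq_along(x$ranked_methods),
                    x$ranked_methods), collapse = "\n"), "\n")
  cat("note:", x$caveat, "\n")
  invisible(x)
}

# grid (de)serialization ------------------------------------------------

#' Save / load a benchmark grid as YAML
#'
#' Serializes patterns, shapes and seeds of a scenario grid to a plain
#' YAML file, so grids can be versioned and re-expanded elsewhere.
#'
#' @param grid a `"benchmark_grid"`.
#' @param path YAML file path.
#' @return `save_grid`: `path` invisibly; `load_grid`: the grid.
#' @export
save_grid <- function(grid, path) {
  ser <- lapply(grid, function(s) {
    pat <- Filter(Negate(is.null), unclass(s$pattern))
    if (!is.null(pat$mixture_weights)) {
      pat$mixture_weights <- as.list(pat$mixture_weights)  # YAML map
    }
    list(scenario_id = s$scenario_id,
         seed = s$seed,
         config = unclass(s$config),
         pattern = pat)
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  ser <- yaml::read_yaml(path)
  out <- lapply(ser, function(s) {
    cfg <- do.call(simulation_config, s$config)
    pat_args <- s$pattern
    if (!is.null(pat_args$mixture_weights)) {
      pat_args$mixture_weights <- unlist(pat_args$mixture_weights)
    }
    pat <- do.call(amputation_pattern, pat_args)
    structure(list(scenario_id = s$scenario_id, config = cfg,
                   pattern = pat, seed = as.integer(s$seed)),
              class = "benchmark_scenario")
  })
  structure(out, class = c("benchmark_grid", "list"))
}
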