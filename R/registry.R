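# method registry -----------------------------------------------------

.registry <- new.env(parent = emptyenv())

#' Register an imputation method
#'
#' Adds a method to the dispatch registry used by [impute()] and the
#' benchmark harness. The eleven built-in methods are registered when
#' the package loads; this function is mainly useful for plugging
#' experimental or test methods into the harness.
#'
#' @param name unique method name.
#' @param fun function with signature `function(x, params, verbose,
#'   seed)` returning an `"imputation_result"` (or a completed matrix,
#'   which is wrapped automatically).
#' @param family free-text family label.
#' @param defaults named list of complete default hyperparameters.
#' @param stochastic does the method consume a seed?
#' @param overwrite replace an existing entry of the same name.
#' @return `name`, invisibly.
#' @export
register_method <- function(name, fun, family = "custom", defaults = list(),
                            stochastic = FALSE, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  if (!overwrite && !is.null(.registry$methods[[name]])) {
    stop("method '", name, "' is already registered", call. = FALSE)
  }
  entry <- list(name = name, family = family, defaults = defaults,
                stochastic = stochastic, fun = fun)
  if (is.null(.registry$methods)) .registry$methods <- list()
  .registry$methods[[name]] <- entry
  invisible(name)
}

registry_get <- function(name) {
  entry <- .registry$methods[[name]]
  if (is.null(entry)) {
    stop("unknown imputation method '", name, "'; registered methods: ",
         paste(names(.registry$methods), collapse = ", "), call. = FALSE)
  }
  entry
}

#' List registered imputation methods
#'
#' @return data frame with one row per method: `name`, `family`,
#'   `stochastic`, and `defaults` (deparsed), in stable registration
#'   order (the 11 built-ins first).
#' @examples
#' list_methods()
#' @export
list_methods <- function() {
  entries <- .registry$methods
  data.frame(
    name = vapply(entries, `[[`, character(1), "name"),
    family = vapply(entries, `[[`, character(1), "family"),
    stochastic = vapply(entries, `[[`, logical(1), "stochastic"),
    defaults = vapply(entries, function(e) {
      if (length(e$defaults) == 0) return("")
      paste(names(e$defaults), vapply(e$defaults, format, character(1)),
            sep = "=", collapse = ", ")
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Impute missing values by method name
#'
#' Uniform dispatcher over the method registry: defaults are overlaid
#' with `params`, stochastic methods receive (or derive and record) a
#' seed, and the result always satisfies the package contract — observed
#' cells come back bit-identical and, on convergence, no missing cells
#' remain.
#'
#' @param x an [intensity_matrix()].
#' @param method registered method name; built-ins are `"zero"`,
#'   `"min"`, `"half_min"`, `"mean"`, `"median"`, `"random"`, `"knn"`,
#'   `"svd"`, `"iterative_pca"`, `"forest"`, `"qrilc"`.
#' @param params named list overriding the method's default
#'   hyperparameters; unknown names are an error.
#' @param verbose print progress output (default `FALSE`: silent).
#' @param seed integer seed for stochastic methods; when omitted one is
#'   drawn and recorded in the result.
#' @return an `"imputation_result"`; see [impute_constant()].
#' @examples
#' m <- intensity_matrix(matrix(c(2, 4, NA, 1, 2, 3), nrow = 3))
#' impute(m, "mean")$completed
#' @export
impute <- function(x, method, params = list(), verbose = FALSE, seed = NULL) {
  stopifnot(is_intensity_matrix(x))
  entry <- registry_get(method)
  unknown <- setdiff(names(params), names(entry$defaults))
  if (length(unknown) > 0) {
    stop("invalid parameter(s) for method '", method, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(entry$defaults, params)
  if (entry$stochastic && is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1L)
    if (verbose) message("derived seed for '", method, "': ", seed)
  }
  res <- entry$fun(x, merged, verbose, seed)
  if (!inherits(res, "imputation_result")) {
    res <- new_imputation_result(x, as.matrix(res), method,
                                 seed = if (is.null(seed)) NULL else as.integer(seed))
  }
  if (entry$stochastic) res$seed <- as.integer(seed)
  res$method <- method
  res
}

register_builtins <- function() {
  for (strat in c("zero", "min", "half_min", "mean", "median")) {
    local({
      s <- strat
      register_method(s, function(x, params, verbose, seed) {
        impute_constant(x, s)
      }, family = "constant", overwrite = TRUE)
    })
  }
  register_method("random", function(x, params, verbose, seed) {
    impute_random(x, seed = seed)
  }, family = "random", stochastic = TRUE, overwrite = TRUE)
  register_method("knn", function(x, params, verbose, seed) {
    impute_knn(x, k = params$k, log_transform = params$log_transform)
  }, family = "neighbour", defaults = list(k = 5L, log_transform = TRUE),
  overwrite = TRUE)
  register_method("svd", function(x, params, verbose, seed) {
    impute_svd(x, rank = params$rank, tol = params$tol,
               max_iter = params$max_iter, log_transform = params$log_transform)
  }, family = "low_rank",
  defaults = list(rank = 2L, tol = 1e-4, max_iter = 100L, log_transform = TRUE),
  overwrite = TRUE)
  register_method("iterative_pca", function(x, params, verbose, seed) {
    impute_iterative_pca(x, ncomp = params$ncomp,
                         regularization = params$regularization,
                         tol = params$tol, max_iter = params$max_iter,
                         scale = params$scale,
                         log_transform = params$log_transform)
  }, family = "iterative_model",
  defaults = list(ncomp = 2L, regularization = 1, tol = 1e-4,
                  max_iter = 100L, scale = TRUE, log_transform = TRUE),
  overwrite = TRUE)
  register_method("forest", function(x, params, verbose, seed) {
    impute_forest(x, n_trees = params$n_trees, max_iter = params$max_iter,
                  seed = seed, log_transform = params$log_transform,
                  verbose = verbose)
  }, family = "iterative_model", stochastic = TRUE,
  defaults = list(n_trees = 100L, max_iter = 10L, log_transform = TRUE),
  overwrite = TRUE)
  register_method("qrilc", function(x, params, verbose, seed) {
    impute_qrilc(x, tune_sigma = params$tune_sigma, seed = seed,
                 log_transform = params$log_transform)
  }, family = "censored", stochastic = TRUE,
  defaults = list(tune_sigma = 1, log_transform = TRUE), overwrite = TRUE)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtins()
}
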