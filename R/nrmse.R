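#' Normalized root mean squared error over imputed cells
#'
#' The benchmark's accuracy measure: squared imputation errors at the
#' masked cells are normalized by the true variance of their own
#' metabolite before averaging,
#' \deqn{\mathrm{NRMSE} = \sqrt{\mathrm{mean}_{(i,j)\,\mathrm{masked}}
#'   \left[ (c_{ij} - t_{ij})^2 / \mathrm{Var}(t_{\cdot j}) \right]},}
#' which makes the measure insensitive to heteroscedasticity across
#' metabolites: multiplying any single column of truth and completion
#' by a constant leaves it unchanged. `Var` is the sample variance
#' (denominator `n - 1`, R's `var()`).
#'
#' @param truth complete reference matrix (or complete
#'   [intensity_matrix()]).
#' @param completed imputed matrix of the same shape (or an
#'   `"imputation_result"`).
#' @param mask logical matrix marking the cells to score (the amputed
#'   cells); must contain at least one `TRUE`.
#' @return list of class `"nrmse_value"` with `value` (non-negative
#'   real, 0 iff the imputation is perfect on every scored cell) and
#'   `n_cells` (number of cells scored).
#' @examples
#' truth <- matrix(1:5, 5, 1)
#' comp <- truth; comp[c(2, 4), 1] <- 3
#' mask <- matrix(FALSE, 5, 1); mask[c(2, 4), 1] <- TRUE
#' nrmse(truth, comp, mask)$value  # 0.6325
#' @export
nrmse <- function(truth, completed, mask) {
  truth <- as_truth_matrix(truth)
  if (inherits(completed, "imputation_result")) completed <- completed$completed
  completed <- as.matrix(completed)
  mask <- as.matrix(mask)
  if (!identical(dim(truth), dim(completed)) ||
      !identical(dim(truth), dim(mask))) {
    stop("`truth`, `completed` and `mask` must have identical dimensions",
         call. = FALSE)
  }
  if (!any(mask)) stop("`mask` scores no cells", call. = FALSE)

  cols <- which(colSums(mask) > 0)
  vars <- apply(truth[, cols, drop = FALSE], 2, stats::var)
  if (any(vars == 0 | is.na(vars))) {
    bad <- cols[vars == 0 | is.na(vars)]
    nm <- if (!is.null(colnames(truth))) colnames(truth)[bad] else bad
    stop("zero-variance column(s) cannot be scored: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  total <- 0
  for (idx in seq_along(cols)) {
    j <- cols[idx]
    mj <- mask[, j]
    total <- total + sum((completed[mj, j] - truth[mj, j])^2) / vars[idx]
  }
  structure(list(value = unname(sqrt(total / sum(mask))), n_cells = sum(mask)),
            class = "nrmse_value")
}

#' @export
print.nrmse_value <- function(x, ...) {
  cat(sprintf("NRMSE %.4f over %d imputed cells\n", x$value, x$n_cells))
  invisible(x)
}
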