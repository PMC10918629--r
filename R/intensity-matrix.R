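#' Intensity matrix with an explicit missingness mask
#'
#' The central container of the package: a numeric sample-by-metabolite
#' table of non-negative intensities together with a logical mask marking
#' missing cells. Samples are rows, metabolites are columns; the package
#' never auto-transposes. Cells flagged in `mask` are stored as `NA` in
#' `values` so that no code path can accidentally read them as data.
#'
#' @param values numeric matrix (or object coercible to one),
#'   `n_samples x n_metabolites`. `NA`/`NaN` entries are taken as missing.
#' @param mask optional logical matrix of the same shape; `TRUE` marks a
#'   missing cell. Defaults to `is.na(values)`. Cells that are `NA` in
#'   `values` are always masked.
#' @param sample_ids,metabolite_ids optional character vectors of row and
#'   column labels. Default to existing dimnames, or `S1..`/`M1..`.
#'
#' @return An object of class `"intensity_matrix"`: a list with elements
#'   `values`, `mask`, `sample_ids`, `metabolite_ids`.
#'
#' @details Observed values are allowed to violate the non-negativity
#'   contract at construction time; [validate_intensities()] reports such
#'   cells instead of throwing, mirroring a check-then-fix workflow.
#'   Duplicated sample or metabolite identifiers are an error: silently
#'   renamed columns are a classic source of metabolite mix-ups.
#'
#' @examples
#' m <- intensity_matrix(matrix(c(1, 2, NA, 4, 5, 6), nrow = 3))
#' n_missing(m)
#' @export
intensity_matrix <- function(values, mask = NULL, sample_ids = NULL,
                             metabolite_ids = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L) {
    stop("intensity matrix must contain at least one cell", call. = FALSE)
  }
  if (!is.numeric(values)) {
    stop("intensity values must be numeric", call. = FALSE)
  }
  storage.mode(values) <- "double"

  if (is.null(mask)) {
    mask <- is.na(values)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) {
      stop("`mask` and `values` must have identical dimensions", call. = FALSE)
    }
    if (!is.logical(mask) || anyNA(mask)) {
      stop("`mask` must be logical with no NA entries", call. = FALSE)
    }
    mask <- mask | is.na(values)
  }

  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(metabolite_ids)) {
    metabolite_ids <- colnames(values)
    if (is.null(metabolite_ids)) metabolite_ids <- paste0("M", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("`sample_ids` length must equal the number of rows", call. = FALSE)
  }
  if (length(metabolite_ids) != ncol(values)) {
    stop("`metabolite_ids` length must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metabolite_ids)) {
    stop("duplicated metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "),
         call. = FALSE)
  }

  values[mask] <- NA_real_
  dimnames(values) <- list(sample_ids, metabolite_ids)
  dimnames(mask) <- list(sample_ids, metabolite_ids)

  structure(
    list(values = values, mask = mask, sample_ids = sample_ids,
         metabolite_ids = metabolite_ids),
    class = "intensity_matrix"
  )
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
as.matrix.intensity_matrix <- function(x, ...) x$values

#' @export
print.intensity_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<intensity_matrix> %d samples x %d metabolites, %d missing (%.1f%%)\n",
              d[1], d[2], n_missing(x), 100 * n_missing(x) / prod(d)))
  k <- min(5L, d[1])
  print(utils::head(x$values[seq_len(k), , drop = FALSE], k))
  if (d[1] > k) cat(sprintf("... %d more samples\n", d[1] - k))
  invisible(x)
}

is_intensity_matrix <- function(x) inherits(x, "intensity_matrix")

#' Number of missing cells
#' @param x an [intensity_matrix()].
#' @return integer count of masked cells.
#' @export
n_missing <- function(x) {
  stopifnot(is_intensity_matrix(x))
  sum(x$mask)
}

# Coerce a "ground truth" argument (complete intensity_matrix or plain
# numeric matrix) to a bare complete matrix.
as_truth_matrix <- function(truth) {
  if (is_intensity_matrix(truth)) {
    if (any(truth$mask)) {
      stop("ground-truth matrix must be complete (no masked cells)", call. = FALSE)
    }
    return(truth$values)
  }
  truth <- as.matrix(truth)
  if (anyNA(truth)) {
    stop("ground-truth matrix must be complete (no NA cells)", call. = FALSE)
  }
  storage.mode(truth) <- "double"
  if (is.null(rownames(truth))) rownames(truth) <- paste0("S", seq_len(nrow(truth)))
  if (is.null(colnames(truth))) colnames(truth) <- paste0("M", seq_len(ncol(truth)))
  truth
}

#' Validate an intensity matrix
#'
#' Checks the data contract for metabolomics feature tables: every
#' observed cell must be a finite, non-negative number. Problems are
#' reported, not thrown, so that a whole table can be triaged in one pass.
#'
#' @param x an [intensity_matrix()].
#' @return An object of class `"validation_report"`: list with `ok`
#'   (logical), `n_missing`, `missing_fraction_per_metabolite` (named
#'   numeric in `[0, 1]`), and `offending_cells` (data frame with columns
#'   `sample`, `metabolite`, `reason`).
#' @examples
#' m <- intensity_matrix(matrix(c(1, -2.5, 3, 4), 2))
#' validate_intensities(m)$offending_cells
#' @export
validate_intensities <- function(x) {
  stopifnot(is_intensity_matrix(x))
  v <- x$values
  obs <- !x$mask

  bad_nonfinite <- obs & (is.na(v) | !is.finite(v))
  bad_negative <- obs & !bad_nonfinite & (v < 0)

  cells <- function(ind, reason) {
    idx <- which(ind, arr.ind = TRUE)
    data.frame(sample = x$sample_ids[idx[, 1]],
               metabolite = x$metabolite_ids[idx[, 2]],
               reason = rep(reason, nrow(idx)),
               stringsAsFactors = FALSE)
  }
  offending <- rbind(cells(bad_negative, "negative"),
                     cells(bad_nonfinite, "non-finite"))
  offending <- offending[order(match(offending$metabolite, x$metabolite_ids),
                               match(offending$sample, x$sample_ids)), ,
                         drop = FALSE]
  rownames(offending) <- NULL

  frac <- colMeans(x$mask)
  names(frac) <- x$metabolite_ids

  structure(
    list(ok = nrow(offending) == 0L,
         n_missing = sum(x$mask),
         missing_fraction_per_metabolite = frac,
         offending_cells = offending),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok: %s, missing cells: %d\n",
              x$ok, x$n_missing))
  if (!x$ok) {
    cat("offending cells:\n")
    print(x$offending_cells)
  }
  invisible(x)
}

#' Numeric missingness summary
#'
#' Per-metabolite and per-sample missing fractions plus the total missing
#' fraction, for a quick look at the missingness structure before
#' choosing an imputation method.
#'
#' @param x an [intensity_matrix()].
#' @return list of class `"missingness_summary"` with `per_metabolite`
#'   and `per_sample` (named numerics in `[0, 1]`) and `total_fraction`.
#' @export
missingness_summary <- function(x) {
  stopifnot(is_intensity_matrix(x))
  per_met <- colMeans(x$mask)
  names(per_met) <- x$metabolite_ids
  per_samp <- rowMeans(x$mask)
  names(per_samp) <- x$sample_ids
  structure(
    list(per_metabolite = per_met,
         per_sample = per_samp,
         total_fraction = mean(x$mask)),
    class = "missingness_summary"
  )
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat(sprintf("<missingness_summary> total missing fraction: %.4f\n",
              x$total_fraction))
  cat(sprintf("per-metabolite fractions: min %.3f / median %.3f / max %.3f\n",
              min(x$per_metabolite), stats::median(x$per_metabolite),
              max(x$per_metabolite)))
  cat(sprintf("per-sample fractions:     min %.3f / median %.3f / max %.3f\n",
              min(x$per_sample), stats::median(x$per_sample),
              max(x$per_sample)))
  invisible(x)
}
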