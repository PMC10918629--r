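#' Read a metabolomics feature table from delimited text
#'
#' Reads a CSV/TSV file with a header row of metabolite ids and a first
#' column of sample ids into an [intensity_matrix()]. Missing values may
#' be encoded as textual tokens (`NA`, empty cell, ...) and, by the
#' common metabolomics convention, as literal `0` or `1`; the latter two
#' are opt-in because zero and one can also be legitimate intensities.
#'
#' @param path path to an existing delimited text file.
#' @param delimiter single field-separator character; `","` (default) or
#'   e.g. `"\t"`.
#' @param zero_as_missing,one_as_missing logical; treat cells equal to 0
#'   (resp. 1) as missing. Default `FALSE`.
#' @param na_tokens character vector of cell contents denoting a missing
#'   value (compared after whitespace trimming).
#' @return an [intensity_matrix()], labels preserved in file order.
#' @seealso [write_intensity_table()]
#' @export
read_intensity_table <- function(path, delimiter = ",",
                                 zero_as_missing = FALSE,
                                 one_as_missing = FALSE,
                                 na_tokens = c("", "NA", "NaN", "N/A")) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", fileEncoding = "UTF-8")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty table: need at least one sample row and one metabolite column",
         call. = FALSE)
  }
  sample_ids <- trimws(raw[[1]])
  metabolite_ids <- colnames(raw)[-1]
  cells <- trimws(as.matrix(raw[, -1, drop = FALSE]))

  mask <- matrix(cells %in% na_tokens | is.na(cells), nrow = nrow(cells))
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))

  bad <- which(!mask & is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("cannot parse cell [sample '%s', metabolite '%s']: \"%s\"",
                 sample_ids[bad[1, 1]], metabolite_ids[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  if (zero_as_missing) mask <- mask | (!is.na(values) & values == 0)
  if (one_as_missing) mask <- mask | (!is.na(values) & values == 1)

  intensity_matrix(values, mask = mask, sample_ids = sample_ids,
                   metabolite_ids = metabolite_ids)
}

#' Write a feature table as delimited text
#'
#' Inverse of [read_intensity_table()]: header row of metabolite ids,
#' first column of sample ids, masked cells written as `na_token`.
#' Values are serialized with enough digits (C format `%.17g`) that a
#' read/write round trip reproduces doubles exactly.
#'
#' @param x an [intensity_matrix()].
#' @param path output file path.
#' @param delimiter field separator (default `","`).
#' @param na_token string written for masked cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path, delimiter = ",",
                                  na_token = "NA") {
  stopifnot(is_intensity_matrix(x))
  chr <- sprintf("%.17g", x$values)
  dim(chr) <- dim(x$values)
  chr[x$mask] <- na_token
  lines <- c(
    paste(c("sample_id", x$metabolite_ids), collapse = delimiter),
    vapply(seq_len(nrow(chr)), function(i) {
      paste(c(x$sample_ids[i], chr[i, ]), collapse = delimiter)
    }, character(1))
  )
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write to '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
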