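#' Validate a table of posterior draws
#'
#' A draws table is a plain data frame with one row per retained MCMC draw and
#' one named column per model quantity (parameters, outputs, or simulated
#' summary statistics). All value-of-information estimators in this package
#' consume this format.
#'
#' @param draws A data frame of posterior draws (rows = draws, columns =
#'   quantities).
#' @param columns Optional character vector of column names that must be
#'   present.
#' @param min_draws Minimum number of rows required. Estimation entry points
#'   use 1000 by default; structural checks use 1.
#'
#' @return The validated draws as a tibble (invisibly usable in pipes).
#' @export
check_draws <- function(draws, columns = NULL, min_draws = 1L) {
  if (!is.data.frame(draws)) {
    abort("`draws` must be a data frame with one row per posterior draw.")
  }
  draws <- as_tibble(draws)
  if (anyDuplicated(names(draws))) {
    abort("`draws` column names must be unique.")
  }
  if (nrow(draws) < min_draws) {
    abort(sprintf(
      "`draws` has %d rows; at least %d posterior draws are required.",
      nrow(draws), min_draws
    ))
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(draws))
    if (length(missing_cols) > 0) {
      abort(sprintf(
        "Columns not found in `draws`: %s",
        paste(missing_cols, collapse = ", ")
      ))
    }
    bad <- columns[!vapply(draws[columns], is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric draw columns: %s", paste(bad, collapse = ", ")))
    }
    if (!all(complete.cases(draws[columns]))) {
      abort("Draws contain missing or non-finite values in the requested columns.")
    }
  }
  draws
}

#' Read and write draws tables as CSV
#'
#' The on-disk dialect is a plain CSV with a header row of quantity names and
#' one row per retained draw.
#'
#' @param path File path.
#' @return `read_draws()` returns a tibble of draws.
#' @export
read_draws <- function(path) {
  check_draws(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @param draws A draws data frame.
#' @rdname read_draws
#' @export
write_draws <- function(draws, path) {
  readr::write_csv(check_draws(draws), path)
  invisible(path)
}
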