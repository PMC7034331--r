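#' Posterior summary table
#'
#' Median, mean, standard deviation, and a central credible interval for each
#' requested quantity of a draws table.
#'
#' @param draws A data frame of posterior draws.
#' @param quantities Character names of columns to summarise; defaults to all
#'   numeric columns.
#' @param level Credible-interval level (default 0.95).
#' @return A tibble with columns `quantity`, `median`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summaries <- function(draws, quantities = NULL, level = 0.95) {
  draws <- check_draws(draws)
  if (is.null(quantities)) {
    quantities <- names(draws)[vapply(draws, is.numeric, TRUE)]
  }
  if (length(quantities) == 0) abort("No quantities selected to summarise.")
  draws <- check_draws(draws, columns = quantities)
  alpha <- (1 - level) / 2
  purrr::map_dfr(quantities, function(q) {
    v <- draws[[q]]
    tibble(
      quantity = q,
      median = median(v),
      mean = mean(v),
      sd = sd(v),
      lower = quantile(v, alpha, names = FALSE),
      upper = quantile(v, 1 - alpha, names = FALSE)
    )
  })
}
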