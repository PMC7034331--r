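#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a VoI estimate
#'
#' `tidy()` returns the estimate as a plain one-row tibble (value, standard
#' error, baseline and residual loss, proportion of baseline); `glance()`
#' returns one row of fit diagnostics (total basis functions and the worst
#' per-output R-squared of the underlying regressions, when any were fitted).
#'
#' @param x A `voi_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.voi_estimate <- function(x, ...) {
  out <- as_tibble(unclass(x))
  out$targets <- paste(attr(x, "targets"), collapse = ",")
  conditioning <- attr(x, "conditioning")
  out$conditioning <- paste(conditioning, collapse = ",")
  out
}

#' @rdname tidy.voi_estimate
#' @export
glance.voi_estimate <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble(
    voi_kind = x$voi_kind,
    loss_kind = x$loss_kind,
    n_regressions = if (is.null(d)) 0L else nrow(d),
    n_basis_total = if (is.null(d)) NA_integer_ else sum(d$n_basis),
    r_squared_min = if (is.null(d)) NA_real_ else min(d$r_squared),
    negative = x$negative
  )
}

#' @rdname tidy.voi_estimate
#' @export
glance.voi_cmean <- function(x, ...) {
  tibble(
    method = x$method,
    n_draws = length(x$fitted),
    n_basis = x$n_basis,
    r_squared = x$r_squared
  )
}

#' Tidy a posterior draws fit
#'
#' `tidy()` on a draws table returned by [sample_posterior()] is
#' [posterior_summaries()]; `glance()` reports the sampler settings and worst
#' convergence diagnostics.
#'
#' @param x A draws tibble with `"diagnostics"`/`"mcmc_info"` attributes.
#' @param ... Passed to [posterior_summaries()].
#' @export
glance_mcmc <- function(x, ...) {
  d <- attr(x, "diagnostics")
  info <- attr(x, "mcmc_info")
  if (is.null(d) || is.null(info)) {
    abort("Not a draws table produced by sample_posterior().")
  }
  tibble(
    variant = info$variant$undiagnosed_source,
    gumcad_informs_diagnosed = info$variant$gumcad_informs_diagnosed,
    chains = info$chains,
    draws_per_chain = info$draws,
    thin = info$thin,
    rhat_max = max(d$rhat, na.rm = TRUE),
    ess_min = min(d$ess, na.rm = TRUE)
  )
}
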