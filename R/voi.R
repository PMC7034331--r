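#' Expected value of perfect information
#'
#' The expected loss of the optimal decision under current information minus
#' the expected loss if the decision-relevant outputs were known exactly. For
#' finite-action problems this is the classic difference between the minimum
#' posterior-mean loss and the posterior mean of the per-draw minimum; for
#' point estimation it is the generalized variance of the outputs (the
#' full-information residual loss is zero).
#'
#' @param draws A data frame of posterior draws.
#' @param loss A `voi_loss` decision-problem specification.
#' @param min_draws Floor on the number of draws accepted.
#'
#' @return A one-row `voi_estimate` tibble with columns `voi_kind`,
#'   `loss_kind`, `value`, `standard_error`, `baseline_loss`, `residual_loss`,
#'   `proportion`, and `negative`.
#' @export
evpi <- function(draws, loss, min_draws = 1000) {
  check_loss(loss)
  draws <- check_draws(draws, columns = loss$output_columns, min_draws = min_draws)
  y <- as.matrix(draws[loss$output_columns])
  k_draws <- nrow(y)
  if (loss$kind == "finite_action") {
    baseline <- min(colMeans(y))
    per_draw_min <- do.call(pmin, as.data.frame(y))
    residual <- mean(per_draw_min)
    se <- sqrt(var(per_draw_min) / k_draws)
  } else {
    baseline <- loss_functional(cov(y), loss)
    residual <- 0
    se <- if (loss$kind == "scalar_quadratic") {
      v <- y[, 1] - mean(y[, 1])
      sqrt(max(mean(v^4) - var(y[, 1])^2, 0) / k_draws)
    } else {
      NA_real_
    }
  }
  new_voi_estimate("evpi", loss, baseline, residual, se,
                   conditioning = character(0))
}

#' Expected value of partial perfect information by regression
#'
#' Estimates the expected reduction in loss from learning a subset of
#' parameters exactly, using a single Monte Carlo loop: each output is
#' regressed on the conditioning parameters across posterior draws, the fitted
#' values standing in for the conditional means and squared residuals for
#' conditional variances.
#'
#' For scalar quadratic loss the estimate is `var(alpha)` minus the mean
#' squared residual; for A-/D-optimal losses the generalized variance of the
#' outputs minus that of the componentwise residuals; for finite actions the
#' minimum mean loss minus the mean over draws of the minimum fitted loss.
#'
#' @inheritParams evpi
#' @param parameters Character names of the conditioned-on columns (at most 5
#'   for the default backend).
#' @param method,settings Regression backend, see [fit_conditional_mean()].
#' @param se Logical: attach a standard error computed by simulating from the
#'   distribution of the regression coefficients?
#' @param n_sims Number of coefficient simulations for the standard error.
#' @param seed Optional integer seed making the standard error reproducible.
#'
#' @return A one-row `voi_estimate` tibble; the fitted regressions are
#'   attached as attribute `"fits"` and fit diagnostics as `"diagnostics"`.
#' @export
evppi <- function(draws, parameters, loss, method = c("gam", "mars"),
                  settings = list(), se = TRUE, n_sims = 200, seed = NULL,
                  min_draws = 1000) {
  voi_regress(draws, parameters, loss, method = match.arg(method),
              settings = settings, se = se, n_sims = n_sims, seed = seed,
              min_draws = min_draws, voi_kind = "evppi")
}

#' Expected value of sample information by sufficient-statistic regression
#'
#' Identical machinery to [evppi()], but the conditioning columns hold a
#' low-dimensional sufficient statistic `T(y)` of a future dataset, one
#' simulated dataset per posterior draw from the posterior predictive
#' distribution (see [simulate_design()]). For point estimation with quadratic
#' loss the residual loss is the expected posterior variance remaining after
#' the study.
#'
#' @inheritParams evppi
#' @param statistics Character names of the summary-statistic columns.
#' @export
evsi <- function(draws, statistics, loss, method = c("gam", "mars"),
                 settings = list(), se = TRUE, n_sims = 200, seed = NULL,
                 min_draws = 1000) {
  voi_regress(draws, statistics, loss, method = match.arg(method),
              settings = settings, se = se, n_sims = n_sims, seed = seed,
              min_draws = min_draws, voi_kind = "evsi")
}

voi_regress <- function(draws, predictors, loss, method, settings, se, n_sims,
                        seed, min_draws, voi_kind) {
  check_loss(loss)
  stopifnot(is.character(predictors), length(predictors) >= 1)
  draws <- check_draws(draws, columns = unique(c(loss$output_columns, predictors)),
                       min_draws = min_draws)
  x <- as.matrix(draws[predictors])
  y <- as.matrix(draws[loss$output_columns])
  fits <- lapply(seq_len(ncol(y)), function(d) {
    fit_cmean(x, y[, d], method = method, settings = settings)
  })
  names(fits) <- loss$output_columns
  parts <- voi_terms(y, fits, loss)
  se_val <- NA_real_
  if (isTRUE(se)) {
    se_val <- voi_standard_error(fits, loss, n_sims = n_sims, seed = seed)
  }
  out <- new_voi_estimate(voi_kind, loss, parts$baseline, parts$residual, se_val,
                          conditioning = predictors)
  attr(out, "fits") <- fits
  attr(out, "diagnostics") <- tibble(
    output = loss$output_columns,
    n_basis = vapply(fits, function(f) f$n_basis, 0L),
    r_squared = vapply(fits, function(f) f$r_squared, 0)
  )
  out
}

# baseline and residual loss terms given fitted conditional means
voi_terms <- function(y, fits, loss, fitted_matrix = NULL) {
  k_draws <- nrow(y)
  ghat <- fitted_matrix %||%
    vapply(fits, function(f) f$fitted, numeric(k_draws))
  resid <- y - ghat
  if (loss$kind == "finite_action") {
    baseline <- min(colMeans(y))
    residual <- mean(do.call(pmin, as.data.frame(ghat)))
  } else if (loss$kind == "scalar_quadratic") {
    baseline <- var(y[, 1])
    residual <- sum(resid[, 1]^2) / (k_draws - 1)
  } else {
    baseline <- loss_functional(cov(y), loss)
    residual <- loss_functional(cov(resid), loss)
  }
  list(baseline = baseline, residual = residual)
}

#' Standard error of a regression-based VoI estimate
#'
#' Simulates regression coefficient vectors from their asymptotic (or Bayesian
#' posterior, for penalized spline fits) normal distribution, recomputes the
#' VoI estimate from each simulated set of fitted values, and reports the
#' standard deviation across simulations.
#'
#' @param fits A `voi_cmean` fit or a list of them, one per output column of
#'   the loss (in that order).
#' @param loss The `voi_loss` the estimate was computed under.
#' @param n_sims Number of coefficient simulations (at least 100).
#' @param seed Optional integer seed.
#'
#' @return A single nonnegative standard error in loss units.
#' @export
voi_standard_error <- function(fits, loss, n_sims = 200, seed = NULL) {
  check_loss(loss)
  if (inherits(fits, "voi_cmean")) fits <- list(fits)
  if (length(fits) != length(loss$output_columns)) {
    abort("Need one regression fit per output column of the loss.")
  }
  if (n_sims < 100) abort("`n_sims` must be at least 100 for a stable standard error.")
  y <- vapply(fits, function(f) f$response, numeric(length(fits[[1]]$response)))
  with_local_seed(seed, {
    sims <- lapply(fits, simulate_fitted, n_sims = n_sims)
    vals <- vapply(seq_len(n_sims), function(i) {
      ghat <- vapply(sims, function(s) s[, i], numeric(nrow(y)))
      parts <- voi_terms(y, fits = NULL, loss, fitted_matrix = ghat)
      parts$baseline - parts$residual
    }, 0)
    sd(vals)
  })
}

#' Grid of EVPPI proportions over outputs and parameters
#'
#' Computes, for every (output, parameter) pair, the single-parameter EVPPI
#' under scalar quadratic loss, reported as a proportion of the output
#' variance: the fraction of uncertainty in the output attributable to the
#' parameter.
#'
#' @inheritParams evppi
#' @param outputs Character names of output columns (rows of the grid).
#' @param parameters Character names of parameter columns (columns of the
#'   grid); each is conditioned on individually.
#' @param se Attach standard errors (slower)?
#'
#' @return A tibble with columns `output`, `parameter`, `value`, `baseline`,
#'   `proportion`, and optionally `se`.
#' @export
evppi_grid <- function(draws, outputs, parameters, method = c("gam", "mars"),
                       settings = list(), se = FALSE, n_sims = 200,
                       seed = NULL, min_draws = 1000) {
  method <- match.arg(method)
  draws <- check_draws(draws, columns = unique(c(outputs, parameters)),
                       min_draws = min_draws)
  grid <- tidyr::expand_grid(output = outputs, parameter = parameters)
  rows <- purrr::pmap(grid, function(output, parameter) {
    est <- evppi(draws, parameter, loss_quadratic(output), method = method,
                 settings = settings, se = se, n_sims = n_sims, seed = seed,
                 min_draws = min_draws)
    tibble(
      output = output, parameter = parameter, value = est$value,
      baseline = est$baseline_loss, proportion = est$proportion,
      se = est$standard_error
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!se) out$se <- NULL
  out
}

new_voi_estimate <- function(voi_kind, loss, baseline, residual, se,
                             conditioning) {
  value <- baseline - residual
  out <- tibble(
    voi_kind = voi_kind,
    loss_kind = loss$kind,
    value = value,
    standard_error = se,
    baseline_loss = baseline,
    residual_loss = residual,
    proportion = if (baseline > 0) value / baseline else NA_real_,
    negative = value < 0
  )
  attr(out, "targets") <- loss$output_columns
  attr(out, "conditioning") <- conditioning
  class(out) <- c("voi_estimate", class(out))
  out
}

#' @export
print.voi_estimate <- function(x, ...) {
  cat(sprintf(
    "<voi_estimate> %s under %s loss on (%s)%s\n",
    toupper(x$voi_kind), x$loss_kind,
    paste(attr(x, "targets"), collapse = ", "),
    if (length(attr(x, "conditioning"))) {
      paste0(" given (", paste(attr(x, "conditioning"), collapse = ", "), ")")
    } else ""
  ))
  cat(sprintf(
    "  value = %.6g (SE %.3g), baseline loss = %.6g, residual loss = %.6g, proportion = %.3f\n",
    x$value, x$standard_error, x$baseline_loss, x$residual_loss, x$proportion
  ))
  if (isTRUE(x$negative)) {
    cat("  note: negative estimate (regression noise); reported as computed\n")
  }
  invisible(x)
}

# run code under a temporary RNG state when seed is given
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
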