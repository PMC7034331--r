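#' Monetary benefit of a variance reduction
#'
#' Translates an expected reduction of the posterior variance of an estimate
#' into currency:
#'
#' * `kind = "linear_variance"`: every unit of variance reduction is worth the
#'   same, `b = lambda * (v0 - residual)`, with `lambda` the willingness to
#'   pay per unit of variance.
#' * `kind = "halving"`: every halving of the variance is worth the same,
#'   `b = lambda * log2(v0 / residual)`.
#'
#' @param v0 Variance under current information.
#' @param residual Expected variance remaining after the study (`v0 - EVSI`).
#'   Small negative EVSI estimates (regression noise) are clipped so the
#'   benefit is never negative; a warning flags the clip.
#' @param spec A [benefit_spec()].
#' @return Expected benefit in currency units.
#' @export
expected_benefit <- function(v0, residual, spec) {
  stopifnot(inherits(spec, "voi_benefit"), v0 > 0)
  if (any(residual > v0)) {
    warn("Residual variance above current variance (negative EVSI estimate); clipping benefit at 0.")
    residual <- pmin(residual, v0)
  }
  if (spec$kind == "linear_variance") {
    spec$lambda * (v0 - residual)
  } else {
    if (any(residual <= 0)) {
      abort("Variance-halving benefit is undefined at zero residual variance.")
    }
    spec$lambda * log2(v0 / residual)
  }
}

#' Benefit and cost specifications for net-benefit-of-sampling analysis
#'
#' @param kind `"linear_variance"` (willingness to pay per unit of variance
#'   reduction) or `"halving"` (per halving of the variance).
#' @param lambda Willingness to pay, in currency per unit variance or per
#'   halving; nonnegative.
#' @return `benefit_spec()` returns a `voi_benefit`; `cost_spec()` a
#'   `voi_cost`.
#' @export
benefit_spec <- function(kind = c("linear_variance", "halving"), lambda) {
  kind <- arg_match(kind)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0)
  structure(list(kind = kind, lambda = lambda), class = "voi_benefit")
}

#' @param unit_cost Currency per sampled participant.
#' @param fixed_cost Currency per study regardless of size.
#' @rdname benefit_spec
#' @export
cost_spec <- function(unit_cost, fixed_cost = 0) {
  stopifnot(unit_cost >= 0, fixed_cost >= 0)
  structure(list(unit_cost = unit_cost, fixed_cost = fixed_cost),
            class = "voi_cost")
}

#' Expected net benefit of sampling across sample sizes
#'
#' Converts an EVSI curve into expected monetary benefit, subtracts sampling
#' costs, and locates the optimal sample size. Because per-size EVSI
#' estimates carry independent Monte Carlo noise that jitters the argmax, the
#' EVSI curve is first smoothed by monotone (isotonic) regression in `n` and
#' interpolated onto a dense integer grid; the raw (unsmoothed) argmax is also
#' reported.
#'
#' @param evsi_table Output of [evsi_curve()]: columns `n`, `evsi` (and
#'   `residual_loss`).
#' @param benefit A [benefit_spec()].
#' @param cost A [cost_spec()].
#' @param n_grid Integer grid over which to optimize; default `1:max(n)` of
#'   the EVSI table.
#'
#' @return A `voi_enbs` tibble with columns `n`, `expected_benefit`, `cost`,
#'   `net_benefit`; attributes `n_star` (argmax on the smoothed curve),
#'   `n_star_raw` (argmax over the raw EVSI grid points), `benefit`, `cost_spec`.
#' @export
enbs_curve <- function(evsi_table, benefit, cost, n_grid = NULL) {
  stopifnot(inherits(benefit, "voi_benefit"), inherits(cost, "voi_cost"))
  if (!is.data.frame(evsi_table) || nrow(evsi_table) == 0 ||
      !all(c("n", "evsi") %in% names(evsi_table))) {
    abort("`evsi_table` must be a nonempty data frame with columns `n` and `evsi`.")
  }
  tab <- dplyr::arrange(as_tibble(evsi_table), n)
  v0 <- infer_v0(tab)
  if (is.null(n_grid)) n_grid <- seq_len(max(tab$n))

  # isotone smoothing: information value cannot decrease with sample size;
  # monotone Hermite interpolation onto the dense grid keeps the argmax from
  # being quantized to the EVSI evaluation points
  evsi_smooth <- isoreg(tab$n, pmax(pmin(tab$evsi, v0), 0))$yf
  interp <- tryCatch({
    sf <- stats::splinefun(c(0, tab$n), c(0, evsi_smooth), method = "hyman")
    pmin(pmax(sf(pmin(n_grid, max(tab$n))), 0), v0)
  }, error = function(e) {
    approx(c(0, tab$n), c(0, evsi_smooth), xout = n_grid, rule = 2)$y
  })

  bene <- expected_benefit(v0, v0 - interp, benefit)
  cost_n <- cost$fixed_cost + cost$unit_cost * n_grid
  out <- tibble(
    n = n_grid,
    expected_benefit = bene,
    cost = cost_n,
    net_benefit = bene - cost_n
  )
  raw_bene <- expected_benefit(v0, v0 - pmax(pmin(tab$evsi, v0), 0), benefit)
  raw_net <- raw_bene - (cost$fixed_cost + cost$unit_cost * tab$n)
  attr(out, "n_star") <- out$n[which.max(out$net_benefit)]
  attr(out, "n_star_raw") <- tab$n[which.max(raw_net)]
  attr(out, "v0") <- v0
  attr(out, "benefit") <- benefit
  attr(out, "cost_spec") <- cost
  class(out) <- c("voi_enbs", class(out))
  out
}

# current-information variance: recover from residual_loss + evsi when
# available, otherwise take the EVSI asymptote as a lower bound surrogate
infer_v0 <- function(tab) {
  if ("residual_loss" %in% names(tab)) {
    mean(tab$evsi + tab$residual_loss)
  } else {
    max(tab$evsi)
  }
}

#' @export
print.voi_enbs <- function(x, ...) {
  cat(sprintf(
    "<voi_enbs> %d sample sizes; optimal n = %d (smoothed), %d (raw grid)\n",
    nrow(x), attr(x, "n_star"), attr(x, "n_star_raw")
  ))
  NextMethod()
}
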