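#' Specify the decision problem and its loss
#'
#' Value of information is always defined relative to a decision problem. Four
#' families are supported, all satisfying the condition that the expected loss
#' under the optimal decision is a known function of the mean of the
#' decision-relevant outputs:
#'
#' * `loss_quadratic(output)`: point estimation of a single scalar quantity
#'   under squared-error loss. The expected loss under current information is
#'   the posterior variance of the output, so EVPPI/EVSI are expected variance
#'   reductions.
#' * `loss_finite_action(outputs)`: choice among a finite set of actions, one
#'   per output column, where each column holds the loss of that action. The
#'   expected loss is the minimum posterior mean.
#' * `loss_a_optimal(outputs, weights)`: point estimation of a vector of
#'   quantities where the loss is the quadratic form with `H = c c'`; the
#'   expected loss is `c' cov(alpha) c`, so equal weights value equal
#'   *absolute* variance reductions equally (Bayesian A-optimality).
#' * `loss_d_optimal(outputs, standardize)`: point estimation of a vector where
#'   the expected loss is `det(cov(alpha))` (Bayesian D-optimality), valuing
#'   equal *relative* variance reductions equally; with `standardize = TRUE`
#'   the determinant is raised to `1/S` (a geometric mean variance adjusted
#'   for covariance).
#'
#' @param output,outputs Character names of the draws columns holding the
#'   decision-relevant quantities.
#' @param weights Numeric weight vector `c` for A-optimality; recycled scalar 1
#'   by default.
#' @param standardize Logical; report `det^(1/S)` instead of `det`.
#'
#' @return A `voi_loss` specification list with elements `kind`,
#'   `output_columns`, and kind-specific settings.
#' @export
loss_quadratic <- function(output) {
  stopifnot(is.character(output))
  if (length(output) != 1) {
    abort("Scalar quadratic loss requires exactly one output column.")
  }
  new_loss("scalar_quadratic", output)
}

#' @rdname loss_quadratic
#' @export
loss_finite_action <- function(outputs) {
  stopifnot(is.character(outputs))
  if (length(outputs) < 2) {
    abort("A finite-action problem needs at least two actions (output columns).")
  }
  new_loss("finite_action", outputs)
}

#' @rdname loss_quadratic
#' @export
loss_a_optimal <- function(outputs, weights = rep(1, length(outputs))) {
  stopifnot(is.character(outputs), is.numeric(weights))
  if (length(weights) != length(outputs)) {
    abort("`weights` must have one entry per output column.")
  }
  new_loss("a_optimal", outputs, weights = weights)
}

#' @rdname loss_quadratic
#' @export
loss_d_optimal <- function(outputs, standardize = FALSE) {
  stopifnot(is.character(outputs), is.logical(standardize))
  new_loss("d_optimal", outputs, standardize = standardize)
}

new_loss <- function(kind, outputs, ...) {
  structure(
    list(kind = kind, output_columns = outputs, ...),
    class = "voi_loss"
  )
}

#' @export
print.voi_loss <- function(x, ...) {
  cat("<voi_loss>", x$kind, "on", paste(x$output_columns, collapse = ", "), "\n")
  invisible(x)
}

is_point_estimation <- function(loss) {
  loss$kind %in% c("scalar_quadratic", "a_optimal", "d_optimal")
}

check_loss <- function(loss, draws = NULL) {
  if (!inherits(loss, "voi_loss")) {
    abort("`loss` must be created with loss_quadratic(), loss_finite_action(), loss_a_optimal() or loss_d_optimal().")
  }
  if (!is.null(draws)) check_draws(draws, columns = loss$output_columns)
  invisible(loss)
}

#' Expected loss functional of a covariance matrix or means
#'
#' Evaluates the generalized-variance functional `v(.)` that each loss kind
#' applies to the output covariance (point estimation), or the minimum of the
#' action means (finite action). Used internally by all estimators, and
#' exported because it defines the units of every VoI value.
#'
#' @param x For point-estimation losses, the covariance matrix of the outputs
#'   (a scalar variance for `scalar_quadratic`). For `finite_action`, the
#'   vector of posterior means of the action losses.
#' @param loss A `voi_loss`.
#' @param tol Relative tolerance for the symmetry/positive-semi-definiteness
#'   check of covariance input.
#'
#' @return A single number in loss units.
#' @export
loss_functional <- function(x, loss, tol = 1e-8) {
  check_loss(loss)
  s <- length(loss$output_columns)
  if (loss$kind == "finite_action") {
    stopifnot(is.numeric(x))
    if (length(x) != s) abort("Need one mean per action.")
    return(min(x))
  }
  x <- as.matrix(x)
  if (nrow(x) != s || ncol(x) != s) {
    abort(sprintf("Covariance must be %d x %d for this loss.", s, s))
  }
  scale <- max(abs(x), 1e-300)
  if (max(abs(x - t(x))) > tol * scale) abort("Covariance matrix is not symmetric.")
  ev <- eigen((x + t(x)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1e-300)) {
    abort("Covariance matrix is not positive semi-definite.")
  }
  switch(loss$kind,
    scalar_quadratic = x[1, 1],
    a_optimal = drop(crossprod(loss$weights, x %*% loss$weights)),
    d_optimal = {
      d <- det(x)
      if (isTRUE(loss$standardize)) max(d, 0)^(1 / s) else d
    }
  )
}
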