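#' Fit the conditional mean of a model output given parameters
#'
#' The regression step at the heart of the single-loop VoI estimators: the
#' output is written as `alpha = g(phi) + e` with `E(e) = 0`, and `g` is
#' estimated by nonparametric regression on the posterior draws. Fitted values
#' estimate the conditional posterior mean `E(alpha | phi)` draw by draw;
#' squared residuals estimate the conditional variance.
#'
#' Two backends are available:
#' * `"gam"` (default): penalized regression splines via [mgcv::gam()], with a
#'   tensor-product smooth for 2-3 predictors and additive smooths for 4-5.
#' * `"mars"`: an in-package implementation of multivariate adaptive
#'   regression splines (piecewise-linear hinge basis, greedy forward pass,
#'   backward pruning by generalized cross-validation), an unpenalized
#'   least-squares fit on the selected basis.
#'
#' Constant (degenerate) predictor columns are dropped and contribute nothing;
#' predictors with very few distinct values fall back to linear terms.
#'
#' @param data A data frame of posterior draws.
#' @param response Name of the output column.
#' @param predictors Character vector of predictor column names (the
#'   parameters, or simulated summary statistics, being conditioned on).
#' @param method `"gam"` or `"mars"`.
#' @param settings Backend settings. For `"gam"`: `k` (basis dimension of a
#'   one-dimensional smooth, default 10), `k_marginal` (marginal basis of a
#'   tensor smooth, default 5), `max_predictors` (default 5). For `"mars"`:
#'   `degree` (interaction degree, default 2), `nk` (maximum basis functions,
#'   default 21), `penalty` (GCV knot penalty, default 3).
#'
#' @return A `voi_cmean` object with elements `fitted`, `residuals`,
#'   `response`, `n_basis`, `r_squared`, and the machinery needed to simulate
#'   fitted values from the sampling distribution of the regression
#'   coefficients (used for standard errors).
#' @export
fit_conditional_mean <- function(data, response, predictors,
                                 method = c("gam", "mars"), settings = list()) {
  method <- arg_match(method)
  data <- check_draws(data, columns = c(response, predictors))
  y <- data[[response]]
  x <- as.matrix(data[predictors])
  fit_cmean(x, y, method = method, settings = settings)
}

fit_cmean <- function(x, y, method = "gam", settings = list()) {
  x <- as.matrix(x)
  k_obs <- length(y)
  p <- ncol(x)
  stopifnot(p >= 1)
  if (!all(is.finite(y)) || !all(is.finite(x))) {
    abort("Regression inputs must be finite.")
  }
  if (k_obs <= 10 * p) {
    abort(sprintf("Too few draws (%d) for %d predictors; need more than %d.",
                  k_obs, p, 10 * p))
  }
  max_p <- settings$max_predictors %||% 5
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  # drop degenerate predictors: they carry no information about the output
  keep <- apply(x, 2, function(v) length(unique(v)) > 1)
  x_use <- x[, keep, drop = FALSE]
  if (ncol(x_use) > max_p) {
    abort(sprintf(
      "%d predictors exceed the regression backend limit (%d); reduce the conditioning set, e.g. to the parameters with largest individual EVPPI.",
      ncol(x_use), max_p
    ))
  }
  fit <- if (ncol(x_use) == 0 || var(y) == 0) {
    fit_cmean_intercept(y)
  } else if (method == "gam") {
    fit_cmean_gam(x_use, y, settings)
  } else {
    fit_cmean_mars(x_use, y, settings)
  }
  fit$residuals <- y - fit$fitted
  fit$response <- y
  fit$method <- method
  tss <- sum((y - mean(y))^2)
  fit$r_squared <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  class(fit) <- "voi_cmean"
  fit
}

fit_cmean_intercept <- function(y) {
  k_obs <- length(y)
  list(
    fitted = rep(mean(y), k_obs),
    n_basis = 1L,
    coef = mean(y),
    coef_cov = matrix(var(y) / k_obs, 1, 1),
    basis_matrix = matrix(1, k_obs, 1)
  )
}

fit_cmean_gam <- function(x, y, settings) {
  p <- ncol(x)
  k1 <- settings$k %||% 10
  km <- settings$k_marginal %||% 5
  df <- as.data.frame(x)
  df$.y <- y
  n_unique <- apply(x, 2, function(v) length(unique(v)))
  term_for <- function(name, k) {
    if (n_unique[name] <= 3) name else sprintf("s(%s, k = %d)", name, min(k, n_unique[name] - 1))
  }
  rhs <- if (p == 1) {
    term_for(colnames(x)[1], k1)
  } else if (p <= 3 && all(n_unique > 3)) {
    kk <- pmin(km, n_unique - 1)
    sprintf("te(%s, k = c(%s))", paste(colnames(x), collapse = ", "),
            paste(kk, collapse = ", "))
  } else {
    paste(vapply(colnames(x), term_for, "", k = k1), collapse = " + ")
  }
  form <- stats::as.formula(paste(".y ~", rhs))
  # REML emits a step-failure warning on (near-)noiseless responses where the
  # smoothing parameter diverges; the fit itself is the interpolant we want
  gfit <- withCallingHandlers(
    mgcv::gam(form, data = df, method = "REML"),
    warning = function(w) {
      if (grepl("step failure|convergence", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  basis <- predict(gfit, type = "lpmatrix")
  list(
    fitted = as.numeric(gfit$fitted.values),
    n_basis = length(coef(gfit)),
    coef = coef(gfit),
    coef_cov = gfit$Vp,
    basis_matrix = basis
  )
}

fit_cmean_mars <- function(x, y, settings) {
  mfit <- mars_fit(
    x, y,
    degree = settings$degree %||% 2,
    nk = settings$nk %||% 21,
    penalty = settings$penalty %||% 3
  )
  list(
    fitted = mfit$fitted,
    n_basis = ncol(mfit$basis_matrix),
    coef = mfit$coef,
    coef_cov = mfit$coef_cov,
    basis_matrix = mfit$basis_matrix
  )
}

#' @export
print.voi_cmean <- function(x, ...) {
  cat(sprintf(
    "<voi_cmean> %s fit, %d draws, %d basis functions, R^2 = %.3f\n",
    x$method, length(x$fitted), x$n_basis, x$r_squared
  ))
  invisible(x)
}

# Simulate fitted-value vectors from the asymptotic/posterior normal
# distribution of the regression coefficients. Returns a K x n_sims matrix.
simulate_fitted <- function(fit, n_sims) {
  if (is.null(fit$coef_cov) || is.null(fit$basis_matrix)) {
    abort("This regression backend does not expose coefficient uncertainty; standard errors are unavailable for it.")
  }
  b <- mvn_draw(n_sims, fit$coef, fit$coef_cov)
  fit$basis_matrix %*% t(b)
}

mvn_draw <- function(n, mu, sigma) {
  p <- length(mu)
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% t(e$vectors * rep(sqrt(lam), each = p)), 2, mu, "+")
}
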