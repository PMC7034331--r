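#' Conjugate verification fixtures
#'
#' Small generative models with known closed-form or exactly enumerable VoI,
#' used to verify the regression estimators independently of any application
#' model. Four kinds are available:
#'
#' * `"normal_known_var"`: `theta ~ N(mean, prior_sd^2)`, output
#'   `alpha = theta`, future data the mean of `n` observations with known
#'   noise `data_sd`. Preposterior variance is available in closed form.
#' * `"beta_binomial"`: `p ~ Beta(a, b)`, output `alpha = p`, future data
#'   `y ~ Binomial(n, p)`. EVSI is exactly enumerable over `y`.
#' * `"linear_sum"`: independent `phi_i ~ N(0, v_i)` with
#'   `alpha = sum(phi_i) + noise`; the EVPPI of any founder subset is the sum
#'   of its variances.
#' * `"two_action_gaussian"`: a two-action decision with losses `alpha1 = 0`
#'   and `alpha2 = m + phi + noise`, `phi ~ N(0, tau^2)`; EVPI and EVPPI have
#'   Gaussian partial-expectation closed forms.
#'
#' Default hyperparameters are chosen so that single-parameter EVPPI
#' proportions span roughly 10-90% of the output variance, stressing the
#' regression backend at both ends.
#'
#' @param kind Fixture family.
#' @param ... Hyperparameter overrides: `mean`, `prior_sd`, `data_sd`
#'   (normal); `a`, `b` (beta-binomial); `v` (vector of founder variances),
#'   `noise_sd` (linear sum); `m`, `tau`, `sigma` (two-action).
#' @return A `voi_fixture` list with the hyperparameters filled in.
#' @export
conjugate_fixture <- function(kind = c("normal_known_var", "beta_binomial",
                                       "linear_sum", "two_action_gaussian"),
                              ...) {
  kind <- arg_match(kind)
  defaults <- switch(kind,
    normal_known_var = list(mean = 0, prior_sd = 1, data_sd = 1),
    beta_binomial = list(a = 1, b = 1),
    linear_sum = list(v = c(0.25, 1), noise_sd = 0.5),
    two_action_gaussian = list(m = 0, tau = 1, sigma = 1)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown hyperparameters for %s: %s", kind,
                  paste(unknown, collapse = ", ")))
  }
  params <- modifyList(defaults, dots)
  ok <- switch(kind,
    normal_known_var = params$prior_sd > 0 && params$data_sd > 0,
    beta_binomial = params$a > 0 && params$b > 0,
    linear_sum = all(params$v > 0) && params$noise_sd >= 0,
    two_action_gaussian = params$tau > 0 && params$sigma >= 0
  )
  if (!isTRUE(ok)) abort("Invalid fixture hyperparameters.")
  structure(c(list(kind = kind), params), class = "voi_fixture")
}

#' Exact joint draws from a fixture
#'
#' Samples `(phi, alpha)` jointly from the fixture's generative model, plus
#' the sufficient statistic of a future study of size `n` when requested
#' (sampled from the posterior predictive, here equal to the prior predictive
#' as the fixtures carry no current data).
#'
#' @param fixture A [conjugate_fixture()].
#' @param n_draws Number of draws.
#' @param seed Optional integer seed.
#' @param n Future-study size; adds a `statistic` column when not `NULL`.
#' @return A tibble of draws. Columns: `phi1..phip`/`theta`/`p`, `alpha` (or
#'   `alpha1`, `alpha2`), and optionally `statistic`.
#' @export
generate_draws <- function(fixture, n_draws, seed = NULL, n = NULL) {
  stopifnot(inherits(fixture, "voi_fixture"), n_draws >= 1)
  with_local_seed(seed, switch(fixture$kind,
    normal_known_var = {
      theta <- rnorm(n_draws, fixture$mean, fixture$prior_sd)
      out <- tibble(theta = theta, alpha = theta)
      if (!is.null(n)) {
        out$statistic <- rnorm(n_draws, theta, fixture$data_sd / sqrt(n))
      }
      out
    },
    beta_binomial = {
      p <- rbeta(n_draws, fixture$a, fixture$b)
      out <- tibble(p = p, alpha = p)
      if (!is.null(n)) out$statistic <- rbinom(n_draws, n, p)
      out
    },
    linear_sum = {
      p <- length(fixture$v)
      phi <- vapply(fixture$v, function(vi) rnorm(n_draws, 0, sqrt(vi)),
                    numeric(n_draws))
      colnames(phi) <- paste0("phi", seq_len(p))
      out <- as_tibble(phi)
      out$alpha <- rowSums(phi) + rnorm(n_draws, 0, fixture$noise_sd)
      out
    },
    two_action_gaussian = {
      phi <- rnorm(n_draws, 0, fixture$tau)
      tibble(
        phi = phi,
        alpha1 = 0,
        alpha2 = fixture$m + phi + rnorm(n_draws, 0, fixture$sigma)
      )
    }
  ))
}

#' Closed-form EVPPI of a fixture
#'
#' @param fixture A [conjugate_fixture()].
#' @param parameters For `"linear_sum"`, the founder columns conditioned on;
#'   ignored otherwise (the fixtures have a single founder).
#' @return Exact EVPPI in loss units (variance for the point-estimation
#'   fixtures; expected loss for the two-action fixture).
#' @export
closed_form_evppi <- function(fixture, parameters = NULL) {
  stopifnot(inherits(fixture, "voi_fixture"))
  switch(fixture$kind,
    normal_known_var = fixture$prior_sd^2,
    beta_binomial = with(fixture, a * b / ((a + b)^2 * (a + b + 1))),
    linear_sum = {
      idx <- if (is.null(parameters)) seq_along(fixture$v) else {
        as.integer(sub("^phi", "", parameters))
      }
      sum(fixture$v[idx])
    },
    two_action_gaussian = {
      # E min(0, m + phi) with phi ~ N(0, tau^2)
      min(0, fixture$m) - gaussian_min_zero(fixture$m, fixture$tau)
    }
  )
}

# E[min(0, X)] for X ~ N(m, s^2)
gaussian_min_zero <- function(m, s) {
  m * pnorm(-m / s) - s * dnorm(m / s)
}

#' Exact EVSI by enumeration or conjugacy
#'
#' For the beta-binomial fixture, sums the posterior variance of `p` over the
#' finite support of `y ~ BetaBinomial(n, a, b)`; for the known-variance
#' normal fixture, applies the closed-form preposterior variance
#' `sigma0^2 - (1/sigma0^2 + n/s^2)^-1`. Exact (non-stochastic) in both cases.
#'
#' @param fixture A `"beta_binomial"` or `"normal_known_var"` fixture.
#' @param n Future sample size (0 gives 0).
#' @return Exact EVSI in variance units.
#' @export
exact_evsi_enumeration <- function(fixture, n) {
  stopifnot(inherits(fixture, "voi_fixture"), n >= 0)
  if (n == 0) return(0)
  switch(fixture$kind,
    beta_binomial = {
      a <- fixture$a
      b <- fixture$b
      y <- 0:n
      log_pmf <- lchoose(n, y) + lbeta(a + y, b + n - y) - lbeta(a, b)
      post_var <- (a + y) * (b + n - y) / ((a + b + n)^2 * (a + b + n + 1))
      prior_var <- a * b / ((a + b)^2 * (a + b + 1))
      prior_var - sum(exp(log_pmf) * post_var)
    },
    normal_known_var = {
      s0 <- fixture$prior_sd^2
      s0 - 1 / (1 / s0 + n / fixture$data_sd^2)
    },
    abort(sprintf("Exact EVSI is not available for the %s fixture.", fixture$kind))
  )
}

#' Nested Monte Carlo EVPPI (test oracle)
#'
#' The expensive two-loop estimate of EVPPI: sample the conditioned-on
#' parameters in an outer loop, sample the outputs conditionally in an inner
#' loop, and average the conditional expected losses. Used only to
#' cross-validate the single-loop regression estimators.
#'
#' @param fixture A [conjugate_fixture()].
#' @param parameters Founder columns conditioned on (`"linear_sum"` only).
#' @param k_outer,k_inner Outer and inner Monte Carlo sample sizes.
#' @param seed Optional integer seed.
#' @return A list with `value` and its Monte Carlo `standard_error`.
#' @export
nested_mc_evppi <- function(fixture, parameters = NULL, k_outer = 2000,
                            k_inner = 2000, seed = NULL) {
  stopifnot(inherits(fixture, "voi_fixture"), k_outer >= 10, k_inner >= 10)
  with_local_seed(seed, {
    if (fixture$kind == "two_action_gaussian") {
      # finite-action: EVPPI = min_d E(alpha_d) - E_phi[ min_d E(alpha_d | phi) ]
      phi <- rnorm(k_outer, 0, fixture$tau)
      inner_min <- vapply(phi, function(ph) {
        a2 <- fixture$m + ph + rnorm(k_inner, 0, fixture$sigma)
        min(0, mean(a2))
      }, 0)
      baseline <- min(0, fixture$m)
      list(value = baseline - mean(inner_min),
           standard_error = sd(inner_min) / sqrt(k_outer))
    } else {
      # point estimation: EVPPI = var(alpha) - E_phi[ var(alpha | phi) ]
      draw_cond <- switch(fixture$kind,
        normal_known_var = function(k) {
          th <- rnorm(1, fixture$mean, fixture$prior_sd)
          rep(th, k)  # alpha = theta exactly: conditional variance 0
        },
        beta_binomial = function(k) rep(rbeta(1, fixture$a, fixture$b), k),
        linear_sum = {
          idx <- if (is.null(parameters)) seq_along(fixture$v) else {
            as.integer(sub("^phi", "", parameters))
          }
          rest <- setdiff(seq_along(fixture$v), idx)
          function(k) {
            known <- sum(rnorm(length(idx), 0, sqrt(fixture$v[idx])))
            known + colSums(matrix(
              rnorm(k * (length(rest) + 1),
                    0, rep(c(sqrt(fixture$v[rest]), fixture$noise_sd),
                           times = k)),
              nrow = length(rest) + 1
            ))
          }
        }
      )
      cond_vars <- vapply(seq_len(k_outer), function(i) var(draw_cond(k_inner)), 0)
      baseline <- switch(fixture$kind,
        normal_known_var = fixture$prior_sd^2,
        beta_binomial = with(fixture, a * b / ((a + b)^2 * (a + b + 1))),
        linear_sum = sum(fixture$v) + fixture$noise_sd^2
      )
      list(value = baseline - mean(cond_vars),
           standard_error = sd(cond_vars) / sqrt(k_outer))
    }
  })
}
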