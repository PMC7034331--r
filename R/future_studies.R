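#' Simulate sufficient statistics of future studies
#'
#' For each posterior draw, simulates one future dataset of the requested
#' design from the posterior predictive distribution and reduces it to the
#' scalar sufficient statistic used by the EVSI regression:
#'
#' * `simulate_gum_anon()`: a further anonymous GUM-clinic survey of `n`
#'   previously undiagnosed attenders; `y ~ Binomial(n, pi_GA)` per draw and
#'   the statistic is the empirical prevalence `y / n`.
#' * `simulate_gmshs()`: a further venue survey of `n` previously undiagnosed
#'   MSM. The number attending GUM clinics is `N_G ~ Binomial(n, q)` with `q`
#'   drawn per draw from the Beta posterior of the attendance split observed
#'   in the original survey (Jeffreys prior); positives are
#'   `Y_G ~ Binomial(N_G, p_G_GM)` and `Y_N ~ Binomial(n - N_G, p_N_GM)`. The
#'   statistic is the plug-in odds ratio of the Jeffreys-smoothed proportions
#'   `(Y + 0.5) / (N + 1)`, which is finite for all outcomes including empty
#'   denominators.
#'
#' @param draws Posterior draws containing `pi_GA` (GUM Anon) or
#'   `p_G_GM`/`p_N_GM` (GMSHS).
#' @param n Future sample size (at least 1; the value of a study of size 0 is
#'   identically 0, no simulation needed).
#' @param seed Optional integer seed.
#' @param attendance Two Beta shape parameters for the GMSHS attendance
#'   probability `q`; the default is the Jeffreys posterior from the observed
#'   493/945 split.
#'
#' @return A tibble with one row per draw: column `statistic` plus the raw
#'   simulated counts.
#' @export
simulate_gum_anon <- function(draws, n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1)
  if (n < 1) abort("Future sample size must be at least 1 (EVSI of an empty study is 0).")
  draws <- check_draws(draws, columns = "pi_GA")
  k_draws <- nrow(draws)
  with_local_seed(seed, {
    y <- rbinom(k_draws, size = n, prob = draws$pi_GA)
    tibble(statistic = y / n, y = y)
  })
}

#' @rdname simulate_gum_anon
#' @export
simulate_gmshs <- function(draws, n, seed = NULL,
                           attendance = c(493.5, 452.5)) {
  stopifnot(is.numeric(n), length(n) == 1, length(attendance) == 2)
  if (n < 1) abort("Future sample size must be at least 1 (EVSI of an empty study is 0).")
  draws <- check_draws(draws, columns = c("p_G_GM", "p_N_GM"))
  k_draws <- nrow(draws)
  with_local_seed(seed, {
    q <- rbeta(k_draws, attendance[1], attendance[2])
    n_g <- rbinom(k_draws, size = n, prob = q)
    y_g <- rbinom(k_draws, size = n_g, prob = draws$p_G_GM)
    y_n <- rbinom(k_draws, size = n - n_g, prob = draws$p_N_GM)
    p_g <- (y_g + 0.5) / (n_g + 1)
    p_n <- (y_n + 0.5) / (n - n_g + 1)
    tibble(
      statistic = (p_n / (1 - p_n)) / (p_g / (1 - p_g)),
      N_G = n_g, Y_G = y_g, Y_N = y_n
    )
  })
}

#' @param source `"gum_anon"` or `"gmshs"`.
#' @rdname simulate_gum_anon
#' @export
simulate_design <- function(draws, source = c("gum_anon", "gmshs"), n,
                            seed = NULL) {
  source <- arg_match(source)
  switch(source,
    gum_anon = simulate_gum_anon(draws, n, seed),
    gmshs = simulate_gmshs(draws, n, seed)
  )
}

#' EVSI across a grid of future sample sizes
#'
#' Runs one independent simulate-reduce-regress cycle per sample size: future
#' data are simulated from the posterior predictive, reduced to the design's
#' sufficient statistic, and the outputs regressed on it. For quadratic loss
#' the `residual_loss` column is the expected variance remaining after the
#' study, and `residual_sd` its square root.
#'
#' Per-size seeds are derived from `seed` and `n`, so the curve is
#' reproducible and the Monte Carlo noise is independent across sizes.
#'
#' @inheritParams evsi
#' @param source Future-study design, `"gum_anon"` or `"gmshs"`.
#' @param n_grid Strictly increasing vector of future sample sizes.
#' @param seed Integer seed (required for a reproducible curve).
#'
#' @return A tibble with columns `n`, `evsi`, `se`, `residual_loss`,
#'   `residual_sd`.
#' @export
evsi_curve <- function(draws, source = c("gum_anon", "gmshs"), n_grid, loss,
                       method = c("gam", "mars"), settings = list(),
                       se = TRUE, n_sims = 200, seed = 1, min_draws = 1000) {
  source <- arg_match(source)
  method <- match.arg(method)
  check_loss(loss, draws)
  if (length(n_grid) < 1 || any(diff(n_grid) <= 0) || any(n_grid < 1)) {
    abort("`n_grid` must be a strictly increasing vector of sizes >= 1.")
  }
  purrr::map_dfr(n_grid, function(n) {
    seed_n <- derive_seed(seed, n)
    sim <- simulate_design(draws, source, n, seed = seed_n)
    est <- evsi(bind_cols(draws, sim["statistic"]), "statistic", loss,
                method = method, settings = settings, se = se,
                n_sims = n_sims, seed = seed_n, min_draws = min_draws)
    tibble(
      n = n, evsi = est$value, se = est$standard_error,
      residual_loss = est$residual_loss,
      residual_sd = if (est$residual_loss >= 0) sqrt(est$residual_loss) else NA_real_
    )
  })
}

derive_seed <- function(seed, n) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(n) * 104729) %% 2147483629)
}
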