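# Shared posterior fits, computed once per test run and reused across files.
# Sizes are chosen so the whole suite stays fast while leaving enough
# effective draws for the tolerance checks that use them.

.fit_cache <- new.env(parent = emptyenv())

cached_hiv_fit <- function(key = c("base", "variant_a", "variant_b", "prior")) {
  key <- match.arg(key)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  elapsed <- system.time(fit <- switch(key,
    base = suppressWarnings(sample_posterior(
      seed = 901, draws = 5000, thin = 100, warmup = 10000
    )),
    variant_a = suppressWarnings(sample_posterior(
      variant = hiv_variant("gum_anon_only"),
      seed = 902, draws = 5000, thin = 200, warmup = 10000
    )),
    variant_b = suppressWarnings(sample_posterior(
      variant = hiv_variant(gumcad_informs_diagnosed = TRUE),
      seed = 903, draws = 2500, thin = 100, warmup = 10000
    )),
    prior = sample_posterior(prior_only = TRUE, draws = 2500, seed = 904)
  ))["elapsed"]
  attr(fit, "elapsed") <- unname(elapsed)
  .fit_cache[[key]] <- fit
  fit
}

# MCMC standard error of a posterior functional, from the spread of
# independent-chain estimates (chains are stacked in order in the draws)
chain_split_se <- function(fit, fun) {
  info <- attr(fit, "mcmc_info")
  idx <- rep(seq_len(info$chains), each = info$draws)
  vals <- vapply(split(seq_len(nrow(fit)), idx), function(i) fun(fit[i, ]), 0)
  stats::sd(vals) / sqrt(length(vals))
}

# a small synthetic posterior with the columns the future-study designs need
fake_posterior <- function(n, seed = 81) {
  set.seed(seed)
  tibble::tibble(
    pi_GA = rbeta(n, 5, 82),
    p_G_GM = rbeta(n, 21, 474),
    p_N_GM = rbeta(n, 21, 433)
  )
}

# mean estimate and replication standard error of a VoI estimator across
# independently generated fixture draw sets
replicate_voi <- function(fixture, n_reps, n_draws, seeds, fun, size = NULL) {
  vals <- vapply(seq_len(n_reps), function(r) {
    draws <- generate_draws(fixture, n_draws, seed = seeds + r, n = size)
    fun(draws)
  }, 0)
  list(mean = mean(vals), se = sd(vals) / sqrt(n_reps), values = vals)
}
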