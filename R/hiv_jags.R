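# JAGS program assembly and posterior sampling for the HIV model.
#
# The JAGS program only contains the stochastic founders, the deterministic
# nodes that likelihood terms actually need, and the active likelihood blocks;
# every derived output is recomputed in R by derived_outputs() from the
# monitored founder draws, so the R graph is the single source of truth for
# the deterministic structure.

hiv_jags_model <- function(variant = hiv_variant(), sources = hiv_sources()) {
  a <- variant$undiagnosed_source == "gum_anon_only"
  b <- variant$gumcad_informs_diagnosed
  need_mu_d <- any(c("sophid", "handd") %in% sources)
  need_mu_pop <- need_mu_d || "pop" %in% sources

  priors <- c(
    "log_mu_pop ~ dnorm(0, 1.0E-6)",
    "rho[1:4] ~ ddirch(dir_alpha[])",
    "e_S ~ dnorm(1, pow(0.018, -2))",
    "a_H ~ dunif(0, 1)",
    "a_delta_G ~ dunif(0, 1)",
    "a_delta_N ~ dunif(0, 1)",
    "a_delta_P ~ dunif(0, 1)",
    "gamma1 ~ dunif(0, 1)",
    "gamma2 ~ dunif(0, 1)",
    "gamma3 ~ dunif(0, 1)",
    "gamma4 ~ dunif(0, 0.15)",
    "a_UN ~ dunif(log(0.5), log(1.5))",
    "a_OP ~ dunif(0, 1)",
    "p_G_GM ~ dunif(0, 1)",
    "p_N_GM ~ dunif(0, 1)",
    "u_P ~ dunif(0, 1)",
    if (a) "pibar_G ~ dunif(0, 1)"
  )

  cascade <- c(
    "pi_GD <- gamma1 * gamma2 * gamma3 * gamma4",
    "logit(p_UN) <- logit(gamma4) + a_UN",
    "a_EX <- a_OP * (0.15 - gamma4)",
    "pi_UN <- gamma1 * (1 - gamma2) * p_UN",
    "pi_OP <- gamma1 * gamma2 * (1 - gamma3) * (gamma4 + a_EX)",
    if (!a) "pibar_G <- pi_UN + pi_OP",
    "or_GM <- (p_N_GM / (1 - p_N_GM)) / (p_G_GM / (1 - p_G_GM))",
    "odds_N <- (pibar_G / (1 - pibar_G)) * or_GM",
    "pibar_N <- odds_N / (1 + odds_N)",
    "pibar_P <- u_P * pibar_N",
    if (b) {
      "pidelta_G <- (1 - gamma1) + gamma1 * gamma2 * gamma3 * gamma4"
    } else {
      c("delta_G <- a_delta_G * (1 - pibar_G)",
        "pidelta_G <- pibar_G * delta_G / (1 - delta_G)")
    },
    "delta_N <- a_delta_N * (1 - pibar_N)",
    "pidelta_N <- pibar_N * delta_N / (1 - delta_N)",
    "delta_P <- a_delta_P * (1 - pibar_P)",
    "pidelta_P <- pibar_P * delta_P / (1 - delta_P)",
    if (b) "zero_pg ~ dpois(1.0E4 * step(pibar_G + pidelta_G - 1))"
  )

  counts <- c(
    if (need_mu_pop) "mu_pop <- exp(log_mu_pop)",
    if (need_mu_d) c(
      "mu_DG <- mu_pop * rho[1] * pidelta_G",
      "mu_DN <- mu_pop * rho[2] * pidelta_N",
      "mu_DP <- mu_pop * rho[3] * pidelta_P",
      "mu_D <- mu_DG + mu_DN + mu_DP"
    )
  )

  lik <- c(
    if ("pop" %in% sources) "ypop ~ dpois(mu_pop)",
    if ("natsal" %in% sources) "y_nat[1:4] ~ dmulti(rho[], n_nat)",
    if ("gumcad" %in% sources) c(
      "g2 ~ dbin(gamma1, g1)",
      "g3 ~ dbin(gamma2, g2)",
      "g4 ~ dbin(gamma3, g3)",
      "g5 ~ dbin(gamma4, g4)"
    ),
    if ("gum_anon" %in% sources) c(
      "pi_GA <- (pibar_G + pi_GD) / gamma1",
      "pi_GA_safe <- min(pi_GA, 0.999999)",
      "g_A ~ dbin(pi_GA_safe, g_AN)",
      "zero_ga ~ dpois(1.0E4 * step(pi_GA - 1))"
    ),
    if ("sophid" %in% sources) c(
      "mu_M <- e_S * mu_D",
      "y_M ~ dpois(mu_M)"
    ),
    if ("handd" %in% sources) c(
      "p_H <- a_H * mu_DG / mu_D",
      "y_H ~ dbin(p_H, y_M_n)"
    ),
    if ("gmshs" %in% sources) c(
      "y_G_GM ~ dbin(p_G_GM, n_G_GM)",
      "y_N_GM ~ dbin(p_N_GM, n_N_GM)"
    )
  )

  paste0(
    "model {\n  ",
    paste(c(priors, cascade, counts, lik), collapse = "\n  "),
    "\n}\n"
  )
}

hiv_jags_data <- function(obs, sources, variant = hiv_variant()) {
  d <- list(dir_alpha = rep(1, 4))
  if (variant$gumcad_informs_diagnosed) d$zero_pg <- 0
  if ("pop" %in% sources) d$ypop <- obs$ypop
  if ("natsal" %in% sources) {
    d$y_nat <- c(obs$y_G, obs$y_N, obs$y_P, obs$y_NAT - obs$y_G - obs$y_N - obs$y_P)
    d$n_nat <- obs$y_NAT
  }
  if ("gumcad" %in% sources) d[c("g1", "g2", "g3", "g4", "g5")] <- obs[c("g1", "g2", "g3", "g4", "g5")]
  if ("gum_anon" %in% sources) {
    d$g_A <- obs$g_A
    d$g_AN <- obs$g_AN
    d$zero_ga <- 0
  }
  if ("sophid" %in% sources) d$y_M <- obs$y_M
  if ("handd" %in% sources) {
    d$y_H <- obs$y_H
    d$y_M_n <- obs$y_M
  }
  if ("gmshs" %in% sources) {
    d[c("y_G_GM", "n_G_GM", "y_N_GM", "n_N_GM")] <-
      obs[c("y_G_GM", "n_G_GM", "y_N_GM", "n_N_GM")]
  }
  d
}

hiv_jags_inits <- function(obs, variant, chains, seed) {
  jitterify <- function(x, lo = 0, hi = 1, amount = 0.15) {
    z <- qlogis((x - lo) / (hi - lo)) + rnorm(length(x), 0, amount)
    lo + (hi - lo) * plogis(z)
  }
  with_local_seed(seed, lapply(seq_len(chains), function(ch) {
    rho0 <- c(obs$y_G, obs$y_N, obs$y_P, obs$y_NAT - obs$y_G - obs$y_N - obs$y_P) + 1
    rho0 <- rho0 * exp(rnorm(4, 0, 0.05))
    init <- list(
      log_mu_pop = log(obs$ypop) + rnorm(1, 0, 1e-4),
      rho = rho0 / sum(rho0),
      e_S = 1 + rnorm(1, 0, 0.005),
      a_H = jitterify(0.5),
      a_delta_G = jitterify(0.9),
      a_delta_N = jitterify(0.9),
      a_delta_P = jitterify(0.9),
      gamma1 = jitterify(obs$g2 / obs$g1),
      gamma2 = jitterify(obs$g3 / obs$g2),
      gamma3 = jitterify(obs$g4 / obs$g3),
      gamma4 = jitterify(obs$g5 / obs$g4, 0, 0.15),
      a_UN = jitterify(0, log(0.5), log(1.5)),
      a_OP = jitterify(0.5),
      p_G_GM = jitterify((obs$y_G_GM + 1) / (obs$n_G_GM + 2)),
      p_N_GM = jitterify((obs$y_N_GM + 1) / (obs$n_N_GM + 2)),
      u_P = jitterify(0.5),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (seed * 1009L + ch) %% 2147483647L
    )
    if (variant$undiagnosed_source == "gum_anon_only") {
      init$pibar_G <- jitterify(0.03)
    }
    init
  }))
}

#' Sample the HIV model posterior by MCMC
#'
#' Builds the JAGS program for the requested variant and active data sources,
#' runs Gibbs/slice sampling with multiple chains, monitors the founder
#' parameters, and propagates every retained draw through [derived_outputs()].
#' Convergence diagnostics (split R-hat and effective sample size per founder)
#' are attached as the `"diagnostics"` attribute; a split R-hat above 1.01
#' triggers a warning but draws are still returned.
#'
#' The model posterior has strong correlations and heavy upper tails in the
#' undiagnosed case counts, so draws are thinned substantially; the default
#' thinning is heavier for the GUM-Anon-only variant, whose free undiagnosed
#' prevalence mixes the slowest.
#'
#' @param data An [hiv_observations()] list.
#' @param variant An [hiv_variant()].
#' @param chains Number of MCMC chains.
#' @param draws Retained draws per chain after thinning.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param adapt Sampler adaptation iterations.
#' @param thin Thinning interval; default 50 (base), 100 (GUM-Anon-only
#'   variant), 5 (prior-only).
#' @param seed Integer seed controlling initial values and all chain RNG.
#' @param sources Active likelihood terms, see [log_posterior()].
#' @param prior_only If `TRUE`, drop all likelihood terms and return founder
#'   draws from the prior (no derived outputs attached).
#' @param quiet Suppress JAGS progress output.
#'
#' @return A tibble of posterior draws (founders plus derived outputs), with
#'   attributes `"diagnostics"` (tibble of `parameter`, `rhat`, `ess`) and
#'   `"mcmc_info"`.
#' @export
sample_posterior <- function(data = hiv_observations(), variant = hiv_variant(),
                             chains = 4, draws = 5000, warmup = 3000,
                             adapt = 2000, thin = NULL, seed = 1,
                             sources = hiv_sources(), prior_only = FALSE,
                             quiet = TRUE) {
  stopifnot(inherits(data, "hiv_observations"), chains >= 2, draws >= 1)
  if (prior_only) sources <- character(0)
  sources <- match_sources(sources)
  if (is.null(thin)) {
    thin <- if (length(sources) == 0) 5
            else if (variant$undiagnosed_source == "gum_anon_only") 100
            else 50
  }
  monitors <- c(
    "log_mu_pop", "rho", "e_S", "a_H", "a_delta_G", "a_delta_N", "a_delta_P",
    "gamma1", "gamma2", "gamma3", "gamma4", "a_UN", "a_OP",
    "p_G_GM", "p_N_GM", "u_P",
    if (variant$undiagnosed_source == "gum_anon_only") "pibar_G"
  )
  model <- hiv_jags_model(variant, sources)
  jm <- rjags::jags.model(
    textConnection(model),
    data = hiv_jags_data(data, sources, variant),
    inits = hiv_jags_inits(data, variant, chains, seed),
    n.chains = chains, n.adapt = adapt, quiet = quiet
  )
  if (warmup > 0) stats::update(jm, warmup, progress.bar = "none")
  sam <- rjags::coda.samples(jm, monitors, n.iter = draws * thin, thin = thin,
                             progress.bar = "none")

  diag_tbl <- mcmc_diagnostics(sam)
  bad <- diag_tbl$rhat > 1.01
  if (any(bad, na.rm = TRUE)) {
    warn(sprintf(
      "Split R-hat above 1.01 for: %s. Draws returned; consider more iterations or heavier thinning.",
      paste(diag_tbl$parameter[which(bad)], collapse = ", ")
    ))
  }

  m <- as.matrix(sam)
  founders <- tibble(
    log_mu_pop = m[, "log_mu_pop"],
    rho_G = m[, "rho[1]"], rho_N = m[, "rho[2]"], rho_P = m[, "rho[3]"],
    a_S = log(m[, "e_S"]), a_H = m[, "a_H"],
    a_delta_G = m[, "a_delta_G"], a_delta_N = m[, "a_delta_N"],
    a_delta_P = m[, "a_delta_P"],
    gamma1 = m[, "gamma1"], gamma2 = m[, "gamma2"], gamma3 = m[, "gamma3"],
    gamma4 = m[, "gamma4"],
    a_UN = m[, "a_UN"], a_OP = m[, "a_OP"],
    p_G_GM = m[, "p_G_GM"], p_N_GM = m[, "p_N_GM"], u_P = m[, "u_P"]
  )
  if (variant$undiagnosed_source == "gum_anon_only") {
    founders$pibar_G_free <- m[, "pibar_G"]
  }
  out <- if (!"pop" %in% sources) {
    # without the population likelihood the count scale is unidentified (the
    # diffuse size prior overflows); return founders only
    founders
  } else {
    bind_cols(founders, derived_outputs(founders, variant))
  }
  attr(out, "diagnostics") <- diag_tbl
  attr(out, "mcmc_info") <- list(
    variant = variant, sources = sources, chains = chains, draws = draws,
    warmup = warmup, adapt = adapt, thin = thin, seed = seed
  )
  out
}

# split-R-hat and effective sample size for an mcmc.list
mcmc_diagnostics <- function(sam) {
  params <- colnames(sam[[1]])
  rhat <- vapply(params, function(p) {
    ch <- vapply(sam, function(s) as.numeric(s[, p]), numeric(nrow(sam[[1]])))
    split_rhat(ch)
  }, 0)
  ess <- tryCatch(coda::effectiveSize(sam), error = function(e) rep(NA_real_, length(params)))
  tibble(parameter = params, rhat = unname(rhat), ess = unname(ess[params]))
}

split_rhat <- function(chains_matrix) {
  n <- nrow(chains_matrix)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- cbind(chains_matrix[seq_len(half), , drop = FALSE],
                  chains_matrix[(n - half + 1):n, , drop = FALSE])
  if (sd(splits) == 0) return(1)
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}
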