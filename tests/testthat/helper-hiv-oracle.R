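# A second, literal transcription of the HIV model density, written term by
# term against the data-source definitions and kept deliberately independent
# of the package implementation (no calls into derived_outputs()).

oracle_log_posterior <- function(f, obs, variant = hiv_variant(),
                                 sources = hiv_sources()) {
  g1 <- f$gamma1; g2 <- f$gamma2; g3 <- f$gamma3; g4 <- f$gamma4
  # priors
  lp <- dnorm(f$log_mu_pop, mean = 0, sd = 1000, log = TRUE)
  lp <- lp + log(6)                                     # Dirichlet(1,1,1,1)
  lp <- lp + dnorm(exp(f$a_S), 1, 0.018, log = TRUE) + f$a_S
  lp <- lp - log(0.15)                                  # gamma4 ~ U(0, 0.15)
  lp <- lp - log(log(1.5) - log(0.5))                   # a_UN ~ U(log .5, log 1.5)

  # deterministic graph, written out longhand
  mu_pop <- exp(f$log_mu_pop)
  pi_GD <- g1 * g2 * g3 * g4
  p_UN <- 1 / (1 + exp(-(log(g4 / (1 - g4)) + f$a_UN)))
  pi_UN <- g1 * (1 - g2) * p_UN
  pi_OP <- g1 * g2 * (1 - g3) * (g4 + f$a_OP * (0.15 - g4))
  pibar_G <- if (variant$undiagnosed_source == "gum_anon_only") {
    f$pibar_G_free
  } else {
    pi_UN + pi_OP
  }
  or_gm <- (f$p_N_GM / (1 - f$p_N_GM)) / (f$p_G_GM / (1 - f$p_G_GM))
  o_n <- pibar_G / (1 - pibar_G) * or_gm
  pibar_N <- o_n / (1 + o_n)
  pibar_P <- f$u_P * pibar_N
  if (variant$gumcad_informs_diagnosed) {
    pidelta_G <- (1 - g1) + g1 * g2 * g3 * g4
    if (pibar_G + pidelta_G >= 1) return(-Inf)
  } else {
    delta_G <- f$a_delta_G * (1 - pibar_G)
    pidelta_G <- pibar_G / (1 - delta_G) * delta_G
  }
  delta_N <- f$a_delta_N * (1 - pibar_N)
  pidelta_N <- pibar_N / (1 - delta_N) * delta_N
  delta_P <- f$a_delta_P * (1 - pibar_P)
  pidelta_P <- pibar_P / (1 - delta_P) * delta_P
  mu_DG <- mu_pop * f$rho_G * pidelta_G
  mu_DN <- mu_pop * f$rho_N * pidelta_N
  mu_DP <- mu_pop * f$rho_P * pidelta_P
  mu_D <- mu_DG + mu_DN + mu_DP

  # likelihood, one dataset at a time
  if ("pop" %in% sources) {
    lp <- lp + dpois(obs$ypop, mu_pop, log = TRUE)
  }
  if ("natsal" %in% sources) {
    k <- c(obs$y_G, obs$y_N, obs$y_P, obs$y_NAT - obs$y_G - obs$y_N - obs$y_P)
    pr <- c(f$rho_G, f$rho_N, f$rho_P, 1 - f$rho_G - f$rho_N - f$rho_P)
    lp <- lp + lgamma(obs$y_NAT + 1) - sum(lgamma(k + 1)) + sum(k * log(pr))
  }
  if ("gumcad" %in% sources) {
    lp <- lp + dbinom(obs$g2, obs$g1, g1, log = TRUE)
    lp <- lp + dbinom(obs$g3, obs$g2, g2, log = TRUE)
    lp <- lp + dbinom(obs$g4, obs$g3, g3, log = TRUE)
    lp <- lp + dbinom(obs$g5, obs$g4, g4, log = TRUE)
  }
  if ("gum_anon" %in% sources) {
    pi_GA <- (pibar_G + pi_GD) / g1
    if (pi_GA >= 1) return(-Inf)
    lp <- lp + dbinom(obs$g_A, obs$g_AN, pi_GA, log = TRUE)
  }
  if ("sophid" %in% sources) {
    lp <- lp + dpois(obs$y_M, exp(f$a_S) * mu_D, log = TRUE)
  }
  if ("handd" %in% sources) {
    lp <- lp + dbinom(obs$y_H, obs$y_M, f$a_H * mu_DG / mu_D, log = TRUE)
  }
  if ("gmshs" %in% sources) {
    lp <- lp + dbinom(obs$y_G_GM, obs$n_G_GM, f$p_G_GM, log = TRUE)
    lp <- lp + dbinom(obs$y_N_GM, obs$n_N_GM, f$p_N_GM, log = TRUE)
  }
  lp
}

# draw a founder vector from the prior, concentrated near plausible values so
# likelihood terms stay finite-exponent but otherwise arbitrary
random_founders <- function(variant = hiv_variant(), seed) {
  set.seed(seed)
  rho <- as.numeric(rgamma(4, shape = c(8, 39, 11, 770)))
  rho <- rho / sum(rho)
  f <- tibble::tibble(
    log_mu_pop = log(2060000) + rnorm(1, 0, 0.1),
    rho_G = rho[1], rho_N = rho[2], rho_P = rho[3],
    a_S = log(rnorm(1, 1, 0.018)),
    a_H = runif(1), a_delta_G = runif(1), a_delta_N = runif(1),
    a_delta_P = runif(1),
    gamma1 = runif(1, 0.5, 1), gamma2 = runif(1, 0.5, 1),
    gamma3 = runif(1, 0.5, 1), gamma4 = runif(1, 0, 0.15),
    a_UN = runif(1, log(0.5), log(1.5)), a_OP = runif(1),
    p_G_GM = runif(1), p_N_GM = runif(1), u_P = runif(1)
  )
  if (variant$undiagnosed_source == "gum_anon_only") f$pibar_G_free <- runif(1)
  f
}
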