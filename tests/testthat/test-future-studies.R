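test_that("GUM Anon simulation respects degenerate and average behaviour", {
  d <- fake_posterior(20000)
  d0 <- d
  d0$pi_GA <- 0
  s0 <- simulate_gum_anon(d0, n = 50, seed = 1)
  expect_true(all(s0$y == 0) && all(s0$statistic == 0))

  # iterated expectation: the mean simulated prevalence matches the posterior
  # mean of pi_GA
  s <- simulate_gum_anon(d, n = 85, seed = 2)
  mc_se <- sd(s$statistic) / sqrt(nrow(d))
  expect_lt(abs(mean(s$statistic) - mean(d$pi_GA)), 3 * mc_se)
  expect_true(all(s$statistic >= 0 & s$statistic <= 1))
  expect_error(simulate_gum_anon(d, n = 0), "at least 1")
})

test_that("large GUM Anon samples approach partial perfect information", {
  d <- fake_posterior(20000)
  d$alpha <- 10 * d$pi_GA + rnorm(20000, 0, 0.05)
  ceiling_est <- evppi(d, "pi_GA", loss_quadratic("alpha"), se = FALSE)$value
  s_big <- simulate_gum_anon(d, n = 100000, seed = 3)
  e_big <- evsi(dplyr::bind_cols(d, s_big["statistic"]), "statistic",
                loss_quadratic("alpha"), se = FALSE)
  s_small <- simulate_gum_anon(d, n = 20, seed = 3)
  e_small <- evsi(dplyr::bind_cols(d, s_small["statistic"]), "statistic",
                  loss_quadratic("alpha"), se = FALSE)
  expect_lt(e_small$value, e_big$value)
  expect_equal(e_big$value, ceiling_est, tolerance = 0.02)
})

test_that("GMSHS simulation produces finite smoothed odds ratios in all corners", {
  d <- fake_posterior(5000)
  # null odds ratio when the two group prevalences coincide
  dn <- d
  dn$p_N_GM <- dn$p_G_GM <- 0.3
  sn <- simulate_gmshs(dn, n = 4000, seed = 4)
  expect_equal(mean(sn$statistic), 1, tolerance = 0.05)
  # all participants attenders: the empty arm is smoothed, not divided by zero
  s1 <- simulate_gmshs(d, n = 30, seed = 5, attendance = c(1e7, 1))
  expect_true(all(s1$N_G == 30))
  expect_true(all(is.finite(s1$statistic)))
})

test_that("GMSHS statistic matches exhaustive enumeration at small n", {
  # condition on one parameter draw and a fixed attendance probability
  p_g <- 0.3; p_n <- 0.45; q <- 0.6; n <- 10
  d1 <- tibble::tibble(p_G_GM = rep(p_g, 60000), p_N_GM = p_n)
  s <- simulate_gmshs(d1, n = n, seed = 6, attendance = c(q * 1e8, (1 - q) * 1e8))
  # enumerate (N_G, Y_G, Y_N) exactly
  t_exp <- 0
  for (ng in 0:n) {
    p_ng <- dbinom(ng, n, q)
    for (yg in 0:ng) for (yn in 0:(n - ng)) {
      pr <- p_ng * dbinom(yg, ng, p_g) * dbinom(yn, n - ng, p_n)
      pg_hat <- (yg + 0.5) / (ng + 1)
      pn_hat <- (yn + 0.5) / (n - ng + 1)
      t_exp <- t_exp + pr * (pn_hat / (1 - pn_hat)) / (pg_hat / (1 - pg_hat))
    }
  }
  mc_se <- sd(s$statistic) / sqrt(nrow(s))
  expect_lt(abs(mean(s$statistic) - t_exp), 3 * mc_se)
})

test_that("EVSI curves are reproducible, tabular, and validated", {
  d <- fake_posterior(3000)
  d$alpha <- 5 * d$pi_GA + rnorm(3000, 0, 0.1)
  expect_error(
    evsi_curve(d, "gum_anon", c(10, 10), loss_quadratic("alpha")),
    "strictly increasing"
  )
  c1 <- evsi_curve(d, "gum_anon", c(20, 100, 400), loss_quadratic("alpha"),
                   seed = 7, se = FALSE, min_draws = 1000)
  c2 <- evsi_curve(d, "gum_anon", c(20, 100, 400), loss_quadratic("alpha"),
                   seed = 7, se = FALSE, min_draws = 1000)
  expect_equal(c1, c2)
  expect_named(c1, c("n", "evsi", "se", "residual_loss", "residual_sd"))
  expect_equal(c1$residual_sd, sqrt(c1$residual_loss))
  # the information value of the design rises with its size
  expect_gt(c1$evsi[3], c1$evsi[1])
})
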