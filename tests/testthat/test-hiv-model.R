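test_that("the deterministic graph satisfies its boundary and identity cases", {
  f <- random_founders(seed = 71)
  # zero diagnosed fractions kill all diagnosed prevalence and counts
  f0 <- f
  f0$a_delta_G <- f0$a_delta_N <- f0$a_delta_P <- 1e-300
  out0 <- derived_outputs(f0)
  expect_lt(max(out0$delta_G, out0$delta_N, out0$delta_P), 1e-250)
  expect_lt(max(out0$mu_DG, out0$mu_DN, out0$mu_DP), 1e-200)

  # equal GMSHS proportions give a null odds ratio, so the two undiagnosed
  # prevalences coincide
  f1 <- f
  f1$p_N_GM <- f1$p_G_GM
  out1 <- derived_outputs(f1)
  expect_equal(out1$or_GM, 1)
  expect_equal(out1$pibar_N, out1$pibar_G)

  # undiagnosed GMSM prevalence decomposes exactly into unoffered + opt-out
  out <- derived_outputs(f)
  expect_equal(out$pibar_G, out$pi_UN + out$pi_OP, tolerance = 1e-15)
  # count additivity
  expect_equal(out$mu_D, out$mu_DG + out$mu_DN + out$mu_DP)
  expect_equal(out$mu, out$mu_DG + out$mu_DN + out$mu_UG + out$mu_UN)
  expect_equal(out$mu_U_3grp, out$mu_U_2grp + out$mu_UP)
})

test_that("variant toggles rewire the graph as specified", {
  f <- random_founders(hiv_variant("gum_anon_only"), seed = 72)
  f$pibar_G_free <- 0.04
  out_a <- derived_outputs(f, hiv_variant("gum_anon_only"))
  expect_equal(out_a$pibar_G, 0.04)

  fb <- random_founders(seed = 73)
  out_b <- derived_outputs(fb, hiv_variant(gumcad_informs_diagnosed = TRUE))
  expect_equal(out_b$pidelta_G,
               (1 - fb$gamma1) + fb$gamma1 * fb$gamma2 * fb$gamma3 * fb$gamma4)
  expect_equal(out_b$pi_G, out_b$pibar_G + out_b$pidelta_G)

  expect_error(derived_outputs(fb[, -1]), "Missing founder")
  fbad <- fb
  fbad$gamma4 <- 0.2
  expect_error(derived_outputs(fbad), "outside the prior support")
})

test_that("log posterior agrees with an independent transcription", {
  obs <- hiv_observations()
  variants <- list(
    hiv_variant(),
    hiv_variant("gum_anon_only"),
    hiv_variant(gumcad_informs_diagnosed = TRUE),
    hiv_variant("gum_anon_only", gumcad_informs_diagnosed = TRUE)
  )
  for (vi in seq_along(variants)) {
    for (r in 1:8) {
      f <- random_founders(variants[[vi]], seed = 700 + 10 * vi + r)
      lp <- log_posterior(f, obs, variants[[vi]])
      lo <- oracle_log_posterior(f, obs, variants[[vi]])
      if (is.finite(lo)) {
        expect_equal(lp, lo, tolerance = 1e-8)
      } else {
        expect_identical(lp, -Inf)
      }
    }
  }
  # subsets of sources agree too (term-by-term correctness)
  f <- random_founders(seed = 799)
  for (src in list(character(0), "gumcad", c("pop", "natsal"), c("sophid", "handd"))) {
    expect_equal(log_posterior(f, obs, sources = src),
                 oracle_log_posterior(f, obs, sources = src), tolerance = 1e-8)
  }
})

test_that("each data source's term is isolated from unrelated parameters", {
  obs <- hiv_observations()
  f <- random_founders(seed = 75)
  f2 <- f
  f2$a_S <- f$a_S + 0.01
  # changing the reporting-bias adjustment moves only prior + SOPHID terms
  d_all <- log_posterior(f2, obs) - log_posterior(f, obs)
  d_iso <- log_posterior(f2, obs, sources = "sophid") -
    log_posterior(f, obs, sources = "sophid")
  expect_equal(d_all, d_iso, tolerance = 1e-9)
  # and leaves e.g. the GUMCAD likelihood term untouched (the shift in the
  # prior-only density cancels in the difference)
  d_gumcad_lik <- (log_posterior(f2, obs, sources = "gumcad") -
                     log_posterior(f, obs, sources = "gumcad")) -
    (log_posterior(f2, obs, sources = character(0)) -
       log_posterior(f, obs, sources = character(0)))
  expect_equal(d_gumcad_lik, 0, tolerance = 1e-10)
})

test_that("out-of-support founders have zero posterior density", {
  f <- random_founders(seed = 76)
  f$gamma4 <- 0.2
  expect_identical(log_posterior(f, hiv_observations()), -Inf)
  f2 <- random_founders(seed = 77)
  f2$a_UN <- 1
  expect_identical(log_posterior(f2, hiv_observations()), -Inf)
})

test_that("sampling is reproducible and every draw respects the support", {
  fit1 <- suppressWarnings(sample_posterior(
    seed = 78, chains = 2, draws = 150, warmup = 300, adapt = 400, thin = 2
  ))
  fit2 <- suppressWarnings(sample_posterior(
    seed = 78, chains = 2, draws = 150, warmup = 300, adapt = 400, thin = 2
  ))
  expect_equal(as.data.frame(fit1), as.data.frame(fit2))
  expect_true(all(hiv_in_support(fit1)))
  expect_true(all(1 - fit1$delta_G > fit1$pibar_G))
  expect_true(all(1 - fit1$delta_N > fit1$pibar_N))
  expect_true(all(fit1$pi_GA >= 0 & fit1$pi_GA <= 1))
  d <- attr(fit1, "diagnostics")
  expect_true(all(c("parameter", "rhat", "ess") %in% names(d)))
})

test_that("a single isolated binomial arm has the conjugate Beta posterior", {
  iso <- sample_posterior(sources = "gmshs", draws = 2500, seed = 79)
  # p_G_GM | 20 of 493 with a flat prior is Beta(21, 474)
  expect_lt(abs(mean(iso$p_G_GM) - 21 / 495), 3 * sqrt(21 * 474 / (495^2 * 496) / 2500) + 0.002)
  ks <- suppressWarnings(ks.test(iso$p_G_GM, function(q) pbeta(q, 21, 474)))
  expect_gt(ks$p.value, 0.01)
})

test_that("observation container validates its invariants", {
  expect_error(hiv_observations(g2 = 40000), "nonincreasing")
  expect_error(hiv_observations(y_G = 800), "exceed the sample size")
  expect_error(hiv_observations(g_A = 90), "exceed the denominator")
  expect_error(hiv_observations(ypop = -1), "nonnegative")
  expect_error(hiv_observations(bogus = 2), "Unknown observation")
  path <- tempfile(fileext = ".yaml")
  write_hiv_observations(hiv_observations(), path)
  expect_equal(read_hiv_observations(path), hiv_observations())
  shipped <- system.file("extdata", "hiv_observations.yaml", package = "voisynth")
  expect_equal(read_hiv_observations(shipped), hiv_observations())
})
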