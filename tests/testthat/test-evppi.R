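test_that("learning the output itself recovers all of its variance", {
  fx <- conjugate_fixture("normal_known_var")
  d <- generate_draws(fx, 5000, seed = 31)
  e <- evppi(d, "theta", loss_quadratic("alpha"), se = FALSE)
  expect_equal(e$proportion, 1, tolerance = 1e-6)
  expect_equal(e$value, var(d$alpha), tolerance = 1e-6)
})

test_that("an irrelevant parameter has EVPPI near zero", {
  set.seed(32)
  d <- data.frame(alpha = rnorm(20000), noise = runif(20000))
  e <- evppi(d, "noise", loss_quadratic("alpha"), seed = 1)
  # spurious explained variance from ~10 spline df out of 20k draws
  expect_lt(abs(e$value), 0.005 * e$baseline_loss + 3 * e$standard_error)
})

test_that("linear-sum EVPPI matches the conjugate closed form across replicates", {
  fx <- conjugate_fixture("linear_sum", v = c(1, 1), noise_sd = 0)
  rep <- replicate_voi(fx, n_reps = 5, n_draws = 20000, seeds = 330, function(d) {
    evppi(d, "phi1", loss_quadratic("alpha"), se = FALSE)$value
  })
  expect_lt(abs(rep$mean - 1), 3 * rep$se)
  # var(alpha) = 2, so the proportion explained is about one half
  expect_equal(rep$mean / 2, 0.5, tolerance = 0.05)
})

test_that("variance-of-fitted and variance-minus-residual estimators agree", {
  set.seed(34)
  d <- data.frame(x = runif(4000))
  d$y <- d$x^2 + rnorm(4000, 0, 0.1)
  # exact algebraic identity for the unpenalized least-squares backend
  e_mars <- evppi(d, "x", loss_quadratic("y"), method = "mars", se = FALSE)
  f_mars <- attr(e_mars, "fits")[[1]]
  expect_equal(e_mars$value, var(f_mars$fitted), tolerance = 1e-10)
  # near-identity for the penalized spline backend (smoothing leaves a tiny
  # fitted-residual correlation)
  e_gam <- evppi(d, "x", loss_quadratic("y"), method = "gam", se = FALSE)
  f_gam <- attr(e_gam, "fits")[[1]]
  expect_equal(e_gam$value, var(f_gam$fitted), tolerance = 1e-3)
})

test_that("EVPPI of the complete founder set reaches EVPI in a deterministic-link model", {
  fx <- conjugate_fixture("linear_sum", v = c(0.25, 1), noise_sd = 0)
  d <- generate_draws(fx, 20000, seed = 35)
  e_all <- evppi(d, c("phi1", "phi2"), loss_quadratic("alpha"), seed = 1)
  e_pi <- evpi(d, loss_quadratic("alpha"))
  expect_lt(abs(e_all$value - e_pi$value),
            3 * (e_all$standard_error + e_pi$standard_error) + 0.01 * e_pi$value)
})

test_that("EVPPI respects the 0 <= EVPPI <= EVPI ordering on every fixture", {
  for (kind in c("normal_known_var", "beta_binomial", "linear_sum")) {
    fx <- conjugate_fixture(kind)
    d <- generate_draws(fx, 10000, seed = 36)
    phi <- setdiff(names(d), "alpha")[1]
    e <- evppi(d, phi, loss_quadratic("alpha"), seed = 1)
    e0 <- evpi(d, loss_quadratic("alpha"))
    expect_gte(e$value, -3 * e$standard_error - 1e-3 * e0$value)
    expect_lte(e$value, e0$value + 3 * e$standard_error + 1e-6)
  }
  # finite-action fixture against its closed form
  fx2 <- conjugate_fixture("two_action_gaussian")
  d2 <- generate_draws(fx2, 20000, seed = 37)
  e2 <- evppi(d2, "phi", loss_finite_action(c("alpha1", "alpha2")), seed = 1)
  truth <- closed_form_evppi(fx2)
  expect_equal(e2$value, truth, tolerance = 0.06)
  e2pi <- evpi(d2, loss_finite_action(c("alpha1", "alpha2")))
  expect_lte(e2$value, e2pi$value + 3 * (e2$standard_error + e2pi$standard_error))
})

test_that("vector-loss EVPPI reduces to products of variances for independent outputs", {
  set.seed(38)
  n <- 20000
  phi <- rnorm(n)
  d <- data.frame(
    phi = phi,
    a = phi + rnorm(n),
    b = -phi + rnorm(n, 0, 0.5)
  )
  e <- evppi(d, "phi", loss_d_optimal(c("a", "b")), seed = 1)
  # residuals of a and b on phi are independent: det(cov resid) is the product
  fits <- attr(e, "fits")
  r <- cbind(fits[[1]]$residuals, fits[[2]]$residuals)
  expect_equal(det(cov(r)), prod(diag(cov(r))), tolerance = 0.02 * det(cov(r)))
  expect_equal(e$value, det(cov(d[c("a", "b")])) - det(cov(r)), tolerance = 1e-10)
})

test_that("the proportion-of-variance grid is computed cellwise", {
  fx <- conjugate_fixture("linear_sum", v = c(0.25, 1), noise_sd = 0.5)
  d <- generate_draws(fx, 12000, seed = 39)
  g <- evppi_grid(d, outputs = "alpha", parameters = c("phi1", "phi2"))
  expect_equal(nrow(g), 2)
  expect_lt(abs(g$value[g$parameter == "phi1"] - 0.25), 0.06)
  expect_lt(abs(g$value[g$parameter == "phi2"] - 1), 0.09)
  expect_equal(g$value / g$baseline, g$proportion)
  # sanity column: an output regressed on itself explains everything
  g2 <- evppi_grid(d, outputs = "alpha", parameters = "alpha")
  expect_equal(g2$proportion, 1, tolerance = 1e-6)
})
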