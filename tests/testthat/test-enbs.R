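test_that("benefit functions value variance reductions as specified", {
  lin <- benefit_spec("linear_variance", 2)
  hal <- benefit_spec("halving", 100)
  # no variance reduction, no benefit
  expect_equal(expected_benefit(4, 4, lin), 0)
  expect_equal(expected_benefit(4, 4, hal), 0)
  # one halving is worth exactly lambda
  expect_equal(expected_benefit(4, 2, hal), 100)
  expect_equal(expected_benefit(4, 1, hal), 200)
  expect_error(expected_benefit(4, 0, hal), "undefined at zero")
  # a 500-SD reduction from 3271 valued at 5000 fixes lambda
  lam <- 5000 / (3271^2 - 2771^2)
  expect_equal(expected_benefit(3271^2, 2771^2, benefit_spec("linear_variance", lam)), 5000)
  # negative EVSI estimates are clipped with a warning, never negative benefit
  expect_warning(b <- expected_benefit(4, 4.5, lin), "clipping")
  expect_equal(b, 0)
  expect_error(benefit_spec("linear_variance", -1))
})

test_that("net-benefit curve locates the analytic optimum of a synthetic curve", {
  # EVSI(n) = V p n / (n + h): with benefit lambda*EVSI and cost c*n the
  # net benefit is maximized at n* = sqrt(lambda V p h / c) - h
  V <- 9e6; p <- 0.6; h <- 120; cost <- 17; lam <- 2e-3
  n_grid <- c(1, seq(20, 400, by = 20))
  tab <- tibble::tibble(
    n = n_grid,
    evsi = V * p * n_grid / (n_grid + h),
    residual_loss = V - evsi
  )
  curve <- enbs_curve(tab, benefit_spec("linear_variance", lam), cost_spec(cost))
  n_star_true <- sqrt(lam * V * p * h / cost) - h
  expect_lt(abs(attr(curve, "n_star") - n_star_true), 25)
  expect_equal(nrow(curve), 400)
  expect_true(all(diff(curve$cost) > 0))
  # noisy EVSI: smoothing keeps the argmax near the true optimum
  set.seed(91)
  tab_noisy <- tab
  tab_noisy$evsi <- tab$evsi * exp(rnorm(nrow(tab), 0, 0.05))
  tab_noisy$residual_loss <- V - tab$evsi
  curve_n <- enbs_curve(tab_noisy, benefit_spec("linear_variance", lam), cost_spec(cost))
  expect_lt(abs(attr(curve_n, "n_star") - n_star_true), 60)
})

test_that("degenerate configurations behave as documented", {
  tab <- tibble::tibble(n = c(10, 100), evsi = c(100, 400), residual_loss = c(900, 600))
  # free information: spend nothing, gain nothing -> smallest n when lambda 0
  c0 <- enbs_curve(tab, benefit_spec("linear_variance", 0), cost_spec(5))
  expect_equal(attr(c0, "n_star"), 1)
  expect_equal(c0$net_benefit, -c0$cost)
  expect_error(
    enbs_curve(tab[0, ], benefit_spec("linear_variance", 1), cost_spec(1)),
    "nonempty"
  )
  # doubling willingness-to-pay never shrinks the optimal size
  c1 <- enbs_curve(tab, benefit_spec("linear_variance", 1), cost_spec(5))
  c2 <- enbs_curve(tab, benefit_spec("linear_variance", 2), cost_spec(5))
  expect_gte(attr(c2, "n_star"), attr(c1, "n_star"))
})
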