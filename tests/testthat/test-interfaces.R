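test_that("draws round-trip through the CSV dialect", {
  d <- generate_draws(conjugate_fixture("linear_sum"), 1200, seed = 101)
  path <- tempfile(fileext = ".csv")
  write_draws(d, path)
  d2 <- read_draws(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  expect_error(check_draws(d[0, ], min_draws = 10), "at least 10")
  dd <- d
  names(dd)[2] <- "phi1"
  expect_error(check_draws(dd), "unique")
})

test_that("tidy and glance methods summarise estimates and fits", {
  d <- generate_draws(conjugate_fixture("linear_sum"), 3000, seed = 102)
  e <- evppi(d, "phi1", loss_quadratic("alpha"), seed = 1)
  td <- tidy(e)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$value, e$baseline_loss - e$residual_loss)
  gl <- glance(e)
  expect_equal(gl$n_regressions, 1L)
  expect_true(gl$r_squared_min >= 0 && gl$r_squared_min <= 1)
  f <- attr(e, "fits")[[1]]
  expect_named(glance(f), c("method", "n_draws", "n_basis", "r_squared"))
})

test_that("plot builders return ggplot objects without evaluation errors", {
  d <- generate_draws(conjugate_fixture("linear_sum"), 2000, seed = 103)
  g <- evppi_grid(d, "alpha", c("phi1", "phi2"))
  p1 <- plot_evppi_grid(g)
  expect_s3_class(p1, "ggplot")
  curve <- tibble::tibble(n = c(10, 50, 200), evsi = c(1, 2, 2.5),
                          residual_loss = c(4, 3, 2.5),
                          residual_sd = sqrt(c(4, 3, 2.5)))
  expect_s3_class(plot_evsi_curve(curve), "ggplot")
  en <- enbs_curve(curve, benefit_spec("linear_variance", 10), cost_spec(0.05))
  expect_s3_class(autoplot(en), "ggplot")
})

test_that("config commands run end to end in a temporary directory", {
  out <- withr::local_tempdir()
  res <- cmd_test_oracles(list(n_draws = 3000, seed = 5,
                               out_dir = file.path(out, "oracles")))
  expect_true(file.exists(file.path(out, "oracles", "oracle_check.csv")))
  expect_true(file.exists(file.path(out, "oracles", "config_resolved.yaml")))
  expect_equal(nrow(res), 4)
  expect_true(all(abs(res$estimate - res$oracle) <
                    0.2 * pmax(res$oracle, 0.05) + 6 * res$oracle_se))

  # evsi + enbs round trip through files
  d <- fake_posterior(3000)
  d$alpha <- 5 * d$pi_GA + rnorm(3000, 0, 0.1)
  draws_path <- file.path(out, "draws.csv")
  write_draws(d, draws_path)
  cmd_evsi(list(draws = draws_path, source = "gum_anon", output = "alpha",
                n_grid = c(20, 100, 400), seed = 3,
                out_dir = file.path(out, "evsi")))
  curve_path <- file.path(out, "evsi", "evsi_curve.csv")
  expect_true(file.exists(curve_path))
  cmd_enbs(list(evsi_curve = curve_path, lambda = 5, unit_cost = 0.001,
                out_dir = file.path(out, "enbs")))
  expect_true(file.exists(file.path(out, "enbs", "n_star.json")))
  n_star <- jsonlite::read_json(file.path(out, "enbs", "n_star.json"))
  expect_true(n_star$n_star >= 1)

  expect_error(cmd_evsi(list(bogus = 1)), "Unknown config")
  expect_error(cmd_evsi(list(draws = draws_path)), "n_grid")
  expect_error(cmd_enbs(list(evsi_curve = curve_path)), "lambda")
})
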