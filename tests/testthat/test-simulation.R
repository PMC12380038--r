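test_that("the data-generating process hits its closed-form response rates", {
  cfg <- scenario_config(n_trial = 4000, n_external = 4000, beta = 0,
                         beta0 = 0, eta = 0)
  d <- generate_dataset(cfg, seed = 1)
  se <- sqrt(0.25 / 4000)
  expect_lt(abs(mean(d$y[d$z == 1L]) - 0.5), 3 * se)
  expect_lt(abs(mean(d$y[d$z == 0L]) - 0.5), 3 * se)

  # drift eta on the internal source only
  cfg_d <- scenario_config(n_trial = 4000, n_external = 4000, beta = 0,
                           eta = 0.5)
  dd <- generate_dataset(cfg_d, seed = 2)
  expect_lt(abs(mean(dd$y[dd$z == 1L]) - plogis(0.5)), 3 * se)
  expect_lt(abs(mean(dd$y[dd$z == 0L]) - 0.5), 3 * se)
  # and on the external source when flipped
  cfg_e <- scenario_config(n_trial = 2000, n_external = 2000, beta = 0,
                           eta = 0.5, drift_target = "external")
  de <- generate_dataset(cfg_e, seed = 3)
  expect_lt(abs(mean(de$y[de$z == 0L]) - plogis(0.5)), 3 * sqrt(0.25 / 2000))
})

test_that("the mixture collapses onto the trial covariate law at psi = 1", {
  cfg <- scenario_config(n_trial = 3000, n_external = 3000, psi = 1,
                         mu_e = 5)
  d <- generate_dataset(cfg, seed = 4)
  m_t <- colMeans(d[d$z == 1L, paste0("x", 1:5)])
  m_e <- colMeans(d[d$z == 0L, paste0("x", 1:5)])
  expect_true(all(abs(m_t - m_e) < 4 / sqrt(3000)))
  # psi = 0 puts every external subject on the shifted component
  cfg0 <- scenario_config(n_trial = 500, n_external = 3000, psi = 0, mu_e = 5)
  d0 <- generate_dataset(cfg0, seed = 5)
  expect_true(all(abs(colMeans(d0[d0$z == 0L, paste0("x", 1:5)]) - 5) < 0.1))
})

test_that("datasets are reproducible by seed", {
  cfg <- scenario_config(seed = 123)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  expect_false(identical(generate_dataset(cfg, seed = 1),
                         generate_dataset(cfg, seed = 2)))
})

test_that("population truth recovers closed-form rates", {
  cfg <- scenario_config(n_trial = 400, n_external = 0, beta = 0)
  t0 <- population_truth(cfg, n_datasets = 300, seed = 1)
  expect_lt(abs(t0 - 0.5), 3 * sqrt(0.25 / 400 / 300))
  cfg1 <- scenario_config(n_trial = 400, n_external = 0, beta = 0, beta0 = 1)
  t1 <- population_truth(cfg1, n_datasets = 300, seed = 2)
  expect_lt(abs(t1 - plogis(1)), 0.003)
  # symmetric covariate effects leave the rate at 1/2
  cfg5 <- scenario_config(n_trial = 400, n_external = 0, beta = 0.1)
  t5 <- population_truth(cfg5, n_datasets = 300, seed = 3)
  expect_lt(abs(t5 - 0.5), 0.003)
})

test_that("scenario grids encode the study design", {
  g1 <- scenario_grid("drift", 1)
  expect_equal(nrow(g1), 11)
  expect_equal(range(g1$sweep), c(-0.5, 0.5))
  cfg <- g1$config[[1]]
  expect_equal(cfg$n_trial, 400L)
  expect_equal(cfg$n_external, 400L)
  expect_true(all(cfg$beta == 0))
  expect_equal(cfg$eta, -0.5)

  expect_equal(scenario_grid("mixture", 2)$config[[1]]$n_external, 2000L)
  expect_equal(scenario_grid("mixture", 3)$config[[1]]$n_external, 200L)
  expect_equal(scenario_grid("mixture", 4)$config[[1]]$n_covariates, 10L)
  expect_equal(scenario_grid("drift", "small")$config[[1]]$n_trial, 100L)
  m <- scenario_grid("mixture", 1)$config[[6]]
  expect_equal(m$psi, 0.5)
  expect_equal(m$eta, 0)
  expect_equal(m$beta, rep(0.1, 5))
  expect_equal(scenario_grid("no_mixture", 1)$config[[1]]$psi, 0)

  s3 <- scenario_grid("superfluous", 1, n_zero = 3)$config[[1]]
  expect_equal(s3$beta[1:3], rep(0, 3))
  expect_equal(sum(s3$beta), 0.5)  # coefficient total preserved
  expect_error(scenario_grid("drift", 7), "unknown setting")
  expect_error(scenario_grid("nope"), "arg")
})

test_that("a small scenario run is reproducible and well formed", {
  g <- scenario_grid("drift", 1)[c(4, 8), ]
  r1 <- run_scenario(g, methods = c("ignore", "pooling"), n_replicates = 5,
                     seed = 42, n_truth = 30)
  r2 <- run_scenario(g, methods = c("ignore", "pooling"), n_replicates = 5,
                     seed = 42, n_truth = 30)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4)
  expect_setequal(r1$method, c("ignore", "pooling"))
  expect_true(all(r1$rmse >= 0))
  expect_true(all(r1$type_one_error >= 0 & r1$type_one_error <= 1))
  expect_true(all(r1$n_ok == 5))
  expect_false(any(r1$suppressed))
})

test_that("an erroring comparator is counted and its cell suppressed", {
  g <- scenario_grid("drift", 1)[6, ]
  broken <- function(d) stop("boom")
  r <- run_scenario(g, methods = list(ignore = function(d)
    fixed_delta_posterior(d, 0, n_draws = 2),
    broken = broken), n_replicates = 4, seed = 1, n_truth = 10)
  b <- r[r$method == "broken", ]
  expect_equal(b$n_error, 4)
  expect_true(b$suppressed)
  expect_true(is.na(b$rmse))
  expect_false(r$suppressed[r$method == "ignore"])
})
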