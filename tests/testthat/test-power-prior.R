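toy_counts <- function() {
  d <- as_subject_table(tibble::tibble(
    z = c(1L, 1L, 1L, 0L), y = c(1L, 0L, 1L, 1L), x1 = 1:4))
  weighted_counts(d, c(1, 1, 1, 0.5))
}

test_that("weighted counts are exact weighted sums split by source", {
  cnt <- toy_counts()
  expect_equal(cnt$a0, 2)
  expect_equal(cnt$b0, 1)
  expect_equal(cnt$a_e, 0.5)
  expect_equal(cnt$b_e, 0)
  expect_equal(cnt$sum_w_ext, 0.5)

  d <- as_subject_table(tibble::tibble(z = c(1L, 0L, 0L), y = c(1L, 1L, 0L),
                                       x1 = 1:3))
  cnt0 <- weighted_counts(d, c(1, 0, 0))
  expect_equal(cnt0$a_e + cnt0$b_e, 0)
  expect_error(weighted_counts(d, c(1, -0.1, 0)), "negative")

  # published two-source response counts with unit weights
  vem <- counts_from_totals(75, 132, 129, 241)
  expect_equal(vem$a0, 75)
  expect_equal(vem$b0, 57)
  expect_equal(vem$a_e, 129)
  expect_equal(vem$b_e, 112)
})

test_that("log scaling constant matches its closed form and the quadrature oracle", {
  cnt <- counts_from_totals(0, 0, 129, 241)
  expect_equal(log_scaling_constant(0, cnt), 0)
  cnt11 <- counts_from_totals(0, 0, 1, 2)
  expect_equal(log_scaling_constant(1, cnt11), log(1 / 6))
  for (delta in c(0.25, 0.5, 0.9)) {
    expect_equal(log_scaling_constant(delta, cnt),
                 oracle_log_scaling(delta, 129, 112), tolerance = 1e-8)
  }
  expect_error(log_scaling_constant(1.2, cnt), "\\[0, 1\\]")
})

test_that("marginal density of delta agrees with 2-D quadrature", {
  cnt <- toy_counts()
  orc <- oracle_joint(cnt$a_e, cnt$b_e, cnt$a0, cnt$b0)
  grid <- seq(0.05, 0.95, by = 0.1)
  ours <- log_marginal_delta(grid, cnt)
  theirs <- orc$log_density(grid)
  # both unnormalised: compare shapes after anchoring at the first point
  # (tolerance set by the oracle's own trapezoid grid error)
  expect_equal(ours - ours[1], theirs - theirs[1], tolerance = 5e-3)
})

test_that("empty weighted external data reduce the delta posterior to its prior", {
  d <- as_subject_table(tibble::tibble(z = c(1L, 1L, 0L), y = c(1L, 0L, 1L),
                                       x1 = 1:3))
  cnt <- weighted_counts(d, c(1, 1, 0))
  expect_equal(diff(log_marginal_delta(c(0.2, 0.8), cnt)), 0, tolerance = 1e-12)
  ds <- sample_delta(cnt, n_proposals = 10000, seed = 1)
  expect_equal(ds$acceptance_rate, 1)
  mc_se <- sd(ds$draws) / sqrt(length(ds$draws))
  expect_lt(abs(mean(ds$draws) - 0.5), 3 * mc_se)
})

test_that("rejection draws of delta match the quadrature oracle", {
  cnt <- toy_counts()
  orc <- oracle_joint(cnt$a_e, cnt$b_e, cnt$a0, cnt$b0)
  ds <- sample_delta(cnt, n_proposals = 20000, min_draws = 5000, seed = 2)
  mc_se <- sd(ds$draws) / sqrt(length(ds$draws))
  expect_lt(abs(mean(ds$draws) - orc$delta_mean), 3 * mc_se)
  expect_gt(ds$acceptance_rate, 0)
})

test_that("conflicting sources concentrate delta near zero", {
  conflict <- counts_from_totals(90, 100, 10, 100)
  orc <- oracle_joint(10, 90, 90, 10)
  ds <- sample_delta(conflict, n_proposals = 20000, min_draws = 2000, seed = 3)
  mc_se <- sd(ds$draws) / sqrt(length(ds$draws))
  expect_lt(abs(mean(ds$draws) - orc$delta_mean), 3 * mc_se)
  expect_lt(mean(ds$draws), 0.5)  # well below the empty-data baseline
})

test_that("conditional theta draws follow the conjugate Beta law", {
  vem <- counts_from_totals(75, 132)
  set.seed(4)
  th <- sample_theta_given_delta(rep(0, 20000), vem)
  expect_lt(abs(mean(th) - 76 / 134), 3 * sd(th) / sqrt(length(th)))

  pooled <- counts_from_totals(75, 132, 129, 241)
  th1 <- sample_theta_given_delta(rep(1, 20000), pooled)
  expect_lt(abs(mean(th1) - 205 / 375), 3 * sd(th1) / sqrt(length(th1)))

  sym <- counts_from_totals(1, 2, 2, 4)
  th5 <- sample_theta_given_delta(rep(0.5, 20000), sym)
  expect_lt(abs(mean(th5) - 0.5), 3 * sd(th5) / sqrt(length(th5)))
  expect_error(sample_theta_given_delta(c(0.5, 1.2), sym), "\\[0, 1\\]")
})

test_that("fixed-delta posteriors reproduce the analytic case numbers", {
  trial <- fixed_delta_posterior(counts_from_totals(75, 132), delta = 0,
                                 seed = 1)
  th <- trial$summaries[trial$summaries$parameter == "theta", ]
  expect_equal(th$mean, 76 / 134, tolerance = 1e-12)
  expect_equal(round(100 * th$mean, 1), 56.7)
  expect_equal(round(100 * th$lower, 1), 48.3)
  expect_equal(round(100 * th$upper, 1), 65.0)

  eap <- fixed_delta_posterior(counts_from_totals(0, 0, 129, 241), delta = 1,
                               seed = 1)
  the <- eap$summaries[eap$summaries$parameter == "theta", ]
  expect_equal(the$mean, 130 / 243, tolerance = 1e-12)
  expect_equal(round(100 * the$mean, 1), 53.5)
  expect_equal(round(100 * the$lower, 1), 47.2)
  expect_equal(round(100 * the$upper, 1), 59.7)

  # pooling an empty external set is the same as ignoring it
  d <- null_cohort(30, 1, seed = 6)
  d0 <- d[d$z == 1L, ]
  attr(d0, "covariates") <- subject_covariates(d)
  p0 <- fixed_delta_posterior(weighted_counts(d0), delta = 0)
  p1 <- fixed_delta_posterior(weighted_counts(d0), delta = 1)
  expect_equal(p0$shape, p1$shape)
})

test_that("the weighted posterior with unit weights equals the unweighted power prior", {
  d <- null_cohort(n_trial = 150, n_external = 150, seed = 8, p = 0.4)
  a <- propp_posterior(d, weights = 1, seed = 11, min_draws = 4000,
                       n_proposals = 20000)
  b <- mpp_posterior(d, seed = 99, min_draws = 4000, n_proposals = 20000)
  se <- sqrt(sd(a$theta_draws)^2 / a$n_draws + sd(b$theta_draws)^2 / b$n_draws)
  expect_lt(abs(mean(a$theta_draws) - mean(b$theta_draws)), 3 * se)
  se_d <- sqrt(sd(a$delta_draws)^2 / a$n_draws + sd(b$delta_draws)^2 / b$n_draws)
  expect_lt(abs(mean(a$delta_draws) - mean(b$delta_draws)), 3 * se_d)
})

test_that("zero external weights reduce the posterior to the trial-only law", {
  d <- null_cohort(n_trial = 100, n_external = 50, seed = 10)
  w <- ifelse(d$z == 1L, 1, 0)
  p <- propp_posterior(d, weights = w, seed = 5)
  a0 <- sum(d$y[d$z == 1L])
  b0 <- sum(d$z == 1L) - a0
  exact_mean <- (a0 + 1) / (a0 + b0 + 2)
  mc_se <- sd(p$theta_draws) / sqrt(p$n_draws)
  expect_lt(abs(mean(p$theta_draws) - exact_mean), 3 * mc_se)
  expect_equal(p$effective_external_weight, 0)
})

test_that("effective external weight is the delta mean times the summed weights", {
  expect_equal(effective_external_weight(rep(1, 400), rep(0.5, 10)), 200)
  expect_equal(effective_external_weight(rep(0, 400), runif(10)), 0)
  wtab <- tibble::tibble(z = c(1L, 0L, 0L), weight = c(1, 0.5, 0.25))
  expect_equal(effective_external_weight(wtab, rep(0.8, 5)), 0.8 * 0.75)
})

test_that("effective per-patient borrowing never exceeds one", {
  d <- generate_case_fixture(seed = 21)
  p <- suppressWarnings(propp_posterior(d, seed = 3, min_draws = 2000))
  w <- attr(p, "weights")
  expect_true(all(w$weight <= 1 + 1e-12))
  expect_true(all(p$delta_draws <= 1))
  expect_lte(p$effective_external_weight, p$counts$sum_w_ext)
  expect_gte(p$effective_external_weight, 0)
})

test_that("scaling the external weights rescales the scaling constant consistently", {
  cnt <- counts_from_totals(20, 40, 15, 30)
  for (c_scale in c(0.25, 0.6, 1)) {
    scaled <- counts_from_totals(20, 40, 15 * c_scale, 30 * c_scale)
    for (delta in c(0.3, 0.8)) {
      expect_equal(log_scaling_constant(delta, scaled),
                   oracle_log_scaling(delta, 15 * c_scale, 15 * c_scale),
                   tolerance = 1e-8)
    }
  }
})

test_that("posterior results carry coherent summaries and diagnostics", {
  d <- null_cohort(80, 80, seed = 14)
  p <- propp_posterior(d, seed = 7, min_draws = 1000)
  expect_s3_class(tidy(p), "tbl_df")
  expect_setequal(tidy(p)$parameter, c("theta", "delta"))
  expect_true(all(p$theta_draws > 0 & p$theta_draws < 1))
  expect_true(all(p$delta_draws >= 0 & p$delta_draws <= 1))
  expect_equal(length(p$theta_draws), length(p$delta_draws))
  gl <- glance(p)
  expect_equal(gl$method, "propp")
  expect_true(gl$acceptance_rate > 0 && gl$acceptance_rate <= 1)
})
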