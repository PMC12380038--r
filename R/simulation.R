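#' Scenario configuration for the two-source data-generating process
#'
#' Outcomes are Bernoulli with
#' `logit p = beta0 + beta %*% x + eta * I(drifted source)`, where `eta` is a
#' logit-scale drift unexplained by covariates.  Trial covariates are iid
#' `Normal(mu0, sigma0^2)` per coordinate; external covariates come from a
#' two-component mixture: with probability `psi` the trial law, otherwise
#' `Normal(mu_e, sigma_e^2)`.
#'
#' The drift attaches to the internal source (`drift_target = "internal"`)
#' by default; `drift_target = "external"` flips it.  Either way the null
#' truth used for type-I error is the drift-free trial rate.
#'
#' @param n_trial,n_external Source sample sizes.
#' @param n_covariates K, the number of continuous covariates.
#' @param beta0 Logit-scale intercept.
#' @param beta Coefficient vector (recycled to length K).
#' @param eta Drift term (logit scale).
#' @param psi Mixture proportion of external patients sharing the trial
#'   covariate law.
#' @param mu0,sigma0 Trial covariate mean / SD.
#' @param mu_e,sigma_e Shifted-component external covariate mean / SD.
#' @param drift_target `"internal"` or `"external"`.
#' @param scenario_id Free-text label carried into results.
#' @param seed Optional default seed for [generate_dataset()].
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_trial = 400L, n_external = 400L,
                            n_covariates = 5L, beta0 = 0, beta = 0.1,
                            eta = 0, psi = 1, mu0 = 0, sigma0 = 1,
                            mu_e = 0, sigma_e = 1,
                            drift_target = c("internal", "external"),
                            scenario_id = "custom", seed = NULL) {
  drift_target <- match.arg(drift_target)
  beta <- rep_len(beta, n_covariates)
  stopifnot(n_trial >= 1L, n_external >= 0L, psi >= 0, psi <= 1,
            sigma0 > 0, sigma_e > 0)
  structure(
    list(n_trial = as.integer(n_trial), n_external = as.integer(n_external),
         n_covariates = as.integer(n_covariates), beta0 = beta0, beta = beta,
         eta = eta, psi = psi, mu0 = mu0, sigma0 = sigma0, mu_e = mu_e,
         sigma_e = sigma_e, drift_target = drift_target,
         scenario_id = scenario_id, seed = seed),
    class = "scenario_config"
  )
}

#' Simulate one two-source cohort
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A subject table with covariate columns `x1..xK`.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_covariates
  n0 <- config$n_trial
  ne <- config$n_external
  x0 <- matrix(stats::rnorm(n0 * k, config$mu0, config$sigma0), n0, k)
  if (ne > 0L) {
    from_trial <- stats::runif(ne) < config$psi
    xe <- matrix(0, ne, k)
    n_t <- sum(from_trial)
    if (n_t > 0L) {
      xe[from_trial, ] <- stats::rnorm(n_t * k, config$mu0, config$sigma0)
    }
    if (n_t < ne) {
      xe[!from_trial, ] <- stats::rnorm((ne - n_t) * k, config$mu_e,
                                        config$sigma_e)
    }
    x <- rbind(x0, xe)
  } else {
    x <- x0
  }
  z <- c(rep(1L, n0), rep(0L, ne))
  drifted <- if (config$drift_target == "internal") z == 1L else z == 0L
  lp <- config$beta0 + drop(x %*% config$beta) + config$eta * drifted
  y <- stats::rbinom(n0 + ne, 1L, stats::plogis(lp))
  colnames(x) <- paste0("x", seq_len(k))
  as_subject_table(
    tibble::tibble(z = z, y = y, !!!as.data.frame(x)),
    covariates = colnames(x)
  )
}

#' Population mean of the trial response rate under a scenario
#'
#' Obtained as the average empirical trial-arm response rate over a large
#' number of freshly simulated datasets, on a dedicated RNG stream.
#'
#' @param config A [scenario_config()].
#' @param n_datasets Number of auxiliary datasets (default 1000).
#' @param seed Integer seed for the dedicated stream.
#' @return Scalar population response rate.
#' @export
population_truth <- function(config, n_datasets = 1000L, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"), n_datasets >= 1L)
  if (!is.null(seed)) set.seed(seed)
  rates <- vapply(seq_len(n_datasets), function(i) {
    d <- generate_dataset(config, seed = NULL)
    mean(d$y[d$z == 1L])
  }, numeric(1))
  mean(rates)
}

#' Scenario sweep grids
#'
#' Builds the list of configurations for the four study scenarios, each
#' swept over 11 equally spaced grid points:
#' \describe{
#'   \item{drift}{null covariate effects (`beta = 0`), common `N(0,1)`
#'     covariates, drift `eta` swept over \[-0.5, 0.5\].}
#'   \item{mixture}{no drift, `psi = 0.5`, `beta_j = 0.1`, shifted-component
#'     mean `mu_e` swept over \[-0.5, 0.5\].}
#'   \item{no_mixture}{as mixture but `psi = 0` (every external patient from
#'     the shifted component).}
#'   \item{superfluous}{the mixture grid with the first `n_zero` coefficients
#'     forced to zero while the coefficient total is held constant.}
#' }
#' Settings modify the base case `N0 = Ne = 400`, `K = 5`: setting 2 enlarges
#' the external data (`Ne = 2000`), setting 3 shrinks it (`Ne = 200`),
#' setting 4 doubles the covariate count (`K = 10`), and `"small"` uses
#' `N0 = Ne = 100`.
#'
#' @param name One of `"drift"`, `"mixture"`, `"no_mixture"`,
#'   `"superfluous"`.
#' @param setting One of `1:4` or `"small"`.
#' @param n_zero For `"superfluous"`: how many leading coefficients are
#'   zeroed (1-4).
#' @param n_points Grid resolution of the sweep (default 11).
#' @return A tibble with columns `scenario`, `setting`, `sweep` (the swept
#'   parameter value) and a list-column `config`.
#' @export
scenario_grid <- function(name = c("drift", "mixture", "no_mixture",
                                   "superfluous"),
                          setting = 1, n_zero = 1L, n_points = 11L) {
  name <- match.arg(name)
  if (!(as.character(setting) %in% c("1", "2", "3", "4", "small"))) {
    stop("unknown setting: ", setting, call. = FALSE)
  }
  n_trial <- 400L
  n_external <- 400L
  k <- 5L
  if (identical(as.character(setting), "2")) n_external <- 2000L
  if (identical(as.character(setting), "3")) n_external <- 200L
  if (identical(as.character(setting), "4")) k <- 10L
  if (identical(as.character(setting), "small")) {
    n_trial <- 100L
    n_external <- 100L
  }
  sweep <- seq(-0.5, 0.5, length.out = n_points)
  base_beta <- rep(0.1, k)
  configs <- switch(
    name,
    drift = purrr::map(sweep, function(eta)
      scenario_config(n_trial, n_external, k, beta0 = 0, beta = 0, eta = eta,
                      psi = 1, scenario_id = "drift")),
    mixture = purrr::map(sweep, function(mu_e)
      scenario_config(n_trial, n_external, k, beta0 = 0, beta = base_beta,
                      eta = 0, psi = 0.5, mu_e = mu_e,
                      scenario_id = "mixture")),
    no_mixture = purrr::map(sweep, function(mu_e)
      scenario_config(n_trial, n_external, k, beta0 = 0, beta = base_beta,
                      eta = 0, psi = 0, mu_e = mu_e,
                      scenario_id = "no_mixture")),
    superfluous = {
      stopifnot(n_zero >= 1L, n_zero <= k - 1L)
      beta <- rep(0, k)
      # zeroed leading coefficients; remainder rescaled to keep sum(beta)
      beta[(n_zero + 1L):k] <- sum(base_beta) / (k - n_zero)
      purrr::map(sweep, function(mu_e)
        scenario_config(n_trial, n_external, k, beta0 = 0, beta = beta,
                        eta = 0, psi = 0.5, mu_e = mu_e,
                        scenario_id = sprintf("superfluous_%d", n_zero)))
    }
  )
  tibble::tibble(
    scenario = name,
    setting = as.character(setting),
    sweep = sweep,
    config = configs
  )
}

builtin_method <- function(name, n_proposals, min_draws) {
  switch(
    name,
    ignore = function(d) fixed_delta_posterior(d, delta = 0, n_draws = 2L),
    pooling = function(d) fixed_delta_posterior(d, delta = 1, n_draws = 2L),
    mpp = function(d) mpp_posterior(d, n_proposals = n_proposals,
                                    min_draws = min_draws),
    propp = function(d) propp_posterior(d, n_proposals = n_proposals,
                                        min_draws = min_draws),
    stop("unknown method: ", name, call. = FALSE)
  )
}

#' Run a simulation grid
#'
#' For every grid point and method, simulates `n_replicates` cohorts,
#' computes the per-replicate posterior mean and equal-tailed 95% interval of
#' the trial response rate, and aggregates RMSE (against the population
#' truth) and type-I error (against the drift-free null truth).  Replicate
#' seeds derive deterministically from `seed`, so an identical call is
#' byte-reproducible.  A method erroring on a replicate is counted; its cell
#' is suppressed (metrics set to `NA`) when the error rate exceeds 5%.
#'
#' @param grid A [scenario_grid()] tibble (or any tibble with `sweep` and a
#'   `config` list-column).
#' @param methods Character vector from `"ignore"`, `"pooling"`, `"mpp"`,
#'   `"propp"`, and/or a named list of functions `f(subject_table)`
#'   returning a `propp_posterior`-like object (registered comparators).
#' @param n_replicates Replicates per grid point.
#' @param seed Master seed.
#' @param n_truth Auxiliary datasets for the population truth.
#' @param n_proposals,min_draws Sampler size for the power-prior methods.
#' @return A `simulation_result` tibble: one row per grid point and method
#'   with `rmse`, `rmse_mc_se`, `type_one_error`, `mean_delta`,
#'   `truth`, `truth_null`, `n_ok`, `n_error`, `suppressed`.
#' @export
run_scenario <- function(grid, methods = c("ignore", "pooling", "mpp", "propp"),
                         n_replicates = 1000L, seed = 1L, n_truth = 1000L,
                         n_proposals = 10000L, min_draws = 1000L) {
  if (is.character(methods)) {
    methods <- stats::setNames(
      purrr::map(methods, builtin_method, n_proposals = n_proposals,
                 min_draws = min_draws),
      methods)
  }
  stopifnot(is.list(methods), !is.null(names(methods)))
  set.seed(seed)
  seed_pool <- sample.int(.Machine$integer.max,
                          nrow(grid) * (n_replicates + 2L))
  seed_mat <- matrix(seed_pool, nrow = nrow(grid))
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    config <- grid$config[[g]]
    truth <- population_truth(config, n_datasets = n_truth,
                              seed = seed_mat[g, 1L])
    null_config <- config
    null_config$eta <- 0
    truth_null <- if (config$eta == 0) truth else {
      population_truth(null_config, n_datasets = n_truth,
                       seed = seed_mat[g, 2L])
    }
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      rep_seed <- seed_mat[g, r + 2L]
      set.seed(rep_seed)
      d <- generate_dataset(config, seed = NULL)
      purrr::imap_dfr(methods, function(f, m) {
        res <- tryCatch(suppressWarnings(f(d)), error = function(e) NULL)
        if (is.null(res)) {
          return(tibble::tibble(method = m, ok = FALSE, mean = NA_real_,
                                lower = NA_real_, upper = NA_real_,
                                mean_delta = NA_real_))
        }
        s <- res$summaries
        th <- s[s$parameter == "theta", ]
        de <- s[s$parameter == "delta", ]
        tibble::tibble(method = m, ok = TRUE, mean = th$mean,
                       lower = th$lower, upper = th$upper,
                       mean_delta = de$mean)
      })
    })
    reps <- dplyr::bind_rows(reps)
    reps |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        n_ok = sum(.data$ok),
        n_error = sum(!.data$ok),
        rmse = if (sum(.data$ok) > 0)
          rmse(.data$mean[.data$ok], truth) else NA_real_,
        rmse_mc_se = if (sum(.data$ok) > 0)
          rmse_mc_se(.data$mean[.data$ok], truth) else NA_real_,
        type_one_error = if (sum(.data$ok) > 0)
          type_one_error(.data$lower[.data$ok], truth_null,
                         .data$upper[.data$ok]) else NA_real_,
        mean_delta = mean(.data$mean_delta[.data$ok]),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        scenario = if ("scenario" %in% names(grid)) grid$scenario[[g]] else
          config$scenario_id,
        setting = if ("setting" %in% names(grid)) grid$setting[[g]] else NA,
        sweep = grid$sweep[[g]],
        truth = truth,
        truth_null = truth_null,
        n_replicates = n_replicates,
        suppressed = .data$n_error / n_replicates > 0.05
      ) |>
      dplyr::mutate(
        rmse = ifelse(.data$suppressed, NA_real_, .data$rmse),
        type_one_error = ifelse(.data$suppressed, NA_real_,
                                .data$type_one_error)
      ) |>
      dplyr::relocate("scenario", "setting", "sweep", "method")
  })
  class(out) <- c("simulation_result", class(out))
  out
}
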