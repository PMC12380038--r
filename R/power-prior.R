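#' Prior specification for the power parameter
#'
#' The response rate theta always carries a uniform U(0,1) prior, which makes
#' every posterior a Beta distribution conditional on the power parameter
#' delta.  delta carries a Beta(alpha, beta) prior, uniform by default.
#'
#' @param alpha,beta Positive shape parameters of the Beta prior on delta.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(alpha = 1, beta = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta), class = "prior_spec")
}

#' Weighted sufficient statistics for the Bernoulli likelihood
#'
#' Every posterior in the package is driven by four weighted sums: weighted
#' responders and non-responders in each source.  Under the default scheme
#' trial weights are 1, so `a0 + b0 = N0`.
#'
#' @param data A subject table.
#' @param weights Per-subject weights aligned with `data` rows (or the tibble
#'   from [compute_weights()]).  Default: all 1.
#' @return A `weighted_counts` list with `a_e`, `b_e` (external weighted
#'   responders / non-responders), `a0`, `b0` (trial), `sum_w_ext`
#'   (total external weight) and `n_zero_ext` (external subjects with
#'   weight < 1e-6).
#' @export
weighted_counts <- function(data, weights = NULL) {
  data <- as_subject_table(data)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (is.data.frame(weights)) weights <- weights$weight
  stopifnot(length(weights) == nrow(data))
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  z <- data$z
  y <- data$y
  w <- weights
  structure(
    list(
      a_e = sum(w[z == 0L] * y[z == 0L]),
      b_e = sum(w[z == 0L] * (1 - y[z == 0L])),
      a0 = sum(w[z == 1L] * y[z == 1L]),
      b0 = sum(w[z == 1L] * (1 - y[z == 1L])),
      sum_w_ext = sum(w[z == 0L]),
      n_zero_ext = sum(z == 0L & w < 1e-6)
    ),
    class = "weighted_counts"
  )
}

#' Build weighted counts from summary-level counts
#'
#' Convenience constructor when only aggregate responders/totals are known
#' (e.g., published trial tables).
#'
#' @param trial_responders,trial_n Trial responders and size.
#' @param external_responders,external_n External responders and size
#'   (weighted sums are allowed, hence non-integers).
#' @return A `weighted_counts` object.
#' @export
counts_from_totals <- function(trial_responders, trial_n,
                               external_responders = 0, external_n = 0) {
  stopifnot(trial_responders >= 0, trial_n >= trial_responders,
            external_responders >= 0, external_n >= external_responders)
  structure(
    list(
      a_e = external_responders,
      b_e = external_n - external_responders,
      a0 = trial_responders,
      b0 = trial_n - trial_responders,
      sum_w_ext = external_n,
      n_zero_ext = NA_integer_
    ),
    class = "weighted_counts"
  )
}

#' Log scaling constant of the weighted power prior
#'
#' `C(delta)` normalises the delta-discounted external likelihood so that the
#' joint posterior obeys the likelihood principle.  With a uniform prior on
#' theta it is the Beta function `B(delta*a_e + 1, delta*b_e + 1)`, evaluated
#' in log space (the arguments routinely reach hundreds).
#'
#' @param delta Power parameter value(s) in \[0, 1\] (vectorised).
#' @param counts A [weighted_counts()] object.
#' @return `log C(delta)`, same length as `delta`.
#' @export
log_scaling_constant <- function(delta, counts) {
  stopifnot(inherits(counts, "weighted_counts"))
  if (any(delta < 0 | delta > 1)) stop("delta must lie in [0, 1]", call. = FALSE)
  lbeta(delta * counts$a_e + 1, delta * counts$b_e + 1)
}

#' Unnormalised log marginal posterior of the power parameter
#'
#' With theta integrated out under its uniform prior, the marginal density of
#' delta is a ratio of Beta functions times the Beta prior density of delta:
#' `B(d*a_e + a0 + 1, d*b_e + b0 + 1) / B(d*a_e + 1, d*b_e + 1) *
#'  dbeta(d; alpha, beta)`.
#' Under the default uniform prior the density factor vanishes and the
#' expression is the pure Beta-function ratio.
#'
#' @inheritParams log_scaling_constant
#' @param prior A [prior_spec()].
#' @return Unnormalised log density, same length as `delta`.
#' @export
log_marginal_delta <- function(delta, counts, prior = prior_spec()) {
  stopifnot(inherits(counts, "weighted_counts"), inherits(prior, "prior_spec"))
  if (any(delta < 0 | delta > 1)) stop("delta must lie in [0, 1]", call. = FALSE)
  lbeta(delta * counts$a_e + counts$a0 + 1,
        delta * counts$b_e + counts$b0 + 1) -
    log_scaling_constant(delta, counts) +
    stats::dbeta(delta, prior$alpha, prior$beta, log = TRUE)
}

# Supremum of the unnormalised log marginal of delta on [0,1]:
# dense grid then golden-section refinement around the grid argmax.
log_envelope_delta <- function(counts, prior, n_grid = 2048L) {
  grid <- seq(0, 1, length.out = n_grid)
  lp <- log_marginal_delta(grid, counts, prior) -
    stats::dbeta(grid, prior$alpha, prior$beta, log = TRUE)
  # the envelope bounds target/proposal where the proposal is the delta prior,
  # so the prior density cancels and only the Beta-function ratio remains
  i <- which.max(lp)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  ratio <- function(d)
    lbeta(d * counts$a_e + counts$a0 + 1, d * counts$b_e + counts$b0 + 1) -
    lbeta(d * counts$a_e + 1, d * counts$b_e + 1)
  opt <- stats::optimize(ratio, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-10)
  m <- max(lp[i], opt$objective)
  if (!is.finite(m)) stop("degenerate posterior for delta", call. = FALSE)
  m
}

#' Rejection sampler for the power parameter
#'
#' Proposes delta from its Beta prior (uniform by default) and accepts with
#' probability equal to the Beta-function ratio of [log_marginal_delta()]
#' scaled by its supremum, located on a 2048-point grid with golden-section
#' refinement.  Accepted draws are iid from the marginal posterior of delta.
#' When the weighted external data are empty (`a_e + b_e = 0`) the posterior
#' is the prior and is drawn directly without a rejection loop.
#'
#' @inheritParams log_marginal_delta
#' @param n_proposals Proposals per batch (the accepted subset is returned).
#' @param min_draws Keep proposing batches until at least this many draws
#'   have been accepted.
#' @param seed Optional integer seed.
#' @return A list with `draws`, `acceptance_rate`, `n_proposed`.
#' @export
sample_delta <- function(counts, prior = prior_spec(), n_proposals = 10000L,
                         min_draws = 1000L, seed = NULL) {
  stopifnot(inherits(counts, "weighted_counts"), n_proposals >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (counts$a_e + counts$b_e == 0) {
    draws <- stats::rbeta(n_proposals, prior$alpha, prior$beta)
    return(list(draws = draws, acceptance_rate = 1, n_proposed = n_proposals))
  }
  log_m <- log_envelope_delta(counts, prior)
  draws <- numeric(0)
  proposed <- 0L
  repeat {
    d <- stats::rbeta(n_proposals, prior$alpha, prior$beta)
    log_acc <- lbeta(d * counts$a_e + counts$a0 + 1,
                     d * counts$b_e + counts$b0 + 1) -
      lbeta(d * counts$a_e + 1, d * counts$b_e + 1) - log_m
    keep <- log(stats::runif(n_proposals)) < log_acc
    draws <- c(draws, d[keep])
    proposed <- proposed + n_proposals
    if (length(draws) >= max(1L, min_draws)) break
    if (proposed > 1e7) {
      stop("rejection sampler made 1e7 proposals without reaching min_draws",
           call. = FALSE)
    }
  }
  list(draws = draws, acceptance_rate = length(draws) / proposed,
       n_proposed = proposed)
}

#' Conditional draws of the response rate given the power parameter
#'
#' Conditional on delta the posterior of theta is conjugate:
#' `Beta(delta*a_e + a0 + 1, delta*b_e + b0 + 1)`.  One theta is drawn per
#' delta, giving paired draws from the joint posterior.
#'
#' @param delta_draws Draws of delta in \[0, 1\].
#' @inheritParams log_marginal_delta
#' @param seed Optional integer seed.
#' @return Numeric vector of theta draws, same length as `delta_draws`.
#' @export
sample_theta_given_delta <- function(delta_draws, counts, seed = NULL) {
  stopifnot(inherits(counts, "weighted_counts"))
  if (any(delta_draws < 0 | delta_draws > 1)) {
    stop("delta draws must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rbeta(length(delta_draws),
               delta_draws * counts$a_e + counts$a0 + 1,
               delta_draws * counts$b_e + counts$b0 + 1)
}

new_posterior_result <- function(theta_draws, delta_draws, counts,
                                 method, seed = NULL, acceptance_rate = NA_real_,
                                 exact = NULL) {
  summaries <- dplyr::bind_rows(
    dplyr::mutate(summarize_posterior(theta_draws), parameter = "theta"),
    dplyr::mutate(summarize_posterior(delta_draws), parameter = "delta")
  )
  if (!is.null(exact)) {
    # overwrite the theta row with exact Beta moments/quantiles when delta is fixed
    summaries[summaries$parameter == "theta",
              c("mean", "median", "lower", "upper")] <-
      tibble::tibble(mean = exact$mean, median = exact$median,
                     lower = exact$lower, upper = exact$upper)
  }
  summaries <- dplyr::relocate(summaries, "parameter")
  structure(
    list(
      theta_draws = theta_draws,
      delta_draws = delta_draws,
      summaries = summaries,
      counts = counts,
      effective_external_weight = mean(delta_draws) * counts$sum_w_ext,
      n_draws = length(theta_draws),
      acceptance_rate = acceptance_rate,
      seed = seed,
      method = method
    ),
    class = "propp_posterior"
  )
}

#' ProPP posterior for a two-source subject table
#'
#' Runs the full pipeline: fit the trial-membership propensity model, turn
#' fitted probabilities into borrowing weights under the chosen scheme, form
#' the weighted sufficient statistics, draw the power parameter delta by
#' rejection sampling and the response rate theta from its conditional Beta
#' posterior.  With `weights` supplied the propensity stage is skipped
#' (forcing all weights to 1 gives the plain modified power prior).
#'
#' @param data A subject table with both sources.
#' @param scheme A [weight_scheme()] or name; default capped trial-estimand
#'   odds weights.
#' @param prior A [prior_spec()] for delta.
#' @param n_proposals,min_draws Passed to [sample_delta()].
#' @param seed Integer seed making the whole run reproducible.
#' @param weights Optional per-subject weights overriding the propensity
#'   stage.
#' @return A `propp_posterior` object: paired `theta_draws`/`delta_draws`,
#'   a `summaries` tibble (posterior mean, median, equal-tailed 95%
#'   interval per parameter), the `weighted_counts`, the effective external
#'   weight `mean(delta) * sum(external w)`, and sampler diagnostics.
#'   When the propensity stage ran, the fit and weight table are attached
#'   as attributes `"propensity_fit"` and `"weights"`.
#' @export
propp_posterior <- function(data, scheme = weight_scheme("att_trial"),
                            prior = prior_spec(), n_proposals = 10000L,
                            min_draws = 1000L, seed = NULL, weights = NULL) {
  data <- as_subject_table(data, require_external = TRUE)
  fit <- NULL
  wtab <- NULL
  if (is.null(weights)) {
    fit <- fit_propensity(data)
    wtab <- compute_weights(fit, data, scheme)
    w <- wtab$weight
  } else {
    if (length(weights) == 1L) weights <- rep(weights, nrow(data))
    w <- weights
  }
  counts <- weighted_counts(data, w)
  if (!is.null(seed)) set.seed(seed)
  ds <- sample_delta(counts, prior, n_proposals = n_proposals,
                     min_draws = min_draws)
  theta <- sample_theta_given_delta(ds$draws, counts)
  out <- new_posterior_result(theta, ds$draws, counts,
                              method = if (is.null(fit)) "mpp" else "propp",
                              seed = seed, acceptance_rate = ds$acceptance_rate)
  attr(out, "propensity_fit") <- fit
  attr(out, "weights") <- wtab
  out
}

#' Modified power prior posterior (no propensity weighting)
#'
#' The unweighted comparator: all subjects keep weight 1 and only the power
#' parameter discounts the external likelihood.
#'
#' @inheritParams propp_posterior
#' @return A `propp_posterior` object.
#' @export
mpp_posterior <- function(data, prior = prior_spec(), n_proposals = 10000L,
                          min_draws = 1000L, seed = NULL) {
  propp_posterior(data, prior = prior, n_proposals = n_proposals,
                  min_draws = min_draws, seed = seed, weights = 1)
}

#' Posterior with the power parameter held fixed
#'
#' The two naive comparators are special cases: `delta = 0` ignores the
#' external data (trial-only conjugate posterior) and `delta = 1` with unit
#' weights pools the sources.  The theta posterior is the exact
#' `Beta(delta*a_e + a0 + 1, delta*b_e + b0 + 1)`; summaries use exact Beta
#' moments and quantiles, with draws attached for plotting.
#'
#' @param data A subject table, or a [weighted_counts()] /
#'   [counts_from_totals()] object.
#' @param delta Fixed power parameter in \[0, 1\].
#' @param use_weights If `TRUE` and `data` is a subject table, apply the
#'   default capped odds weights; otherwise all weights are 1.
#' @param n_draws Number of draws to attach.
#' @param seed Optional integer seed.
#' @return A `propp_posterior` object with exact summaries.
#' @export
fixed_delta_posterior <- function(data, delta, use_weights = FALSE,
                                  n_draws = 10000L, seed = NULL) {
  stopifnot(length(delta) == 1L, delta >= 0, delta <= 1)
  if (inherits(data, "weighted_counts")) {
    counts <- data
  } else {
    data <- as_subject_table(data)
    w <- if (isTRUE(use_weights)) {
      compute_weights(fit_propensity(data), data)$weight
    } else {
      rep(1, nrow(data))
    }
    counts <- weighted_counts(data, w)
  }
  shape1 <- delta * counts$a_e + counts$a0 + 1
  shape2 <- delta * counts$b_e + counts$b0 + 1
  if (!is.null(seed)) set.seed(seed)
  theta <- stats::rbeta(n_draws, shape1, shape2)
  exact <- list(
    mean = shape1 / (shape1 + shape2),
    median = stats::qbeta(0.5, shape1, shape2),
    lower = stats::qbeta(0.025, shape1, shape2),
    upper = stats::qbeta(0.975, shape1, shape2)
  )
  method <- if (delta == 0) "ignore" else if (delta == 1) "pooling" else "fixed_delta"
  out <- new_posterior_result(theta, rep(delta, n_draws), counts,
                              method = method, seed = seed, exact = exact)
  out$shape <- c(shape1 = shape1, shape2 = shape2)
  out
}

#' Effective weight of the external data
#'
#' The package's stand-in for a prior effective sample size: the posterior
#' mean of delta times the summed external borrowing weights, i.e. the
#' expected number of fully counted external patients.
#'
#' @param weights External weights (or a [compute_weights()] tibble, from
#'   which external rows are taken, or a `weighted_counts` object).
#' @param delta_draws Posterior draws of delta.
#' @return A scalar in \[0, sum of external weights\].
#' @export
effective_external_weight <- function(weights, delta_draws) {
  total <- if (inherits(weights, "weighted_counts")) {
    weights$sum_w_ext
  } else if (is.data.frame(weights)) {
    sum(weights$weight[weights$z == 0L])
  } else {
    sum(weights)
  }
  mean(delta_draws) * total
}

#' @export
print.propp_posterior <- function(x, ...) {
  cat(sprintf("Posterior (%s), %d draws\n", x$method, x$n_draws))
  print(as.data.frame(x$summaries), row.names = FALSE, digits = 4)
  cat(sprintf("effective external weight: %.2f (of %.2f)\n",
              x$effective_external_weight, x$counts$sum_w_ext))
  if (is.finite(x$acceptance_rate)) {
    cat(sprintf("delta rejection-sampler acceptance rate: %.3f\n",
                x$acceptance_rate))
  }
  invisible(x)
}

#' Posterior summaries, one row per parameter
#' @param x A `propp_posterior`.
#' @param ... Unused.
#' @return The summaries tibble.
#' @export
#' @method tidy propp_posterior
tidy.propp_posterior <- function(x, ...) x$summaries

#' One-row summary of a posterior result
#' @inheritParams tidy.propp_posterior
#' @return A one-row tibble.
#' @export
#' @method glance propp_posterior
glance.propp_posterior <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_draws = x$n_draws,
    acceptance_rate = x$acceptance_rate,
    effective_external_weight = x$effective_external_weight,
    sum_w_ext = x$counts$sum_w_ext,
    n_zero_weight_ext = x$counts$n_zero_ext
  )
}
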