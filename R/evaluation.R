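#' Root mean squared error of replicate estimates
#'
#' `sqrt(mean((estimate - truth)^2))` of per-replicate posterior means
#' against the population truth.
#'
#' @param estimates Numeric vector of per-replicate estimates.
#' @param truth Scalar population value.
#' @return A scalar RMSE.
#' @export
rmse <- function(estimates, truth) {
  stopifnot(length(truth) == 1L, is.numeric(truth))
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  sqrt(mean((estimates - truth)^2))
}

# Monte-Carlo standard error of the RMSE (delta method on the mean squared
# error), used to report simulation uncertainty alongside each metric.
rmse_mc_se <- function(estimates, truth) {
  sq <- (estimates - truth)^2
  m <- mean(sq)
  if (m == 0) return(0)
  stats::sd(sq) / sqrt(length(sq)) / (2 * sqrt(m))
}

#' Type I error rate over replicate credible intervals
#'
#' The fraction of replicates whose equal-tailed 95% credible interval
#' excludes the truth.  An interval contains the truth when
#' `lower <= truth <= upper` (closed ends).
#'
#' @param summaries A data frame with columns `lower` and `upper`, one row
#'   per replicate (or two equal-length numeric vectors via `upper`).
#' @param truth Scalar null value of the trial response rate.
#' @param upper Optional: when `summaries` is a numeric vector of lower
#'   bounds, the matching upper bounds.
#' @return The exclusion rate in \[0, 1\].
#' @export
type_one_error <- function(summaries, truth, upper = NULL) {
  if (is.data.frame(summaries)) {
    lo <- summaries$lower
    hi <- summaries$upper
  } else {
    lo <- summaries
    hi <- upper
  }
  stopifnot(length(lo) == length(hi), length(truth) == 1L)
  if (any(lo > hi)) stop("interval with lower > upper", call. = FALSE)
  mean(!(lo <= truth & truth <= hi))
}

#' Summarise a posterior sample
#'
#' Empirical mean, median and equal-tailed 95% interval (2.5%/97.5%
#' linear-interpolation quantiles).
#'
#' @param draws Numeric vector of at least two posterior draws.
#' @return A one-row tibble: `mean`, `median`, `lower`, `upper`, `n_draws`.
#' @export
summarize_posterior <- function(draws) {
  if (length(draws) < 2L) {
    stop("need at least 2 draws to summarise a posterior", call. = FALSE)
  }
  q <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  tibble::tibble(
    mean = mean(draws),
    median = q[2],
    lower = q[1],
    upper = q[3],
    n_draws = length(draws)
  )
}
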