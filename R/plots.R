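#' Plot the propensity-score distribution by source
#'
#' Histogram of fitted trial-membership probabilities, split by data source.
#' The spike at zero identifies external patients whose covariate profiles
#' never occur in the trial; under the capped odds scheme they are excluded
#' from borrowing.
#'
#' @param fit A `propensity_fit`.
#' @param data The subject table the fit was produced from.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_propensity <- function(fit, data, bins = 30) {
  stopifnot(inherits(fit, "propensity_fit"))
  df <- tibble::tibble(
    lambda = fit$lambda,
    source = factor(ifelse(data$z == 1L, "trial", "external"),
                    levels = c("external", "trial"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, fill = .data$source)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::labs(x = "fitted membership probability λ",
                  y = "patients", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Density plot of the posterior draws
#' @param object A `propp_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot propp_posterior
autoplot.propp_posterior <- function(object, ...) {
  df <- tibble::tibble(parameter = "theta (response rate)",
                       value = object$theta_draws)
  if (stats::sd(object$delta_draws) > 0) {
    # skip the delta facet when delta was held fixed
    df <- dplyr::bind_rows(
      df,
      tibble::tibble(parameter = "delta (power parameter)",
                     value = object$delta_draws))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey70") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Operating-characteristic curves of a simulation run
#'
#' RMSE and type-I error against the swept parameter, one line per method.
#' @param object A `simulation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot simulation_result
autoplot.simulation_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "sweep", "method", "rmse", "type_one_error"),
    c("rmse", "type_one_error"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$value,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "swept parameter", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot covariate balance before and after weighting
#'
#' @param balance A [balance_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_balance <- function(balance) {
  df <- tidyr::pivot_longer(balance, c("smd_raw", "smd_weighted"),
                            names_to = "stage", values_to = "smd")
  df$stage <- ifelse(df$stage == "smd_raw", "raw", "weighted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                   colour = .data$stage)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standardised mean difference (external - trial)",
                  y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
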