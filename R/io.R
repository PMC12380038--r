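#' Write an analysis result to disk
#'
#' Posterior and bootstrap results are serialised to JSON (summaries plus
#' run metadata: package version, seed, number of draws); simulation results
#' to tidy CSV with one row per grid point and method.  Existing files are
#' never overwritten without `force = TRUE`.
#'
#' @param result A `propp_posterior`, `simulation_result`,
#'   `propp_case_report` or `propp_bootstrap` object.
#' @param path Output path (`.json` or `.csv` as appropriate).
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, force = FALSE) {
  refuse_overwrite(path, force)
  meta <- list(package = "propp",
               version = as.character(utils::packageVersion("propp")))
  if (inherits(result, "simulation_result")) {
    utils::write.csv(as.data.frame(dplyr::select(result, -dplyr::any_of("config"))),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(result, "propp_posterior")) {
    list(
      meta = c(meta, list(seed = result$seed, method = result$method,
                          n_draws = result$n_draws)),
      summaries = result$summaries,
      effective_external_weight = result$effective_external_weight,
      acceptance_rate = result$acceptance_rate,
      counts = unclass(result$counts)
    )
  } else if (inherits(result, "propp_case_report")) {
    list(
      meta = c(meta, list(seed = result$seed)),
      posteriors = result$posteriors,
      lambda_by_source = result$lambda_by_source,
      n_zero_weight = result$n_zero_weight,
      effective_external_weight = result$effective_external_weight,
      balance = result$balance
    )
  } else if (inherits(result, "propp_bootstrap")) {
    list(
      meta = c(meta, list(seed = result$seed, n_boot = result$n_boot,
                          resample = result$resample)),
      summary = result$summary,
      results = result$results
    )
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read back a JSON results file
#' @param path Path written by [write_results()].
#' @return A list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
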