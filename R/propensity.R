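#' Fit the trial-membership propensity model
#'
#' Estimates lambda_i = Pr(z = 1 | x), the probability that patient i belongs
#' to the internal trial rather than the external source, by unpenalised
#' maximum-likelihood logistic regression of `z` on the covariates (with
#' intercept).  Categorical covariates are one-hot encoded against a
#' reference level by the model-matrix machinery; the fitted terms object is
#' stored so that bootstrap refits can score new coefficient vectors on the
#' original encoding.
#'
#' Two maximum-likelihood balance identities hold for any converged
#' intercept-containing fit and are relied upon downstream:
#' `sum(lambda) = N0` (the number of trial patients) and
#' `mean(lambda) = N0/N`.
#'
#' Quasi-complete separation (a covariate level present in only one source)
#' is not an error: the affected subjects get fitted probabilities that are
#' numerically 0 or 1, are flagged in `separation_flags`, and a warning is
#' raised.  Under the default capped-odds weighting scheme those external
#' subjects simply receive weight 0, which is the intended behaviour.
#'
#' @param data A subject table (see [as_subject_table()]).
#' @param covariates Optional subset of covariate columns to use.
#' @param epsilon Convergence tolerance on the relative deviance change.
#' @param maxit Iteration cap for the iteratively reweighted least squares.
#'
#' @return An object of class `propensity_fit`: a list with elements
#'   `coefficients`, `lambda` (per-subject fitted probability, in row
#'   order), `converged`, `separation_flags`, `deviance`, `n_trial`, `n`,
#'   and the fitted `glm` object (`model`) for scoring new data.
#' @export
fit_propensity <- function(data, covariates = NULL,
                           epsilon = 1e-8, maxit = 100L) {
  data <- as_subject_table(data, covariates = covariates)
  if (sum(data$z == 0L) < 1L || sum(data$z == 1L) < 1L) {
    stop("no contrast in membership: all subjects come from one source",
         call. = FALSE)
  }
  cov <- subject_covariates(data)
  if (length(cov) == 0L) {
    stop("at least one covariate is required to fit a propensity model",
         call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", cov), response = "z")
  separation_seen <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation_seen <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop(sprintf(
      "propensity model did not converge in %d iterations (last deviance %.6g)",
      maxit, fit$deviance), call. = FALSE)
  }
  lambda <- as.numeric(stats::fitted(fit))
  eps_sep <- 1e-6
  flags <- lambda < eps_sep | lambda > 1 - eps_sep
  if (separation_seen || any(flags)) {
    warning(sprintf(
      "quasi-separation: %d subject(s) have fitted membership probability numerically 0 or 1; their borrowing weights will be 0 (or capped)",
      sum(flags)), call. = FALSE)
  }
  structure(
    list(
      coefficients = stats::coef(fit),
      lambda = lambda,
      converged = fit$converged,
      separation_flags = flags,
      deviance = fit$deviance,
      n_trial = sum(data$z == 1L),
      n = nrow(data),
      covariates = cov,
      model = fit
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("Trial-membership propensity fit\n")
  cat(sprintf("  subjects: %d (trial %d, external %d)\n",
              x$n, x$n_trial, x$n - x$n_trial))
  cat(sprintf("  sum(lambda) = %.4f (= N0 at the MLE)\n", sum(x$lambda)))
  cat(sprintf("  separated subjects: %d\n", sum(x$separation_flags)))
  invisible(x)
}

#' Score a propensity fit on (possibly new) subjects
#'
#' Applies the stored coefficients and encoding to a subject table, returning
#' lambda for every row.  Used by the bootstrap, which refits the model on a
#' resample and scores the original cohort.
#'
#' @param fit A `propensity_fit`.
#' @param data A subject table with the covariate columns the fit used.
#' @return Numeric vector of membership probabilities.
#' @export
predict_lambda <- function(fit, data) {
  stopifnot(inherits(fit, "propensity_fit"))
  as.numeric(stats::predict(fit$model, newdata = data, type = "response"))
}

#' Propensity-score weighting schemes
#'
#' The three schemes target different populations of interest:
#' \describe{
#'   \item{`att_trial`}{average treatment effect of the trial population
#'     (the default estimand): trial weight 1, external weight the
#'     membership odds `lambda/(1-lambda)`, capped at 1 so that no external
#'     patient counts more than a trial patient.}
#'   \item{`ate`}{average treatment effect: inverse-probability weights
#'     `1/lambda` (trial) and `1/(1-lambda)` (external).}
#'   \item{`att_external`}{average treatment effect of the external
#'     population: trial weight `(1-lambda)/lambda`, external weight 1.}
#' }
#'
#' @param name One of `"att_trial"`, `"ate"`, `"att_external"`.
#' @param cap_at_one Cap every weight at 1.  Defaults to `TRUE` for
#'   `att_trial` and `FALSE` otherwise.
#' @return A `weight_scheme` list.
#' @export
weight_scheme <- function(name = c("att_trial", "ate", "att_external"),
                          cap_at_one = NULL) {
  name <- match.arg(name)
  if (is.null(cap_at_one)) cap_at_one <- identical(name, "att_trial")
  structure(list(name = name, cap_at_one = isTRUE(cap_at_one)),
            class = "weight_scheme")
}

#' Convert fitted membership probabilities into borrowing weights
#'
#' @param fit A `propensity_fit` (its `lambda` must align with `data` rows).
#' @param data The subject table the fit was produced from.
#' @param scheme A [weight_scheme()] or a scheme name.
#' @return A tibble with `subject_id`, `z`, `lambda`, `weight`.
#' @export
compute_weights <- function(fit, data, scheme = weight_scheme("att_trial")) {
  stopifnot(inherits(fit, "propensity_fit"))
  if (is.character(scheme)) scheme <- weight_scheme(scheme)
  data <- as_subject_table(data)
  lambda <- fit$lambda
  if (length(lambda) != nrow(data)) {
    stop("fit and subject table have different numbers of rows", call. = FALSE)
  }
  z <- data$z
  eps <- 1e-12
  w <- switch(
    scheme$name,
    att_trial = {
      # min{1, odds} is well defined at lambda = 0 and 1; no clamping needed
      odds <- ifelse(lambda >= 1, Inf, lambda / (1 - lambda))
      ifelse(z == 1L, 1, pmin(1, odds))
    },
    ate = {
      if (any(z == 1L & lambda <= 0) || any(z == 0L & lambda >= 1)) {
        stop("non-overlap: infinite weight under the ate scheme", call. = FALSE)
      }
      lam <- pmin(pmax(lambda, eps), 1 - eps)
      ifelse(z == 1L, 1 / lam, 1 / (1 - lam))
    },
    att_external = {
      if (any(z == 1L & lambda <= 0)) {
        stop("non-overlap: infinite weight under the att_external scheme",
             call. = FALSE)
      }
      lam <- pmin(pmax(lambda, eps), 1 - eps)
      ifelse(z == 1L, (1 - lam) / lam, 1)
    }
  )
  if (scheme$cap_at_one) w <- pmin(w, 1)
  tibble::tibble(subject_id = data$subject_id, z = z,
                 lambda = lambda, weight = w)
}

#' Covariate balance before and after weighting
#'
#' Standardised mean differences (external minus trial, divided by the pooled
#' unweighted standard deviation) for every covariate, raw and after applying
#' the external borrowing weights.  Categorical covariates are expanded into
#' level indicators.  When the total external weight is zero the weighted
#' column is reported as `NA` with `weighted_defined = FALSE` rather than
#' producing NaNs.
#'
#' @param data A subject table.
#' @param weights The `weight` column (or tibble from [compute_weights()]).
#' @return A tibble with one row per (expanded) covariate: `covariate`,
#'   `smd_raw`, `smd_weighted`, `weighted_defined`.
#' @export
balance_summary <- function(data, weights) {
  data <- as_subject_table(data)
  if (is.data.frame(weights)) weights <- weights$weight
  stopifnot(length(weights) == nrow(data))
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  cov <- subject_covariates(data)
  xm <- stats::model.matrix(
    stats::reformulate(sprintf("`%s`", cov), intercept = FALSE),
    data = data)
  z <- data$z
  w_ext <- weights[z == 0L]
  ext_defined <- sum(w_ext) > 0
  purrr::map_dfr(colnames(xm), function(col) {
    xt <- xm[z == 1L, col]
    xe <- xm[z == 0L, col]
    sd_pool <- sqrt((stats::var(xt) + stats::var(xe)) / 2)
    smd <- function(me) {
      if (!is.finite(sd_pool) || sd_pool == 0) {
        return(if (isTRUE(all.equal(mean(xt), me))) 0 else NA_real_)
      }
      (me - mean(xt)) / sd_pool
    }
    tibble::tibble(
      covariate = col,
      smd_raw = smd(mean(xe)),
      smd_weighted = if (ext_defined) smd(sum(w_ext * xe) / sum(w_ext)) else NA_real_,
      weighted_defined = ext_defined
    )
  })
}

#' Tidy the propensity coefficients
#' @param x A `propensity_fit`.
#' @param ... Unused.
#' @return A tibble of coefficient estimates.
#' @export
#' @method tidy propensity_fit
tidy.propensity_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' One-row summary of a propensity fit
#' @inheritParams tidy.propensity_fit
#' @return A one-row tibble.
#' @export
#' @method glance propensity_fit
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_trial = x$n_trial,
    n_external = x$n - x$n_trial,
    deviance = x$deviance,
    converged = x$converged,
    n_separated = sum(x$separation_flags),
    sum_lambda = sum(x$lambda)
  )
}
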