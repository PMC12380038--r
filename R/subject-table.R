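#' Validate a subject-level two-source table
#'
#' The universal input of the package is one row per patient with a source
#' indicator `z` (1 = internal trial, 0 = external data), a binary outcome
#' `y`, and any number of covariate columns.  `as_subject_table()` checks the
#' coding, attaches a `subject_id` when absent, and records which columns are
#' covariates.
#'
#' @param data A data frame with columns `z` and `y` (both coded 0/1) and
#'   covariate columns.
#' @param covariates Character vector of covariate column names.  Default
#'   `NULL` takes every column other than `subject_id`, `z` and `y`.
#' @param require_external If `TRUE`, insist on at least one row per source.
#'
#' @return A tibble with class `subject_table`; the covariate names are kept
#'   in the `"covariates"` attribute.
#' @export
as_subject_table <- function(data, covariates = NULL, require_external = FALSE) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L) {
    stop("subject table is empty", call. = FALSE)
  }
  for (col in c("z", "y")) {
    if (!col %in% names(data)) {
      stop("required column `", col, "` is missing", call. = FALSE)
    }
    v <- data[[col]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad) > 0L) {
      stop("column `", col, "` must be coded 0/1; offending row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    data[[col]] <- as.integer(v)
  }
  if (!"subject_id" %in% names(data)) {
    data$subject_id <- seq_len(nrow(data))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("subject_id", "z", "y"))
  } else {
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov) > 0L) {
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
  }
  for (col in covariates) {
    if (anyNA(data[[col]])) {
      stop("missing values in covariate `", col,
           "`; imputation is not supported", call. = FALSE)
    }
  }
  if (anyNA(data$y) || anyNA(data$z)) {
    stop("missing values in `z`/`y`", call. = FALSE)
  }
  if (sum(data$z == 1L) < 1L) {
    stop("no internal-trial rows (z = 1)", call. = FALSE)
  }
  if (require_external && sum(data$z == 0L) < 1L) {
    stop("no external rows (z = 0)", call. = FALSE)
  }
  data <- dplyr::relocate(data, "subject_id", "z", "y")
  attr(data, "covariates") <- covariates
  class(data) <- c("subject_table", class(data))
  data
}

#' Covariate columns of a subject table
#' @param data A `subject_table` (or any data frame; falls back to all
#'   non-reserved columns).
#' @return Character vector of covariate names.
#' @export
subject_covariates <- function(data) {
  cov <- attr(data, "covariates")
  if (is.null(cov)) cov <- setdiff(names(data), c("subject_id", "z", "y"))
  cov
}

#' Read a subject table from delimited text
#'
#' Expects a comma-separated file with a header and at least the columns
#' `z` and `y`, both strictly 0/1.  All other columns are covariates unless
#' `covariates` names a subset.
#'
#' @inheritParams as_subject_table
#' @param path Path to a CSV file.
#' @return A validated [as_subject_table()] tibble.
#' @export
read_subject_table <- function(path, covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty subject file: ", path, call. = FALSE)
  as_subject_table(raw, covariates = covariates)
}

#' Write a subject table to CSV
#' @param data A subject table.
#' @param path Output path.
#' @param force Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(data, path, force = FALSE) {
  refuse_overwrite(path, force)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

refuse_overwrite <- function(path, force) {
  if (file.exists(path) && !isTRUE(force)) {
    stop("refusing to overwrite existing file `", path,
         "`; pass force = TRUE", call. = FALSE)
  }
  invisible(path)
}
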