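#' Read an ordinal response matrix from CSV
#'
#' Expects a rectangular CSV with a header row of item labels and integer
#' 0-based category codes; missing or non-integer cells are an error (missing
#' data are out of scope, not an imputation trigger).
#'
#' @param path File path.
#' @return Integer matrix with item names; the per-column observed category
#'   counts are attached as attribute `"category_counts"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_ordinal_csv(matrix(c(0L, 1L, 1L, 0L), 2, 2), f)
#' read_ordinal_csv(f)
#' @export
read_ordinal_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  if (anyNA(df)) {
    bad <- names(df)[vapply(df, anyNA, TRUE)]
    abort(paste0(
      "Missing values in column(s): ", paste(bad, collapse = ", "),
      ". Missing data are not supported."
    ))
  }
  x <- as_ordinal_matrix(df, arg = basename(path))
  attr(x, "category_counts") <- apply(x, 2, function(col) length(unique(col)))
  x
}

#' Write an ordinal response matrix to CSV
#'
#' @param data Person x item integer matrix or data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ordinal_csv <- function(data, path) {
  x <- as_ordinal_matrix(data)
  readr::write_csv(as_tibble(as.data.frame(x)), path)
  invisible(path)
}

#' Read / write a square correlation matrix as CSV
#'
#' The CSV carries item labels in the header; rows follow the same order.
#'
#' @param matrix Square numeric matrix (or `cor_estimate` / `smooth_result`).
#' @param path File path.
#' @return `write_cor_csv()`: `path`, invisibly; `read_cor_csv()`: a numeric
#'   matrix with dimnames.
#' @export
write_cor_csv <- function(matrix, path) {
  m <- cor_matrix_of(matrix)
  if (is.null(colnames(m))) colnames(m) <- sprintf("item%02d", seq_len(ncol(m)))
  readr::write_csv(as_tibble(as.data.frame(m)), path)
  invisible(path)
}

#' @rdname write_cor_csv
#' @export
read_cor_csv <- function(path) {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  )
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) abort("Correlation CSV must be square.")
  rownames(m) <- colnames(m)
  m
}

#' Write a parallel-analysis result to JSON
#'
#' Serialises all fields of a `pa_result` (configuration, observed
#' eigenvalues, thresholds, retained count, indefiniteness flag, smoothing
#' report) with a schema version; [read_pa_json()] reconstructs the object.
#'
#' @param result A `pa_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pa_json <- function(result, path) {
  stopifnot(inherits(result, "pa_result"))
  payload <- list(
    schema = "ordipa/pa_result/1",
    config = result$config,
    observed_eigenvalues = result$observed_eigenvalues,
    reference_thresholds = result$reference_thresholds,
    retained = result$retained,
    indefinite_input = result$indefinite_input,
    n_failed_draws = result$n_failed_draws,
    smoothing_report = result$smoothing_report
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_pa_json
#' @export
read_pa_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "ordipa/pa_result/1")) {
    abort("Unrecognised result schema.")
  }
  structure(
    list(
      observed_eigenvalues = as.numeric(payload$observed_eigenvalues),
      reference_thresholds = as.numeric(payload$reference_thresholds),
      retained = as.integer(payload$retained),
      indefinite_input = as.logical(payload$indefinite_input),
      smoothing_report = payload$smoothing_report,
      n_failed_draws = as.integer(payload$n_failed_draws),
      config = payload$config
    ),
    class = "pa_result"
  )
}

#' Write a study table to CSV
#'
#' @param table Wide tibble from [tabulate_study()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}
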