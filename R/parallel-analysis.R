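#' Permute each item column independently
#'
#' Builds one reference dataset for permutation-based parallel analysis:
#' every column is independently shuffled across respondents, destroying
#' inter-item association while preserving each column's marginal
#' distribution exactly.
#'
#' @param data Person x item data frame or integer matrix.
#' @param seed Optional integer seed.
#' @return Integer matrix of the same dimension and column marginals.
#' @examples
#' m <- build_population_model(condition_spec())
#' x <- simulate_responses(m, n = 50, seed = 1)
#' p <- permute_columns(x, seed = 2)
#' identical(sort(p[, 1]), sort(x[, 1]))
#' @export
permute_columns <- function(data, seed = NULL) {
  x <- as_ordinal_matrix(data)
  with_seed_(seed, {
    for (jj in seq_len(ncol(x))) {
      x[, jj] <- x[sample.int(nrow(x)), jj]
    }
    x
  })
}

#' Eigenvalues for principal component extraction
#'
#' All eigenvalues of a correlation matrix, sorted descending.  For a J x J
#' correlation matrix they sum to J.
#'
#' @param R Symmetric correlation matrix (or a `cor_estimate`).
#' @return Numeric vector of eigenvalues, descending.
#' @examples
#' eigenvalues_pca(diag(5))
#' @export
eigenvalues_pca <- function(R) {
  r <- cor_matrix_of(R)
  if (max(abs(r - t(r))) > 1e-8) abort("`R` must be symmetric.")
  sort(eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
}

cor_matrix_of <- function(R) {
  if (inherits(R, "cor_estimate")) R$matrix else if (inherits(R, "smooth_result")) R$matrix else R
}

#' Replace the diagonal with communality estimates
#'
#' Principal-axis reduction: the unit diagonal of an invertible correlation
#' matrix is replaced by squared multiple correlations,
#' `SMC_i = 1 - 1 / (R^{-1})_{ii}`, clipped to `[0, 1]`; off-diagonal entries
#' are unchanged.
#'
#' @param R Invertible correlation matrix (or a `cor_estimate`).
#' @return The communality-reduced matrix.
#' @examples
#' r <- matrix(0.5, 5, 5); diag(r) <- 1
#' diag(reduce_with_communalities(r))  # all 0.4
#' @export
reduce_with_communalities <- function(R) {
  r <- cor_matrix_of(R)
  rinv <- tryCatch(solve(r), error = function(e) {
    abort("Correlation matrix is singular; communalities are undefined.")
  })
  smc <- pmin(pmax(1 - 1 / diag(rinv), 0), 1)
  diag(r) <- smc
  r
}

#' Eigenvalues for principal axis factoring
#'
#' Eigenvalues (possibly negative) of the communality-reduced correlation
#' matrix of [reduce_with_communalities()], sorted descending.  Their sum
#' equals the sum of the squared multiple correlations.
#'
#' @inheritParams reduce_with_communalities
#' @return Numeric vector of eigenvalues, descending.
#' @examples
#' eigenvalues_pafa(diag(5))  # all zero
#' @export
eigenvalues_pafa <- function(R) {
  red <- reduce_with_communalities(R)
  sort(eigen((red + t(red)) / 2, symmetric = TRUE, only.values = TRUE)$values,
    decreasing = TRUE
  )
}

# One pass of the estimation pipeline: data -> eigenvalues, recording whether
# the (pre-smoothing) correlation estimate was indefinite.
pipeline_eigenvalues <- function(x, correlation, smoothing, extraction,
                                 delta = 0.1, tol = 1e-6) {
  est <- switch(correlation,
    pearson = pearson_matrix(x),
    polychoric = polychoric_matrix(x, tol = tol),
    abort(sprintf("Unknown correlation method '%s'.", correlation))
  )
  indefinite <- !est$is_pd
  r <- est$matrix
  report <- NULL
  if (smoothing != "none") {
    sm <- smoother_for(smoothing, delta = delta)(r)
    r <- sm$matrix
    report <- sm$report
  }
  ev <- switch(extraction,
    pca = eigenvalues_pca(r),
    pafa = eigenvalues_pafa(r),
    abort(sprintf("Unknown extraction method '%s'.", extraction))
  )
  list(eigenvalues = ev, indefinite = indefinite, smoothing_report = report)
}

# Eigenvalues of n_draws column-permuted replicas of x, run through the same
# pipeline as the observed data.  Failed draws (for example a singular matrix
# in the communality reduction) are tolerated up to `max_failure_rate`.
reference_eigenvalue_draws <- function(x, correlation, smoothing, extraction,
                                       n_draws = 100L, delta = 0.1, tol = 1e-6,
                                       max_failure_rate = 0.25) {
  draws <- vector("list", n_draws)
  failures <- 0L
  for (b in seq_len(n_draws)) {
    perm <- permute_columns(x)
    draws[[b]] <- tryCatch(
      pipeline_eigenvalues(perm, correlation, smoothing, extraction, delta, tol)$eigenvalues,
      error = function(e) NULL
    )
    if (is.null(draws[[b]])) failures <- failures + 1L
  }
  if (failures > max_failure_rate * n_draws) {
    abort(sprintf(
      "%d of %d reference draws failed (more than %.0f%%); aborting.",
      failures, n_draws, 100 * max_failure_rate
    ))
  }
  list(
    eigenvalues = do.call(rbind, draws[!vapply(draws, is.null, TRUE)]),
    n_failed = failures
  )
}

# Per-position criterion values from a draws x J eigenvalue matrix.
# The 95th percentile uses stats::quantile type 7 (linear interpolation of
# order statistics), R's default.
criterion_thresholds <- function(eig_draws, criterion) {
  switch(criterion,
    mean = colMeans(eig_draws),
    p95 = apply(eig_draws, 2, quantile, probs = 0.95, type = 7, names = FALSE),
    abort(sprintf("Unknown criterion '%s'.", criterion))
  )
}

#' Permutation reference thresholds for parallel analysis
#'
#' Runs the full estimation pipeline (correlation, optional smoothing,
#' optional communality reduction) on `n_draws` independently column-permuted
#' copies of the data and summarises the k-th largest eigenvalues by the Horn
#' (mean) or Glorfeld (95th percentile, `stats::quantile` type 7) criterion.
#'
#' @inheritParams run_parallel_analysis
#' @return Numeric vector of per-position threshold values.
#' @examples
#' m <- build_population_model(condition_spec())
#' x <- simulate_responses(m, n = 100, seed = 1)
#' reference_thresholds(x, n_draws = 10, seed = 2)
#' @export
reference_thresholds <- function(data, extraction = c("pca", "pafa"),
                                 correlation = c("pearson", "polychoric"),
                                 smoothing = c("none", "higham", "knol_berger", "bentler_yuan"),
                                 criterion = c("p95", "mean"),
                                 n_draws = 100L, delta = 0.1, seed = NULL) {
  extraction <- match.arg(extraction)
  correlation <- match.arg(correlation)
  smoothing <- match.arg(smoothing)
  criterion <- match.arg(criterion)
  x <- as_ordinal_matrix(data)
  ref <- with_seed_(
    seed,
    reference_eigenvalue_draws(x, correlation, smoothing, extraction, n_draws, delta)
  )
  criterion_thresholds(ref$eigenvalues, criterion)
}

#' Sequential retention rule
#'
#' Number of dimensions retained by the sequential comparison: the largest
#' `k` such that every observed eigenvalue up to position `k` exceeds its
#' threshold; the comparison stops at the first failure.
#'
#' @param observed Observed eigenvalues, descending.
#' @param thresholds Reference thresholds of equal length.
#' @return Integer count in `0:length(observed)`.
#' @examples
#' retained_dimensions(c(2.5, 1.4, 1.2, 0.3), c(1.3, 1.2, 1.25, 1.0))  # 2
#' @export
retained_dimensions <- function(observed, thresholds) {
  if (length(observed) != length(thresholds)) {
    abort("`observed` and `thresholds` must have equal length.")
  }
  exceeds <- observed > thresholds
  if (!exceeds[1]) {
    return(0L)
  }
  failures <- which(!exceeds)
  if (length(failures) == 0) length(observed) else failures[1] - 1L
}

#' Parallel analysis of an ordinal dataset
#'
#' Decides the number of dimensions underlying a set of ordered categorical
#' items.  The pipeline: estimate the configured correlation matrix of the
#' observed data (recording indefiniteness before any smoothing), smooth it
#' to positive definiteness if requested, extract eigenvalues (principal
#' components, or principal axis factoring with squared-multiple-correlation
#' communalities), build the permutation reference distribution with
#' [reference_thresholds()], and retain dimensions by the sequential rule of
#' [retained_dimensions()].
#'
#' Pearson correlation matrices are positive semidefinite by construction and
#' may not be combined with smoothing; polychoric matrices may be analysed
#' unsmoothed (`smoothing = "none"`) to study the indefinite arm.
#'
#' @param data Person x item data frame or integer matrix of 0-based category
#'   codes.
#' @param extraction `"pca"` or `"pafa"`.
#' @param correlation `"pearson"` or `"polychoric"`.
#' @param smoothing `"none"`, `"higham"`, `"knol_berger"` or `"bentler_yuan"`.
#' @param criterion `"p95"` (Glorfeld) or `"mean"` (Horn).
#' @param n_draws Number of permutation reference draws (default 100).
#' @param delta Eigenvalue floor for Knol-Berger smoothing.
#' @param seed Optional integer seed; fixing it makes the whole analysis
#'   reproducible bit for bit.
#' @return A `pa_result` object: observed eigenvalues, per-position
#'   thresholds, the retained dimension count, an indefiniteness flag for the
#'   observed correlation matrix, the smoothing report (if any), and the
#'   configuration.
#' @examples
#' m <- build_population_model(condition_spec())
#' x <- simulate_responses(m, n = 200, seed = 1)
#' fit <- run_parallel_analysis(x, n_draws = 20, seed = 2)
#' fit$retained
#' @export
run_parallel_analysis <- function(data,
                                  extraction = c("pca", "pafa"),
                                  correlation = c("pearson", "polychoric"),
                                  smoothing = c("none", "higham", "knol_berger", "bentler_yuan"),
                                  criterion = c("p95", "mean"),
                                  n_draws = 100L, delta = 0.1, seed = NULL) {
  extraction <- match.arg(extraction)
  correlation <- match.arg(correlation)
  smoothing <- match.arg(smoothing)
  criterion <- match.arg(criterion)
  if (correlation == "pearson" && smoothing != "none") {
    abort("Pearson correlation matrices are never smoothed; use smoothing = \"none\".")
  }
  x <- as_ordinal_matrix(data)
  with_seed_(seed, {
    obs <- pipeline_eigenvalues(x, correlation, smoothing, extraction, delta)
    ref <- reference_eigenvalue_draws(x, correlation, smoothing, extraction, n_draws, delta)
    thresholds <- criterion_thresholds(ref$eigenvalues, criterion)
    structure(
      list(
        observed_eigenvalues = obs$eigenvalues,
        reference_thresholds = thresholds,
        retained = retained_dimensions(obs$eigenvalues, thresholds),
        indefinite_input = obs$indefinite,
        smoothing_report = obs$smoothing_report,
        n_failed_draws = ref$n_failed,
        config = list(
          extraction = extraction, correlation = correlation,
          smoothing = smoothing, criterion = criterion,
          n_draws = as.integer(n_draws), delta = delta, seed = seed
        )
      ),
      class = "pa_result"
    )
  })
}

#' @export
print.pa_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Parallel analysis (%s, %s correlations%s, %s criterion)\n",
    toupper(cfg$extraction), cfg$correlation,
    if (cfg$smoothing == "none") "" else paste0(", ", cfg$smoothing, " smoothing"),
    cfg$criterion
  ))
  cat(sprintf(
    "  retained dimensions: %d of %d\n", x$retained,
    length(x$observed_eigenvalues)
  ))
  if (x$indefinite_input) {
    cat("  observed correlation matrix was indefinite before smoothing\n")
  }
  k <- min(5L, length(x$observed_eigenvalues))
  cat(sprintf(
    "  eigenvalues:  %s\n  thresholds:   %s\n",
    paste(sprintf("%.3f", x$observed_eigenvalues[1:k]), collapse = " "),
    paste(sprintf("%.3f", x$reference_thresholds[1:k]), collapse = " ")
  ))
  invisible(x)
}

#' Tidy a parallel-analysis result
#'
#' @param x A `pa_result`.
#' @param ... Unused.
#' @return A tibble with one row per eigenvalue position: `position`,
#'   `observed`, `threshold`, `exceeds` and `retained`.
#' @export
tidy.pa_result <- function(x, ...) {
  tibble(
    position = seq_along(x$observed_eigenvalues),
    observed = x$observed_eigenvalues,
    threshold = x$reference_thresholds,
    exceeds = x$observed_eigenvalues > x$reference_thresholds,
    retained = seq_along(x$observed_eigenvalues) <= x$retained
  )
}

#' One-row summary of a parallel-analysis result
#'
#' @inheritParams tidy.pa_result
#' @return A one-row tibble with the configuration, retained count and
#'   indefiniteness flag.
#' @export
glance.pa_result <- function(x, ...) {
  cfg <- x$config
  tibble(
    extraction = cfg$extraction,
    correlation = cfg$correlation,
    smoothing = cfg$smoothing,
    criterion = cfg$criterion,
    n_items = length(x$observed_eigenvalues),
    n_draws = cfg$n_draws,
    retained = x$retained,
    indefinite_input = x$indefinite_input,
    n_failed_draws = x$n_failed_draws
  )
}

#' Scree plot with permutation thresholds
#'
#' @param object A `pa_result`.
#' @param ... Unused.
#' @return A ggplot: observed eigenvalues against position, the reference
#'   threshold line, and retained positions highlighted.
#' @export
autoplot.pa_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed, colour = .data$retained), size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey50")) +
    ggplot2::labs(
      x = "Component / factor", y = "Eigenvalue",
      colour = "Retained",
      title = sprintf(
        "Parallel analysis: %d dimension(s) retained", object$retained
      ),
      subtitle = "Dashed line: permutation reference threshold"
    ) +
    ggplot2::theme_minimal()
}
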