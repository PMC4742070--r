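#' Cross-tabulate one item pair
#'
#' @param x,y Integer category vectors of equal length.
#' @return Integer contingency matrix over the observed categories of `x`
#'   (rows) and `y` (columns), with category labels as dimnames.
#' @examples
#' pairwise_contingency(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
pairwise_contingency <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  tab <- table(x, y)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

# Rectangle (cell) probabilities of a bivariate normal with correlation rho,
# given interior row/column thresholds a and b.
polychoric_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  grid <- pbvnorm(rep(aa, times = length(bb)), rep(bb, each = length(aa)), rho)
  cdf <- matrix(grid, length(aa), length(bb))
  cdf[-1, -1, drop = FALSE] - cdf[-nrow(cdf), -1, drop = FALSE] -
    cdf[-1, -ncol(cdf), drop = FALSE] + cdf[-nrow(cdf), -ncol(cdf), drop = FALSE]
}

#' Two-step polychoric correlation for one contingency table
#'
#' Olsson's two-step estimator with pair-specific thresholds: step one fixes
#' the thresholds at the standard-normal quantiles of the table's cumulative
#' marginal proportions; step two maximizes the multinomial log-likelihood
#' `sum(n_ij * log(pi_ij(rho)))`, where `pi_ij(rho)` is the bivariate-normal
#' rectangle probability between consecutive thresholds, over
#' `rho` in `(-0.999, 0.999)` by bounded scalar maximization.
#'
#' Empty cells contribute nothing to the likelihood (`0 * log(pi) := 0`); no
#' continuity correction is applied.  Tables exhibiting perfect association
#' push the optimum to the boundary and are clipped to `+/-0.999` with
#' convergence flag `"boundary"`.  Tables in which a variable shows a single
#' observed category cannot identify a correlation and are flagged
#' `"degenerate"` with an `NA` estimate.
#'
#' @param tab Contingency matrix (see [pairwise_contingency()]).
#' @param tol Convergence tolerance of the scalar optimizer.
#' @param bound Box constraint on `|rho|` (0.999).
#' @return A list: `rho`, `convergence` (`"converged"`, `"boundary"` or
#'   `"degenerate"`), `thresholds_row`, `thresholds_col`, `loglik`.
#' @examples
#' tab <- matrix(c(40, 10, 10, 40), 2, 2)
#' polychoric_pair(tab)$rho
#' @export
polychoric_pair <- function(tab, tol = 1e-6, bound = 0.999) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Contingency table must contain nonnegative integer counts.")
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(
      rho = NA_real_, convergence = "degenerate",
      thresholds_row = numeric(0), thresholds_col = numeric(0),
      loglik = NA_real_
    ))
  }
  n <- sum(tab)
  a <- qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  b <- qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]

  negll <- function(rho) {
    p <- polychoric_cell_probs(a, b, rho)
    -sum(tab * log(pmax(p, 1e-300)))
  }
  opt <- optimize(negll, c(-bound, bound), tol = tol)
  rho <- opt$minimum
  convergence <- "converged"
  if (abs(rho) > bound - 1e-4) {
    rho <- sign(rho) * bound
    convergence <- "boundary"
  }
  list(
    rho = rho, convergence = convergence,
    thresholds_row = a, thresholds_col = b,
    loglik = -negll(rho)
  )
}

new_cor_estimate <- function(matrix, method, smoothing = "none",
                             convergence = NULL, pd_tol = 1e-8) {
  matrix <- (matrix + t(matrix)) / 2
  pd <- is_positive_definite(matrix, tol = pd_tol)
  structure(
    list(
      matrix = matrix,
      method = method,
      smoothing = smoothing,
      min_eigenvalue = pd$min_eigenvalue,
      is_pd = pd$is_pd,
      convergence = convergence
    ),
    class = "cor_estimate"
  )
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf(
    "%s correlation estimate (%d items), smoothing: %s\n",
    x$method, ncol(x$matrix), x$smoothing
  ))
  cat(sprintf(
    "  min eigenvalue: %.6g (%s)\n",
    x$min_eigenvalue, if (x$is_pd) "positive definite" else "indefinite"
  ))
  invisible(x)
}

#' Pairwise polychoric correlation matrix
#'
#' Assembles the J x J matrix of two-step pairwise polychoric correlations
#' (see [polychoric_pair()]) and diagnoses its definiteness.  Because each
#' coefficient uses its own pair-specific thresholds, the assembled matrix is
#' not guaranteed to be positive definite; the result records the smallest
#' eigenvalue so indefinite matrices can be smoothed downstream.
#'
#' @param data Person x item data frame or integer matrix of 0-based category
#'   codes.
#' @param tol,bound Passed to [polychoric_pair()].
#' @return A `cor_estimate` object: the symmetric unit-diagonal matrix plus
#'   method (`"polychoric"`), smoothing state (`"none"`), smallest eigenvalue,
#'   a definiteness flag, and a tibble of per-pair convergence flags.
#' @examples
#' m <- build_population_model(condition_spec())
#' x <- simulate_responses(m, n = 200, seed = 1)
#' polychoric_matrix(x)
#' @export
polychoric_matrix <- function(data, tol = 1e-6, bound = 0.999) {
  x <- as_ordinal_matrix(data)
  j <- ncol(x)
  if (j < 2) {
    abort("At least two items are required.")
  }
  r <- diag(j)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  flags <- character(nrow(pairs))
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1]
    k <- pairs[idx, 2]
    est <- polychoric_pair(pairwise_contingency(x[, i], x[, k]), tol = tol, bound = bound)
    flags[idx] <- est$convergence
    r[i, k] <- r[k, i] <- est$rho
  }
  if (any(flags == "degenerate")) {
    bad <- pairs[flags == "degenerate", , drop = FALSE]
    items <- sort(unique(colnames(x)[c(bad)]))
    abort(paste0(
      "Degenerate item pair(s): a variable with a single observed category. ",
      "Items involved: ", paste(items, collapse = ", ")
    ))
  }
  dimnames(r) <- list(colnames(x), colnames(x))
  new_cor_estimate(
    r,
    method = "polychoric",
    convergence = tibble(
      item_i = colnames(x)[pairs[, 1]],
      item_j = colnames(x)[pairs[, 2]],
      convergence = flags
    )
  )
}

#' Pearson correlation matrix of category codes
#'
#' Product-moment correlations of the raw integer category codes; always
#' positive semidefinite up to rounding.
#'
#' @inheritParams polychoric_matrix
#' @return A `cor_estimate` with method `"pearson"`.
#' @examples
#' m <- build_population_model(condition_spec())
#' pearson_matrix(simulate_responses(m, n = 200, seed = 1))
#' @export
pearson_matrix <- function(data) {
  x <- as_ordinal_matrix(data)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort(paste0(
      "Zero-variance column(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    ))
  }
  r <- cor(x)
  new_cor_estimate(r, method = "pearson")
}

#' Test a symmetric matrix for positive definiteness
#'
#' @param matrix Symmetric numeric matrix.
#' @param tol Smallest-eigenvalue tolerance: the matrix is declared positive
#'   definite iff its smallest eigenvalue exceeds `tol`.
#' @return A list with `is_pd` (logical) and `min_eigenvalue`.
#' @examples
#' is_positive_definite(diag(3))
#' @export
is_positive_definite <- function(matrix, tol = 1e-8) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    abort("`matrix` must be square.")
  }
  if (max(abs(matrix - t(matrix))) > 1e-8) {
    abort("`matrix` must be symmetric.")
  }
  ev <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(is_pd = min(ev) > tol, min_eigenvalue = min(ev))
}
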