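#' Build the population factor model for one condition
#'
#' Assembles the latent correlation matrix underlying the simulated ordinal
#' responses.  Each of the J = `n_major_factors * vars_per_factor` latent
#' variables loads on exactly one major factor with loading 1; optionally 40
#' weak minor factors with loadings drawn independently from Uniform(-1, 1)
#' model structured noise; the remainder is unique variance.  The latent
#' correlation matrix is
#'
#'   Sigma = w_ma Lma Lma' + w_mi Lmi Lmi' + w_un I
#'
#' with `w_ma = 0.5` ("high" loadings, 50\% of latent variance from major
#' factors) or `0.3` ("medium").  When minor factors are present, `w_mi` is
#' scaled so the expected minor-factor contribution to each latent variance is
#' `0.2 * w_ma`, and `w_un = 1 - 1.2 * w_ma`; because the realized
#' `diag(Lmi Lmi')` varies across variables, the assembled matrix is rescaled
#' to an exact correlation matrix (the discretization step assumes
#' standard-normal marginals).
#'
#' Minor-factor loadings are random: rebuild the model for every simulated
#' replicate so the nuisance structure is not shared across datasets.
#'
#' @param spec A one-row condition tibble (see [condition_spec()], [pa_grid()]).
#' @param n_minor_factors Number of minor factors when `minors_present` (40).
#' @param seed Optional integer seed for the minor-factor draws.
#' @return An object of class `population_model`: a list with the loading
#'   matrices, weights, the population correlation matrix `sigma`, the
#'   discretization `thresholds` and design category probabilities.
#' @examples
#' m <- build_population_model(condition_spec(loading_level = "high"))
#' m$sigma[1, 2]  # 0.5 for a one-factor, no-minors, high-loading condition
#' @export
build_population_model <- function(spec, n_minor_factors = 40L, seed = NULL) {
  spec <- as_condition_spec(spec)
  k <- spec$n_major_factors
  j <- k * spec$vars_per_factor

  lambda_major <- matrix(0, j, k)
  lambda_major[cbind(seq_len(j), rep(seq_len(k), each = spec$vars_per_factor))] <- 1

  w_ma <- if (spec$loading_level == "high") 0.5 else 0.3
  if (spec$minors_present) {
    lambda_minor <- with_seed_(
      seed,
      matrix(runif(j * n_minor_factors, -1, 1), j, n_minor_factors)
    )
    # E[lambda^2] = 1/3 for U(-1,1): normalise so the expected minor
    # contribution to each latent variance is 0.2 * w_ma.
    w_mi <- 0.2 * w_ma / (n_minor_factors / 3)
    w_un <- 1 - w_ma - 0.2 * w_ma
  } else {
    lambda_minor <- NULL
    w_mi <- 0
    w_un <- 1 - w_ma
  }

  sigma <- w_ma * tcrossprod(lambda_major) + w_un * diag(j)
  if (!is.null(lambda_minor)) {
    sigma <- sigma + w_mi * tcrossprod(lambda_minor)
  }
  d <- 1 / sqrt(diag(sigma))
  sigma <- sigma * tcrossprod(d)
  diag(sigma) <- 1

  structure(
    list(
      spec = spec,
      lambda_major = lambda_major,
      lambda_minor = lambda_minor,
      w_ma = w_ma, w_mi = w_mi, w_un = w_un,
      sigma = sigma,
      thresholds = category_thresholds(spec$n_categories, spec$skewed),
      category_probs = category_probs(spec$n_categories, spec$skewed)
    ),
    class = "population_model"
  )
}

#' @export
print.population_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Population model: %d major factor(s) x %d variables, %s loadings\n",
    s$n_major_factors, s$vars_per_factor, s$loading_level
  ))
  cat(sprintf(
    "  categories: %d (%s), minor factors: %s\n",
    s$n_categories, if (s$skewed) "skewed" else "symmetric",
    if (s$minors_present) ncol(x$lambda_minor) else "none"
  ))
  cat(sprintf(
    "  weights: w_ma = %.3f, w_mi = %.4f, w_un = %.3f\n",
    x$w_ma, x$w_mi, x$w_un
  ))
  invisible(x)
}

#' Simulate ordinal responses from a population model
#'
#' Draws `n` respondents from a multivariate standard normal with the model's
#' latent correlation matrix, then discretizes each coordinate at the model
#' thresholds into 0-based category codes.
#'
#' @param model A `population_model` from [build_population_model()].
#' @param n Number of respondents; defaults to the condition's sample size.
#' @param seed Optional integer seed.
#' @return Integer matrix (`n` x J) with entries in `0:(n_categories - 1)`,
#'   item names as column names and the category count as attribute
#'   `n_categories`.
#' @examples
#' m <- build_population_model(condition_spec())
#' x <- simulate_responses(m, n = 100, seed = 1)
#' table(x[, 1])
#' @export
simulate_responses <- function(model, n = NULL, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  n <- as.integer(n %||% model$spec$n_respondents)
  j <- ncol(model$sigma)
  cf <- tryCatch(chol(model$sigma), error = function(e) {
    abort("Population correlation matrix is not positive semidefinite.")
  })
  z <- with_seed_(seed, matrix(rnorm(n * j), n, j)) %*% cf
  x <- matrix(0L, n, j)
  for (jj in seq_len(j)) {
    x[, jj] <- findInterval(z[, jj], model$thresholds)
  }
  storage.mode(x) <- "integer"
  colnames(x) <- sprintf("item%02d", seq_len(j))
  attr(x, "n_categories") <- model$spec$n_categories
  x
}
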