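#' Design category probabilities
#'
#' Expected relative frequencies of the response categories under the
#' symmetric and skewed designs.  Symmetric conditions use equal frequencies;
#' skewed conditions place most of the mass on the top category:
#' `c(0.2, 0.8)`, `c(0.1, 0.2, 0.7)` and `c(0.1, 0.1, 0.1, 0.7)` for two,
#' three and four categories, giving a marginal skewness of about 1.4 in
#' magnitude.
#'
#' @param n_categories Number of response categories (2, 3 or 4).
#' @param skewed Logical; skewed or symmetric frequencies.
#' @return Numeric probability vector of length `n_categories`, summing to 1.
#' @examples
#' category_probs(3, skewed = TRUE)
#' @export
category_probs <- function(n_categories, skewed = FALSE) {
  n_categories <- as.integer(n_categories)
  if (!n_categories %in% 2:4) {
    abort("`n_categories` must be 2, 3 or 4.")
  }
  if (!skewed) {
    return(rep(1 / n_categories, n_categories))
  }
  switch(as.character(n_categories),
    "2" = c(0.2, 0.8),
    "3" = c(0.1, 0.2, 0.7),
    "4" = c(0.1, 0.1, 0.1, 0.7)
  )
}

#' Discretization thresholds on the latent scale
#'
#' Cut points on the latent standard-normal scale that produce the design
#' category frequencies of [category_probs()]: the standard-normal quantiles
#' of the cumulative category probabilities.
#'
#' @inheritParams category_probs
#' @return Strictly increasing numeric vector of length `n_categories - 1`.
#' @examples
#' category_thresholds(2)                 # 0: a median split
#' category_thresholds(4, skewed = TRUE)  # qnorm(c(.1, .2, .3))
#' @export
category_thresholds <- function(n_categories, skewed = FALSE) {
  probs <- category_probs(n_categories, skewed)
  qnorm(cumsum(probs)[-length(probs)])
}

#' Population skewness of a discrete category distribution
#'
#' Third standardized central moment of a distribution over integer category
#' scores `0, 1, ..., C - 1`.
#'
#' @param category_probs Nonnegative probability vector summing to 1; element
#'   `c` is the probability of score `c - 1`.
#' @return The population skewness (signed).
#' @examples
#' population_skewness(c(0.1, 0.2, 0.7))  # about -1.4
#' population_skewness(c(0.2, 0.8))       # -1.5 exactly
#' @export
population_skewness <- function(category_probs) {
  p <- as.numeric(category_probs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("`category_probs` must be nonnegative and sum to 1.")
  }
  x <- seq_along(p) - 1
  mu <- sum(p * x)
  v <- sum(p * (x - mu)^2)
  if (v <= .Machine$double.eps) {
    abort("Degenerate distribution: zero variance, skewness undefined.")
  }
  sum(p * (x - mu)^3) / v^1.5
}
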