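# Shared fixtures and independent oracles, built in code at test time.

# Classic 3x3 indefinite unit-diagonal fixture: pairwise correlations that no
# trivariate normal can generate.
indefinite3 <- function() {
  matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
}

# Random unit-diagonal symmetric matrix, retried until indefinite.
random_indefinite <- function(j = 5, tries = 200) {
  for (i in seq_len(tries)) {
    z <- matrix(rnorm(j * 3), j, 3)
    r <- stats::cov2cor(tcrossprod(z) + diag(j) * 0.01)
    noise <- matrix(rnorm(j * j, sd = 0.35), j, j)
    noise <- (noise + t(noise)) / 2
    r <- r + noise
    r <- pmin(pmax(r, -0.99), 0.99)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-4) {
      return(r)
    }
  }
  stop("could not generate an indefinite matrix")
}

# Random PD correlation matrix (factor structure plus ridge).
random_pd_correlation <- function(j = 5) {
  z <- matrix(rnorm(j * (j + 2)), j, j + 2)
  stats::cov2cor(tcrossprod(z) + diag(j))
}

# Random contingency table from a discretized bivariate normal.
random_table <- function(n = 200, c1 = sample(2:4, 1), c2 = sample(2:4, 1),
                         rho = runif(1, -0.85, 0.85)) {
  z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  cut1 <- sort(qnorm(seq_len(c1 - 1) / c1) + rnorm(c1 - 1, sd = 0.2))
  cut2 <- sort(qnorm(seq_len(c2 - 1) / c2) + rnorm(c2 - 1, sd = 0.2))
  x <- findInterval(z[, 1], cut1)
  y <- findInterval(z[, 2], cut2)
  pairwise_contingency(x, y)
}

# Independent likelihood grid-search oracle for the two-step polychoric
# estimate: same fixed thresholds, rho maximized over an explicit grid
# (coarse 1e-2 sweep, then 1e-4 refinement around the coarse argmax).
polychoric_grid_oracle <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  a <- qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  b <- qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  ll <- function(rho) {
    aa <- c(-Inf, a, Inf)
    bb <- c(-Inf, b, Inf)
    cdf <- matrix(
      pbvnorm(rep(aa, times = length(bb)), rep(bb, each = length(aa)), rho),
      length(aa), length(bb)
    )
    p <- cdf[-1, -1] - cdf[-length(aa), -1] - cdf[-1, -length(bb)] +
      cdf[-length(aa), -length(bb)]
    sum(tab * log(pmax(p, 1e-300)))
  }
  coarse <- seq(-0.99, 0.99, by = 0.01)
  l1 <- vapply(coarse, ll, numeric(1))
  c0 <- coarse[which.max(l1)]
  fine <- seq(max(-0.999, c0 - 0.011), min(0.999, c0 + 0.011), by = 1e-4)
  l2 <- vapply(fine, ll, numeric(1))
  fine[which.max(l2)]
}

# Long-iteration alternating-projection oracle for the nearest correlation
# matrix (no early stopping, no strict-PD floor).
higham_long_oracle <- function(r, iterations = 10000) {
  y <- r
  ds <- matrix(0, nrow(r), ncol(r))
  psd <- function(m) {
    e <- eigen(m, symmetric = TRUE)
    out <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    (out + t(out)) / 2
  }
  for (i in seq_len(iterations)) {
    rr <- y - ds
    x <- psd(rr)
    ds <- x - rr
    y <- x
    diag(y) <- 1
  }
  y
}

# Direct application of the eigenvalue-clipping formula
# R(delta) = Diag(K D+ K')^{-1/2} K D+ K' Diag(K D+ K')^{-1/2}.
kb_formula_oracle <- function(r, delta = 0.1) {
  e <- eigen(r, symmetric = TRUE)
  m <- e$vectors %*% diag(pmax(e$values, delta)) %*% t(e$vectors)
  s <- diag(1 / sqrt(diag(m)))
  s %*% m %*% s
}

# One-factor binary dataset used by several retention tests.
strong_one_factor_data <- function(n = 1000, seed = 1) {
  model <- build_population_model(condition_spec(
    n_major_factors = 1, vars_per_factor = 5, n_respondents = n,
    n_categories = 2, skewed = FALSE, minors_present = FALSE,
    loading_level = "high"
  ))
  simulate_responses(model, n = n, seed = seed)
}

# Pure-noise ordinal data: independent uniform categories.
noise_data <- function(n = 200, j = 5, c = 3, seed = NULL) {
  gen <- function() matrix(sample.int(c, n * j, replace = TRUE) - 1L, n, j)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
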