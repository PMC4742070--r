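test_that("column permutation preserves marginals and kills association", {
  x <- strong_one_factor_data(n = 2000, seed = 2)
  p <- permute_columns(x, seed = 3)
  for (jj in 1:ncol(x)) {
    expect_identical(sort(p[, jj]), sort(x[, jj]))
  }
  # two perfectly correlated columns decorrelate under permutation
  y <- cbind(a = x[, 1], b = x[, 1])
  py <- permute_columns(y, seed = 4)
  expect_lt(abs(cor(py[, 1], py[, 2])), 3 / sqrt(nrow(y)))
  # single column: same multiset
  one <- permute_columns(x[, 1, drop = FALSE], seed = 5)
  expect_identical(sort(one[, 1]), sort(x[, 1]))
})

test_that("PCA eigenvalues match closed forms and conserve trace", {
  expect_equal(eigenvalues_pca(diag(5)), rep(1, 5))
  r <- matrix(0.5, 5, 5)
  diag(r) <- 1
  expect_equal(eigenvalues_pca(r), c(3, rep(0.5, 4)))
  set.seed(71)
  for (i in 1:10) {
    rr <- random_pd_correlation(sample(3:8, 1))
    ev <- eigenvalues_pca(rr)
    expect_equal(sum(ev), nrow(rr), tolerance = 1e-8)
    expect_true(all(diff(ev) <= 0))
  }
  expect_error(eigenvalues_pca(matrix(1:4, 2)), "symmetric")
})

test_that("communality reduction uses squared multiple correlations", {
  # identity: all SMC zero, all eigenvalues zero
  expect_equal(reduce_with_communalities(diag(5)), diag(0, 5))
  expect_equal(eigenvalues_pafa(diag(5)), rep(0, 5))
  # equicorrelation closed form:
  # SMC = 1 - (1 - rho)(1 + (J-1) rho) / (1 + (J-2) rho)
  for (rho in c(0.3, 0.5, 0.7)) {
    j <- 5
    r <- matrix(rho, j, j)
    diag(r) <- 1
    smc <- 1 - (1 - rho) * (1 + (j - 1) * rho) / (1 + (j - 2) * rho)
    red <- reduce_with_communalities(r)
    expect_equal(diag(red), rep(smc, j), tolerance = 1e-12)
    # off-diagonals untouched
    expect_equal(red[upper.tri(red)], r[upper.tri(r)])
    # eigenvalue sum equals the SMC sum; dominant first factor
    ev <- eigenvalues_pafa(r)
    expect_equal(sum(ev), j * smc, tolerance = 1e-10)
    expect_gt(ev[1], 10 * abs(ev[2]))
  }
  expect_error(reduce_with_communalities(matrix(1, 3, 3)), "singular")
})

test_that("reference thresholds behave as a permutation null", {
  x <- noise_data(n = 300, j = 6, c = 3, seed = 7)
  thr <- reference_thresholds(x, extraction = "pca", criterion = "mean", n_draws = 60, seed = 8)
  # noise eigenvalue spread straddles 1
  expect_gt(thr[1], 1)
  expect_lt(thr[6], 1)
  expect_true(all(diff(thr) < 0))
  # Glorfeld is at least Horn for the dominant position (same draws)
  thr95 <- reference_thresholds(x, extraction = "pca", criterion = "p95", n_draws = 60, seed = 8)
  expect_gte(thr95[1], thr[1])
  # a single draw makes both criteria degenerate and equal
  t1m <- reference_thresholds(x, criterion = "mean", n_draws = 1, seed = 9)
  t1p <- reference_thresholds(x, criterion = "p95", n_draws = 1, seed = 9)
  expect_equal(t1m, t1p)
})

test_that("retention rule is sequential and stops at the first failure", {
  expect_equal(retained_dimensions(c(3.0, 0.5, 0.4), c(1.3, 1.15, 1.0)), 1L)
  expect_equal(retained_dimensions(c(0.9, 0.5), c(1.3, 1.15)), 0L)
  expect_equal(
    retained_dimensions(c(2.5, 1.4, 1.2, 0.3), c(1.3, 1.2, 1.25, 1.0)),
    2L
  )
  # all exceed: bounded by the number of positions
  expect_equal(retained_dimensions(c(2, 2), c(1, 1)), 2L)
  expect_error(retained_dimensions(1:3, 1:2), "equal length")
  # monotonicity: raising any threshold never increases retention
  set.seed(73)
  for (i in 1:50) {
    obs <- sort(rexp(6), decreasing = TRUE)
    thr <- sort(rexp(6), decreasing = TRUE)
    base <- retained_dimensions(obs, thr)
    bump <- thr + runif(6, 0, 0.5)
    expect_lte(retained_dimensions(obs, sort(bump, decreasing = TRUE)), base)
  }
})

test_that("the full analysis is reproducible bit for bit under a seed", {
  x <- strong_one_factor_data(n = 300, seed = 11)
  a <- run_parallel_analysis(x,
    correlation = "polychoric", smoothing = "knol_berger",
    n_draws = 15, seed = 99
  )
  b <- run_parallel_analysis(x,
    correlation = "polychoric", smoothing = "knol_berger",
    n_draws = 15, seed = 99
  )
  expect_identical(a, b)
})

test_that("strong one-factor data retains one dimension across variants", {
  x <- strong_one_factor_data(n = 1000, seed = 12)
  for (cfg in list(
    list(correlation = "pearson", smoothing = "none"),
    list(correlation = "polychoric", smoothing = "none"),
    list(correlation = "polychoric", smoothing = "bentler_yuan")
  )) {
    fit <- run_parallel_analysis(x,
      extraction = "pca", correlation = cfg$correlation,
      smoothing = cfg$smoothing, criterion = "p95", n_draws = 40, seed = 101
    )
    expect_equal(fit$retained, 1L)
  }
})

test_that("pure-noise data retains nothing under the 95th-percentile null", {
  retained <- vapply(1:8, function(s) {
    x <- noise_data(n = 250, j = 5, c = 3, seed = 200 + s)
    run_parallel_analysis(x, criterion = "p95", n_draws = 40, seed = s)$retained
  }, integer(1))
  # the p95 criterion admits a ~5% false positive per dataset
  expect_gte(sum(retained == 0), 7)
})

test_that("PCA reference eigenvalue vectors conserve the trace", {
  x <- noise_data(n = 200, j = 5, c = 3, seed = 14)
  fit <- run_parallel_analysis(x, criterion = "mean", n_draws = 25, seed = 15)
  expect_equal(sum(fit$observed_eigenvalues), 5, tolerance = 1e-8)
  # the mean of per-position means over full eigenvalue vectors keeps J too
  expect_equal(sum(fit$reference_thresholds), 5, tolerance = 1e-8)
})

test_that("smoothing precedes the communality reduction for PAFA", {
  r <- indefinite3()
  sm <- smooth_knol_berger(r)$matrix
  red <- reduce_with_communalities(sm)
  # off-diagonals of the reduced matrix are the smoothed (not raw) values
  expect_equal(red[upper.tri(red)], sm[upper.tri(sm)])
  expect_false(isTRUE(all.equal(red[upper.tri(red)], r[upper.tri(r)])))
})

test_that("invalid configurations are rejected", {
  x <- noise_data(n = 50, j = 4, c = 2, seed = 16)
  expect_error(
    run_parallel_analysis(x, correlation = "pearson", smoothing = "higham"),
    "never smoothed"
  )
  expect_error(run_parallel_analysis(cbind(x, NA)), "missing")
})

test_that("tidy, glance and autoplot expose the result", {
  x <- strong_one_factor_data(n = 300, seed = 18)
  fit <- run_parallel_analysis(x, n_draws = 15, seed = 19)
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_named(td, c("position", "observed", "threshold", "exceeds", "retained"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$retained, fit$retained)
  expect_s3_class(autoplot(fit), "ggplot")
})
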