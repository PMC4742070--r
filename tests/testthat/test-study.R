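test_that("method grid builds the labelled study arms", {
  m <- pa_methods()
  expect_equal(nrow(m), 12)
  expect_equal(m$method[1:4], c("PCA95KB", "PCAmKB", "PAFA95KB", "PAFAmKB"))
  expect_equal(m$method[9:12], c("PCA95Pear", "PCAmPear", "PAFA95Pear", "PAFAmPear"))
  expect_true(all(m$smoothing[m$correlation == "pearson"] == "none"))
  raw <- pa_methods(arms = "raw", extraction = "pca", criterion = "p95")
  expect_equal(raw$method, "PCA95Ind")
  expect_equal(raw$smoothing, "none")
})

test_that("a condition run returns one row per replicate and method", {
  cond <- condition_spec(
    n_major_factors = 1, vars_per_factor = 5, n_respondents = 200,
    n_categories = 3
  )
  methods <- pa_methods(arms = c("kb", "pearson"), extraction = "pca")
  res <- run_condition(cond,
    methods = methods, n_replicates = 3, n_draws = 10, seed = 5
  )
  expect_equal(nrow(res), 3 * nrow(methods))
  expect_setequal(unique(res$method), methods$method)
  expect_true(all(res$retained >= 0 & res$retained <= 5))
  expect_true(all(res$correct == (res$retained == 1), na.rm = TRUE))
  # same seed reproduces the whole result table exactly
  res2 <- run_condition(cond,
    methods = methods, n_replicates = 3, n_draws = 10, seed = 5
  )
  expect_identical(res, res2)
})

test_that("structureless models defeat every method", {
  # a 'one-factor' label on white-noise data: accuracy must be ~0
  cond <- condition_spec(n_respondents = 300, n_categories = 3)
  methods <- pa_methods(arms = "pearson", extraction = "pca")
  res <- run_condition(cond, methods = methods, n_replicates = 2, n_draws = 10, seed = 31)
  # rebuild with a flat model by hand: permuted data has no structure at all
  x <- noise_data(n = 300, j = 5, c = 3, seed = 32)
  fits <- lapply(1:3, function(s) {
    run_parallel_analysis(x, criterion = "p95", n_draws = 10, seed = s)
  })
  expect_true(all(vapply(fits, function(f) f$retained, integer(1)) != 1))
  expect_true(all(!is.na(res$correct)))
})

test_that("pearson correlation matrices are never indefinite", {
  set.seed(33)
  for (i in 1:5) {
    m <- build_population_model(pa_grid()[sample.int(288, 1), ])
    x <- simulate_responses(m, n = 150, seed = i)
    expect_true(pearson_matrix(x)$is_pd)
  }
})

test_that("smoothing arms agree on replicates with PD observed matrices", {
  cond <- condition_spec(
    n_major_factors = 1, vars_per_factor = 5, n_respondents = 500,
    n_categories = 3, skewed = FALSE
  )
  res <- run_condition(cond,
    methods = pa_methods(arms = c("kb", "by", "higham", "raw"), extraction = "pca", criterion = "p95"),
    n_replicates = 3, n_draws = 20, seed = 77
  )
  pd_reps <- res %>%
    dplyr::filter(!.data$indefinite) %>%
    dplyr::group_by(.data$replicate) %>%
    dplyr::summarise(n_distinct_retained = dplyr::n_distinct(.data$retained))
  expect_true(all(pd_reps$n_distinct_retained == 1))
})

test_that("study runner enumerates, checkpoints and resumes", {
  g <- pa_grid(
    n_major_factors = 1, vars_per_factor = 5, n_respondents = 200,
    n_categories = 2, skewed = FALSE, minors_present = FALSE
  )
  expect_equal(nrow(g), 2) # high and medium loadings
  dir <- file.path(tempdir(), "ordipa-ckpt-test")
  unlink(dir, recursive = TRUE)
  methods <- pa_methods(arms = "pearson", extraction = "pca", criterion = "p95")
  r1 <- run_study(g, methods = methods, n_replicates = 2, n_draws = 10, seed = 3, checkpoint_dir = dir)
  expect_equal(sort(unique(r1$condition)), 1:2)
  expect_true(file.exists(file.path(dir, "condition-001.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # resuming from checkpoints reproduces the same cells
  r2 <- run_study(g, methods = methods, n_replicates = 2, n_draws = 10, seed = 3, checkpoint_dir = dir)
  expect_equal(r1$correct, r2$correct)
  expect_equal(r1$retained, r2$retained)
  # a corrupt checkpoint is recomputed, not trusted
  writeLines("garbage", file.path(dir, "condition-002.csv"))
  r3 <- run_study(g, methods = methods, n_replicates = 2, n_draws = 10, seed = 3, checkpoint_dir = dir)
  expect_equal(r3$retained, r1$retained)
  unlink(dir, recursive = TRUE)
  expect_error(run_study(g[0, ]), "empty")
})

test_that("tabulation computes percent-correct marginals", {
  # hand-built results: one condition, 10 replicates, 7 correct
  fake <- tibble::tibble(
    n_major_factors = 1L, vars_per_factor = 5L, n_respondents = 200L,
    n_categories = 2L, skewed = FALSE, minors_present = FALSE,
    loading_level = "high",
    method = "PCA95Pear", replicate = 1:10,
    retained = c(rep(1L, 7), rep(2L, 3)),
    correct = c(rep(TRUE, 7), rep(FALSE, 3)),
    failed = FALSE, indefinite = FALSE, condition = 1L
  )
  tab <- tabulate_study(fake)
  expect_equal(tab$major_1[tab$method == "PCA95Pear"], 70)
  expect_equal(tab$n_200[tab$method == "PCA95Pear"], 70)
  expect_equal(tab$major_1[tab$method == "% Ind. Matrices"], 0)
  prov <- attr(tab, "n_datasets")
  expect_true(all(prov$n_datasets[prov$method == "PCA95Pear"] == 10))
  # all-correct results give 100 everywhere
  fake2 <- dplyr::mutate(fake, correct = TRUE)
  tab2 <- tabulate_study(fake2)
  expect_true(all(tab2[tab2$method == "PCA95Pear", -1] == 100))
})

test_that("overall summary pools replicates with equal weight", {
  fake <- dplyr::bind_rows(
    tibble::tibble(
      condition = 1L, replicate = 1:4, method = "PCA95Pear",
      correct = TRUE, failed = FALSE, indefinite = FALSE
    ),
    tibble::tibble(
      condition = 2L, replicate = 1:4, method = "PCA95Pear",
      correct = FALSE, failed = FALSE, indefinite = TRUE
    )
  )
  s <- overall_summary(fake)
  expect_equal(s$accuracy$percent_correct, 50)
  expect_equal(s$indefinite_rate, 50)
})

test_that("indefinite polychoric matrices arise more often under skew", {
  # matched small-sample binary three-factor conditions, aggregate over reps
  base <- list(
    n_major_factors = 3, vars_per_factor = 5, n_respondents = 200,
    n_categories = 2, minors_present = FALSE, loading_level = "high"
  )
  count_indef <- function(skewed, seed) {
    spec <- do.call(condition_spec, c(base, list(skewed = skewed)))
    n <- 0L
    for (r in 1:12) {
      x <- with_seed <- withr::with_seed(seed + r, {
        m <- build_population_model(spec)
        simulate_responses(m)
      })
      if (!polychoric_matrix(x)$is_pd) n <- n + 1L
    }
    n
  }
  expect_gte(count_indef(TRUE, 400), count_indef(FALSE, 400))
  expect_gt(count_indef(TRUE, 400), 0)
})
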