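#' Method arms for the Monte-Carlo study
#'
#' Builds the grid of parallel-analysis variants to run per simulated
#' dataset.  An "arm" names the correlation/smoothing combination:
#' `"kb"` (polychoric, eigenvalue clipping), `"by"` (polychoric,
#' Heywood-variable rescaling), `"higham"` (polychoric, nearest correlation
#' matrix), `"raw"` (polychoric, unsmoothed/indefinite) and `"pearson"`.
#' Labels follow the `PCA95KB` / `PAFAmPear` convention: extraction, then
#' criterion (`95` = Glorfeld 95th percentile, `m` = Horn mean), then arm.
#'
#' @param arms Character subset of `c("kb", "by", "higham", "raw", "pearson")`.
#' @param extraction Character subset of `c("pca", "pafa")`.
#' @param criterion Character subset of `c("p95", "mean")`.
#' @return A tibble with columns `method`, `extraction`, `criterion`,
#'   `correlation`, `smoothing`, ordered arm-major as in the study tables.
#' @examples
#' pa_methods()
#' pa_methods(arms = "pearson", extraction = "pca")
#' @export
pa_methods <- function(arms = c("kb", "by", "pearson"),
                       extraction = c("pca", "pafa"),
                       criterion = c("p95", "mean")) {
  arm_info <- list(
    kb = list(label = "KB", correlation = "polychoric", smoothing = "knol_berger"),
    by = list(label = "BY", correlation = "polychoric", smoothing = "bentler_yuan"),
    higham = list(label = "Hig", correlation = "polychoric", smoothing = "higham"),
    raw = list(label = "Ind", correlation = "polychoric", smoothing = "none"),
    pearson = list(label = "Pear", correlation = "pearson", smoothing = "none")
  )
  arms <- match.arg(arms, names(arm_info), several.ok = TRUE)
  extraction <- match.arg(extraction, c("pca", "pafa"), several.ok = TRUE)
  criterion <- match.arg(criterion, c("p95", "mean"), several.ok = TRUE)
  rows <- list()
  for (arm in arms) {
    info <- arm_info[[arm]]
    for (ex in c("pca", "pafa")) {
      if (!ex %in% extraction) next
      for (cr in c("p95", "mean")) {
        if (!cr %in% criterion) next
        rows[[length(rows) + 1]] <- tibble(
          method = paste0(
            toupper(ex), if (cr == "p95") "95" else "m", info$label
          ),
          extraction = ex, criterion = cr,
          correlation = info$correlation, smoothing = info$smoothing
        )
      }
    }
  }
  bind_rows(rows)
}

# All PA arms for one simulated dataset, sharing the permutation draws and
# the (expensive) correlation matrices across methods.
run_replicate_ <- function(spec, methods, n_draws, delta, max_failure_rate) {
  model <- build_population_model(spec)
  x <- simulate_responses(model)
  perms <- replicate(n_draws, permute_columns(x), simplify = FALSE)

  cors <- list()
  for (cr in unique(methods$correlation)) {
    fit <- if (cr == "pearson") pearson_matrix else polychoric_matrix
    obs <- tryCatch(fit(x), error = function(e) e)
    ref <- map(perms, function(p) tryCatch(fit(p)$matrix, error = function(e) NULL))
    cors[[cr]] <- list(obs = obs, ref = ref)
  }
  poly_obs <- cors[["polychoric"]]$obs
  indefinite <- if (inherits(poly_obs, "cor_estimate")) !poly_obs$is_pd else NA

  cache <- new.env(parent = emptyenv())
  smoothed_mats <- function(cr, sm) {
    key <- paste0("sm|", cr, "|", sm)
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    smf <- smoother_for(sm, delta = delta)
    app <- function(m) {
      if (is.null(m)) {
        return(NULL)
      }
      if (is.null(smf)) m else tryCatch(smf(m)$matrix, error = function(e) NULL)
    }
    obs <- cors[[cr]]$obs
    val <- list(
      obs = if (inherits(obs, "cor_estimate")) app(obs$matrix) else NULL,
      ref = map(cors[[cr]]$ref, app)
    )
    cache[[key]] <- val
    val
  }
  eig_sets <- function(cr, sm, ex) {
    key <- paste0("ev|", cr, "|", sm, "|", ex)
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    mats <- smoothed_mats(cr, sm)
    extract <- if (ex == "pca") eigenvalues_pca else eigenvalues_pafa
    ev_of <- function(m) {
      if (is.null(m)) {
        return(NULL)
      }
      tryCatch(extract(m), error = function(e) NULL)
    }
    val <- list(obs = ev_of(mats$obs), ref = purrr::compact(map(mats$ref, ev_of)))
    cache[[key]] <- val
    val
  }

  one_method <- function(method, extraction, criterion, correlation, smoothing) {
    ev <- eig_sets(correlation, smoothing, extraction)
    n_failed <- n_draws - length(ev$ref)
    failed <- is.null(ev$obs) || n_failed > max_failure_rate * n_draws
    retained <- NA_integer_
    if (!failed) {
      thr <- criterion_thresholds(do.call(rbind, ev$ref), criterion)
      retained <- retained_dimensions(ev$obs, thr)
    }
    tibble(
      method = method, extraction = extraction, criterion = criterion,
      correlation = correlation, smoothing = smoothing,
      retained = retained, failed = failed, n_failed_draws = n_failed
    )
  }
  res <- pmap(methods, one_method) %>% bind_rows()
  res$correct <- !res$failed & !is.na(res$retained) &
    res$retained == spec$n_major_factors
  res$indefinite <- indefinite
  res
}

#' Run all method arms on one simulation condition
#'
#' Simulates `n_replicates` datasets under the condition (rebuilding the
#' population model per replicate so minor-factor loadings are redrawn) and
#' runs every configured parallel-analysis variant on each.  Permutation
#' draws and correlation matrices are shared across arms within a replicate.
#' A replicate counts as correct for a method iff the retained dimension
#' count equals the condition's number of major factors; indefiniteness of
#' the observed polychoric matrix is recorded once per replicate.
#'
#' @param spec One-row condition tibble ([condition_spec()] or a [pa_grid()]
#'   row).
#' @param methods Method tibble from [pa_methods()].
#' @param n_replicates Simulated datasets per condition (study default 100).
#' @param n_draws Permutation reference draws per dataset (study default 100).
#' @param seed Master seed; replicate `r` runs under the derived seed
#'   `derive_seed(seed, r)`, so conditions can be distributed safely.
#' @param delta Eigenvalue floor for the clipping smoother.
#' @param max_failure_rate Tolerated fraction of failed reference draws.
#' @return A tibble with one row per replicate x method: the design columns,
#'   `replicate`, `rep_seed`, `method`, `retained`, `correct`, `failed`,
#'   `indefinite`, `n_failed_draws`.
#' @examples
#' \donttest{
#' res <- run_condition(condition_spec(), n_replicates = 2, n_draws = 10, seed = 1)
#' dplyr::count(res, method, correct)
#' }
#' @export
run_condition <- function(spec, methods = pa_methods(), n_replicates = 100L,
                          n_draws = 100L, seed = 1L, delta = 0.1,
                          max_failure_rate = 0.25) {
  spec <- as_condition_spec(spec)
  stopifnot(n_replicates >= 1)
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, r)
    res <- with_seed_(
      rep_seed,
      run_replicate_(spec, methods, n_draws, delta, max_failure_rate)
    )
    res$replicate <- r
    res$rep_seed <- rep_seed
    out[[r]] <- res
  }
  res <- bind_rows(out)
  dplyr::bind_cols(spec[rep(1, nrow(res)), ], res)
}

#' Run the Monte-Carlo study over a condition grid
#'
#' Executes [run_condition()] for every row of `grid` under per-condition
#' derived seeds.  With `checkpoint_dir`, per-condition results are written
#' as CSV and finished conditions are skipped on re-run (corrupt checkpoint
#' files are recomputed); a `manifest.json` records seeds, configuration and
#' timestamps.
#'
#' @param grid Condition tibble, e.g. [pa_grid()] or a filtered subset.
#' @inheritParams run_condition
#' @param checkpoint_dir Optional directory for resumable per-condition
#'   checkpoints and the run manifest.
#' @param verbose Print per-condition progress.
#' @return A tibble of per-replicate, per-method results with a `condition`
#'   index column.
#' @examples
#' \donttest{
#' g <- pa_grid(n_major_factors = 1, vars_per_factor = 5, n_respondents = 200,
#'              n_categories = 2, minors_present = FALSE, loading_level = "high")
#' res <- run_study(g, n_replicates = 2, n_draws = 10, seed = 1)
#' }
#' @export
run_study <- function(grid, methods = pa_methods(), n_replicates = 100L,
                      n_draws = 100L, seed = 1L, delta = 0.1,
                      checkpoint_dir = NULL, verbose = FALSE,
                      max_failure_rate = 0.25) {
  if (nrow(grid) == 0) abort("`grid` is empty.")
  started <- Sys.time()
  cond_seeds <- vapply(seq_len(nrow(grid)), function(i) derive_seed(seed, 0L, i), integer(1))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cp <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("condition-%03d.csv", i))
    }
    res <- NULL
    if (!is.null(cp) && file.exists(cp)) {
      res <- tryCatch(read_condition_checkpoint(cp), error = function(e) NULL)
    }
    if (is.null(res)) {
      res <- run_condition(grid[i, ],
        methods = methods, n_replicates = n_replicates,
        n_draws = n_draws, seed = cond_seeds[i], delta = delta,
        max_failure_rate = max_failure_rate
      )
      if (!is.null(cp)) readr::write_csv(res, cp)
    }
    res$condition <- i
    out[[i]] <- res
    if (verbose) {
      message(sprintf(
        "condition %d/%d: %.1f%% correct overall", i, nrow(grid),
        100 * mean(res$correct, na.rm = TRUE)
      ))
    }
  }
  results <- bind_rows(out)
  if (!is.null(checkpoint_dir)) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("ordipa")),
      master_seed = seed,
      condition_seeds = cond_seeds,
      n_conditions = nrow(grid),
      n_replicates = n_replicates,
      n_draws = n_draws,
      delta = delta,
      methods = as.list(methods$method),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(checkpoint_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  results
}

read_condition_checkpoint <- function(path) {
  res <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("method", "retained", "correct", "failed", "indefinite", "replicate")
  if (!all(needed %in% names(res)) || nrow(res) == 0) {
    abort("Corrupt checkpoint file.")
  }
  res
}

#' Tabulate accuracy marginals in the study-table layout
#'
#' Summarises per-replicate results as the percentage of datasets in which
#' the number of major factors was detected exactly, marginal over each
#' design factor in turn (number of major factors, variables per factor,
#' respondents, response categories), one row per method plus a final
#' `% Ind. Matrices` row with the share of replicates whose observed
#' polychoric matrix was indefinite.  Typically called on a subset of
#' conditions, e.g. symmetric response distributions without minor factors.
#'
#' @param results Result tibble from [run_study()] or [run_condition()].
#' @param digits Rounding for the percentage cells.
#' @return A wide tibble (rows = methods in `results` order, columns =
#'   margin levels such as `major_1`, `vpf_15`, `n_500`, `cat_2`).  The
#'   attribute `"n_datasets"` holds a long tibble with the replicate count
#'   behind every cell.
#' @examples
#' \donttest{
#' res <- run_condition(condition_spec(), n_replicates = 2, n_draws = 10, seed = 1)
#' tabulate_study(res)
#' }
#' @export
tabulate_study <- function(results, digits = 2) {
  if (nrow(results) == 0) abort("`results` is empty.")
  if (!"condition" %in% names(results)) results$condition <- 1L
  margins <- c(
    n_major_factors = "major", vars_per_factor = "vpf",
    n_respondents = "n", n_categories = "cat"
  )
  method_order <- unique(results$method)
  cells <- list()
  prov <- list()
  for (mvar in names(margins)) {
    lv <- sort(unique(results[[mvar]]))
    for (l in lv) {
      sub <- results[results[[mvar]] == l, ]
      acc <- sub %>%
        group_by(.data$method) %>%
        summarise(
          value = round(100 * mean(.data$correct, na.rm = TRUE), digits),
          n_datasets = sum(!is.na(.data$correct)),
          .groups = "drop"
        )
      ind <- sub %>%
        distinct(.data$condition, .data$replicate, .data$indefinite) %>%
        summarise(
          value = round(100 * mean(.data$indefinite, na.rm = TRUE), digits),
          n_datasets = dplyr::n()
        )
      col <- paste0(margins[[mvar]], "_", l)
      cells[[col]] <- c(
        setNames(acc$value, acc$method),
        setNames(ind$value, "% Ind. Matrices")
      )
      prov[[col]] <- tibble(
        column = col, margin = mvar, level = l,
        method = c(acc$method, "% Ind. Matrices"),
        n_datasets = c(acc$n_datasets, ind$n_datasets)
      )
    }
  }
  rows <- c(method_order, "% Ind. Matrices")
  tab <- tibble(method = rows)
  for (col in names(cells)) {
    tab[[col]] <- unname(cells[[col]][rows])
  }
  attr(tab, "n_datasets") <- bind_rows(prov)
  tab
}

#' Pooled accuracy and indefinite rate
#'
#' Pools all replicates with equal weight: per-method percentage of datasets
#' with the correct number of major factors, and the overall percentage of
#' replicates with an indefinite observed polychoric matrix.
#'
#' @param results Result tibble from [run_study()] or [run_condition()].
#' @return A list with `accuracy` (tibble: `method`, `percent_correct`,
#'   `n_datasets`) and `indefinite_rate` (scalar percentage).
#' @examples
#' \donttest{
#' res <- run_condition(condition_spec(), n_replicates = 2, n_draws = 10, seed = 1)
#' overall_summary(res)
#' }
#' @export
overall_summary <- function(results) {
  if (nrow(results) == 0) abort("`results` is empty.")
  if (!"condition" %in% names(results)) results$condition <- 1L
  accuracy <- results %>%
    group_by(.data$method) %>%
    summarise(
      percent_correct = 100 * mean(.data$correct, na.rm = TRUE),
      percent_correct_completed = 100 * mean(.data$correct[!.data$failed], na.rm = TRUE),
      n_datasets = dplyr::n(),
      n_failed = sum(.data$failed, na.rm = TRUE),
      .groups = "drop"
    )
  ind <- results %>%
    distinct(.data$condition, .data$replicate, .data$indefinite)
  list(
    accuracy = accuracy,
    indefinite_rate = 100 * mean(ind$indefinite, na.rm = TRUE)
  )
}
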