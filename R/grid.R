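#' Enumerate the factorial simulation grid
#'
#' Builds the full factorial crossing of the seven design factors of the
#' ordinal-item simulation study: number of major factors, variables per
#' factor, respondent sample size, response categories, skewness of the
#' response distribution, presence of 40 weak minor factors, and the strength
#' of the major-factor loadings.  The default levels yield the complete
#' 2 x 2 x 3 x 3 x 2 x 2 x 2 = 288-condition design.
#'
#' @param n_major_factors Integer levels for the number of major factors.
#' @param vars_per_factor Integer levels for the number of items per factor.
#' @param n_respondents Integer levels for the respondent sample size.
#' @param n_categories Integer levels for the number of response categories
#'   (2, 3 or 4 are supported downstream).
#' @param skewed Logical levels: symmetric (`FALSE`) and/or skewed (`TRUE`)
#'   category frequencies.
#' @param minors_present Logical levels: whether 40 minor nuisance factors are
#'   added to the population model.
#' @param loading_level Character levels, `"high"` (50\% of latent variance
#'   from major factors) and/or `"medium"` (30\%).
#'
#' @return A tibble with one row per condition, in deterministic order, with
#'   columns named after the seven design factors.
#' @examples
#' nrow(pa_grid())  # 288
#' pa_grid(n_major_factors = 1, minors_present = FALSE)
#' @export
pa_grid <- function(n_major_factors = c(1L, 3L),
                    vars_per_factor = c(5L, 15L),
                    n_respondents = c(200L, 500L, 1000L),
                    n_categories = c(2L, 3L, 4L),
                    skewed = c(FALSE, TRUE),
                    minors_present = c(FALSE, TRUE),
                    loading_level = c("high", "medium")) {
  loading_level <- match.arg(loading_level, c("high", "medium"), several.ok = TRUE)
  grid <- tidyr::expand_grid(
    n_major_factors = as.integer(n_major_factors),
    vars_per_factor = as.integer(vars_per_factor),
    n_respondents = as.integer(n_respondents),
    n_categories = as.integer(n_categories),
    skewed = as.logical(skewed),
    minors_present = as.logical(minors_present),
    loading_level = loading_level
  )
  grid
}

#' Construct a single simulation condition
#'
#' Validates one cell of the simulation design (see [pa_grid()]).
#'
#' @inheritParams pa_grid
#' @return A one-row tibble.
#' @examples
#' condition_spec(n_major_factors = 3, vars_per_factor = 5, n_categories = 2)
#' @export
condition_spec <- function(n_major_factors = 1L,
                           vars_per_factor = 5L,
                           n_respondents = 500L,
                           n_categories = 2L,
                           skewed = FALSE,
                           minors_present = FALSE,
                           loading_level = "high") {
  spec <- tibble(
    n_major_factors = as.integer(n_major_factors),
    vars_per_factor = as.integer(vars_per_factor),
    n_respondents = as.integer(n_respondents),
    n_categories = as.integer(n_categories),
    skewed = as.logical(skewed),
    minors_present = as.logical(minors_present),
    loading_level = match.arg(loading_level, c("high", "medium"))
  )
  validate_condition_spec(spec)
  spec
}

validate_condition_spec <- function(spec) {
  needed <- c(
    "n_major_factors", "vars_per_factor", "n_respondents", "n_categories",
    "skewed", "minors_present", "loading_level"
  )
  missing <- setdiff(needed, names(spec))
  if (length(missing) > 0) {
    abort(paste0("Condition spec lacks fields: ", paste(missing, collapse = ", ")))
  }
  if (nrow(as_tibble(spec[needed])) != 1) {
    abort("Condition spec must describe exactly one condition.")
  }
  stopifnot(
    spec$n_major_factors >= 1, spec$vars_per_factor >= 2,
    spec$n_respondents >= 1, spec$n_categories %in% 2:4,
    spec$loading_level %in% c("high", "medium")
  )
  invisible(spec)
}

as_condition_spec <- function(spec) {
  if (is.list(spec) && !is.data.frame(spec)) spec <- as_tibble(spec[!vapply(spec, is.null, TRUE)])
  spec <- as_tibble(spec)
  validate_condition_spec(spec)
  spec
}
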