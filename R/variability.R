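#' Fano factor of an intensity trace
#'
#' Variance-to-mean ratio of a cell's spot-intensity time series, used as
#' a noise-to-signal measure. The variance uses divisor `n` by default
#' (the trace is the full observation, not a sample of a longer
#' stationary record); set `unbiased = TRUE` for divisor `n - 1`. The
#' ratio is undefined (NA, `defined = FALSE`) when the mean is not
#' positive.
#'
#' @param x an [intensity_trace()] or a numeric vector of intensities
#'   (>= 2 values).
#' @param unbiased use the n - 1 variance divisor.
#' @return List of class `variability_stats` with `mean`, `variance`,
#'   `fano`, `defined`.
#' @export
fano_factor <- function(x, unbiased = FALSE) {
  if (inherits(x, "intensity_trace")) x <- x$intensities
  stopifnot(is.numeric(x), length(x) >= 2)
  mu <- mean(x)
  v <- stats::var(x)
  if (!unbiased) v <- v * (length(x) - 1) / length(x)
  defined <- mu > 0
  structure(list(mean = mu, variance = v,
                 fano = if (defined) v / mu else NA_real_,
                 defined = defined),
            class = "variability_stats")
}

## Shared OLS helper returning slope/intercept/r2.
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-12) {
    e <- simpleError("singular fit: predictor has no variation")
    class(e) <- c("singular_fit", class(e))
    stop(e)
  }
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       n = length(x))
}

#' Fano factor versus mean intensity regression
#'
#' Ordinary least squares of per-cell Fano factor on per-cell mean spot
#' intensity; the slope measures how fast intra-cell variability grows
#' with expression level within a group of cells (e.g. one
#' differentiation stage).
#'
#' @param mean_intensity,fano numeric vectors (>= 3 cells with defined
#'   Fano factors).
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fano_mean_regression <- function(mean_intensity, fano) {
  ok <- is.finite(mean_intensity) & is.finite(fano)
  res <- ols_fit(mean_intensity[ok], fano[ok])
  structure(res, class = "regression_result")
}

#' Relative transcriptional variability per stage
#'
#' Ratio of each stage's Fano-versus-mean regression slope to the slope of
#' all cells pooled (observed over expected).
#'
#' @param stage_slopes named numeric vector of per-stage slopes.
#' @param pooled_slope slope of the pooled regression (non-zero).
#' @return Named numeric vector of ratios.
#' @export
relative_variability <- function(stage_slopes, pooled_slope) {
  if (!is.numeric(pooled_slope) || pooled_slope == 0)
    stop("pooled slope must be non-zero")
  stage_slopes / pooled_slope
}

#' Variance in mean intensity explained by ON fraction
#'
#' r-squared of the OLS regression of per-cell mean spot intensity on
#' per-cell ON fraction.
#'
#' @param on_fraction,mean_intensity numeric vectors (>= 3 cells).
#' @return r-squared in \[0, 1\].
#' @export
explained_variance <- function(on_fraction, mean_intensity) {
  ols_fit(on_fraction, mean_intensity)$r_squared
}

#' Bootstrap percentile confidence interval for the median
#'
#' Resamples `subsample_n` values with replacement `n_resamples` times and
#' takes the 2.5th and 97.5th percentiles of the resampled medians. The
#' default subsample size of 31 matches the smallest per-stage cell count
#' the procedure was designed around, so stages of unequal size are
#' compared at equal bootstrap resolution.
#'
#' @param values numeric vector (non-empty).
#' @param subsample_n resample size (drawn with replacement).
#' @param n_resamples number of bootstrap resamples.
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return List of class `bootstrap_ci`: `point_median`, `ci_low`,
#'   `ci_high`, `n_resamples`, `subsample_n`, `seed`.
#' @export
bootstrap_median_ci <- function(values, subsample_n = 31,
                                n_resamples = 10000, seed = NULL,
                                conf = 0.95) {
  stopifnot(length(values) >= 1, subsample_n >= 1, n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(sample(values, subsample_n * n_resamples, replace = TRUE),
                  nrow = subsample_n)
  meds <- apply(draws, 2, stats::median)
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(list(point_median = stats::median(values),
                 ci_low = qs[1], ci_high = qs[2],
                 n_resamples = n_resamples, subsample_n = subsample_n,
                 seed = seed),
            class = "bootstrap_ci")
}

#' Pairwise Mann-Whitney comparisons between stages
#'
#' Two-sided Mann-Whitney U tests between the requested pairs of groups
#' (by default the early-versus-peak and peak-versus-late contrasts
#' DS1 vs DS4 and DS4 vs DS6). No multiple-testing correction is applied
#' by default; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param groups named list of numeric vectors (each >= 3 values for the
#'   tested pairs).
#' @param pairs list of length-2 character vectors naming group pairs;
#'   default all consecutive of `c("DS1","DS4")`, `c("DS4","DS6")` when
#'   present, else all pairs.
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (default) mirrors uncorrected
#'   reporting.
#' @return data.frame with columns `group1`, `group2`, `U`, `p_value`.
#' @export
compare_stages <- function(groups, pairs = NULL, p_adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group supplied")
  nm <- names(groups)
  if (is.null(pairs)) {
    if (all(c("DS1", "DS4", "DS6") %in% nm))
      pairs <- list(c("DS1", "DS4"), c("DS4", "DS6"))
    else
      pairs <- utils::combn(nm, 2, simplify = FALSE)
  }
  res <- lapply(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    stopifnot(length(a) >= 3, length(b) >= 3)
    # exact null distribution for small tie-free samples, normal
    # approximation (with continuity correction) otherwise
    wt <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2],
               U = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
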