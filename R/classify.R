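#' Robust locally weighted regression (LOWESS)
#'
#' Local linear regression with tricube neighbourhood weights and
#' bisquare robustness reweighting, fitted at each requested evaluation
#' point. Conventions (documented for reproducibility): the neighbourhood
#' of an evaluation point is its `k = max(2, ceiling(span * n))` nearest
#' x-values; the tricube bandwidth is the largest neighbour distance (a
#' point whose neighbours are all at distance 0 receives their weighted
#' mean); robustness weights after each of `iter` passes are
#' `(1 - (r / (6 m))^2)^2` for residuals `|r| < 6 m`, `m` the median
#' absolute residual (when `m = 0` the bisquare limit is used: weight 1
#' for exactly fitted points, 0 otherwise).
#'
#' @param x,y numeric vectors of equal length.
#' @param span fraction of points in each local neighbourhood, in (0, 1].
#' @param iter number of bisquare robustifying iterations.
#' @param eval_x evaluation grid; defaults to the sorted unique `x`.
#' @return data.frame with columns `x` (the grid) and `y` (smoothed
#'   values).
#' @export
robust_lowess <- function(x, y, span = 0.3, iter = 3, eval_x = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            span > 0, span <= 1, iter >= 0)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  if (is.null(eval_x)) eval_x <- unique(x)
  rw <- rep(1, n)

  fit_at <- function(x0, rw) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h <= 0) {
      w <- rw * (d == 0)
      if (sum(w) == 0) return(NA_real_)
      return(sum(w * y) / sum(w))
    }
    w <- numeric(n)
    inside <- d < h * (1 + 1e-12)
    w[inside] <- (1 - pmin(d[inside] / h, 1)^3)^3
    w <- w * rw
    sw <- sum(w)
    if (sw == 0) return(NA_real_)
    xw <- sum(w * x) / sw
    yw <- sum(w * y) / sw
    sxx <- sum(w * (x - xw)^2)
    if (sxx <= 1e-12 * sum(w * x^2 + 1e-300)) return(yw)
    b <- sum(w * (x - xw) * (y - yw)) / sxx
    yw + b * (x0 - xw)
  }

  for (pass in seq_len(iter)) {
    fitted_all <- vapply(x, fit_at, numeric(1), rw = rw)
    r <- y - fitted_all
    m <- stats::median(abs(r))
    if (m <= 0) {
      # majority of residuals exactly zero: bisquare limit keeps the
      # perfectly fitted points and drops the rest (e.g. a lone outlier)
      rw <- as.numeric(r == 0)
    } else {
      u <- r / (6 * m)
      rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    }
  }
  data.frame(x = eval_x,
             y = vapply(eval_x, fit_at, numeric(1), rw = rw))
}

#' Smoothed ON duration versus transcriptional output curve
#'
#' Fits the robust LOWESS of per-cell transcriptional output on per-cell
#' ON duration and evaluates it on the sorted grid of observed durations.
#' This curve is the backbone of the behaviour classification: its
#' gradient reflects the average burst amplitude at a given ON duration.
#'
#' @param on_duration,output numeric vectors (>= 20 cells).
#' @param span LOWESS span in (0, 1].
#' @param iter robustifying iterations.
#' @param window total imaging window (min), used to express the
#'   inflection as a fraction of the window.
#' @return List of class `duration_output_curve`: `grid`, `smoothed`,
#'   `span`, `window`.
#' @export
fit_duration_output_curve <- function(on_duration, output, span = 0.3,
                                      iter = 3, window = 60) {
  ok <- is.finite(on_duration) & is.finite(output)
  if (sum(ok) < 20) {
    e <- simpleError("insufficient data: need at least 20 cells")
    class(e) <- c("insufficient_data", class(e))
    stop(e)
  }
  stopifnot(span > 0, span <= 1)
  sm <- robust_lowess(on_duration[ok], output[ok], span = span, iter = iter)
  structure(list(grid = sm$x, smoothed = sm$y, span = span,
                 window = window),
            class = "duration_output_curve")
}

#' Inflection of the duration-output curve
#'
#' Computes the finite-difference gradient of the smoothed curve, lightly
#' smooths it with a running mean, and returns the grid point with the
#' largest positive step in the gradient (maximal positive second
#' difference). When the gradient carries no step (a near-linear curve) a
#' `no_inflection` error is raised.
#'
#' @param curve a `duration_output_curve`.
#' @param smooth_k running-mean window (grid points) applied to the
#'   gradient before differencing.
#' @param min_rel_step minimal gradient step relative to the gradient's
#'   overall range for an inflection to count.
#' @return List: `inflection_duration` (min), `inflection_fraction`
#'   (duration / window), `index`.
#' @export
find_inflection <- function(curve, smooth_k = 5, min_rel_step = 0.05) {
  g <- unique(data.frame(x = curve$grid, y = curve$smoothed))
  if (nrow(g) < 10) stop("need at least 10 distinct grid points")
  grad <- diff(g$y) / diff(g$x)
  k <- max(1L, as.integer(smooth_k))
  gs <- stats::filter(grad, rep(1 / k, k), sides = 2)
  gs[is.na(gs)] <- grad[is.na(gs)]
  gs <- as.numeric(gs)
  step <- diff(gs)
  rng <- max(gs) - min(gs)
  scale <- max(abs(gs), 1e-12)
  no_inf <- function() {
    e <- simpleError("no inflection: gradient has no positive step")
    class(e) <- c("no_inflection", class(e))
    stop(e)
  }
  if (rng <= 1e-8 * scale) no_inf()
  i <- which.max(step)
  if (step[i] <= min_rel_step * rng) no_inf()
  # gradient step between segments i and i+1 -> knee at grid point i + 1
  xi <- g$x[i + 1]
  list(inflection_duration = xi,
       inflection_fraction = xi / curve$window,
       index = i + 1L)
}

#' Split cells into High-ON and Low-ON groups
#'
#' `HIGH_ON` when the ON duration strictly exceeds the inflection
#' duration; ties go to `LOW_ON`.
#'
#' @param on_duration numeric vector (min).
#' @param inflection_duration inflection of the duration-output curve
#'   (min).
#' @return factor with levels `LOW_ON`, `HIGH_ON`.
#' @export
split_high_low_on <- function(on_duration, inflection_duration) {
  factor(ifelse(on_duration > inflection_duration, "HIGH_ON", "LOW_ON"),
         levels = c("LOW_ON", "HIGH_ON"))
}

#' Quadratic fit to the basal (Low-ON) duration-output relation
#'
#' Least-squares quadratic through the Low-ON segment of the smoothed
#' duration-output curve; extrapolated over the full duration range it
#' estimates the transcriptional output a basal-amplitude cell of any ON
#' duration would produce.
#'
#' @param grid,smoothed Low-ON portion of the LOWESS grid and values
#'   (>= 3 distinct durations).
#' @return List of class `basal_quadratic`: `coefficients` `(a, b, c)` of
#'   `a d^2 + b d + c`, `domain`, and `predict(d)` via
#'   [predict.basal_quadratic()].
#' @export
fit_basal_quadratic <- function(grid, smoothed) {
  ok <- is.finite(grid) & is.finite(smoothed)
  grid <- grid[ok]; smoothed <- smoothed[ok]
  if (length(unique(grid)) < 3) {
    e <- simpleError("singular fit: need >= 3 distinct durations")
    class(e) <- c("singular_fit", class(e))
    stop(e)
  }
  fit <- stats::lm(smoothed ~ grid + I(grid^2))
  cf <- stats::coef(fit)
  structure(list(coefficients = c(a = unname(cf[3]), b = unname(cf[2]),
                                  c = unname(cf[1])),
                 domain = range(grid)),
            class = "basal_quadratic")
}

#' @rdname fit_basal_quadratic
#' @param object a `basal_quadratic`.
#' @param d ON durations at which to evaluate (extrapolation allowed).
#' @param ... unused.
#' @export
predict.basal_quadratic <- function(object, d, ...) {
  cf <- object$coefficients
  unname(cf["a"] * d^2 + cf["b"] * d + cf["c"])
}

#' Classify bursting behaviour from the basal amplitude deviation score
#'
#' Each cell's deviation score is the residual of its transcriptional
#' output from the basal quadratic at the same ON duration, normalised by
#' the ON duration (cells with zero ON duration score 0: a silent gene
#' exhibits no amplitude). The high-amplitude threshold is the median
#' plus one standard deviation of the Low-ON cells' scores; cells above
#' it are `HIGH_AMPLITUDE`. Final classes: `BASAL` for basal amplitude
#' (whether Low or High ON), `HIGH_ON_HIGH_AMP`, `LOW_ON_HIGH_AMP`.
#'
#' @param cells data.frame with columns `cell_id`, `on_duration`,
#'   `output`, `on_group` (factor from [split_high_low_on()]).
#' @param basal_quadratic a [fit_basal_quadratic()] result.
#' @return List: `cells` (input plus `deviation_score`, `amplitude_group`,
#'   `final_class`) and `threshold` (the deviation-score cut used).
#' @export
classify_behaviour <- function(cells, basal_quadratic) {
  stopifnot(all(c("cell_id", "on_duration", "output", "on_group")
                %in% names(cells)))
  expected <- predict(basal_quadratic, cells$on_duration)
  score <- ifelse(cells$on_duration > 0,
                  (cells$output - expected) / cells$on_duration, 0)
  low <- cells$on_group == "LOW_ON"
  if (!any(low)) {
    e <- simpleError("cannot calibrate: no Low-ON cells")
    class(e) <- c("cannot_calibrate", class(e))
    stop(e)
  }
  threshold <- stats::median(score[low]) + stats::sd(score[low])
  amp <- factor(ifelse(score > threshold, "HIGH_AMPLITUDE", "BASAL"),
                levels = c("BASAL", "HIGH_AMPLITUDE"))
  final <- ifelse(amp == "BASAL", "BASAL",
                  ifelse(cells$on_group == "HIGH_ON",
                         "HIGH_ON_HIGH_AMP", "LOW_ON_HIGH_AMP"))
  out <- cells
  out$deviation_score <- score
  out$amplitude_group <- amp
  out$final_class <- factor(final, levels = c("BASAL", "HIGH_ON_HIGH_AMP",
                                              "LOW_ON_HIGH_AMP"))
  list(cells = out, threshold = threshold)
}

#' End-to-end behaviour classification of a burst-summary table
#'
#' Convenience wrapper: fits the duration-output LOWESS, finds the
#' inflection, splits High/Low ON, fits the basal quadratic on the
#' Low-ON portion of the smoothed curve and classifies every cell.
#'
#' @param summary data.frame with columns `cell_id`, `on_duration`,
#'   `output` (e.g. from [summarize_bursts_all()]).
#' @param span,iter LOWESS settings.
#' @param window imaging window (min).
#' @return List: `cells`, `threshold`, `curve`, `inflection`,
#'   `basal_quadratic`.
#' @export
classify_population <- function(summary, span = 0.3, iter = 3, window = 60) {
  curve <- fit_duration_output_curve(summary$on_duration, summary$output,
                                     span = span, iter = iter,
                                     window = window)
  infl <- find_inflection(curve)
  on_group <- split_high_low_on(summary$on_duration,
                                infl$inflection_duration)
  low_grid <- curve$grid <= infl$inflection_duration
  quad <- fit_basal_quadratic(curve$grid[low_grid],
                              curve$smoothed[low_grid])
  cl <- classify_behaviour(
    data.frame(cell_id = summary$cell_id,
               on_duration = summary$on_duration,
               output = summary$output, on_group = on_group,
               stringsAsFactors = FALSE),
    quad)
  c(cl, list(curve = curve, inflection = infl, basal_quadratic = quad))
}

#' Per-stage proportions of bursting behaviours
#'
#' @param stage factor/character of stage labels per cell.
#' @param final_class factor of behaviour classes per cell.
#' @return List: `proportions` (stages x classes, rows summing to 1; NA
#'   rows for empty stages) and `counts`.
#' @export
stage_proportions <- function(stage, final_class) {
  stopifnot(length(stage) == length(final_class))
  counts <- table(stage = stage, class = final_class)
  totals <- rowSums(counts)
  props <- sweep(counts, 1, totals, "/")
  props[totals == 0, ] <- NA_real_
  list(proportions = props, counts = counts)
}
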