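#' ON intervals of a trace by linear interpolation against a threshold
#'
#' The trace is treated as a piecewise-linear interpolant between samples;
#' threshold crossings are solved exactly on each segment. A sample lying
#' exactly at the threshold counts as ON (intervals are closed and the
#' threshold response is right-continuous). Zero-length touches (the
#' interpolant reaching the threshold at a single instant from below) are
#' dropped. Intervals are clipped to the observation window.
#'
#' @param trace an [intensity_trace()].
#' @param threshold ON/OFF threshold (a.u.); default 350.
#' @return data.frame with columns `start`, `end` (min); zero rows if the
#'   trace never reaches the threshold.
#' @export
find_on_intervals <- function(trace, threshold = 350) {
  stopifnot(inherits(trace, "intensity_trace"))
  t <- trace$times
  f <- trace$intensities - threshold
  n <- length(t)
  starts <- numeric(0); ends <- numeric(0)
  open <- NA_real_   # start of the interval currently being built
  if (f[1] >= 0) open <- t[1]
  for (i in seq_len(n - 1)) {
    f1 <- f[i]; f2 <- f[i + 1]
    if (f1 < 0 && f2 >= 0) {          # upward crossing
      tc <- if (f2 == 0) t[i + 1] else t[i] + (t[i + 1] - t[i]) * (-f1) / (f2 - f1)
      open <- tc
    } else if (f1 >= 0 && f2 < 0) {   # downward crossing
      tc <- t[i] + (t[i + 1] - t[i]) * (-f1) / (f2 - f1)
      starts <- c(starts, open); ends <- c(ends, tc)
      open <- NA_real_
    }
    # f1 >= 0 && f2 >= 0: interval continues; f1 < 0 && f2 < 0: nothing
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, t[n]) }
  keep <- (ends - starts) > 0
  data.frame(start = starts[keep], end = ends[keep])
}

## Area of (interpolated trace - threshold)+ over [a, b], where the trace
## is at or above threshold throughout [a, b]. Exact trapezoid integration
## of each linear piece.
interval_area <- function(times, intens, threshold, a, b) {
  val <- function(x) stats::approx(times, intens, xout = x)$y - threshold
  knots <- times[times > a & times < b]
  xs <- c(a, knots, b)
  ys <- val(xs)
  ys <- pmax(ys, 0)  # endpoints at crossings are 0 up to rounding
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Burst statistics of a single trace
#'
#' Converts the ON intervals of a trace into per-burst records and a
#' per-cell summary. A burst is *complete* when the interpolated trace is
#' below the threshold immediately before its start and after its end;
#' intervals touching the window edges are incomplete. Each interval's
#' size is the area between the interpolated trace and the threshold over
#' the interval (a.u. min). The summary's `output` sums the sizes of all
#' intervals, complete and incomplete; `on_fraction` divides total ON time
#' by the full observation window.
#'
#' @param trace an [intensity_trace()].
#' @param threshold ON/OFF threshold (a.u.).
#' @return List with `summary` (data.frame: cell_id, on_fraction,
#'   on_duration, output, n_complete_bursts, n_bursts, mean_intensity) and
#'   `bursts` (data.frame: cell_id, start, end, duration, size, complete).
#' @export
summarize_bursts <- function(trace, threshold = 350) {
  iv <- find_on_intervals(trace, threshold)
  t <- trace$times
  window <- t[length(t)] - t[1]
  if (nrow(iv) > 0) {
    iv$duration <- iv$end - iv$start
    iv$size <- vapply(seq_len(nrow(iv)), function(i)
      interval_area(t, trace$intensities, threshold, iv$start[i], iv$end[i]),
      numeric(1))
    iv$complete <- iv$start > t[1] & iv$end < t[length(t)]
  } else {
    iv$duration <- numeric(0); iv$size <- numeric(0)
    iv$complete <- logical(0)
  }
  summary <- data.frame(
    cell_id = trace$cell_id,
    on_fraction = sum(iv$duration) / window,
    on_duration = sum(iv$duration),
    output = sum(iv$size),
    n_complete_bursts = sum(iv$complete),
    n_bursts = nrow(iv),
    mean_intensity = mean(trace$intensities),
    stringsAsFactors = FALSE)
  bursts <- if (nrow(iv) > 0)
    cbind(data.frame(cell_id = trace$cell_id, stringsAsFactors = FALSE), iv)
  else
    data.frame(cell_id = character(0), start = numeric(0), end = numeric(0),
               duration = numeric(0), size = numeric(0),
               complete = logical(0))
  list(summary = summary, bursts = bursts)
}

#' Burst summaries for a list of traces
#'
#' @param traces list of [intensity_trace()] objects.
#' @param threshold ON/OFF threshold (a.u.).
#' @return List with row-bound `summary` and `bursts` data.frames.
#' @export
summarize_bursts_all <- function(traces, threshold = 350) {
  res <- lapply(traces, summarize_bursts, threshold = threshold)
  list(summary = do.call(rbind, lapply(res, `[[`, "summary")),
       bursts = do.call(rbind, lapply(res, `[[`, "bursts")))
}

#' Complete-burst counts across a grid of ON thresholds
#'
#' Counts complete bursts summed over all traces at each candidate
#' threshold. On a bursting population the count peaks at an intermediate
#' threshold: thresholds below the baseline never see an OFF period, and
#' thresholds above the burst peaks never see a burst.
#'
#' @param traces list of [intensity_trace()] objects.
#' @param thresholds numeric grid of thresholds (a.u.).
#' @return List with `table` (data.frame threshold, n_complete) and
#'   `peak_threshold` (threshold with the maximal count).
#' @export
threshold_sweep <- function(traces, thresholds) {
  stopifnot(length(thresholds) >= 1)
  counts <- vapply(thresholds, function(th) {
    sum(vapply(traces, function(tr)
      summarize_bursts(tr, th)$summary$n_complete_bursts, numeric(1)))
  }, numeric(1))
  list(table = data.frame(threshold = thresholds, n_complete = counts),
       peak_threshold = thresholds[which.max(counts)])
}

#' Information loss of temporal subsampling (RMSE)
#'
#' Subsamples a trace by keeping every k-th sample starting at the first
#' time point (k = `interval` / native spacing, rounded to the nearest
#' achievable multiple), linearly interpolates the subsampled trace back
#' onto the raw time grid (constant extension beyond the last kept
#' sample), and reports the root-mean-squared error over all raw points:
#' `rmse = sqrt(sum((y_sub - y_raw)^2) / n)`.
#'
#' @param trace an [intensity_trace()] with (near-)uniform sampling.
#' @param interval target sampling interval, same units as the trace
#'   times; must be >= the native spacing.
#' @return List of class `subsample_comparison` with `y_raw`, `y_sub`,
#'   `n`, `rmse`, `interval`, `k`.
#' @export
subsample_rmse <- function(trace, interval) {
  t <- trace$times; y <- trace$intensities
  native <- stats::median(diff(t))
  if (interval < native - 1e-9)
    stop("interval must be at least the native sampling interval")
  k <- max(1L, as.integer(round(interval / native)))
  keep <- seq(1L, length(t), by = k)
  y_sub <- stats::approx(t[keep], y[keep], xout = t, rule = 2)$y
  structure(list(y_raw = y, y_sub = y_sub, n = length(y),
                 rmse = sqrt(sum((y_sub - y)^2) / length(y)),
                 interval = interval, k = k),
            class = "subsample_comparison")
}

#' Choose an imaging interval under an information-loss budget
#'
#' For each candidate interval, computes the median per-cell subsampling
#' RMSE over a set of densely sampled reference traces, then recommends
#' the largest candidate whose median RMSE stays within the budget (least
#' light exposure at acceptable information loss). If none qualifies, the
#' smallest candidate is returned with a warning flag.
#'
#' @param traces list of [intensity_trace()] objects (reference sampling).
#' @param candidate_intervals ascending candidate intervals (same time
#'   units as the traces).
#' @param rmse_budget maximal acceptable median RMSE (a.u.).
#' @return List with `recommended`, `within_budget` (logical flag) and
#'   `table` (data.frame interval, median_rmse).
#' @export
select_interval <- function(traces, candidate_intervals, rmse_budget) {
  stopifnot(length(candidate_intervals) >= 1,
            !is.unsorted(candidate_intervals))
  med <- vapply(candidate_intervals, function(iv) {
    stats::median(vapply(traces, function(tr)
      subsample_rmse(tr, iv)$rmse, numeric(1)))
  }, numeric(1))
  ok <- med <= rmse_budget
  if (any(ok)) {
    rec <- max(candidate_intervals[ok])
    flag <- TRUE
  } else {
    rec <- candidate_intervals[1]
    flag <- FALSE
    warning("no candidate interval satisfies the RMSE budget; ",
            "returning the smallest candidate")
  }
  list(recommended = rec, within_budget = flag,
       table = data.frame(interval = candidate_intervals,
                          median_rmse = med))
}
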