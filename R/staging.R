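#' Compressive marker transform
#'
#' Monotone, invertible asinh transform `x' = asinh(x / cofactor)` used to
#' place raw CD71/Ter119 intensities on a biexponential-style display scale
#' before curve projection. For `x >> cofactor` it behaves like
#' `log(2 x / cofactor)`; near zero it is linear.
#'
#' @param x raw intensities (a.u.); negative values are permitted.
#' @param cofactor positive scale parameter (a.u.).
#' @return Transformed values.
#' @export
transform_markers <- function(x, cofactor = 150) {
  stopifnot(cofactor > 0)
  asinh(x / cofactor)
}

#' @rdname transform_markers
#' @export
inverse_transform_markers <- function(x, cofactor = 150) {
  stopifnot(cofactor > 0)
  sinh(x) * cofactor
}

#' Build equal-arc-length differentiation curves
#'
#' Resamples each control-point polyline to `P` points equally spaced along
#' cumulative arc length (equivalent to Matlab's `interparc` for
#' polylines), and attaches the cumulative arc-length fraction of each
#' point.
#'
#' @param families list of numeric matrices, each with >= 2 rows and two
#'   columns (transformed CD71, Ter119 control points in order).
#' @param P number of discretised points per curve (>= 2); default 10000.
#' @return List of `differentiation_curve` objects with fields `curve_id`,
#'   `control_points`, `points` (P x 2 matrix) and `fraction` (arc-length
#'   fraction in \[0, 1\], strictly increasing).
#' @export
build_curve_set <- function(families, P = 10000) {
  stopifnot(is.list(families), length(families) >= 1, P >= 2)
  lapply(seq_along(families), function(i) {
    cp <- as.matrix(families[[i]])
    stopifnot(ncol(cp) == 2, nrow(cp) >= 2)
    seg <- sqrt(rowSums(diff(cp)^2))
    if (any(seg == 0))
      stop("duplicate consecutive control points collapse arc length")
    cum <- c(0, cumsum(seg))
    total <- cum[length(cum)]
    s <- seq(0, total, length.out = P)
    pts <- cbind(stats::approx(cum, cp[, 1], xout = s)$y,
                 stats::approx(cum, cp[, 2], xout = s)$y)
    structure(list(curve_id = i, control_points = cp, points = pts,
                   fraction = s / total),
              class = "differentiation_curve")
  })
}

#' Default differentiation curve family
#'
#' Three trajectories in transformed (asinh) CD71/Ter119 space spanning
#' low, medium and high CD71 starts. Each follows the canonical erythroid
#' marker progression: CD71 rises first while Ter119 stays low, then Ter119
#' rises while CD71 plateaus and finally declines. The family is a package
#' default standing in for empirically drawn curves and can be replaced by
#' any list accepted by [build_curve_set()].
#'
#' @param P number of discretised points per curve.
#' @return List of `differentiation_curve` objects.
#' @export
default_curves <- function(P = 10000) {
  fam <- list(
    low = cbind(c(0.3, 2.2, 4.6, 4.9, 4.4),
                c(0.25, 0.35, 0.8, 2.9, 5.3)),
    mid = cbind(c(0.5, 3.0, 5.4, 5.7, 5.1),
                c(0.30, 0.40, 0.9, 3.0, 5.5)),
    high = cbind(c(0.8, 3.8, 6.1, 6.4, 5.8),
                 c(0.35, 0.45, 1.0, 3.1, 5.7)))
  build_curve_set(fam, P = P)
}

## Point(s) on a curve at arc-length fraction(s) f, by linear interpolation
## between the discretised points.
curve_point_at <- function(curve, f) {
  cbind(stats::approx(curve$fraction, curve$points[, 1], xout = f)$y,
        stats::approx(curve$fraction, curve$points[, 2], xout = f)$y)
}

#' Project cells onto the nearest differentiation curve
#'
#' For every cell, finds the Euclidean nearest discretised point over all
#' curves in transformed marker space; the cell's differentiation position
#' is that point's cumulative arc-length fraction. Ties are broken toward
#' the lowest curve id, then the lowest point index.
#'
#' @param cd71_t,ter119_t transformed marker intensities (same length).
#' @param curves list of `differentiation_curve` objects.
#' @return data.frame with columns `position`, `nearest_curve`,
#'   `distance` (one row per cell).
#' @export
project_cells <- function(cd71_t, ter119_t, curves) {
  stopifnot(length(curves) >= 1, length(cd71_t) == length(ter119_t))
  n <- length(cd71_t)
  best_d2 <- rep(Inf, n)
  best_curve <- integer(n)
  best_frac <- numeric(n)
  for (cv in curves) {
    px <- cv$points[, 1]; py <- cv$points[, 2]
    # chunk cells to bound the n x P distance matrix
    chunk <- max(1L, floor(5e6 / length(px)))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      d2 <- outer(cd71_t[idx], px, "-")^2 + outer(ter119_t[idx], py, "-")^2
      j <- max.col(-d2, ties.method = "first")
      dmin <- d2[cbind(seq_along(idx), j)]
      better <- dmin < best_d2[idx]   # strict: earlier curve wins ties
      upd <- idx[better]
      best_d2[upd] <- dmin[better]
      best_curve[upd] <- cv$curve_id
      best_frac[upd] <- cv$fraction[j[better]]
    }
  }
  data.frame(position = best_frac, nearest_curve = best_curve,
             distance = sqrt(best_d2))
}

#' Stage cells on the differentiation axis
#'
#' Convenience wrapper: transform raw markers, project onto the curve set
#' and bin positions into stages DS1-DS6.
#'
#' @param markers data.frame with columns `cell_id`, `cd71`, `ter119`
#'   (raw a.u.).
#' @param curves curve family (default [default_curves()]).
#' @param cofactor asinh cofactor.
#' @param boundaries stage bin boundaries, see [bin_stages()].
#' @return data.frame `cell_id`, `cd71_t`, `ter119_t`, `position`,
#'   `nearest_curve`, `distance`, `stage`.
#' @export
stage_cells <- function(markers, curves = default_curves(), cofactor = 150,
                        boundaries = seq(1 / 6, 5 / 6, by = 1 / 6)) {
  ct <- transform_markers(markers$cd71, cofactor)
  tt <- transform_markers(markers$ter119, cofactor)
  pr <- project_cells(ct, tt, curves)
  cbind(data.frame(cell_id = markers$cell_id, cd71_t = ct, ter119_t = tt,
                   stringsAsFactors = FALSE),
        pr, stage = bin_stages(pr$position, boundaries))
}

#' Bin differentiation positions into stages DS1-DS6
#'
#' Half-open bins `[0, b1), [b1, b2), ..., [b5, 1]`: a position exactly at
#' a boundary belongs to the later stage. Default boundaries are equal
#' sextiles.
#'
#' @param positions numeric positions in \[0, 1\].
#' @param boundaries five strictly increasing cut points in (0, 1).
#' @return factor with levels DS1-DS6.
#' @export
bin_stages <- function(positions, boundaries = seq(1 / 6, 5 / 6, by = 1 / 6)) {
  if (any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing")
  stopifnot(all(boundaries > 0), all(boundaries < 1),
            all(positions >= 0), all(positions <= 1))
  idx <- findInterval(positions, c(0, boundaries))
  factor(paste0("DS", idx), levels = paste0("DS", seq_len(length(boundaries) + 1)))
}

## Binned moving-median size profile along the axis.
size_profile <- function(position, size, n_bins) {
  bin <- pmin(floor(position * n_bins) + 1L, n_bins)
  med <- tapply(size, factor(bin, levels = seq_len(n_bins)), stats::median)
  med <- as.numeric(med)
  # moving median, window 3, keeping ends
  sm <- med
  for (i in seq_along(med)) {
    w <- med[max(1, i - 1):min(length(med), i + 1)]
    sm[i] <- stats::median(w, na.rm = TRUE)
  }
  sm
}

#' Align two differentiation axes by cell-size fluctuations
#'
#' Builds a binned, moving-median profile of cell size versus position for
#' a reference and a query dataset, then finds the global shift (in
#' position units) that maximises the Pearson correlation of the
#' overlapping profile segments. `shift` is the estimated displacement of
#' the query axis relative to the reference (query = reference + shift);
#' the returned mapping is the monotone map
#' `position -> clip(position - shift, 0, 1)` taking query positions into
#' reference coordinates.
#'
#' @param reference,query data.frames with numeric columns `position` and
#'   `size` (>= 50 rows each).
#' @param n_bins number of position bins for the profiles.
#' @param max_shift maximum absolute shift searched (position units).
#' @param min_cor minimum peak correlation; below it alignment fails.
#' @return List of class `axis_alignment` with `shift`, `correlation`, and
#'   `mapping` (a function).
#' @export
align_axes <- function(reference, query, n_bins = 40, max_shift = 0.25,
                       min_cor = 0.5) {
  stopifnot(nrow(reference) >= 50, nrow(query) >= 50)
  ref_p <- size_profile(reference$position, reference$size, n_bins)
  qry_p <- size_profile(query$position, query$size, n_bins)
  ok <- is.finite(ref_p) & is.finite(qry_p)
  if (stats::sd(ref_p[ok]) < 1e-9 || stats::sd(qry_p[ok]) < 1e-9)
    stop("alignment failure: size profiles carry no fluctuation signal")
  max_lag <- min(n_bins - 5L, ceiling(max_shift * n_bins))
  lags <- -max_lag:max_lag
  cors <- vapply(lags, function(l) {
    # query shifted by +l bins aligns query position p with reference p + l/n_bins
    if (l >= 0) {
      a <- ref_p[(1 + l):n_bins]; b <- qry_p[1:(n_bins - l)]
    } else {
      a <- ref_p[1:(n_bins + l)]; b <- qry_p[(1 - l):n_bins]
    }
    keep <- is.finite(a) & is.finite(b)
    if (sum(keep) < 5 || stats::sd(a[keep]) < 1e-12 ||
        stats::sd(b[keep]) < 1e-12) return(NA_real_)
    stats::cor(a[keep], b[keep])
  }, numeric(1))
  if (all(is.na(cors)) || max(cors, na.rm = TRUE) < min_cor)
    stop("alignment failure: no shift reaches the correlation threshold")
  best <- lags[which.max(cors)]
  # best lag l matches qry_p[i] with ref_p[i + l], i.e. the query axis is
  # displaced by -l bins relative to the reference
  shift <- -best / n_bins
  structure(list(shift = shift, correlation = max(cors, na.rm = TRUE),
                 mapping = function(p) pmin(pmax(p - shift, 0), 1)),
            class = "axis_alignment")
}
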