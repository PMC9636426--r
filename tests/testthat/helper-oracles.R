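# Independent oracles used across the suite. Each reimplements a quantity
# with a different method than the package (root refinement instead of
# closed-form crossings, double loops instead of vectorised fits,
# enumeration instead of approximations) so agreement is evidence, not
# tautology.

# Burst quantities from a dense grid with numerically refined crossings:
# sign changes of the interpolant are bracketed on a `step`-spaced grid and
# polished with uniroot; ON time and area-above-threshold are integrated by
# trapezoid over the union of grid, sample and crossing points.
oracle_burst <- function(times, intensities, threshold, step = 1e-3) {
  f <- stats::approxfun(times, intensities)
  grid <- sort(unique(c(seq(times[1], times[length(times)], by = step),
                        times)))
  fg <- f(grid) - threshold
  crossings <- c()
  sgn <- fg >= 0
  idx <- which(diff(sgn) != 0)
  for (i in idx) {
    r <- stats::uniroot(function(x) f(x) - threshold,
                        c(grid[i], grid[i + 1]), tol = 1e-12)
    crossings <- c(crossings, r$root)
  }
  pts <- sort(unique(c(grid, crossings)))
  fy <- pmax(f(pts) - threshold, 0)
  area <- sum(diff(pts) * (head(fy, -1) + tail(fy, -1)) / 2)
  # ON time: segments whose midpoint is at/above threshold
  mids <- (head(pts, -1) + tail(pts, -1)) / 2
  on_time <- sum(diff(pts)[f(mids) >= threshold])
  # complete bursts: ON runs with crossings strictly inside the window
  on_runs <- rle(f(mids) >= threshold)
  ends <- cumsum(on_runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  run_start_t <- pts[starts]
  run_end_t <- pts[ends + 1]
  on_i <- which(on_runs$values)
  n_complete <- sum(run_start_t[on_i] > times[1] + 1e-9 &
                    run_end_t[on_i] < times[length(times)] - 1e-9)
  list(on_time = on_time, area = area, n_complete = n_complete)
}

# Naive double-loop robust LOWESS with the package's documented
# conventions (tricube over k nearest neighbours, local linear fit,
# bisquare reweighting at scale 6 * median |residual|).
naive_rlowess <- function(x, y, span = 0.3, iter = 3,
                          eval_x = sort(unique(x))) {
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  k <- max(2, ceiling(span * n))
  rw <- rep(1, n)
  fit1 <- function(x0, rw) {
    d <- abs(x - x0)
    h <- sort(d)[k]
    if (h <= 0) {
      w <- rw * (d == 0)
      return(sum(w * y) / sum(w))
    }
    w <- rep(0, n)
    ins <- d < h * (1 + 1e-12)
    w[ins] <- (1 - pmin(d[ins] / h, 1)^3)^3
    w <- w * rw
    sw <- sum(w); xw <- sum(w * x) / sw; yw <- sum(w * y) / sw
    sxx <- sum(w * (x - xw)^2)
    if (sxx <= 1e-12 * sum(w * x^2 + 1e-300)) return(yw)
    yw + sum(w * (x - xw) * (y - yw)) / sxx * (x0 - xw)
  }
  for (p in seq_len(iter)) {
    r <- y - sapply(x, fit1, rw = rw)
    m <- stats::median(abs(r))
    if (m <= 0) rw <- as.numeric(r == 0)
    else { u <- r / (6 * m); rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0) }
  }
  sapply(eval_x, fit1, rw = rw)
}

# Exact two-sided Mann-Whitney p-value by enumerating all group
# assignments (tie-free data, n + m small).
oracle_mwu_p <- function(a, b) {
  nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - nb * (nb + 1) / 2
  u_obs <- u_of((length(a) + 1):(length(a) + nb))
  mu <- nb * length(a) / 2
  combs <- utils::combn(length(pooled), nb)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Quadratic least squares via the normal equations.
oracle_quadratic <- function(x, y) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(a = beta[3], b = beta[2], c = beta[1])
}

# Random piecewise-linear trace around an ON threshold of 350.
random_trace <- function(id, n = 25, dt = 2.5) {
  intensity_trace(id, seq(0, by = dt, length.out = n),
                  stats::runif(n, 0, 900))
}

# Intersection-over-union of two masks.
iou <- function(a, b) sum(a & b) / sum(a | b)

# Map generator regime labels to classifier classes.
regime_to_class <- c(basal = "BASAL",
                     high_on_high_amp = "HIGH_ON_HIGH_AMP",
                     low_on_high_amp = "LOW_ON_HIGH_AMP")
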