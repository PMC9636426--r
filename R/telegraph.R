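#' Two-state (telegraph) promoter parameters
#'
#' Bundle the kinetic and intensity parameters of a two-state promoter:
#' the gene switches OFF -> ON at rate `k_on` and ON -> OFF at rate `k_off`
#' (both per minute), and while ON adds `amplitude` arbitrary intensity
#' units of nascent-spot signal on top of `baseline`. Measurement noise is
#' additive Gaussian with standard deviation `noise_sd`.
#'
#' The stationary probability of the ON state is `k_on / (k_on + k_off)`.
#'
#' @param k_on OFF -> ON switching rate (1/min), > 0.
#' @param k_off ON -> OFF switching rate (1/min), > 0.
#' @param amplitude mean spot intensity added while ON (a.u.), >= 0.
#' @param baseline background intensity level (a.u.).
#' @param noise_sd additive Gaussian measurement noise SD (a.u.), >= 0.
#' @param regime regime label, one of `"basal"`, `"high_on_high_amp"`,
#'   `"low_on_high_amp"`.
#' @return An object of class `telegraph_params`.
#' @export
telegraph_params <- function(k_on, k_off, amplitude, baseline = 100,
                             noise_sd = 60,
                             regime = c("basal", "high_on_high_amp",
                                        "low_on_high_amp")) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(k_on), length(k_on) == 1L, k_on > 0,
            is.numeric(k_off), length(k_off) == 1L, k_off > 0,
            is.numeric(amplitude), amplitude >= 0,
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(k_on = k_on, k_off = k_off, amplitude = amplitude,
                 baseline = baseline, noise_sd = noise_sd, regime = regime),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "telegraph_params [%s]: k_on=%.4g k_off=%.4g (p_on=%.3f) amp=%.4g base=%.4g noise_sd=%.4g\n",
    x$regime, x$k_on, x$k_off, x$k_on / (x$k_on + x$k_off),
    x$amplitude, x$baseline, x$noise_sd))
  invisible(x)
}

#' Spot-intensity time series of one cell
#'
#' @param cell_id cell identifier.
#' @param times strictly increasing sample times (min), length >= 2.
#' @param intensities spot intensities (a.u.); may be negative after
#'   background subtraction.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(cell_id, times, intensities) {
  stopifnot(length(times) == length(intensities), length(times) >= 2,
            all(diff(times) > 0), all(is.finite(times)),
            all(is.finite(intensities)))
  structure(list(cell_id = cell_id, times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("intensity_trace '%s': %d samples, t in [%.3g, %.3g] min\n",
              as.character(x$cell_id), length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

## Draw alternating exponential dwell times until `duration` is exceeded.
## Returns switching times in (0, duration); state before the first switch
## is `state0`.
telegraph_switch_times <- function(k_on, k_off, duration, state0) {
  t_end <- 0
  dwells <- numeric(0)
  state_first <- state0
  repeat {
    n <- 32L
    # dwell i leaves the state the promoter is in before switch i
    st <- rep_len(c(state_first, 1 - state_first), length(dwells) + n)
    st <- st[(length(dwells) + 1L):(length(dwells) + n)]
    rates <- ifelse(st == 1, k_off, k_on)
    dwells <- c(dwells, stats::rexp(n, rate = rates))
    t_end <- sum(dwells)
    if (t_end > duration) break
  }
  sw <- cumsum(dwells)
  sw[sw < duration]
}

## Cumulative ON time C(t) for a piecewise-constant state path given by
## state0 and switch times; evaluated at (sorted) times t in [0, duration].
cumulative_on_time <- function(t, switch_times, state0) {
  knots <- c(0, switch_times)
  states <- rep_len(c(state0, 1 - state0), length(knots))
  # cumulative ON time at each knot
  if (length(knots) > 1) {
    seg <- diff(knots) * states[-length(states)]
    cum_knot <- c(0, cumsum(seg))
  } else {
    cum_knot <- 0
  }
  idx <- findInterval(t, knots)
  cum_knot[idx] + states[idx] * (t - knots[idx])
}

#' Simulate a nascent-transcription spot trace from a telegraph promoter
#'
#' The promoter state is simulated exactly in continuous time (alternating
#' exponential dwells; Gillespie-style), starting from a draw of the
#' stationary distribution. Spot intensity at each sample time is
#' `baseline + amplitude * occupancy + N(0, noise_sd)` where `occupancy`
#' is, by default, the fraction of the preceding frame interval spent ON
#' (mimicking camera integration); with `mode = "instantaneous"` it is the
#' promoter state at the sample instant. The first sample always uses the
#' instantaneous state.
#'
#' @param params a [telegraph_params()] object.
#' @param duration total imaging time (min), > 0.
#' @param frame_interval sampling interval (min), > 0 and <= duration.
#' @param seed optional integer seed; identical seeds give identical traces.
#' @param cell_id identifier stored on the returned trace.
#' @param mode promoter-to-intensity mapping; `"frame_average"` (default)
#'   or `"instantaneous"`.
#' @return An [intensity_trace()] with attributes `occupancy` (per-frame ON
#'   fraction), `state` (instantaneous 0/1 state at each sample) and
#'   `params`, retained as simulation ground truth.
#' @export
simulate_trace <- function(params, duration = 60, frame_interval = 2.5,
                           seed = NULL, cell_id = "cell",
                           mode = c("frame_average", "instantaneous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.numeric(duration) || duration <= 0 ||
      !is.numeric(frame_interval) || frame_interval <= 0 ||
      duration < frame_interval)
    stop("duration and frame_interval must be positive with duration >= frame_interval")
  if (!is.null(seed)) set.seed(seed)

  times <- seq(0, duration, by = frame_interval)
  p_on <- params$k_on / (params$k_on + params$k_off)
  state0 <- stats::rbinom(1L, 1L, p_on)
  sw <- telegraph_switch_times(params$k_on, params$k_off, duration, state0)

  cum_on <- cumulative_on_time(times, sw, state0)
  n_sw_before <- findInterval(times, sw)
  state_t <- ifelse(n_sw_before %% 2 == 0, state0, 1 - state0)

  occ <- c(state_t[1], diff(cum_on) / frame_interval)
  signal <- if (mode == "frame_average") occ else state_t
  noise <- if (params$noise_sd > 0)
    stats::rnorm(length(times), 0, params$noise_sd) else 0
  intensities <- params$baseline + params$amplitude * signal + noise

  tr <- intensity_trace(cell_id, times, intensities)
  attr(tr, "occupancy") <- occ
  attr(tr, "state") <- state_t
  attr(tr, "params") <- params
  tr
}

#' Per-stage generator profile
#'
#' A differentiation stage's sub-interval of the axis, its mixture of the
#' three bursting regimes, and the telegraph parameters of each regime.
#'
#' @param stage stage label (`"DS1"` ... `"DS6"`).
#' @param position_range length-2 numeric sub-interval of \[0, 1\].
#' @param regime_weights named numeric mixture weights over
#'   `basal`, `high_on_high_amp`, `low_on_high_amp`; must sum to 1.
#' @param params_per_regime named list of [telegraph_params()], one per
#'   regime.
#' @return An object of class `stage_profile`.
#' @export
stage_profile <- function(stage, position_range, regime_weights,
                          params_per_regime) {
  regimes <- c("basal", "high_on_high_amp", "low_on_high_amp")
  stopifnot(length(position_range) == 2, position_range[1] < position_range[2],
            position_range[1] >= 0, position_range[2] <= 1,
            setequal(names(regime_weights), regimes),
            setequal(names(params_per_regime), regimes),
            all(regime_weights >= 0))
  if (abs(sum(regime_weights) - 1) > 1e-9)
    stop("regime_weights must sum to 1")
  structure(list(stage = stage, position_range = position_range,
                 regime_weights = regime_weights[regimes],
                 params_per_regime = params_per_regime[regimes]),
            class = "stage_profile")
}

#' Default stage profiles DS1-DS6
#'
#' Generator defaults for the six differentiation stages. The basal regime's
#' stationary ON probability rises from early stages to a mid-differentiation
#' peak and falls late (0.42, 0.56, 0.75, 0.68, 0.50, 0.30 for DS1-DS6);
#' high-ON/high-amplitude bursting is enriched at the mid stages and
#' low-ON/high-amplitude sporadic bursting at the flanking stages. Amplitudes
#' default to 500 a.u. (basal) and 1200 a.u. (high; ratio 2.4) over a
#' baseline of 100 a.u. with noise SD 60 a.u. These are generator defaults
#' describing a plausible population, not estimates of any measured dataset.
#'
#' @param baseline baseline intensity (a.u.).
#' @param basal_amplitude ON amplitude of the basal regime (a.u.).
#' @param high_amplitude ON amplitude of the high-amplitude regimes (a.u.).
#' @param noise_sd measurement noise SD (a.u.).
#' @return A list of six [stage_profile()] objects whose position ranges
#'   partition \[0, 1\].
#' @export
default_stage_profiles <- function(baseline = 100, basal_amplitude = 500,
                                   high_amplitude = 1200, noise_sd = 60) {
  stages <- paste0("DS", 1:6)
  basal_p_on <- c(0.42, 0.56, 0.75, 0.68, 0.50, 0.30)
  k_off_basal <- 0.25   # mean ON dwell 4 min
  weights <- list(
    DS1 = c(basal = 0.72, high_on_high_amp = 0.08, low_on_high_amp = 0.20),
    DS2 = c(basal = 0.72, high_on_high_amp = 0.10, low_on_high_amp = 0.18),
    DS3 = c(basal = 0.74, high_on_high_amp = 0.20, low_on_high_amp = 0.06),
    DS4 = c(basal = 0.72, high_on_high_amp = 0.20, low_on_high_amp = 0.08),
    DS5 = c(basal = 0.70, high_on_high_amp = 0.12, low_on_high_amp = 0.18),
    DS6 = c(basal = 0.76, high_on_high_amp = 0.08, low_on_high_amp = 0.16))
  lapply(seq_along(stages), function(i) {
    p <- basal_p_on[i]
    params <- list(
      basal = telegraph_params(k_on = p / (1 - p) * k_off_basal,
                               k_off = k_off_basal,
                               amplitude = basal_amplitude,
                               baseline = baseline, noise_sd = noise_sd,
                               regime = "basal"),
      # nearly always active, bright bursts
      high_on_high_amp = telegraph_params(k_on = 0.95, k_off = 0.05,
                                          amplitude = high_amplitude,
                                          baseline = baseline,
                                          noise_sd = noise_sd,
                                          regime = "high_on_high_amp"),
      # sporadic bright bursts
      low_on_high_amp = telegraph_params(k_on = 0.07, k_off = 0.25,
                                         amplitude = high_amplitude,
                                         baseline = baseline,
                                         noise_sd = noise_sd,
                                         regime = "low_on_high_amp"))
    stage_profile(stages[i], c((i - 1) / 6, i / 6), weights[[i]], params)
  })
}

#' Simulated marker intensities along the differentiation axis
#'
#' Returns raw CD71 and Ter119 intensities for a cell at a given position on
#' the differentiation axis. The noiseless mean trajectory is exactly the
#' middle member of the default staging curve family (CD71 rises early then
#' declines late; Ter119 rises late), evaluated at arc-length fraction
#' `position` and mapped back to raw units by the inverse marker transform.
#' Noise is multiplicative lognormal with coefficient of variation
#' `noise_cv`, preserving the mean.
#'
#' @param position position on the differentiation axis, in \[0, 1\].
#' @param noise_cv coefficient of variation of the lognormal noise (>= 0).
#' @param seed optional integer seed.
#' @param curves curve family as returned by [default_curves()]; the middle
#'   curve is used as the generating trajectory.
#' @param cofactor asinh cofactor of the marker transform (a.u.).
#' @return Named numeric vector `c(cd71 = ..., ter119 = ...)` (a.u.).
#' @export
simulate_markers <- function(position, noise_cv = 0.2, seed = NULL,
                             curves = default_curves(),
                             cofactor = 150) {
  if (any(position < 0 | position > 1))
    stop("position must lie in [0, 1]")
  stopifnot(noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  mid <- curves[[(length(curves) + 1L) %/% 2L]]
  pts <- curve_point_at(mid, position)   # transformed space
  cd71 <- inverse_transform_markers(pts[, 1], cofactor)
  ter119 <- inverse_transform_markers(pts[, 2], cofactor)
  if (noise_cv > 0) {
    s <- sqrt(log(1 + noise_cv^2))
    cd71 <- cd71 * stats::rlnorm(length(cd71), -s^2 / 2, s)
    ter119 <- ter119 * stats::rlnorm(length(ter119), -s^2 / 2, s)
  }
  if (length(position) == 1L) c(cd71 = cd71, ter119 = ter119)
  else cbind(cd71 = cd71, ter119 = ter119)
}

## Mean cell area (um^2) along the axis: erythroid cells shrink with
## maturation; superimposed regular fluctuations (~4 division cycles) give
## the size signal used for axis alignment.
mean_cell_size <- function(position) {
  120 - 60 * position + 8 * sin(2 * pi * 4 * position)
}

#' Simulate a synthetic cell population across differentiation stages
#'
#' Each cell draws a position uniformly within its stage's interval, a
#' bursting regime from the stage's mixture weights, a trace via
#' [simulate_trace()], raw CD71/Ter119 marker intensities via
#' [simulate_markers()] and a cell size (shrinking with differentiation,
#' with regular fluctuations). Reproducible under a single master seed:
#' cell `i` (in generation order) uses the derived seed
#' `(seed * 1000003 + i) mod (2^31 - 1)`, a documented counter scheme that
#' decorrelates nearby master seeds and allows parallel generation.
#'
#' @param profiles list of [stage_profile()] covering DS1-DS6.
#' @param n_cells_per_stage integer count per stage (recycled to the number
#'   of profiles).
#' @param duration,frame_interval imaging parameters (min).
#' @param marker_noise_cv lognormal CV of the simulated marker noise.
#' @param size_noise_sd Gaussian SD of cell-size noise (um^2).
#' @param seed master seed (integer).
#' @param mode promoter-to-intensity mapping, see [simulate_trace()].
#' @return A list of `synthetic_cell` objects (fields: `cell_id`, `stage`,
#'   `true_regime`, `true_position`, `trace`, `cd71`, `ter119`,
#'   `cell_size`). Use [population_table()] for a data.frame of the ground
#'   truth.
#' @export
simulate_population <- function(profiles, n_cells_per_stage,
                                duration = 60, frame_interval = 2.5,
                                marker_noise_cv = 0.2, size_noise_sd = 4,
                                seed = 1, mode = "frame_average") {
  stopifnot(length(profiles) >= 1)
  n_cells_per_stage <- rep_len(as.integer(n_cells_per_stage),
                               length(profiles))
  stopifnot(all(n_cells_per_stage >= 0))
  for (pr in profiles) {
    if (abs(sum(pr$regime_weights) - 1) > 1e-9)
      stop("regime_weights must sum to 1")
  }
  curves <- default_curves()
  cells <- list()
  counter <- 0L
  for (s in seq_along(profiles)) {
    pr <- profiles[[s]]
    for (j in seq_len(n_cells_per_stage[s])) {
      counter <- counter + 1L
      cell_seed <- (as.numeric(seed) * 1000003 + counter) %% 2147483647
      set.seed(cell_seed)
      pos <- stats::runif(1, pr$position_range[1], pr$position_range[2])
      regime <- sample(names(pr$regime_weights), 1,
                       prob = pr$regime_weights)
      id <- sprintf("%s_c%04d", pr$stage, counter)
      trace <- simulate_trace(pr$params_per_regime[[regime]], duration,
                              frame_interval, seed = NULL, cell_id = id,
                              mode = mode)
      mk <- simulate_markers(pos, noise_cv = marker_noise_cv, seed = NULL,
                             curves = curves)
      size <- max(mean_cell_size(pos) + stats::rnorm(1, 0, size_noise_sd),
                  20)
      cells[[counter]] <- structure(
        list(cell_id = id, stage = pr$stage, true_regime = regime,
             true_position = pos, trace = trace,
             cd71 = unname(mk["cd71"]), ter119 = unname(mk["ter119"]),
             cell_size = size),
        class = "synthetic_cell")
    }
  }
  cells
}

#' Ground-truth table of a synthetic population
#'
#' @param cells list of `synthetic_cell` objects from
#'   [simulate_population()].
#' @return data.frame with one row per cell (cell_id, stage, true_regime,
#'   true_position, cd71, ter119, cell_size).
#' @export
population_table <- function(cells) {
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(cell_id = cl$cell_id, stage = cl$stage,
               true_regime = cl$true_regime,
               true_position = cl$true_position,
               cd71 = cl$cd71, ter119 = cl$ter119,
               cell_size = cl$cell_size, stringsAsFactors = FALSE)
  }))
}

#' Long-format trace table of a synthetic population
#'
#' @param cells list of `synthetic_cell` objects.
#' @return data.frame with columns cell_id, time_min, intensity_au.
#' @export
trace_table <- function(cells) {
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(cell_id = cl$cell_id, time_min = cl$trace$times,
               intensity_au = cl$trace$intensities,
               stringsAsFactors = FALSE)
  }))
}
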