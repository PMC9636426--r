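test_that("ON intervals handle always-on, always-off and exact crossings", {
  t <- seq(0, 60, by = 2.5)
  on <- intensity_trace("on", t, rep(500, length(t)))
  expect_equal(find_on_intervals(on, 350),
               data.frame(start = 0, end = 60))

  off <- intensity_trace("off", t, rep(100, length(t)))
  expect_equal(nrow(find_on_intervals(off, 350)), 0)

  tri <- intensity_trace("tri", c(0, 2.5, 5), c(0, 700, 0))
  iv <- find_on_intervals(tri, 350)
  expect_equal(iv$start, 1.25)
  expect_equal(iv$end, 3.75)

  # samples exactly at threshold count as ON
  flat <- intensity_trace("flat", c(0, 10), c(350, 350))
  ivf <- find_on_intervals(flat, 350)
  expect_equal(ivf, data.frame(start = 0, end = 10))

  # an instantaneous touch from below is not an interval
  touch <- intensity_trace("touch", c(0, 2.5, 5), c(300, 350, 300))
  expect_equal(nrow(find_on_intervals(touch, 350)), 0)
})

test_that("triangle burst has the analytic duration, size and output", {
  tri <- intensity_trace("tri", c(0, 2.5, 5), c(0, 700, 0))
  res <- summarize_bursts(tri, 350)
  expect_equal(res$summary$on_fraction, 0.5)
  expect_equal(res$summary$on_duration, 2.5)
  expect_equal(res$summary$output, 437.5)
  expect_equal(res$summary$n_complete_bursts, 1)
  expect_equal(res$bursts$duration, 2.5)
  expect_equal(res$bursts$size, 437.5)
  expect_true(res$bursts$complete)
})

test_that("window-edge intervals are incomplete but count in output", {
  t <- seq(0, 60, by = 2.5)
  const <- intensity_trace("c", t, rep(350 + 40, length(t)))
  res <- summarize_bursts(const, 350)
  expect_equal(res$summary$n_complete_bursts, 0)
  expect_equal(res$summary$n_bursts, 1)
  expect_equal(res$summary$output, 60 * 40)
  expect_false(res$bursts$complete)
})

test_that("burst quantities match the refined dense-grid oracle", {
  set.seed(42)
  for (i in 1:150) {
    tr <- random_trace(i)
    res <- summarize_bursts(tr, 350)
    orc <- oracle_burst(tr$times, tr$intensities, 350)
    expect_equal(res$summary$on_duration, orc$on_time,
                 tolerance = 1e-6)
    expect_equal(res$summary$output, orc$area, tolerance = 1e-6)
    expect_equal(res$summary$n_complete_bursts, orc$n_complete)
  }
})

test_that("on fraction and output are non-increasing in the threshold", {
  set.seed(7)
  ths <- seq(100, 800, by = 50)
  for (i in 1:20) {
    tr <- random_trace(i)
    res <- lapply(ths, function(th) summarize_bursts(tr, th)$summary)
    onf <- vapply(res, `[[`, numeric(1), "on_fraction")
    out <- vapply(res, `[[`, numeric(1), "output")
    expect_true(all(diff(onf) <= 1e-12))
    expect_true(all(diff(out) <= 1e-9))
  }
})

test_that("summary aggregates are additive over intervals", {
  set.seed(9)
  for (i in 1:20) {
    tr <- random_trace(i)
    res <- summarize_bursts(tr, 350)
    if (nrow(res$bursts) > 0) {
      expect_equal(res$summary$output, sum(res$bursts$size))
      expect_equal(res$summary$on_duration, sum(res$bursts$duration))
    }
    expect_equal(res$summary$on_fraction, res$summary$on_duration / 60)
  }
})

test_that("threshold sweep counts match a per-trace recount", {
  set.seed(12)
  traces <- lapply(1:30, random_trace)
  ths <- seq(50, 950, by = 100)
  sw <- threshold_sweep(traces, ths)
  recount <- vapply(ths, function(th) {
    sum(vapply(traces, function(tr)
      oracle_burst(tr$times, tr$intensities, th)$n_complete, numeric(1)))
  }, numeric(1))
  expect_equal(sw$table$n_complete, recount)

  # extreme thresholds see no complete burst
  glob <- range(unlist(lapply(traces, `[[`, "intensities")))
  expect_equal(threshold_sweep(traces, glob[1] - 10)$table$n_complete, 0)
  expect_equal(threshold_sweep(traces, glob[2] + 10)$table$n_complete, 0)
})

test_that("subsampling RMSE follows its defining formula", {
  t <- seq(0, 60, by = 2.5)
  tr <- intensity_trace("a", t, runif(length(t), 0, 900))
  expect_equal(subsample_rmse(tr, 2.5)$rmse, 0)

  worked <- intensity_trace("w", c(0, 10, 20), c(0, 10, 0))
  expect_equal(subsample_rmse(worked, 20)$rmse, sqrt(100 / 3))

  const <- intensity_trace("c", t, rep(200, length(t)))
  for (iv in c(2.5, 5, 10, 20))
    expect_equal(subsample_rmse(const, iv)$rmse, 0)

  expect_error(subsample_rmse(tr, 1), "native")
})

test_that("interval selection respects the RMSE budget", {
  set.seed(21)
  p <- telegraph_params(0.5, 0.5, 600, baseline = 100, noise_sd = 0)
  traces <- lapply(1:30, function(i)
    simulate_trace(p, 10, 1 / 6, seed = i, cell_id = i))
  cands <- (1:12) / 6

  res_inf <- select_interval(traces, cands, Inf)
  expect_equal(res_inf$recommended, 2)
  expect_true(res_inf$within_budget)

  # zero budget over strictly coarser candidates: nothing qualifies
  coarser <- (2:12) / 6
  expect_warning(res0 <- select_interval(traces, coarser, 0), "budget")
  expect_equal(res0$recommended, 2 / 6)
  expect_false(res0$within_budget)

  # slowly bursting genes tolerate longer intervals than fast ones
  fast <- lapply(1:40, function(i)
    simulate_trace(telegraph_params(0.5, 0.5, 600, noise_sd = 0),
                   10, 1 / 6, seed = i, cell_id = i))
  slow <- lapply(1:40, function(i)
    simulate_trace(telegraph_params(0.05, 0.05, 600, noise_sd = 0),
                   10, 1 / 6, seed = 100 + i, cell_id = i))
  budget <- 60
  rec_fast <- select_interval(fast, cands, budget)$recommended
  rec_slow <- select_interval(slow, cands, budget)$recommended
  expect_gte(rec_slow, rec_fast)
})
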