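test_that("degenerate promoters give flat traces", {
  # zero amplitude: nothing but baseline
  p <- telegraph_params(1, 1, amplitude = 0, baseline = 100, noise_sd = 0)
  tr <- simulate_trace(p, duration = 60, frame_interval = 2.5, seed = 1)
  expect_length(tr$times, 25)
  expect_true(all(tr$intensities == 100))

  # effectively always-ON promoter saturates at baseline + amplitude
  p2 <- telegraph_params(10, 1e-9, amplitude = 600, baseline = 100,
                         noise_sd = 0)
  tr2 <- simulate_trace(p2, 60, 2.5, seed = 2)
  expect_equal(tr2$intensities, rep(700, 25))

  # effectively always-OFF promoter stays at baseline
  p3 <- telegraph_params(1e-9, 10, amplitude = 600, baseline = 100,
                         noise_sd = 0)
  tr3 <- simulate_trace(p3, 60, 2.5, seed = 3)
  expect_equal(tr3$intensities, rep(100, 25))
})

test_that("invalid simulation arguments are rejected", {
  p <- telegraph_params(1, 1, 500)
  expect_error(simulate_trace(p, duration = -1), "positive")
  expect_error(simulate_trace(p, duration = 60, frame_interval = 0),
               "positive")
  expect_error(simulate_trace(p, duration = 1, frame_interval = 2.5),
               "positive")
  expect_error(telegraph_params(0, 1, 500))
  expect_error(telegraph_params(1, 1, -5))
})

test_that("traces are reproducible under a fixed seed", {
  p <- telegraph_params(0.3, 0.4, 500, noise_sd = 60)
  a <- simulate_trace(p, 60, 2.5, seed = 11)
  b <- simulate_trace(p, 60, 2.5, seed = 11)
  expect_identical(a$intensities, b$intensities)
  expect_identical(attr(a, "occupancy"), attr(b, "occupancy"))
})

test_that("frame occupancy converges to the stationary ON probability", {
  p <- telegraph_params(0.5, 0.5, 500, noise_sd = 0)
  occ <- vapply(seq_len(2000), function(i) {
    mean(attr(simulate_trace(p, 60, 2.5, seed = i), "occupancy"))
  }, numeric(1))
  expect_lt(abs(mean(occ) - 0.5), 0.01)

  # asymmetric rates: p_on = 0.2 / (0.2 + 0.6) = 0.25
  p2 <- telegraph_params(0.2, 0.6, 500, noise_sd = 0)
  occ2 <- vapply(seq_len(2000), function(i) {
    mean(attr(simulate_trace(p2, 60, 2.5, seed = 10000 + i), "occupancy"))
  }, numeric(1))
  expect_lt(abs(mean(occ2) - 0.25), 0.015)
})

test_that("population generation honours weights, counts and seeds", {
  profiles <- default_stage_profiles()

  # degenerate mixture: every cell basal
  pr <- stage_profile("DS1", c(0, 1),
                      c(basal = 1, high_on_high_amp = 0,
                        low_on_high_amp = 0),
                      profiles[[1]]$params_per_regime)
  cells <- simulate_population(list(pr), 5, seed = 3)
  expect_length(cells, 5)
  expect_true(all(vapply(cells, `[[`, character(1), "true_regime") ==
                    "basal"))

  # zero counts: empty population
  expect_length(simulate_population(profiles, 0, seed = 1), 0)

  # invalid weights rejected
  bad <- pr; bad$regime_weights["basal"] <- 0.5
  expect_error(simulate_population(list(bad), 5, seed = 1), "sum to 1")

  # reproducibility under the master seed / per-cell counter scheme
  a <- simulate_population(profiles, 10, seed = 99)
  b <- simulate_population(profiles, 10, seed = 99)
  expect_identical(population_table(a), population_table(b))
  expect_identical(a[[7]]$trace$intensities, b[[7]]$trace$intensities)
})

test_that("per-stage regime draws stay within binomial bounds", {
  profiles <- default_stage_profiles()
  cells <- simulate_population(profiles, 50, seed = 202)
  truth <- population_table(cells)
  expect_equal(nrow(truth), 300)
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    sub <- truth[truth$stage == pr$stage, ]
    expect_true(all(sub$true_position >= pr$position_range[1] &
                      sub$true_position <= pr$position_range[2]))
    for (reg in names(pr$regime_weights)) {
      w <- pr$regime_weights[[reg]]
      obs <- mean(sub$true_regime == reg)
      # 99.9% binomial bound at n = 50, wide enough for 18 comparisons
      expect_lt(abs(obs - w), 3.3 * sqrt(w * (1 - w) / 50) + 1e-9)
    }
  }
})

test_that("marker trajectory endpoints and noise behave as specified", {
  curves <- default_curves()
  mid <- curves[[2]]
  m0 <- simulate_markers(0, noise_cv = 0, curves = curves)
  m1 <- simulate_markers(1, noise_cv = 0, curves = curves)
  expect_equal(unname(m0["cd71"]),
               inverse_transform_markers(mid$points[1, 1]))
  expect_equal(unname(m0["ter119"]),
               inverse_transform_markers(mid$points[1, 2]))
  expect_equal(unname(m1["cd71"]),
               inverse_transform_markers(mid$points[nrow(mid$points), 1]))

  expect_error(simulate_markers(1.2), "position")

  # lognormal noise recovers the requested coefficient of variation
  set.seed(5)
  draws <- simulate_markers(rep(0.5, 1000), noise_cv = 0.2)
  cv <- apply(draws, 2, function(v) sd(v) / mean(v))
  expect_true(all(cv > 0.15 & cv < 0.25))
  expect_true(all(draws > 0))
})
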