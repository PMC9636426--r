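test_that("robust lowess reproduces lines and resists outliers", {
  set.seed(1)
  x <- sort(runif(100, 0, 60)); y <- 2 * x
  sm <- robust_lowess(x, y, span = 0.3)
  expect_lt(max(abs(sm$y - 2 * sm$x)), 1e-6)

  y_out <- y; y_out[50] <- y_out[50] + 5000
  sm_out <- robust_lowess(x, y_out, span = 0.3)
  interior <- sm$x > 10 & sm$x < 50
  expect_lt(max(abs(sm_out$y[interior] - sm$y[interior]) /
                  pmax(abs(sm$y[interior]), 1)), 0.05)
})

test_that("robust lowess agrees with independent implementations", {
  set.seed(2)
  x <- runif(150, 0, 60)
  y <- 100 + 5 * x + 0.2 * x^2 + rnorm(150, 0, 40)
  sm <- robust_lowess(x, y, span = 0.3)

  expect_equal(sm$y, naive_rlowess(x, y, span = 0.3), tolerance = 1e-9)

  ref <- stats::lowess(x, y, f = 0.3, iter = 3, delta = 0)
  expect_equal(sm$y, unique(data.frame(x = ref$x, y = ref$y))$y,
               tolerance = 1e-6)
})

test_that("inflection detection finds a constructed knee and rejects lines", {
  d0 <- 40
  grid <- seq(0, 60, length.out = 121)
  kneed <- ifelse(grid <= d0, grid, d0 + 4 * (grid - d0))
  curve <- structure(list(grid = grid, smoothed = kneed, span = 0.3,
                          window = 60),
                     class = "duration_output_curve")
  infl <- find_inflection(curve, smooth_k = 1)
  expect_equal(infl$inflection_duration, d0, tolerance = diff(grid)[1])
  expect_equal(infl$inflection_fraction, d0 / 60, tolerance = 0.01)

  # default gradient smoothing stays within a few grid steps of the knee
  infl5 <- find_inflection(curve)
  expect_lt(abs(infl5$inflection_duration - d0), 3 * diff(grid)[1] + 1e-9)

  lin <- structure(list(grid = grid, smoothed = 2 * grid, span = 0.3,
                        window = 60),
                   class = "duration_output_curve")
  expect_error(find_inflection(lin), class = "no_inflection")
})

test_that("high/low ON split is a strict threshold with ties low", {
  expect_equal(as.character(split_high_low_on(60, 53)), "HIGH_ON")
  expect_equal(as.character(split_high_low_on(0, 53)), "LOW_ON")
  expect_equal(as.character(split_high_low_on(53, 53)), "LOW_ON")
  set.seed(3)
  d <- runif(200, 0, 60)
  expect_equal(split_high_low_on(d, 40) == "HIGH_ON", d > 40)
})

test_that("basal quadratic matches the normal-equations oracle", {
  d <- seq(1, 30, by = 1)
  q <- fit_basal_quadratic(d, d^2)
  expect_equal(unname(q$coefficients), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(predict(q, 45), 2025, tolerance = 1e-6)

  ql <- fit_basal_quadratic(d, 3 * d + 2)
  expect_equal(unname(ql$coefficients["a"]), 0, tolerance = 1e-9)
  expect_equal(predict(ql, 50), 152, tolerance = 1e-6)

  set.seed(4)
  x <- runif(40, 0, 50); y <- 5 + 2 * x - 0.1 * x^2 + rnorm(40, 0, 3)
  qr <- fit_basal_quadratic(x, y)
  expect_equal(unname(qr$coefficients), unname(oracle_quadratic(x, y)),
               tolerance = 1e-8)

  expect_error(fit_basal_quadratic(c(1, 1, 1), c(1, 2, 3)),
               class = "singular_fit")
})

test_that("deviation scores behave affinely and calibrate on Low-ON cells", {
  q <- fit_basal_quadratic(seq(1, 30), 250 * seq(1, 30))
  cells <- data.frame(cell_id = as.character(1:40),
                      on_duration = runif(40, 1, 55),
                      on_group = factor(rep(c("LOW_ON", "HIGH_ON"), 20),
                                        levels = c("LOW_ON", "HIGH_ON")))
  cells$output <- 250 * cells$on_duration

  # cells exactly on the basal curve score 0 and stay BASAL
  cl <- classify_behaviour(cells, q)
  expect_true(all(abs(cl$cells$deviation_score) < 1e-9))
  expect_true(all(cl$cells$final_class == "BASAL"))

  # adding k * on_duration to outputs shifts every score by exactly k
  k <- 123.4
  shifted <- cells; shifted$output <- cells$output + k * cells$on_duration
  cl2 <- classify_behaviour(shifted, q)
  expect_equal(cl2$cells$deviation_score, cl$cells$deviation_score + k,
               tolerance = 1e-9)

  # no Low-ON cells: calibration impossible
  high <- cells; high$on_group[] <- "HIGH_ON"
  expect_error(classify_behaviour(high, q), class = "cannot_calibrate")

  # a silent cell scores 0 by definition
  silent <- rbind(cells,
                  data.frame(cell_id = "z", on_duration = 0, on_group =
                               factor("LOW_ON",
                                      levels = c("LOW_ON", "HIGH_ON")),
                             output = 0))
  cls <- classify_behaviour(silent, q)
  expect_equal(cls$cells$deviation_score[cls$cells$cell_id == "z"], 0)
})

test_that("classification is invariant to cell order", {
  set.seed(5)
  cells <- simulate_population(default_stage_profiles(), 30, seed = 77)
  bm <- summarize_bursts_all(lapply(cells, `[[`, "trace"), 350)
  cl <- classify_population(bm$summary)
  perm <- sample(nrow(bm$summary))
  cl_p <- classify_population(bm$summary[perm, ])
  m <- merge(cl$cells[, c("cell_id", "final_class", "deviation_score")],
             cl_p$cells[, c("cell_id", "final_class", "deviation_score")],
             by = "cell_id")
  expect_equal(as.character(m$final_class.x), as.character(m$final_class.y))
  expect_equal(m$deviation_score.x, m$deviation_score.y)
  expect_equal(cl$threshold, cl_p$threshold)
})

test_that("the classifier recovers generating regimes", {
  cells <- simulate_population(default_stage_profiles(), 50, seed = 11)
  truth <- population_table(cells)
  bm <- summarize_bursts_all(lapply(cells, `[[`, "trace"), 350)
  cl <- classify_population(bm$summary)
  cc <- merge(cl$cells, truth[, c("cell_id", "true_regime")],
              by = "cell_id")
  acc <- mean(as.character(cc$final_class) ==
                regime_to_class[cc$true_regime])
  expect_gte(acc, 0.9)
  # the knee sits in the high-ON-duration region of the window
  expect_gt(cl$inflection$inflection_fraction, 0.5)
})

test_that("stage proportions normalise and follow the generator design", {
  lab <- factor(rep("BASAL", 60),
                levels = c("BASAL", "HIGH_ON_HIGH_AMP", "LOW_ON_HIGH_AMP"))
  stg <- factor(rep(paste0("DS", 1:6), each = 10))
  pp <- stage_proportions(stg, lab)
  expect_true(all(pp$proportions[, "BASAL"] == 1))
  expect_true(all(abs(rowSums(pp$proportions) - 1) < 1e-12))

  set.seed(6)
  rnd <- factor(sample(levels(lab), 300, replace = TRUE), levels = levels(lab))
  stg2 <- factor(sample(paste0("DS", 1:6), 300, replace = TRUE))
  pp2 <- stage_proportions(stg2, rnd)
  expect_true(all(abs(rowSums(pp2$proportions) - 1) < 1e-12))

  # generator design: sporadic high-amplitude bursting enriched at
  # flanking stages, sustained high-ON bursting at mid stages
  cells <- simulate_population(default_stage_profiles(), 100, seed = 21)
  truth <- population_table(cells)
  bm <- summarize_bursts_all(lapply(cells, `[[`, "trace"), 350)
  cl <- classify_population(bm$summary)
  cc <- merge(cl$cells, truth[, c("cell_id", "stage")], by = "cell_id")
  pr <- stage_proportions(cc$stage, cc$final_class)$proportions
  low <- pr[, "LOW_ON_HIGH_AMP"]; high <- pr[, "HIGH_ON_HIGH_AMP"]
  flank <- c("DS1", "DS2", "DS5", "DS6"); mid <- c("DS3", "DS4")
  expect_gt(mean(low[flank]), mean(low[mid]))
  expect_gt(mean(high[mid]), mean(high[flank]))
})
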