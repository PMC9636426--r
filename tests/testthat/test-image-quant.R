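seg_spec <- function(...) {
  cell_image_spec(nx = 65, ny = 65, nz = 25, cell_radius_um = 2.4,
                  nuclear_radius_um = 1.5, spot_offset_um = c(0.86, 0, 0),
                  ...)
}

test_that("noiseless three-level stacks segment exactly", {
  st <- render_stack(seg_spec(spot_amplitude = 0, noise_sd = 0))
  m <- segment_two_step_kmeans(st$gfp, st$centroid_px)
  expect_identical(m$cell_mask, st$cell_mask)
  expect_identical(m$nuclear_mask, st$nuclear_mask)
  # nesting invariant
  expect_true(all(m$cell_mask[m$nuclear_mask]))
})

test_that("uniform stacks raise a segmentation failure", {
  u <- image_stack(array(100, dim = c(20, 20, 8)))
  expect_error(segment_two_step_kmeans(u, c(10, 10)),
               class = "segmentation_failure")
  expect_error(segment_two_step_kmeans(u, c(100, 10)), "bounds")
})

test_that("noisy stacks segment with high overlap", {
  st <- render_stack(seg_spec(spot_amplitude = 600,
                              noise_sd = (400 - 120) / 5), seed = 11)
  m <- segment_two_step_kmeans(st$gfp, st$centroid_px)
  expect_gte(iou(m$cell_mask, st$cell_mask), 0.9)
  expect_gte(iou(m$nuclear_mask, st$nuclear_mask), 0.85)
})

test_that("spot quantification is exact on uniform regions", {
  vox <- array(200, dim = c(61, 61, 25))
  st <- image_stack(vox)
  ctr <- c(30 * 0.086, 30 * 0.086, 12 * 0.5)
  # make everything within the ovoid's bounding box 1000
  co <- burststage:::voxel_coords_um(st)
  bx <- abs(co$x - ctr[1]) <= 0.55
  by <- abs(co$y - ctr[2]) <= 0.55
  bz <- abs(co$z - ctr[3]) <= 1.55
  st$voxels[bx, by, bz] <- 1000
  bg_ctr <- c(ctr[1] + 1.6, ctr[2], ctr[3])
  # background cuboid shrunk to avoid the spot box
  q <- quantify_spot(st, ctr, bg_ctr, background_um = c(1, 1, 1))
  expect_equal(q$raw_mean, 1000)
  expect_equal(q$background_mean, 200)
  expect_equal(q$corrected, 800)

  # same centre: a uniform stack self-subtracts to zero
  u <- image_stack(array(300, dim = c(61, 61, 25)))
  q0 <- quantify_spot(u, ctr, ctr)
  expect_equal(q0$corrected, 0)

  expect_error(quantify_spot(u, c(0, 0, 0), ctr), "bounds")
})

test_that("corrected spot intensity matches the quadrature oracle", {
  # full-size geometry: the background region sits well clear of the spot
  st <- render_stack(cell_image_spec(spot_amplitude = 600, noise_sd = 0))
  ctr <- st$spot$center_um
  bgc <- burststage:::default_background_center(st$gfp, ctr,
                                                st$nuclear_mask)
  q <- quantify_spot(st$gfp, ctr, bgc, background_mask = st$nuclear_mask)

  # dense numerical integration of the Gaussian over the ovoid
  u <- seq(-1, 1, length.out = 120)
  gr <- expand.grid(x = ctr[1] + 0.5 * u, y = ctr[2] + 0.5 * u,
                    z = ctr[3] + 1.5 * u)
  inside <- ((gr$x - ctr[1]) / 0.5)^2 + ((gr$y - ctr[2]) / 0.5)^2 +
    ((gr$z - ctr[3]) / 1.5)^2 <= 1
  d2 <- (gr$x - ctr[1])^2 + (gr$y - ctr[2])^2 + (gr$z - ctr[3])^2
  oracle <- mean(600 * exp(-d2[inside] / (2 * 0.3^2)))
  expect_lt(abs(q$corrected - oracle) / oracle, 0.05)
})

test_that("spot detection finds true spots and reports absences", {
  st <- render_stack(seg_spec(spot_amplitude = 600, noise_sd = 0))
  found <- detect_spot(st$gfp, st$nuclear_mask)
  expect_false(is.null(found))
  expect_true(all(abs(found - st$spot$center_um) <=
                    st$gfp$voxel_size_nm / 1000 + 1e-9))

  none <- render_stack(seg_spec(spot_amplitude = 0, noise_sd = 0))
  expect_null(detect_spot(none$gfp, none$nuclear_mask))

  # two spots at 2:1 amplitude, moderate noise: the brighter one wins
  two <- render_stack(seg_spec(spot_amplitude = 600,
                               noise_sd = (400 - 120) / 5), seed = 5)
  co <- burststage:::voxel_coords_um(two$gfp)
  alt <- two$spot$center_um - c(1.72, 0, 0)
  d2 <- array(0, dim = dim(two$gfp$voxels))
  for (k in seq_along(co$z))
    d2[, , k] <- outer((co$x - alt[1])^2, rep(1, length(co$y))) +
      outer(rep(1, length(co$x)), (co$y - alt[2])^2) + (co$z[k] - alt[3])^2
  two$gfp$voxels <- two$gfp$voxels + 300 * exp(-d2 / (2 * 0.3^2))
  got <- detect_spot(two$gfp, two$nuclear_mask)
  expect_lt(sqrt(sum((got - two$spot$center_um)^2)), 0.5)
})

test_that("marker measurement removes flat and gradient backgrounds", {
  sp <- cell_image_spec(nx = 41, ny = 41, nz = 15, cell_radius_um = 1.2,
                        nuclear_radius_um = 0.7, spot_amplitude = 0,
                        spot_offset_um = c(0, 0, 0), cd71_level = 300,
                        noise_sd = 0)
  st <- render_stack(sp)
  mm <- measure_marker(st$cd71, st$cell_mask)
  expect_equal(mm$value, 300, tolerance = 1e-6)

  # linear-gradient background + constant cell signal
  co <- burststage:::voxel_coords_um(st$cd71)
  vox <- st$cd71$voxels * 0
  for (k in seq_along(co$z))
    vox[, , k] <- outer(100 + 40 * co$x, rep(1, 41)) +
      outer(rep(1, 41), 20 * co$y) + 5 * co$z[k]
  vox[st$cell_mask] <- vox[st$cell_mask] + 250
  mg <- measure_marker(image_stack(vox), st$cell_mask)
  expect_lt(abs(mg$value - 250) / 250, 0.05)

  # no outside voxels: no background can be estimated
  expect_error(measure_marker(st$cd71,
                              array(TRUE, dim = dim(st$cd71$voxels))),
               "outside")
})

test_that("measurements are shift- and scale-equivariant", {
  st <- render_stack(seg_spec(spot_amplitude = 600,
                              noise_sd = (400 - 120) / 5), seed = 9)
  ctr <- st$spot$center_um
  bgc <- burststage:::default_background_center(st$gfp, ctr,
                                                st$nuclear_mask)
  q1 <- quantify_spot(st$gfp, ctr, bgc, background_mask = st$nuclear_mask)

  shifted <- st$gfp; shifted$voxels <- shifted$voxels + 500
  q2 <- quantify_spot(shifted, ctr, bgc, background_mask = st$nuclear_mask)
  expect_equal(q2$corrected, q1$corrected, tolerance = 1e-9)

  scaled <- st$gfp; scaled$voxels <- scaled$voxels * 3
  q3 <- quantify_spot(scaled, ctr, bgc, background_mask = st$nuclear_mask)
  expect_equal(q3$corrected, 3 * q1$corrected, tolerance = 1e-9)

  sp <- cell_image_spec(nx = 41, ny = 41, nz = 15, cell_radius_um = 1.2,
                        nuclear_radius_um = 0.7, spot_amplitude = 0,
                        spot_offset_um = c(0, 0, 0), cd71_level = 300,
                        noise_sd = 10)
  stm <- render_stack(sp, seed = 4)
  m1 <- measure_marker(stm$cd71, stm$cell_mask)
  sh <- stm$cd71; sh$voxels <- sh$voxels + 200
  m2 <- measure_marker(sh, stm$cell_mask)
  expect_equal(m2$value, m1$value, tolerance = 0.05)
})

test_that("cell size uses the central z-slice", {
  sp <- cell_image_spec(nx = 41, ny = 41, nz = 15, cell_radius_um = 1.2,
                        nuclear_radius_um = 0.7, spot_amplitude = 0,
                        spot_offset_um = c(0, 0, 0), noise_sd = 0)
  st <- render_stack(sp)
  cs <- cell_size(st$cell_mask)
  # within one pixel-ring of the analytic circle area
  expect_lt(abs(cs$area_um2 - pi * 1.2^2), 2 * pi * 1.2 * 0.086)
  # symmetric mask: the central slice is the middle one
  expect_equal(cs$central_slice, 8)

  single <- array(FALSE, dim = c(5, 5, 3)); single[3, 3, 2] <- TRUE
  cs1 <- cell_size(single)
  expect_equal(cs1$area_um2, 0.086^2)
  expect_equal(cs1$central_slice, 2)
})
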