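## ---- small 3D binary-array utilities (6-connectivity) -------------------

## Shift a 3D array by one voxel along an axis, padding with `fill`.
shift3 <- function(a, axis, by, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- lapply(d, seq_len)
  dst <- src
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
  else if (by < 0) { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L))
    out <- out | shift3(mask, ax, s, FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (s in c(-1L, 1L))
    out <- out & shift3(mask, ax, s, TRUE)
  out
}

close6 <- function(mask) erode6(dilate6(mask))

## Label 6-connected components of a logical 3D array. Returns an integer
## array (0 = background) using igraph on the foreground voxel graph.
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dim = d)
  if (length(idx) == 0L) return(lab)
  coord <- arrayInd(idx, d)
  rank <- integer(prod(d)); rank[idx] <- seq_along(idx)
  strides <- c(1L, d[1], d[1] * d[2])
  edges <- list()
  for (ax in 1:3) {
    ok <- coord[, ax] < d[ax]
    nb <- idx[ok] + strides[ax]
    both <- mask[nb]
    if (any(both))
      edges[[ax]] <- cbind(rank[idx[ok][both]], rank[nb[both]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0)
    g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

## Keep the largest component; if centroid (1-based x, y) given, prefer the
## component containing a voxel in that xy column, falling back to largest.
largest_component <- function(mask, centroid_px = NULL) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  if (!is.null(centroid_px)) {
    col_labs <- lab[centroid_px[1], centroid_px[2], ]
    col_labs <- col_labs[col_labs > 0]
    if (length(col_labs) > 0) {
      keep <- as.integer(names(which.max(table(col_labs))))
      return(lab == keep)
    }
  }
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

## Fill interior holes: background components not touching the array border
## become foreground.
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (max(lab) == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (lab > 0 & !(lab %in% border))
}

## ---- segmentation --------------------------------------------------------

#' Two-step k-means segmentation of cell and pseudo-nucleus
#'
#' Step 1 clusters all voxel intensities with k-means (k = 2, 10 seeded
#' restarts); the brighter cluster, after morphological closing, is reduced
#' to the connected component under the given xy centroid and its interior
#' holes are filled to give the cell mask. Step 2 clusters the intensities
#' within the cell mask (k = 2 again); the dimmer cluster's largest
#' connected component is the nuclear mask (the nucleus is relatively
#' GFP-depleted, so it appears as the dark interior of the bright cell).
#'
#' @param stack an [image_stack()] of the GFP channel.
#' @param centroid_px 1-based (x, y) pixel coordinates of the cell centre.
#' @param seed seed for the k-means restarts (default 1; deterministic).
#' @return List of class `cell_masks` with logical arrays `cell_mask` and
#'   `nuclear_mask` (`nuclear_mask` is contained in `cell_mask`).
#' @export
segment_two_step_kmeans <- function(stack, centroid_px, seed = 1) {
  v <- stack$voxels
  d <- dim(v)
  if (centroid_px[1] < 1 || centroid_px[1] > d[1] ||
      centroid_px[2] < 1 || centroid_px[2] > d[2])
    stop("centroid outside stack bounds")
  seg_fail <- function(msg, ...) {
    e <- simpleError(sprintf(paste0("segmentation failure: ", msg), ...))
    class(e) <- c("segmentation_failure", class(e))
    stop(e)
  }
  if (stats::sd(v) < 1e-12 || length(unique(as.vector(v))) < 2)
    seg_fail("uniform intensity stack, no clusters")
  set.seed(seed)
  km1 <- stats::kmeans(as.vector(v), centers = 2, nstart = 10)
  bright <- which.max(km1$centers)
  mask1 <- array(km1$cluster == bright, dim = d)
  if (!any(mask1)) seg_fail("empty bright cluster")
  mask1 <- close6(mask1)
  mask1 <- largest_component(mask1, centroid_px)
  cell_mask <- fill_holes(mask1)
  if (!any(cell_mask)) seg_fail("no cell component at the centroid")

  inside <- v[cell_mask]
  if (stats::sd(inside) < 1e-12) seg_fail("no intensity contrast inside cell")
  set.seed(seed + 1L)
  km2 <- stats::kmeans(inside, centers = 2, nstart = 10)
  dim_cl <- which.min(km2$centers)
  mask2 <- array(FALSE, dim = d)
  mask2[cell_mask] <- km2$cluster == dim_cl
  mask2 <- close6(mask2) & cell_mask
  nuclear_mask <- largest_component(mask2)
  if (!any(nuclear_mask)) seg_fail("nucleus not found within cell mask")
  structure(list(cell_mask = cell_mask, nuclear_mask = nuclear_mask),
            class = "cell_masks")
}

## ---- spot and marker measurement ----------------------------------------

## Logical membership arrays for an axis-aligned ellipsoid / cuboid of
## given extent (um) centred at center_um, by voxel-centre inclusion.
region_members <- function(stack, center_um, extent_um,
                           shape = c("ellipsoid", "cuboid")) {
  shape <- match.arg(shape)
  co <- voxel_coords_um(stack)
  half <- extent_um / 2
  lims_lo <- center_um - half
  lims_hi <- center_um + half
  rng <- vapply(1:3, function(i) c(min(co[[i]]), max(co[[i]])),
                numeric(2))
  if (any(lims_lo < rng[1, ] - 1e-9) || any(lims_hi > rng[2, ] + 1e-9))
    stop("measurement region out of stack bounds")
  d <- dim(stack$voxels)
  if (shape == "cuboid") {
    inx <- abs(co$x - center_um[1]) <= half[1] + 1e-12
    iny <- abs(co$y - center_um[2]) <= half[2] + 1e-12
    inz <- abs(co$z - center_um[3]) <= half[3] + 1e-12
    m <- array(FALSE, dim = d)
    m[inx, iny, inz] <- TRUE
  } else {
    ux <- (co$x - center_um[1]) / half[1]
    uy <- (co$y - center_um[2]) / half[2]
    uz <- (co$z - center_um[3]) / half[3]
    m <- array(FALSE, dim = d)
    for (k in which(abs(uz) <= 1)) {
      m[, , k] <- outer(ux^2, rep(1, d[2])) +
        outer(rep(1, d[1]), uy^2) + uz[k]^2 <= 1 + 1e-12
    }
  }
  if (!any(m)) stop("measurement region contains no voxel centres")
  m
}

#' Ovoid spot quantification with nuclear background subtraction
#'
#' Measures the mean intensity within an axis-aligned ovoid (default
#' 1 x 1 x 3 um in x, y, z) centred on the transcription spot, subtracts
#' the mean within a background cuboid (default 3 x 3 x 3 um) placed
#' inside the nucleus at the same z but displaced in xy, and reports the
#' corrected value. Voxels belong to a region when their centre lies
#' inside it.
#'
#' @param stack an [image_stack()].
#' @param spot_center_um spot centre (x, y, z) in um.
#' @param background_center_um background-region centre (x, y, z) in um.
#' @param ovoid_um ovoid extents (x, y, z) in um.
#' @param background_um cuboid extents in um.
#' @param background_mask optional logical array; when supplied the
#'   background cuboid is intersected with it (keeping the background
#'   region within the nucleus even when the full cuboid would not fit).
#' @return List of class `spot_measurement` with `raw_mean`,
#'   `background_mean`, `corrected` (may be negative) and `spot_center_um`.
#' @export
quantify_spot <- function(stack, spot_center_um, background_center_um,
                          ovoid_um = c(1, 1, 3), background_um = c(3, 3, 3),
                          background_mask = NULL) {
  spot_m <- region_members(stack, spot_center_um, ovoid_um, "ellipsoid")
  bg_m <- region_members(stack, background_center_um, background_um,
                         "cuboid")
  if (!is.null(background_mask)) {
    bg_m <- bg_m & background_mask
    if (!any(bg_m))
      stop("background cuboid does not intersect the background mask")
  }
  raw <- mean(stack$voxels[spot_m])
  bg <- mean(stack$voxels[bg_m])
  structure(list(raw_mean = raw, background_mean = bg,
                 corrected = raw - bg, spot_center_um = spot_center_um),
            class = "spot_measurement")
}

## Default background placement: same z as the spot, displaced in xy
## toward the nuclear centroid (default 3 um), the centre clamped to the
## nuclear bounding box and the stack bounds. Pair with the nuclear mask
## as `background_mask` in quantify_spot() so the measured region stays
## within the nucleus.
default_background_center <- function(stack, spot_center_um, nuclear_mask,
                                      displacement_um = 3,
                                      background_um = c(3, 3, 3)) {
  co <- voxel_coords_um(stack)
  idx <- which(nuclear_mask)
  stopifnot(length(idx) > 0)
  ci <- arrayInd(idx, dim(nuclear_mask))
  nuc_c <- c(mean(co$x[ci[, 1]]), mean(co$y[ci[, 2]]), mean(co$z[ci[, 3]]))
  dirv <- nuc_c[1:2] - spot_center_um[1:2]
  nrm <- sqrt(sum(dirv^2))
  dirv <- if (nrm < 1e-9) c(1, 0) else dirv / nrm
  ctr <- c(spot_center_um[1:2] + displacement_um * dirv, spot_center_um[3])
  # clamp into the nuclear bounding box, then into the stack bounds
  bbox <- rbind(c(min(co$x[ci[, 1]]), min(co$y[ci[, 2]]), min(co$z[ci[, 3]])),
                c(max(co$x[ci[, 1]]), max(co$y[ci[, 2]]), max(co$z[ci[, 3]])))
  ctr <- pmin(pmax(ctr, bbox[1, ]), bbox[2, ])
  half <- background_um / 2
  for (i in 1:3) {
    lo <- min(co[[i]]) + half[i]; hi <- max(co[[i]]) - half[i]
    ctr[i] <- min(max(ctr[i], lo), hi)
  }
  ctr
}

## Separable Gaussian smoothing with replicate padding; sigma_px per axis
## (0 skips an axis).
gauss_smooth <- function(a, sigma_px) {
  for (ax in 1:3) {
    s <- sigma_px[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (j in seq_along(w)) {
      off <- j - r - 1L
      acc <- acc + w[j] * shift_clamp(a, ax, off)
    }
    a <- acc
  }
  a
}

## Shift with replicate (clamped-index) padding.
shift_clamp <- function(a, axis, by) {
  if (by == 0) return(a)
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  a[idx[[1]], idx[[2]], idx[[3]]]
}

## Erode a mask by (approximately) a physical margin in um, accounting
## for anisotropic voxels; stops early rather than emptying the mask.
erode_margin <- function(mask, voxel_size_nm, margin_um) {
  iters <- round(margin_um / (voxel_size_nm / 1000))
  for (ax in 1:3) {
    for (i in seq_len(iters[ax])) {
      m2 <- mask & shift3(mask, ax, 1L, TRUE) & shift3(mask, ax, -1L, TRUE)
      if (!any(m2)) return(mask)
      mask <- m2
    }
  }
  mask
}

#' Detect the brightest nuclear transcription spot
#'
#' Applies a difference-of-Gaussians band-pass filter at the expected spot
#' scale and returns the brightest local response inside the nuclear
#' mask eroded by a physical margin (suppressing the band-pass response of
#' the nuclear boundary), provided its prominence over the in-nucleus
#' median response exceeds `prominence` times the robust spread (MAD) and
#' an absolute floor. Absence of a spot is a valid outcome (`NULL`);
#' callers typically reuse the last visible spot's coordinates.
#'
#' @param stack an [image_stack()].
#' @param nuclear_mask logical array congruent with the stack.
#' @param spot_sigma_um expected spot scale (um).
#' @param prominence required prominence in MAD units.
#' @param min_response absolute response floor (a.u.).
#' @param erode_margin_um physical margin eroded off the nuclear mask
#'   before searching (um).
#' @return Spot centre `c(x, y, z)` in um, or `NULL` when no spot clears
#'   the prominence criterion.
#' @export
detect_spot <- function(stack, nuclear_mask, spot_sigma_um = 0.3,
                        prominence = 5, min_response = 25,
                        erode_margin_um = 0.6) {
  stopifnot(any(nuclear_mask))
  vs <- stack$voxel_size_nm / 1000
  s1 <- spot_sigma_um / vs
  s2 <- 3 * s1
  band <- gauss_smooth(stack$voxels, s1) - gauss_smooth(stack$voxels, s2)
  m <- erode_margin(nuclear_mask, stack$voxel_size_nm, erode_margin_um)
  vals <- band[m]
  med <- stats::median(vals)
  spread <- stats::mad(vals)
  peak <- max(vals)
  if (peak - med <= max(prominence * spread, min_response)) return(NULL)
  idx <- which(m)[which.max(vals)]
  ci <- arrayInd(idx, dim(band))[1, ]
  co <- voxel_coords_um(stack)
  # refine within the full nuclear mask near the interior argmax (the
  # erosion may have clipped the true peak voxel)
  r <- max(2 * spot_sigma_um, 0.3)
  d <- dim(band)
  win <- lapply(1:3, function(ax) {
    coords <- co[[ax]]
    which(abs(coords - coords[ci[ax]]) <= r)
  })
  local <- array(FALSE, dim = d)
  local[win[[1]], win[[2]], win[[3]]] <- TRUE
  local <- local & nuclear_mask
  idx2 <- which(local)[which.max(band[local])]
  ci <- arrayInd(idx2, dim(band))[1, ]
  c(x = co$x[ci[1]], y = co$y[ci[2]], z = co$z[ci[3]])
}

#' Marker intensity with iteratively smoothed background
#'
#' Estimates the background field by iterative neighbourhood smoothing of
#' the voxels outside the cell mask: masked voxels are repeatedly replaced
#' by the mean of their 6-neighbours (red-black over-relaxed updates)
#' while outside voxels stay fixed at their observed values, until the
#' largest per-voxel change falls below `tol`. The marker measurement is
#' the mean observed intensity inside the mask minus the mean of the
#' converged background field over the same footprint.
#'
#' @param stack_marker an [image_stack()] of the marker channel.
#' @param cell_mask logical array congruent with the stack.
#' @param tol convergence tolerance (a.u.).
#' @param max_iter maximum smoothing iterations; a `convergence_error` is
#'   raised when exceeded.
#' @param omega over-relaxation factor in \[1, 2).
#' @return List of class `marker_measurement` with `value` (corrected mean
#'   marker intensity), `inside_mean`, `background_mean`, `iterations`.
#' @export
measure_marker <- function(stack_marker, cell_mask, tol = 0.01,
                           max_iter = 2000, omega = 1.9) {
  v <- stack_marker$voxels
  stopifnot(identical(dim(v), dim(cell_mask)), any(cell_mask))
  if (all(cell_mask))
    stop("cell mask covers the whole stack; no outside voxels to estimate background")
  # work on the mask bounding box (+2 voxel margin) for speed
  full_dim <- dim(v)
  ci_all <- arrayInd(which(cell_mask), full_dim)
  lo <- pmax(apply(ci_all, 2, min) - 2L, 1L)
  hi <- pmin(apply(ci_all, 2, max) + 2L, full_dim)
  v <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cell_mask <- cell_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(v)
  u <- v
  u[cell_mask] <- mean(v[!cell_mask])
  # checkerboard parity for red-black updates
  ci <- arrayInd(which(cell_mask), d)
  parity <- (rowSums(ci) %% 2) == 0
  idx_in <- which(cell_mask)
  red <- idx_in[parity]; black <- idx_in[!parity]
  neigh_mean <- function(u) {
    acc <- array(0, dim = d); cnt <- array(0, dim = d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      acc <- acc + shift3(u, ax, s, 0)
      cnt <- cnt + shift3(array(1, dim = d), ax, s, 0)
    }
    acc / cnt
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    for (grp in list(red, black)) {
      nm <- neigh_mean(u)
      newv <- u[grp] + omega * (nm[grp] - u[grp])
      delta <- max(delta, max(abs(newv - u[grp])))
      u[grp] <- newv
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    e <- simpleError("background smoothing did not converge within max_iter")
    class(e) <- c("convergence_error", class(e))
    stop(e)
  }
  inside <- mean(v[cell_mask])
  bg <- mean(u[cell_mask])
  structure(list(value = inside - bg, inside_mean = inside,
                 background_mean = bg, iterations = it),
            class = "marker_measurement")
}

#' Cell area from the central z-slice
#'
#' The central slice is the rounded z-centroid of the mask voxels; the
#' area is that slice's voxel count times the pixel area.
#'
#' @param cell_mask logical 3D array.
#' @param voxel_size_nm voxel size (x, y, z) in nm.
#' @return List with `area_um2` and `central_slice` (1-based z index).
#' @export
cell_size <- function(cell_mask, voxel_size_nm = c(86, 86, 500)) {
  stopifnot(any(cell_mask))
  d <- dim(cell_mask)
  counts <- vapply(seq_len(d[3]), function(k) sum(cell_mask[, , k]),
                   numeric(1))
  zc <- sum(seq_len(d[3]) * counts) / sum(counts)
  k0 <- as.integer(round(zc))
  px_area <- prod(voxel_size_nm[1:2] / 1000)
  list(area_um2 = sum(cell_mask[, , k0]) * px_area, central_slice = k0)
}
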