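#' 3D image stack container
#'
#' A light container for a single-channel 3D fluorescence stack. Voxels
#' are stored as an array indexed `[x, y, z]`; physical coordinates are in
#' micrometres with the origin at the centre of voxel (0, 0, 0) (0-based
#' voxel indices).
#'
#' @param voxels numeric 3D array (x, y, z), non-negative intensities.
#' @param voxel_size_nm numeric length-3 vector (x, y, z) in nm; default
#'   the acquisition voxel of 86 x 86 x 500 nm.
#' @param channel channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_nm = c(86, 86, 500),
                        channel = "GFP") {
  stopifnot(length(dim(voxels)) == 3, all(dim(voxels) >= 1),
            length(voxel_size_nm) == 3, all(voxel_size_nm > 0))
  structure(list(voxels = voxels,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack [%s]: %d x %d x %d voxels, %.0f x %.0f x %.0f nm\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size_nm[1], x$voxel_size_nm[2], x$voxel_size_nm[3]))
  invisible(x)
}

## Physical voxel-centre coordinate grids (um) for a stack.
voxel_coords_um <- function(stack) {
  d <- dim(stack$voxels)
  vs <- stack$voxel_size_nm / 1000
  list(x = (seq_len(d[1]) - 1) * vs[1],
       y = (seq_len(d[2]) - 1) * vs[2],
       z = (seq_len(d[3]) - 1) * vs[3])
}

#' Geometry and intensity settings of a synthetic cell image
#'
#' @param nx,ny,nz stack dimensions in voxels.
#' @param voxel_size_nm voxel size (x, y, z) in nm.
#' @param cell_radius_um,nuclear_radius_um radii of the spherical cell and
#'   nucleus (um); the nucleus (including any offset) must lie strictly
#'   inside the cell.
#' @param nucleus_offset_um nucleus centre offset from the cell centre (um).
#' @param background,nuclear_level,cyto_level intensity levels (a.u.) with
#'   `cyto_level > nuclear_level >= background`: the GFP channel shows a
#'   bright cytoplasm and a relatively GFP-depleted nucleus.
#' @param spot_amplitude peak intensity of the nuclear transcription spot
#'   above the nuclear level (a.u.); 0 disables the spot.
#' @param spot_sigma_um isotropic (in um) Gaussian spot width.
#' @param spot_offset_um spot centre offset from the nucleus centre (um);
#'   must stay inside the nucleus.
#' @param noise_sd additive Gaussian noise SD (a.u.); 0 disables.
#' @param poisson_noise if TRUE, voxel values are Poisson-resampled before
#'   Gaussian noise is added (shot noise).
#' @param cd71_level,ter119_level if non-NULL, marker channels are rendered
#'   as `background + level` inside the cell mask (plus the same noise
#'   model).
#' @return An object of class `cell_image_spec` (a validated list).
#' @export
cell_image_spec <- function(nx = 96, ny = 96, nz = 30,
                            voxel_size_nm = c(86, 86, 500),
                            cell_radius_um = 3.6, nuclear_radius_um = 2.2,
                            nucleus_offset_um = c(0, 0, 0),
                            background = 50, nuclear_level = 120,
                            cyto_level = 400,
                            spot_amplitude = 600, spot_sigma_um = 0.3,
                            spot_offset_um = c(0.8, 0, 0),
                            noise_sd = 0, poisson_noise = FALSE,
                            cd71_level = NULL, ter119_level = NULL) {
  stopifnot(cell_radius_um > 0, nuclear_radius_um > 0,
            all(voxel_size_nm > 0),
            cyto_level > nuclear_level, nuclear_level >= background,
            spot_amplitude >= 0, spot_sigma_um > 0, noise_sd >= 0)
  if (sqrt(sum(nucleus_offset_um^2)) + nuclear_radius_um >= cell_radius_um)
    stop("nucleus not strictly contained in the cell")
  if (sqrt(sum(spot_offset_um^2)) >= nuclear_radius_um)
    stop("spot centre must lie inside the nucleus")
  structure(as.list(environment()), class = "cell_image_spec")
}

#' Render a synthetic 3D cell stack with ground truth
#'
#' Builds a stack with a flat background, a bright spherical cytoplasm, a
#' GFP-depleted spherical nucleus and an isotropic-in-um Gaussian
#' transcription spot inside the nucleus, then applies the configured
#' noise. Ground-truth masks and spot parameters are returned alongside
#' the image. Rendering is deterministic under a fixed seed.
#'
#' @param spec a [cell_image_spec()].
#' @param seed optional integer seed for the noise.
#' @return List of class `synthetic_stack`: `gfp` ([image_stack()]),
#'   optional `cd71`/`ter119` stacks, `cell_mask`, `nuclear_mask` (logical
#'   arrays), `spot` (list: center_um, amplitude, sigma_um), `centroid_px`
#'   (cell centre, 1-based x/y pixel indices), `spec`.
#' @export
render_stack <- function(spec = cell_image_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cell_image_spec"))
  if (!is.null(seed)) set.seed(seed)
  vs <- spec$voxel_size_nm / 1000
  xs <- (seq_len(spec$nx) - 1) * vs[1]
  ys <- (seq_len(spec$ny) - 1) * vs[2]
  zs <- (seq_len(spec$nz) - 1) * vs[3]
  centre <- c(mean(range(xs)), mean(range(ys)), mean(range(zs)))
  dx2 <- outer(xs - centre[1], rep(1, spec$ny))^2
  # squared distance from the cell centre, voxel by voxel
  d2 <- array(0, dim = c(spec$nx, spec$ny, spec$nz))
  for (k in seq_len(spec$nz))
    d2[, , k] <- dx2 + outer(rep(1, spec$nx), (ys - centre[2])^2) +
      (zs[k] - centre[3])^2
  cell_mask <- d2 <= spec$cell_radius_um^2
  nuc_centre <- centre + spec$nucleus_offset_um
  d2n <- array(0, dim = dim(d2))
  for (k in seq_len(spec$nz))
    d2n[, , k] <- outer((xs - nuc_centre[1])^2, rep(1, spec$ny)) +
      outer(rep(1, spec$nx), (ys - nuc_centre[2])^2) +
      (zs[k] - nuc_centre[3])^2
  nuclear_mask <- d2n <= spec$nuclear_radius_um^2
  nuclear_mask <- nuclear_mask & cell_mask

  img <- array(spec$background, dim = dim(d2))
  img[cell_mask] <- spec$cyto_level
  img[nuclear_mask] <- spec$nuclear_level

  spot_centre <- nuc_centre + spec$spot_offset_um
  if (spec$spot_amplitude > 0) {
    d2s <- array(0, dim = dim(d2))
    for (k in seq_len(spec$nz))
      d2s[, , k] <- outer((xs - spot_centre[1])^2, rep(1, spec$ny)) +
        outer(rep(1, spec$nx), (ys - spot_centre[2])^2) +
        (zs[k] - spot_centre[3])^2
    img <- img + spec$spot_amplitude * exp(-d2s / (2 * spec$spot_sigma_um^2))
  }

  add_noise <- function(a) {
    if (spec$poisson_noise) a <- array(stats::rpois(length(a), pmax(a, 0)),
                                       dim = dim(a))
    if (spec$noise_sd > 0) a <- a + stats::rnorm(length(a), 0, spec$noise_sd)
    a
  }
  out <- list(gfp = image_stack(add_noise(img), spec$voxel_size_nm, "GFP"),
              cell_mask = cell_mask, nuclear_mask = nuclear_mask,
              spot = list(center_um = spot_centre,
                          amplitude = spec$spot_amplitude,
                          sigma_um = spec$spot_sigma_um),
              centroid_px = c(x = which.min(abs(xs - centre[1])),
                              y = which.min(abs(ys - centre[2]))),
              spec = spec)
  for (ch in c("cd71", "ter119")) {
    lvl <- spec[[paste0(ch, "_level")]]
    if (!is.null(lvl)) {
      m <- array(spec$background, dim = dim(d2))
      m[cell_mask] <- spec$background + lvl
      out[[ch]] <- image_stack(add_noise(m), spec$voxel_size_nm,
                               toupper(ch))
    }
  }
  class(out) <- "synthetic_stack"
  out
}

#' Write / read a stack as multi-page TIFF with a JSON sidecar
#'
#' One 32-bit page per z-slice. Intensities are stored divided by a fixed
#' scale of 65535 a.u. (the TIFF writer requires values in \[0, 1\]);
#' voxel size, channel and the scale are recorded in a plain-text JSON
#' sidecar `<path>.json`. When the sidecar is absent, `read_stack_tiff`
#' falls back to the `voxel_size_nm` argument and the default scale.
#' Requires the `tiff` package.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF IO")
  d <- dim(stack$voxels)
  scale <- 65535
  offset <- min(0, floor(min(stack$voxels)))
  if (max(stack$voxels) - offset > scale)
    stop("intensity range exceeds the fixed TIFF storage scale of 65535 a.u.")
  # tiff expects row-major matrices (y rows, x cols) per page
  pages <- lapply(seq_len(d[3]), function(k)
    (t(stack$voxels[, , k]) - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_nm = stack$voxel_size_nm,
                            channel = stack$channel,
                            intensity_scale = scale,
                            intensity_offset = offset),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param voxel_size_nm fallback voxel size when the sidecar is missing.
#' @export
read_stack_tiff <- function(path, voxel_size_nm = c(86, 86, 500)) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF IO")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  channel <- "GFP"; scale <- 65535; offset <- 0
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(meta)) {
      if (!is.null(meta$voxel_size_nm)) voxel_size_nm <- meta$voxel_size_nm
      if (!is.null(meta$channel)) channel <- meta$channel
      if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
      if (!is.null(meta$intensity_offset)) offset <- meta$intensity_offset
    }
  }
  vox <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- t(pages[[k]]) * scale + offset
  image_stack(vox, voxel_size_nm, channel)
}
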