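# Voxelized steady velocity fields: the common container for 4D-flow-MRI-like
# and CFD-like data. Cell-centered coordinates: voxel (i, j, k) (1-based in R)
# sits at origin + (i - 1/2, j - 1/2, k - 1/2) * spacing.

#' Construct a voxel velocity field
#'
#' A steady, three-component velocity field sampled on a regular grid with a
#' lumen mask. Velocities are zero outside the mask and must be finite inside.
#'
#' @param origin Coordinates of the grid corner (3-vector, m); voxel centers
#'   are offset by half a spacing.
#' @param spacing Voxel edge lengths (3-vector, m), all positive.
#' @param velocity 4-D numeric array `dims x 3` (m/s).
#' @param mask 3-D logical array of the lumen.
#' @return An object of class `"velocity_field"` with components `origin`,
#'   `spacing`, `dims`, `velocity`, `mask`.
#' @export
velocity_field <- function(origin, spacing, velocity, mask) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_af("spacing must be 3 positive lengths",
            class = "aortaflow_validation")
  dims <- dim(mask)
  if (length(dims) != 3L)
    stop_af("mask must be a 3-D array", class = "aortaflow_validation")
  if (!identical(dim(velocity), as.integer(c(dims, 3L))))
    stop_af("velocity must be a dims x 3 array matching the mask",
            class = "aortaflow_validation")
  mask <- array(as.logical(mask), dim = dims)
  if (!any(mask))
    stop_af("lumen mask is empty", class = "aortaflow_validation")
  vm <- matrix(velocity, ncol = 3L)
  inside <- as.vector(mask)
  if (any(!is.finite(vm[inside, ])))
    stop_af("velocities must be finite inside the mask",
            class = "aortaflow_validation")
  vm[!inside, ] <- 0
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = as.integer(dims),
                 velocity = array(vm, dim = c(dims, 3L)), mask = mask),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- paste(sprintf("%.2f", 1e3 * x$spacing), collapse = " x ")
  cat(sprintf("Velocity field: %s voxels at %s mm, %d in lumen\n",
              paste(x$dims, collapse = " x "), sp, sum(x$mask)))
  vmag <- field_speed(x)
  cat(sprintf("  peak speed %.3f m/s\n", max(vmag)))
  invisible(x)
}

# Voxel center coordinates along each axis.
axis_centers <- function(field) {
  lapply(1:3, function(k)
    field$origin[k] + (seq_len(field$dims[k]) - 0.5) * field$spacing[k])
}

# Per-voxel speed (3-D array).
field_speed <- function(field) {
  v <- matrix(field$velocity, ncol = 3L)
  array(sqrt(rowSums(v * v)), dim = field$dims)
}

# Trilinear interpolation of a 3-D array at world points (n x 3). Values
# outside the grid (beyond the outermost voxel centers) return `outside`.
interp_trilinear <- function(arr, origin, spacing, pts, outside = 0) {
  pts <- rbind(pts)
  d <- dim(arr)
  # continuous index: voxel centers at index i <-> coordinate origin+(i-0.5)h
  gi <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 0.5
  i0 <- floor(gi)
  fr <- gi - i0
  # clamp to valid cell range [1, d-1]; record which points are in range
  ok <- rep(TRUE, nrow(pts))
  for (k in 1:3) {
    ok <- ok & gi[, k] >= 1 & gi[, k] <= d[k]
    i0[, k] <- pmin(pmax(i0[, k], 1), d[k] - 1)
  }
  fr <- gi - i0
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  idx <- function(di, dj, dk)
    (i0[, 1] + di) + d[1] * ((i0[, 2] + dj - 1) + d[2] * (i0[, 3] + dk - 1))
  w <- function(di, dj, dk)
    (if (di == 0) 1 - fr[, 1] else fr[, 1]) *
    (if (dj == 0) 1 - fr[, 2] else fr[, 2]) *
    (if (dk == 0) 1 - fr[, 3] else fr[, 3])
  val <- numeric(nrow(pts))
  av <- as.vector(arr)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
    val <- val + w(di, dj, dk) * av[idx(di, dj, dk)]
  val[!ok] <- outside
  val
}

# Interpolate the 3 velocity components at world points -> n x 3 matrix.
interp_velocity <- function(field, pts) {
  pts <- rbind(pts)
  sapply(1:3, function(c3)
    interp_trilinear(field$velocity[, , , c3], field$origin, field$spacing,
                     pts, outside = 0))
}

#' Voxelize an aorta geometry
#'
#' Builds the regular grid covering the lumen (with margin), the lumen mask,
#' and the per-voxel centerline mapping (arclength, radial distance, in-plane
#' coordinates). The result is reused by [generate_velocity_field()] so that
#' many jets can be synthesized on one geometry without repeating the
#' (comparatively expensive) centerline projection.
#'
#' @param geometry An `aorta_geometry`.
#' @param spacing Voxel size (scalar or 3-vector, m).
#' @param margin Padding around the lumen bounding box (m).
#' @return An object of class `"aorta_voxelization"`: `origin`, `spacing`,
#'   `dims`, `mask`, and for lumen voxels the vectors `s`, `r`, `u`, `v` plus
#'   `index` (linear voxel indices).
#' @export
voxelize_geometry <- function(geometry, spacing = 1e-3, margin = 4e-3) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  rmax <- max(geometry$radius)
  lo <- apply(geometry$points, 2, min) - rmax - margin
  hi <- apply(geometry$points, 2, max) + rmax + margin
  dims <- pmax(ceiling((hi - lo) / spacing), 2L)
  centers <- lapply(1:3, function(k)
    lo[k] + (seq_len(dims[k]) - 0.5) * spacing[k])
  pts <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  # cheap prefilter: keep points within rmax + spacing of the centerline
  # bounding box per axis is already done; full projection is chunked
  pr <- project_to_centerline(geometry, pts)
  inside <- pr$r <= radius_at(geometry, pr$s) &
    pr$s > 0 & pr$s < geometry$length
  mask <- array(inside, dim = dims)
  structure(list(origin = lo, spacing = spacing, dims = as.integer(dims),
                 mask = mask, index = which(inside),
                 s = pr$s[inside], r = pr$r[inside],
                 u = pr$u[inside], v = pr$v[inside],
                 geometry = geometry),
            class = "aorta_voxelization")
}

# Arclength of each masked voxel of `field` along `geometry`'s centerline
# (NA outside the mask). Cached on the field as attribute "s_map".
field_arclengths <- function(field, geometry) {
  cached <- attr(field, "s_map")
  if (!is.null(cached)) return(cached)
  centers <- axis_centers(field)
  idx <- which(field$mask)
  ai <- arrayInd(idx, field$dims)
  pts <- cbind(centers[[1]][ai[, 1]], centers[[2]][ai[, 2]],
               centers[[3]][ai[, 3]])
  pr <- project_to_centerline(geometry, pts)
  s_map <- array(NA_real_, dim = field$dims)
  s_map[idx] <- pr$s
  s_map
}
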