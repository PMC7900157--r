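# Shared fixtures, built in code. Expensive objects (geometries,
# voxelizations) are memoised per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Straight tube geometry: ascending + descending with zero arch angle.
tube_geometry <- function(radius = 0.015, length = 0.1, s_stj = 0.02,
                          s_bca = 0.08, ds = 0.001) {
  build_idealized_aorta(aorta_config(
    ascending_length = length / 2, arch_angle_deg = 0,
    descending_length = length / 2, radius_start = radius,
    radius_end = radius, s_stj = s_stj, s_bca = s_bca, ds = ds))
}

default_geometry <- function()
  cached("geo_default", build_idealized_aorta())

default_voxelization_1mm <- function()
  cached("vox_1mm", voxelize_geometry(default_geometry(), spacing = 1e-3))

default_sections <- function()
  cached("sections_default", place_standard_sections(default_geometry()))

tube_geometry_cached <- function()
  cached("geo_tube", tube_geometry())

tube_voxelization_1mm <- function()
  cached("vox_tube_1mm", voxelize_geometry(tube_geometry_cached(),
                                           spacing = 1e-3))

tube_sections <- function()
  cached("sections_tube", place_standard_sections(tube_geometry_cached()))

# Velocity field built directly on a cylindrical grid (axis +z), from a
# per-point velocity function v(x, y, z) -> n x 3. Independent of the
# package's generator; used as an oracle-side construction.
cylinder_field <- function(vfun, radius = 0.01, height = 0.08,
                           spacing = 1e-3, pad = 2e-3) {
  half <- radius + pad
  nx <- ceiling(2 * half / spacing)
  nz <- ceiling(height / spacing)
  origin <- c(-half, -half, 0)
  cx <- origin[1] + (seq_len(nx) - 0.5) * spacing
  cz <- origin[3] + (seq_len(nz) - 0.5) * spacing
  g <- expand.grid(x = cx, y = cx, z = cz)
  mask <- array(g$x^2 + g$y^2 <= radius^2, dim = c(nx, nx, nz))
  v <- vfun(g$x, g$y, g$z)
  if (nrow(v) == 1L) v <- v[rep(1L, length(g$x)), , drop = FALSE]
  v[!as.vector(mask), ] <- 0
  velocity_field(origin, rep(spacing, 3),
                 array(v, dim = c(nx, nx, nz, 3)), mask)
}

# Solid-body rotation about z plus uniform axial flow; trilinear
# interpolation reproduces this linear field exactly, so streamline errors
# are purely the integrator's.
helical_cylinder_field <- function(omega = 100, vz = 1, radius = 0.01,
                                   height = 0.08, spacing = 1e-3) {
  cylinder_field(function(x, y, z) cbind(-omega * y, omega * x, vz),
                 radius = radius, height = height, spacing = spacing)
}

table2_path <- function() aortaflow_example("table2.csv")
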