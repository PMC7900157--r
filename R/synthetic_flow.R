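# Synthetic peak-systolic valve-jet fields with closed-form ground truth.
# The jet is a blunted power-law axial profile carried along the centerline,
# offset within the lumen and optionally swirling (solid-body rotation about
# the jet axis). Because every cross-sectional profile is axisymmetric about
# the jet center, the section statistics (v_max, SFD, NFD) have closed forms
# that serve as ground truth for the voxel-based estimators.

#' Specification of a synthetic valve jet
#'
#' @param v_peak Peak axial jet velocity (m/s).
#' @param jet_radius_fraction Jet radius as a fraction of the local lumen
#'   radius, in (0, 1].
#' @param offset_fraction Jet-center offset from the lumen center as a
#'   fraction of the local lumen radius, in `[0, 1)`. The jet must stay
#'   inside the lumen: `offset_fraction + jet_radius_fraction <= 1`.
#' @param offset_angle_deg Direction of the offset in the local in-plane
#'   frame (degrees from the first in-plane basis vector).
#' @param swirl_ratio Peak azimuthal (solid-body) velocity divided by
#'   `v_peak`; 0 disables swirl.
#' @param profile_exponent Bluntness exponent `p >= 1` of the axial profile
#'   `v(r') = v_peak (1 - (r'/r_jet)^p)`; large `p` gives a top-hat jet.
#' @param decay_length E-folding arclength (m) over which the jet relaxes
#'   toward a full-lumen profile (jet radius grows to the lumen radius, the
#'   offset decays to zero). `Inf` (default) keeps the jet unchanged along
#'   the vessel.
#' @return A list of class `"jet_spec"`.
#' @export
jet_spec <- function(v_peak = 2, jet_radius_fraction = 0.6,
                     offset_fraction = 0.2, offset_angle_deg = 0,
                     swirl_ratio = 0, profile_exponent = 4,
                     decay_length = Inf) {
  check_number(v_peak, "v_peak", positive = TRUE)
  check_number(jet_radius_fraction, "jet_radius_fraction", positive = TRUE)
  check_number(offset_fraction, "offset_fraction", nonneg = TRUE)
  check_number(swirl_ratio, "swirl_ratio", nonneg = TRUE)
  if (jet_radius_fraction > 1 || offset_fraction >= 1)
    stop_af("jet_radius_fraction must be in (0,1], offset_fraction in [0,1)",
            class = "aortaflow_validation")
  if (offset_fraction + jet_radius_fraction > 1 + 1e-12)
    stop_af("jet outside lumen: offset_fraction + jet_radius_fraction ",
            "must be <= 1", class = "aortaflow_validation")
  if (!is.numeric(profile_exponent) || profile_exponent < 1)
    stop_af("profile_exponent must be >= 1", class = "aortaflow_validation")
  if (!(is.numeric(decay_length) && decay_length > 0))
    stop_af("decay_length must be > 0 (possibly Inf)",
            class = "aortaflow_validation")
  structure(list(v_peak = v_peak,
                 jet_radius_fraction = jet_radius_fraction,
                 offset_fraction = offset_fraction,
                 offset_angle_deg = offset_angle_deg,
                 swirl_ratio = swirl_ratio,
                 profile_exponent = profile_exponent,
                 decay_length = decay_length),
            class = "jet_spec")
}

# Effective jet parameters at arclength s (relative to the valve plane):
# the jet radius relaxes toward the lumen radius and the offset decays, both
# with the same e-folding length, so the jet never leaves the lumen.
jet_local_params <- function(jet, s_rel, lumen_radius) {
  decay <- if (is.infinite(jet$decay_length)) rep(1, length(s_rel)) else
    exp(-pmax(s_rel, 0) / jet$decay_length)
  r_eff <- lumen_radius * (1 - (1 - jet$jet_radius_fraction) * decay)
  e_eff <- lumen_radius * jet$offset_fraction * decay
  list(r_eff = r_eff, e_eff = e_eff)
}

# Closed-form section statistics of the analytic jet profile at arclength s
# (from the valve plane) in a circular lumen of radius R. With x = r'/r_eff
# the in-jet profile is axial = v_peak (1 - x^p), swirl = sr v_peak x
# (both zero outside the jet), so:
#   v_max = v_peak * max_x sqrt((1 - x^p)^2 + (sr x)^2)   (> v_peak when
#           swirl is on: the swirl adds to the speed quadratically)
#   NFD   = e_eff / (2 R)   (profile is axisymmetric about the jet center,
#           so the flow-weighted centroid IS the jet center; D_h = 2R)
#   SFD   = [int w x dx] / [int axial x dx]
#         = sr * (1/3) / (p / (2 (p + 2)))
#         = sr * 2 (p + 2) / (3 p)                 (independent of r_eff)
jet_section_truth <- function(jet, s_rel, lumen_radius) {
  loc <- jet_local_params(jet, s_rel, lumen_radius)
  p <- jet$profile_exponent
  sr <- jet$swirl_ratio
  sfd <- sr * 2 * (p + 2) / (3 * p)
  speed2 <- function(x) (1 - x^p)^2 + (sr * x)^2
  vmax_factor <- if (sr == 0) 1 else
    sqrt(max(speed2(c(0, 1)),
             optimize(speed2, c(0, 1), maximum = TRUE)$objective))
  list(v_max = jet$v_peak * vmax_factor,
       nfd = loc$e_eff / (2 * lumen_radius),
       sfd = rep(sfd, length(s_rel)))
}

#' Generate a synthetic voxel velocity field with ground truth
#'
#' Samples the analytic jet profile onto a regular voxel grid covering the
#' aorta lumen and returns both the field and the closed-form ground-truth
#' statistics at the three standard sections. The axial component follows a
#' blunted power law about the (possibly offset) jet center; the in-plane
#' component is a solid-body swirl about the jet axis capped at
#' `swirl_ratio * v_peak`. Ground truth is evaluated from the analytic
#' profile, never from the voxels.
#'
#' @param geometry An `aorta_geometry`.
#' @param jet A [jet_spec()].
#' @param grid_spacing Voxel size (m); should resolve the jet with at least
#'   ~8 voxels across its diameter.
#' @param seed Integer seed recorded in the ground truth (the generator
#'   itself is deterministic; the seed also feeds downstream degradation).
#' @param voxelization Optional precomputed [voxelize_geometry()] result for
#'   this geometry/spacing, to amortize the centerline projection across
#'   many jets.
#' @return A list with components `field` (a [velocity_field()]) and `truth`
#'   (class `"jet_ground_truth"`: `true_v_max`, per-section `true_sfd` and
#'   `true_nfd` named `stj`, `mid_aa`, `pre_bca`, and `seed`).
#' @export
#' @examples
#' geo <- build_idealized_aorta(aorta_config(ds = 0.002))
#' gen <- generate_velocity_field(geo, jet_spec(offset_fraction = 0.3),
#'                                grid_spacing = 2e-3, seed = 1)
#' gen$truth
generate_velocity_field <- function(geometry, jet = jet_spec(),
                                    grid_spacing = 1e-3, seed = 0L,
                                    voxelization = NULL) {
  if (!inherits(jet, "jet_spec")) jet <- do.call(jet_spec, jet)
  if (is.null(voxelization))
    voxelization <- voxelize_geometry(geometry, spacing = grid_spacing)
  vox <- voxelization
  n_across <- 2 * jet$jet_radius_fraction * min(radius_at(geometry,
    c(geometry$landmarks$s_stj))) / max(vox$spacing)
  if (n_across < 4)
    warning("jet is resolved by fewer than 4 voxels across; ",
            "estimates will be coarse")
  s_rel <- vox$s - geometry$landmarks$s_valve
  lumen_r <- radius_at(geometry, vox$s)
  loc <- jet_local_params(jet, s_rel, lumen_r)
  ang <- jet$offset_angle_deg * pi / 180
  eu <- loc$e_eff * cos(ang)
  ev <- loc$e_eff * sin(ang)
  du <- vox$u - eu
  dv <- vox$v - ev
  rj <- sqrt(du * du + dv * dv)
  x <- pmin(rj / loc$r_eff, 1)
  in_jet <- rj <= loc$r_eff
  axial <- jet$v_peak * pmax(0, 1 - x^jet$profile_exponent)
  # solid-body swirl about the jet axis, confined to the jet like the axial
  # profile; azimuthal direction (-dv, du)/rj
  wmag <- jet$swirl_ratio * jet$v_peak * x * in_jet
  wu <- ifelse(rj > 0, -dv / rj, 0) * wmag
  wv <- ifelse(rj > 0, du / rj, 0) * wmag
  # assemble world-frame velocity at lumen voxels
  tg <- sapply(1:3, function(k)
    approx(geometry$s, geometry$tangent[, k], xout = vox$s, rule = 2)$y)
  n1 <- sapply(1:3, function(k)
    approx(geometry$s, geometry$n1[, k], xout = vox$s, rule = 2)$y)
  n2 <- matrix(rep(c(0, 1, 0), each = length(vox$s)), ncol = 3)
  vel_lumen <- axial * tg + wu * n1 + wv * n2
  velocity <- array(0, dim = c(vox$dims, 3L))
  vm <- matrix(velocity, ncol = 3L)
  vm[vox$index, ] <- vel_lumen
  velocity <- array(vm, dim = c(vox$dims, 3L))
  field <- velocity_field(vox$origin, vox$spacing, velocity, vox$mask)
  s_map <- array(NA_real_, dim = vox$dims)
  s_map[vox$index] <- vox$s
  attr(field, "s_map") <- s_map
  lm <- geometry$landmarks
  s_sections <- c(stj = lm$s_stj, mid_aa = (lm$s_stj + lm$s_bca) / 2,
                  pre_bca = lm$s_bca)
  tr <- jet_section_truth(jet, s_sections - lm$s_valve,
                          radius_at(geometry, s_sections))
  truth <- structure(list(true_v_max = tr$v_max,
                          true_sfd = setNames(tr$sfd, names(s_sections)),
                          true_nfd = setNames(tr$nfd, names(s_sections)),
                          section_s = s_sections,
                          seed = as.integer(seed), jet = jet),
                     class = "jet_ground_truth")
  list(field = field, truth = truth)
}

#' @export
print.jet_ground_truth <- function(x, ...) {
  cat(sprintf("Jet ground truth (seed %d): v_max = %.3f m/s\n",
              x$seed, x$true_v_max))
  cat("  SFD:", paste(sprintf("%s=%.3f", names(x$true_sfd), x$true_sfd),
                      collapse = ", "), "\n")
  cat("  NFD:", paste(sprintf("%s=%.3f", names(x$true_nfd), x$true_nfd),
                      collapse = ", "), "\n")
  invisible(x)
}

#' MRI-like degradation specification
#'
#' @param target_spacing Voxel size of the degraded field (3-vector, m).
#'   Default 2.80 x 2.25 x 2.25 mm, a typical 4D flow MRI reconstruction.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to each
#'   velocity component inside the resampled lumen (m/s).
#' @param seed Integer seed for the noise.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(target_spacing = c(2.80e-3, 2.25e-3, 2.25e-3),
                       noise_sd = 0, seed = 0L) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3L)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop_af("target_spacing must be 3 positive lengths",
            class = "aortaflow_validation")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(target_spacing = target_spacing, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# 1-D box-average operator from a source grid (n cells of width hs) onto the
# target grid (cells of width ht, same origin): rows are target cells,
# weighted by fractional overlap. Target cells not fully covered are dropped.
box_average_operator <- function(n_src, h_src, h_tgt) {
  n_tgt <- floor(n_src * h_src / h_tgt + 1e-9)
  if (n_tgt < 1)
    stop_af("target grid coarser than the whole source extent",
            class = "aortaflow_validation")
  if (abs(h_tgt / h_src - 1) < 1e-12) return(diag(n_src))
  w <- matrix(0, n_tgt, n_src)
  src_lo <- (seq_len(n_src) - 1) * h_src
  src_hi <- src_lo + h_src
  for (k in seq_len(n_tgt)) {
    lo <- (k - 1) * h_tgt; hi <- k * h_tgt
    ov <- pmin(src_hi, hi) - pmax(src_lo, lo)
    ov[ov < 0] <- 0
    w[k, ] <- ov / h_tgt
  }
  # zap roundoff slivers and renormalize so constants are preserved exactly
  w[w < 1e-9] <- 0
  w / rowSums(w)
}

apply_axis <- function(arr, w, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  r <- w %*% m
  out <- array(r, dim = c(nrow(w), d[setdiff(1:3, axis)]))
  aperm(out, order(perm))
}

#' Degrade a fine velocity field to MRI-like resolution
#'
#' Box-average (partial-volume) resampling of each velocity component onto a
#' coarser grid with the same origin, followed by seeded i.i.d. Gaussian
#' noise per component inside the resampled lumen. A coarse voxel belongs to
#' the lumen if at least half of its volume was lumen in the source field.
#' Velocities outside the source mask are zero and participate in the
#' averaging, emulating partial-volume dilution at the lumen border.
#'
#' @param field A [velocity_field()].
#' @param noise A [noise_spec()]; `target_spacing` must be at least as coarse
#'   as the source spacing on every axis.
#' @return A degraded [velocity_field()].
#' @export
degrade_to_mri <- function(field, noise = noise_spec()) {
  if (!inherits(noise, "noise_spec")) noise <- do.call(noise_spec, noise)
  if (any(noise$target_spacing < field$spacing - 1e-12))
    stop_af("target spacing finer than source spacing",
            class = "aortaflow_validation")
  ops <- lapply(1:3, function(k)
    box_average_operator(field$dims[k], field$spacing[k],
                         noise$target_spacing[k]))
  avg3 <- function(a) apply_axis(apply_axis(apply_axis(a, ops[[1]], 1),
                                            ops[[2]], 2), ops[[3]], 3)
  cover <- avg3(array(as.numeric(field$mask), dim = field$dims))
  new_mask <- cover >= 0.5
  if (!any(new_mask))
    stop_af("degraded lumen mask is empty", class = "aortaflow_validation")
  comps <- lapply(1:3, function(c3) avg3(field$velocity[, , , c3]))
  nd <- dim(cover)
  vel <- array(0, dim = c(nd, 3L))
  for (c3 in 1:3) vel[, , , c3] <- comps[[c3]]
  if (noise$noise_sd > 0) {
    n_in <- sum(new_mask)
    eps <- with_seed(noise$seed,
                     matrix(rnorm(3L * n_in, sd = noise$noise_sd), ncol = 3L))
    vm <- matrix(vel, ncol = 3L)
    vm[as.vector(new_mask), ] <- vm[as.vector(new_mask), ] + eps
    vel <- array(vm, dim = c(nd, 3L))
  }
  velocity_field(field$origin, noise$target_spacing, vel, new_mask)
}

#' Analytic Poiseuille reference profile
#'
#' Fully developed laminar pipe-flow profile
#' `v(r) = 2 (q / (pi R^2)) (1 - r^2 / R^2)`, used as an independent oracle
#' for maximum-velocity and section statistics (peak velocity equals twice
#' the mean).
#'
#' @param radius Tube radius R (m).
#' @param q Volumetric flow rate (m^3/s).
#' @return A list of class `"poiseuille_profile"` with fields `radius`, `q`,
#'   `v_mean`, `v_peak`, and a vectorized function `velocity(r)`.
#' @export
#' @examples
#' p <- poiseuille_reference(0.01, q = 0.5 * pi * 1e-4)  # mean 0.5 m/s
#' p$v_peak
poiseuille_reference <- function(radius, q) {
  check_number(radius, "radius", positive = TRUE)
  check_number(q, "q", positive = TRUE)
  v_mean <- q / (pi * radius^2)
  structure(list(radius = radius, q = q, v_mean = v_mean,
                 v_peak = 2 * v_mean,
                 velocity = function(r)
                   ifelse(r <= radius, 2 * v_mean * (1 - (r / radius)^2), 0)),
            class = "poiseuille_profile")
}
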