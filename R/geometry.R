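# Idealized aorta geometry: candy-cane centerline (straight ascending segment,
# circular arch in the x-z plane, straight descending segment) with a radius
# profile and the landmarks needed to place evaluation cross sections.

#' Configuration for the idealized aorta
#'
#' Parameters of the idealized thoracic aorta used in place of a
#' patient-specific segmentation: a straight ascending segment starting at the
#' valve plane, a circular arch of configurable angle in the x-z plane, and a
#' straight descending segment. The lumen radius varies linearly with
#' arclength between `radius_start` and `radius_end`.
#'
#' Defaults give an adult-scale aorta: ascending lumen radius 1.5 cm tapering
#' to 1.2 cm at the descending end, a 180 degree arch of 3.5 cm centerline
#' radius, and supra-aortic branch diameters in the usual adult range. The
#' sinotubular junction landmark sits 2.5 cm downstream of the valve plane;
#' the pre-brachiocephalic landmark sits at the end of the ascending segment,
#' where the arch begins.
#'
#' @param ascending_length Length of the straight ascending segment (m).
#' @param arch_radius Centerline radius of the arch (m).
#' @param arch_angle_deg Arch angle in degrees; 0 gives a straight tube.
#' @param descending_length Length of the straight descending segment (m).
#' @param radius_start,radius_end Lumen radius at the valve plane and at the
#'   distal end (m); the profile is linear in arclength.
#' @param s_valve,s_stj,s_bca Landmark arclengths (m): valve plane,
#'   sinotubular junction, and the section directly proximal to the
#'   brachiocephalic artery. `s_bca = NULL` places it at the end of the
#'   ascending segment. Must satisfy `s_valve < s_stj < s_bca`.
#' @param d_bca,d_lcc,d_lsa Diameters of the brachiocephalic, left common
#'   carotid and left subclavian arteries (m), used by the Murray outflow
#'   split.
#' @param ds Centerline sampling step (m).
#' @return A list of class `"aorta_config"`.
#' @export
aorta_config <- function(ascending_length = 0.07,
                         arch_radius = 0.035,
                         arch_angle_deg = 180,
                         descending_length = 0.08,
                         radius_start = 0.015,
                         radius_end = 0.012,
                         s_valve = 0,
                         s_stj = 0.025,
                         s_bca = NULL,
                         d_bca = 0.0125,
                         d_lcc = 0.008,
                         d_lsa = 0.0095,
                         ds = 0.001) {
  check_number(ascending_length, "ascending_length", positive = TRUE)
  check_number(arch_radius, "arch_radius", positive = TRUE)
  check_number(arch_angle_deg, "arch_angle_deg", nonneg = TRUE)
  check_number(descending_length, "descending_length", nonneg = TRUE)
  check_number(radius_start, "radius_start", positive = TRUE)
  check_number(radius_end, "radius_end", positive = TRUE)
  check_number(ds, "ds", positive = TRUE)
  for (d in c(d_bca = d_bca, d_lcc = d_lcc, d_lsa = d_lsa))
    check_number(d, "branch diameter", positive = TRUE)
  if (is.null(s_bca)) s_bca <- ascending_length
  check_number(s_valve, "s_valve", nonneg = TRUE)
  check_number(s_stj, "s_stj", positive = TRUE)
  check_number(s_bca, "s_bca", positive = TRUE)
  if (!(s_valve < s_stj && s_stj < s_bca))
    stop_af("landmarks must be ordered: s_valve < s_stj < s_bca",
            class = "aortaflow_validation")
  structure(list(ascending_length = ascending_length,
                 arch_radius = arch_radius,
                 arch_angle_deg = arch_angle_deg,
                 descending_length = descending_length,
                 radius_start = radius_start, radius_end = radius_end,
                 s_valve = s_valve, s_stj = s_stj, s_bca = s_bca,
                 d_bca = d_bca, d_lcc = d_lcc, d_lsa = d_lsa, ds = ds),
            class = "aorta_config")
}

#' Build an idealized aorta geometry
#'
#' Constructs the sampled centerline (points, arclength, unit tangents, and a
#' continuous in-plane frame), the linear lumen radius profile, and landmark
#' arclengths from an [aorta_config()]. The ascending segment runs along +z
#' from the origin (the valve plane); the arch bends in the x-z plane.
#'
#' The in-plane frame is `n2 = (0, 1, 0)` (perpendicular to the arch plane)
#' and `n1 = n2 x t`, which is smooth along the whole centerline because the
#' tangent never leaves the x-z plane.
#'
#' @param config An [aorta_config()]; the default gives an adult-scale aorta.
#' @return An object of class `"aorta_geometry"` with components `points`
#'   (n x 3 matrix, m), `s` (arclength, m), `tangent`, `n1`, `n2` (n x 3 unit
#'   vectors), `radius` (lumen radius at each `s`, m), `landmarks` (list with
#'   `s_valve`, `s_stj`, `s_bca`), `branch_diameters` (list `d_bca`, `d_lcc`,
#'   `d_lsa`), `length` (total arclength) and `config`.
#' @export
#' @examples
#' geo <- build_idealized_aorta()
#' range(geo$radius)
#' geo$landmarks
build_idealized_aorta <- function(config = aorta_config()) {
  if (!inherits(config, "aorta_config")) config <- do.call(aorta_config, config)
  asc <- config$ascending_length
  phi_max <- config$arch_angle_deg * pi / 180
  arch_len <- config$arch_radius * phi_max
  total <- asc + arch_len + config$descending_length
  if (config$s_bca > total)
    stop_af("s_bca lies beyond the end of the centerline",
            class = "aortaflow_validation")
  s <- seq(0, total, by = config$ds)
  if (s[length(s)] < total) s <- c(s, total)
  # ensure landmarks are exactly on the sample set (simplifies tests, not
  # required by any consumer: sections interpolate in s anyway)
  pts <- matrix(0, length(s), 3)
  tg <- matrix(0, length(s), 3)
  cx <- config$arch_radius  # arch center (cx, 0, asc)
  for (i in seq_along(s)) {
    si <- s[i]
    if (si <= asc) {
      pts[i, ] <- c(0, 0, si)
      tg[i, ] <- c(0, 0, 1)
    } else if (si <= asc + arch_len) {
      phi <- (si - asc) / config$arch_radius
      pts[i, ] <- c(cx - cx * cos(phi), 0, asc + cx * sin(phi))
      tg[i, ] <- c(sin(phi), 0, cos(phi))
    } else {
      d <- si - asc - arch_len
      p0 <- c(cx - cx * cos(phi_max), 0, asc + cx * sin(phi_max))
      t0 <- c(sin(phi_max), 0, cos(phi_max))
      pts[i, ] <- p0 + d * t0
      tg[i, ] <- t0
    }
  }
  n2 <- matrix(rep(c(0, 1, 0), each = length(s)), ncol = 3)
  n1 <- cbind(tg[, 3], 0, -tg[, 1])  # (0,1,0) x t
  radius <- config$radius_start +
    (config$radius_end - config$radius_start) * s / total
  structure(list(points = pts, s = s, tangent = tg, n1 = n1, n2 = n2,
                 radius = radius,
                 landmarks = list(s_valve = config$s_valve,
                                  s_stj = config$s_stj,
                                  s_bca = config$s_bca),
                 branch_diameters = list(d_bca = config$d_bca,
                                         d_lcc = config$d_lcc,
                                         d_lsa = config$d_lsa),
                 length = total, config = config),
            class = "aorta_geometry")
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat("Idealized aorta geometry\n")
  cat(sprintf("  centerline: %d points, total arclength %.1f cm\n",
              nrow(x$points), 100 * x$length))
  cat(sprintf("  lumen radius: %.2f -> %.2f cm\n",
              100 * x$radius[1], 100 * x$radius[length(x$radius)]))
  cat(sprintf("  landmarks (cm): valve %.2f, STJ %.2f, pre-BCA %.2f\n",
              100 * x$landmarks$s_valve, 100 * x$landmarks$s_stj,
              100 * x$landmarks$s_bca))
  invisible(x)
}

# Lumen radius, centerline point, and frame at arbitrary arclength s
# (linear interpolation between centerline samples).
radius_at <- function(geometry, s) {
  approx(geometry$s, geometry$radius, xout = s, rule = 2)$y
}

interp_rows <- function(m, s_grid, s) {
  sapply(1:3, function(k) approx(s_grid, m[, k], xout = s, rule = 2)$y)
}

centerline_at <- function(geometry, s) {
  p <- interp_rows(geometry$points, geometry$s, s)
  if (is.null(dim(p))) p else p
}

frame_at <- function(geometry, s) {
  t <- normalize(interp_rows(geometry$tangent, geometry$s, s))
  n2 <- c(0, 1, 0)
  n1 <- normalize(cross3(n2, t))
  list(tangent = t, n1 = n1, n2 = n2)
}

# Map arbitrary 3-D points onto the centerline: for each point, the nearest
# centerline sample refined by projection onto the local tangent. Returns
# arclength s, radial distance, and in-plane coordinates (u along n1, v along
# n2). Chunked so the distance matrix stays small.
project_to_centerline <- function(geometry, pts, chunk = 20000L) {
  pts <- rbind(pts)
  n <- nrow(pts)
  cl <- geometry$points
  cl_sq <- rowSums(cl * cl)
  out_s <- numeric(n); out_r <- numeric(n)
  out_u <- numeric(n); out_v <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    x <- pts[idx, , drop = FALSE]
    d2 <- outer(rowSums(x * x), cl_sq, "+") - 2 * tcrossprod(x, cl)
    near <- max.col(-d2, ties.method = "first")
    p0 <- cl[near, , drop = FALSE]
    tg <- geometry$tangent[near, , drop = FALSE]
    dx <- x - p0
    dt <- rowSums(dx * tg)
    s_here <- pmin(pmax(geometry$s[near] + dt, 0), geometry$length)
    rad_vec <- dx - dt * tg
    u <- rowSums(rad_vec * geometry$n1[near, , drop = FALSE])
    v <- rowSums(rad_vec * geometry$n2[near, , drop = FALSE])
    out_s[idx] <- s_here
    out_r[idx] <- sqrt(rowSums(rad_vec * rad_vec))
    out_u[idx] <- u
    out_v[idx] <- v
  }
  list(s = out_s, r = out_r, u = out_u, v = out_v)
}
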