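# Planar lumen cross sections: in-plane sampling of the lumen, area,
# perimeter (marching squares on a signed inside/outside function), and the
# hydraulic diameter D_h = 4A/P used to normalize flow displacement.

#' Extract a planar cross section of the lumen
#'
#' Intersects a plane with the lumen of either an idealized aorta geometry or
#' a voxelized velocity field and samples the intersection on a regular
#' in-plane grid. Area is the number of covered grid cells times the cell
#' area; the perimeter is measured with marching squares on a signed
#' inside/outside function (signed distance to the lumen surface for
#' geometries, interpolated mask minus 1/2 for voxel fields), so both
#' estimates converge as `resolution` shrinks.
#'
#' @param x An `aorta_geometry` or `velocity_field` object.
#' @param origin Point on the plane (3-vector, m).
#' @param normal Plane normal (3-vector; normalized internally).
#' @param resolution In-plane sampling step (m). Default 0.5 mm.
#' @param half_width Half-width of the sampled in-plane square (m); defaults
#'   to a bound derived from the object.
#' @return An object of class `"cross_section"` with components `origin`,
#'   `normal`, `basis` (2 x 3 orthonormal in-plane vectors), `uv` (k x 2
#'   in-plane coordinates of lumen samples), `points` (k x 3 world
#'   coordinates), `weights` (area elements, m^2), `area` (m^2), `perimeter`
#'   (m) and `hydraulic_diameter` (m).
#' @seealso [place_standard_sections()] for the three standard aortic
#'   sections.
#' @export
#' @examples
#' geo <- build_idealized_aorta()
#' cs <- lumen_cross_section(geo, origin = c(0, 0, 0.03), normal = c(0, 0, 1))
#' c(area_cm2 = 1e4 * cs$area, dh_mm = 1e3 * cs$hydraulic_diameter)
lumen_cross_section <- function(x, origin, normal, resolution = 5e-4,
                                half_width = NULL) {
  UseMethod("lumen_cross_section")
}

section_from_level <- function(level_fun, origin, normal, resolution,
                               half_width) {
  check_number(resolution, "resolution", positive = TRUE)
  normal <- normalize(normal)
  # in-plane basis: any vector not parallel to normal
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(ref - sum(ref * normal) * normal)
  e2 <- cross3(normal, e1)
  nu <- ceiling(half_width / resolution)
  grid1 <- (seq(-nu, nu)) * resolution
  uv <- as.matrix(expand.grid(u = grid1, v = grid1))
  pts <- matrix(origin, nrow(uv), 3, byrow = TRUE) +
    uv[, 1] %*% t(e1) + uv[, 2] %*% t(e2)
  f <- level_fun(pts)
  inside <- f >= 0
  if (!any(inside))
    stop_af("plane does not intersect the lumen (empty cross section)",
            class = "aortaflow_empty_section")
  if (any(inside[uv[, 1]^2 + uv[, 2]^2 >= (nu * resolution - resolution)^2]))
    warning("lumen may extend beyond the sampled in-plane window")
  fm <- matrix(f, 2 * nu + 1, 2 * nu + 1)  # u varies fastest -> rows = u
  mea <- marching_squares_measure(fm, resolution)
  area <- mea$area
  perim <- mea$perimeter
  dh <- 4 * area / perim
  structure(list(origin = origin, normal = normal,
                 basis = rbind(e1, e2),
                 uv = uv[inside, , drop = FALSE],
                 points = pts[inside, , drop = FALSE],
                 weights = rep(resolution^2, sum(inside)),
                 area = area, perimeter = perim, hydraulic_diameter = dh,
                 resolution = resolution),
            class = "cross_section")
}

#' @export
lumen_cross_section.aorta_geometry <- function(x, origin, normal,
                                               resolution = 5e-4,
                                               half_width = NULL) {
  if (is.null(half_width)) half_width <- 2.5 * max(x$radius)
  level <- function(pts) {
    pr <- project_to_centerline(x, pts)
    radius_at(x, pr$s) - pr$r  # signed distance-like: >0 inside lumen
  }
  section_from_level(level, origin, normal, resolution, half_width)
}

#' @export
lumen_cross_section.velocity_field <- function(x, origin, normal,
                                               resolution = 5e-4,
                                               half_width = NULL) {
  if (is.null(half_width))
    half_width <- max(x$dims * x$spacing) / 2
  maskd <- array(as.numeric(x$mask), dim = x$dims)
  level <- function(pts) {
    interp_trilinear(maskd, x$origin, x$spacing, pts, outside = 0) - 0.5
  }
  section_from_level(level, origin, normal, resolution, half_width)
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(paste0("Lumen cross section: %d samples, A = %.3f cm^2, ",
                     "P = %.2f cm, D_h = %.2f mm\n"),
              nrow(x$uv), 1e4 * x$area, 100 * x$perimeter,
              1e3 * x$hydraulic_diameter))
  invisible(x)
}

# Perimeter and area of the zero level-set of a scalar field sampled on a
# regular grid (marching squares with linear edge interpolation; saddle cells
# decided by the cell-center average). Both are measured on the SAME
# piecewise-linear contour: the perimeter sums the crossing chords and the
# area sums the per-cell clipped polygons (cell-edge pieces cancel between
# neighbors), so the pair describes one closed polygon and the isoperimetric
# inequality P^2 >= 4 pi A holds by construction.
marching_squares_measure <- function(f, h) {
  ni <- nrow(f); nj <- ncol(f)
  a <- f[-ni, -nj]; b <- f[-1, -nj]; cc <- f[-1, -1]; d <- f[-ni, -1]
  inside_full <- a >= 0 & b >= 0 & cc >= 0 & d >= 0
  code <- (a >= 0) + 2L * (b >= 0) + 4L * (cc >= 0) + 8L * (d >= 0)
  mixed <- which(code != 0L & code != 15L)
  area <- sum(inside_full)
  perim <- 0
  if (length(mixed)) {
    frac <- function(p, q) p / (p - q)  # zero crossing from corner p to q
    shoelace <- function(poly) {
      n <- nrow(poly)
      j <- c(2:n, 1)
      abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
    }
    for (m in mixed) {
      vals <- c(a[m], b[m], cc[m], d[m])
      # corners in traversal order with the crossing on the following edge
      corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
      nxt <- c(2, 3, 4, 1)
      cross_pt <- function(i) {
        t <- frac(vals[i], vals[nxt[i]])
        corners[i, ] + t * (corners[nxt[i], ] - corners[i, ])
      }
      # a saddle disconnects into two corner triangles when the cell center
      # is outside the region
      split_saddle <- code[m] %in% c(5L, 10L) && mean(vals) < 0
      if (split_saddle) {
        # two disjoint corner triangles
        ins <- which(vals >= 0)
        for (i in ins) {
          prev <- which(nxt == i)
          poly <- rbind(cross_pt(prev), corners[i, ], cross_pt(i))
          area <- area + shoelace(poly)
          perim <- perim + sqrt(sum((poly[1, ] - poly[3, ])^2))
        }
      } else {
        poly <- NULL
        chord_from <- NULL
        for (i in 1:4) {
          if (vals[i] >= 0) poly <- rbind(poly, corners[i, ])
          if ((vals[i] >= 0) != (vals[nxt[i]] >= 0)) {
            cp <- cross_pt(i)
            # a chord runs from a crossing that leaves the region to the
            # next crossing that re-enters it
            if (vals[i] >= 0) chord_from <- cp
            else if (!is.null(chord_from)) {
              perim <- perim + sqrt(sum((cp - chord_from)^2))
              chord_from <- NULL
            }
            poly <- rbind(poly, cp)
          }
        }
        # wrap-around chord (left the region after the last crossing)
        if (!is.null(chord_from)) {
          first_cross <- which((vals >= 0) != (vals[nxt] >= 0))[1]
          perim <- perim + sqrt(sum((cross_pt(first_cross) - chord_from)^2))
        }
        area <- area + shoelace(poly)
      }
    }
  }
  list(perimeter = perim * h, area = area * h^2)
}

#' Place the three standard aortic cross sections
#'
#' Returns cross sections at the sinotubular junction, in the middle of the
#' ascending aorta (midway between the two outer sections), and directly
#' proximal to the brachiocephalic artery. Each section is perpendicular to
#' the local centerline tangent at its landmark arclength. These are the
#' planes on which secondary flow degree and normalized flow displacement are
#' evaluated.
#'
#' @param geometry An `aorta_geometry` with landmarks set.
#' @param resolution In-plane sampling step passed to
#'   [lumen_cross_section()] (m).
#' @return Named list of three `cross_section` objects: `stj`, `mid_aa`,
#'   `pre_bca`, each carrying its arclength as attribute `"s"`.
#' @export
place_standard_sections <- function(geometry, resolution = 5e-4) {
  lm <- geometry$landmarks
  if (is.null(lm$s_stj) || is.null(lm$s_bca))
    stop_af("geometry landmarks s_stj and s_bca must be set",
            class = "aortaflow_validation")
  s_vals <- c(stj = lm$s_stj, mid_aa = (lm$s_stj + lm$s_bca) / 2,
              pre_bca = lm$s_bca)
  out <- lapply(s_vals, function(s) {
    fr <- frame_at(geometry, s)
    cs <- lumen_cross_section(geometry, origin = centerline_at(geometry, s),
                              normal = fr$tangent, resolution = resolution)
    attr(cs, "s") <- s
    cs
  })
  names(out) <- names(s_vals)
  out
}
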