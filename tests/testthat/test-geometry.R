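test_that("straight-tube and curved configurations satisfy the geometric contracts", {
  tube <- tube_geometry(radius = 0.015, length = 0.1)
  # centerline is a straight segment along +z with constant radius
  expect_equal(unique(round(tube$points[, 1], 12)), 0)
  expect_equal(unique(round(tube$points[, 2], 12)), 0)
  expect_true(all(diff(tube$s) > 0))
  expect_equal(unique(tube$radius), 0.015)

  geo <- build_idealized_aorta()
  expect_true(all(diff(geo$s) > 0))
  expect_true(all(geo$radius > 0))
  lm <- geo$landmarks
  expect_true(lm$s_valve < lm$s_stj && lm$s_stj < lm$s_bca)
  mid <- (lm$s_stj + lm$s_bca) / 2
  expect_true(lm$s_stj < mid && mid < lm$s_bca)
  # tangents are unit vectors everywhere
  expect_equal(max(abs(sqrt(rowSums(geo$tangent^2)) - 1)), 0,
               tolerance = 1e-12)

  # linear taper 1.5 -> 1.2 cm: radius at the arclength midpoint is 1.35 cm
  expect_equal(radius_at <- approx(geo$s, geo$radius,
                                   xout = geo$length / 2)$y,
               0.0135, tolerance = 1e-10)

  # unordered landmarks are rejected
  expect_error(aorta_config(s_stj = 0.08, s_bca = 0.03), "ordered")
})

test_that("cross sections of a circular tube recover area, perimeter, hydraulic diameter", {
  tube <- tube_geometry(radius = 0.01, length = 0.1)
  cs <- lumen_cross_section(tube, origin = c(0, 0, 0.05),
                            normal = c(0, 0, 1), resolution = 2.5e-4)
  expect_equal(cs$area, pi * 1e-4, tolerance = 0.01)
  expect_equal(cs$hydraulic_diameter, 0.02, tolerance = 0.01)
  # isoperimetric bound, with near-equality for a circle
  expect_lte(cs$hydraulic_diameter,
             2 * sqrt(cs$area / pi) * (1 + 1e-6))
  expect_equal(cs$hydraulic_diameter, 2 * sqrt(cs$area / pi),
               tolerance = 1e-3)

  # area estimate converges: halving resolution changes A by < 0.5%
  cs2 <- lumen_cross_section(tube, origin = c(0, 0, 0.05),
                             normal = c(0, 0, 1), resolution = 1.25e-4)
  expect_lt(abs(cs2$area - cs$area) / cs2$area, 0.005)

  # plane that misses the lumen errors
  expect_error(lumen_cross_section(tube, origin = c(0.5, 0, 0.05),
                                   normal = c(0, 0, 1)),
               class = "aortaflow_empty_section")
})

test_that("a tilted plane through a tube yields the analytic ellipse", {
  tube <- tube_geometry(radius = 0.01, length = 0.1)
  th <- 60 * pi / 180
  n <- c(sin(th), 0, cos(th))
  cs <- lumen_cross_section(tube, origin = c(0, 0, 0.05), normal = n,
                            resolution = 2.5e-4)
  a <- 0.01 / cos(th); b <- 0.01
  expect_equal(cs$area, pi * a * b, tolerance = 0.02)
  # perimeter against a numeric-quadrature ellipse arclength oracle
  per_oracle <- integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                          0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(cs$perimeter, per_oracle, tolerance = 0.02)
})

test_that("standard sections sit at the landmark arclengths with tangent normals", {
  geo <- default_geometry()
  secs <- place_standard_sections(geo)
  lm <- geo$landmarks
  expect_equal(unname(vapply(secs, attr, numeric(1), "s")),
               c(lm$s_stj, (lm$s_stj + lm$s_bca) / 2, lm$s_bca))

  # straight tube: all three normals equal the axis
  tsecs <- tube_sections()
  for (cs in tsecs) expect_equal(cs$normal, c(0, 0, 1), tolerance = 1e-9)

  # curved geometry: normals match a finite-difference tangent oracle.
  # Landmarks are placed away from the straight/arch junction (where the
  # curvature jumps and a symmetric difference is not the tangent) by
  # putting the distal landmark halfway around the arch.
  arch_len <- 0.035 * pi
  geo2 <- build_idealized_aorta(aorta_config(s_stj = 0.03,
                                             s_bca = 0.07 + arch_len / 2,
                                             ds = 1e-4))
  secs2 <- place_standard_sections(geo2, resolution = 1e-3)
  for (cs in secs2) {
    s <- attr(cs, "s")
    h <- 5e-4
    p1 <- sapply(1:3, function(k) approx(geo2$s, geo2$points[, k], s + h)$y)
    p0 <- sapply(1:3, function(k) approx(geo2$s, geo2$points[, k], s - h)$y)
    fd <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
    expect_equal(cs$normal, fd, tolerance = 1e-3)
  }
})

test_that("prosthesis internal diameter calibrates from the reference flow/Reynolds pair", {
  # invert Re = 4 rho Q / (pi mu D) on the size-23 reference row
  ratio <- calibrate_internal_ratio(354, 6997, 23)
  expect_equal(ratio, default_internal_ratio(), tolerance = 1e-9)
  expect_equal(1e3 * prosthesis_internal_diameter(23), 19.325,
               tolerance = 1e-3)
  # linear scaling across sizes
  expect_equal(1e3 * prosthesis_internal_diameter(21),
               19.32515 * 21 / 23, tolerance = 1e-3)
  # identity ratio
  expect_equal(prosthesis_internal_diameter(25, internal_ratio = 1), 0.025)
  expect_error(prosthesis_internal_diameter(24), "must be one of")
})

test_that("one internal ratio fits the whole packaged cohort", {
  t2 <- read_patient_table(table2_path())
  ratios <- mapply(calibrate_internal_ratio, t2$q_peak_ml_s, t2$reynolds,
                   t2$size_as_mm)
  expect_lt(diff(range(ratios)) / mean(ratios), 0.003)
})
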