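test_that("Carreau-Yasuda viscosity hits both limits and is shear-thinning", {
  expect_equal(carreau_yasuda_viscosity(0), 0.16)
  expect_equal(round(carreau_yasuda_viscosity(1e6), 4), 0.0035)
  # closed-form oracle at an intermediate shear rate
  p <- rheology_params()
  mu100 <- p$mu_inf + (p$mu0 - p$mu_inf) *
    (1 + (p$lam * 100)^p$a)^((p$n - 1) / p$a)
  expect_equal(carreau_yasuda_viscosity(100), mu100)
  expect_equal(mu100, 0.00428, tolerance = 1e-3)
  # monotone non-increasing over a log-spaced grid
  g <- 10^seq(-3, 6, length.out = 200)
  expect_true(all(diff(carreau_yasuda_viscosity(g)) <= 0))
  expect_error(carreau_yasuda_viscosity(-1), class = "aortaflow_validation")
})

test_that("orifice Reynolds numbers reproduce the packaged cohort", {
  d23 <- prosthesis_internal_diameter(23)
  expect_lte(abs(round(reynolds_number(539e-6, d23)) - 10653), 2)
  expect_lte(abs(round(reynolds_number(235e-6, d23)) - 4645), 2)
  # linearity in flow rate
  expect_equal(reynolds_number(2 * 354e-6, d23),
               2 * reynolds_number(354e-6, d23))
  expect_error(reynolds_number(-1, d23), class = "aortaflow_validation")
})

test_that("maximum velocity handles uniform, Poiseuille, and jet fields", {
  uni <- cylinder_field(function(x, y, z) cbind(0, 0, 1))
  expect_equal(max_velocity(uni), 1)

  R <- 0.01
  pois <- poiseuille_reference(R, q = 0.5 * pi * R^2)
  pf <- cylinder_field(function(x, y, z)
    cbind(0, 0, pois$velocity(sqrt(x^2 + y^2))),
    radius = R, spacing = 2.5e-4)
  expect_equal(max_velocity(pf), 1.0, tolerance = 0.01)

  gen <- generate_velocity_field(tube_geometry_cached(),
                                 jet_spec(v_peak = 2, swirl_ratio = 0),
                                 grid_spacing = 1e-3, seed = 1,
                                 voxelization = tube_voxelization_1mm())
  expect_equal(max_velocity(gen$field), 2, tolerance = 0.02)

  # a quantile guard never exceeds the strict maximum and damps noise
  noisy <- degrade_to_mri(gen$field, noise_spec(noise_sd = 0.1, seed = 1))
  expect_lte(max_velocity(noisy, quantile_guard = 0.99),
             max_velocity(noisy))
  expect_lt(abs(max_velocity(noisy, quantile_guard = 0.999) - 2),
            abs(max_velocity(noisy) - 2))

  # empty region errors
  empty <- array(FALSE, dim = uni$dims)
  expect_error(max_velocity(uni, region = empty),
               class = "aortaflow_empty_region")
})

test_that("simplified Bernoulli gradient follows 4 v^2", {
  expect_equal(bernoulli_dp(0), 0)
  expect_equal(bernoulli_dp(1), 4)
  expect_equal(bernoulli_dp(2.1), 17.64)
  expect_equal(round(bernoulli_dp(2.1)), 18)
  expect_error(bernoulli_dp(-0.1), class = "aortaflow_validation")
})

test_that("secondary flow degree matches constant-ratio and helical oracles", {
  tube <- tube_geometry(radius = 0.01, length = 0.1)
  cs <- lumen_cross_section(tube, c(0, 0, 0.05), c(0, 0, 1),
                            resolution = 2.5e-4)
  # purely axial flow -> 0
  axial <- cylinder_field(function(x, y, z) cbind(0, 0, 1))
  expect_equal(secondary_flow_degree(axial, cs), 0)
  # uniform in-plane 0.5 with through-plane 1 -> 0.5 everywhere
  mixed <- cylinder_field(function(x, y, z) cbind(0.5, 0, 1))
  expect_equal(secondary_flow_degree(mixed, cs), 0.5, tolerance = 1e-6)
  # helical field with in-plane speed equal to axial speed at every point
  helix <- cylinder_field(function(x, y, z) {
    r <- sqrt(x^2 + y^2)
    cbind(-y * 100, x * 100, r * 100)
  })
  expect_equal(secondary_flow_degree(helix, cs), 1, tolerance = 0.02)
  # zero through-plane flow is an error, not infinity
  swirl_only <- cylinder_field(function(x, y, z) cbind(-y * 10, x * 10, 0))
  expect_error(secondary_flow_degree(swirl_only, cs),
               class = "aortaflow_undefined")
})

test_that("normalized flow displacement matches symmetry and uniform-jet oracles", {
  tube <- tube_geometry(radius = 0.015, length = 0.1)
  cs <- lumen_cross_section(tube, c(0, 0, 0.05), c(0, 0, 1),
                            resolution = 2.5e-4)
  # axisymmetric profile -> 0
  pois <- poiseuille_reference(0.015, q = 1e-4)
  pf <- cylinder_field(function(x, y, z)
    cbind(0, 0, pois$velocity(sqrt(x^2 + y^2))), radius = 0.015,
    spacing = 5e-4)
  expect_lt(normalized_flow_displacement(pf, cs), 1e-3)
  # uniform jet of radius 5 mm centered 4.5 mm off-axis: NFD = 4.5/30
  jf <- cylinder_field(function(x, y, z)
    cbind(0, 0, as.numeric((x - 4.5e-3)^2 + y^2 <= 5e-3^2)),
    radius = 0.015, spacing = 5e-4)
  expect_equal(normalized_flow_displacement(jf, cs), 0.15,
               tolerance = 0.01)
  # no forward flow is an error
  back <- cylinder_field(function(x, y, z) cbind(0, 0, -1), radius = 0.015)
  expect_error(normalized_flow_displacement(back, cs),
               class = "aortaflow_undefined")
})

test_that("SFD and NFD are invariant under rotation of the jet about the vessel axis", {
  geo <- tube_geometry_cached()
  secs <- tube_sections()
  vals <- lapply(c(0, 37, 90), function(ang) {
    gen <- generate_velocity_field(
      geo, jet_spec(offset_fraction = 0.25, swirl_ratio = 0.3,
                    offset_angle_deg = ang),
      grid_spacing = 1e-3, seed = 1, voxelization = tube_voxelization_1mm())
    c(vapply(secs, function(s) secondary_flow_degree(gen$field, s),
             numeric(1)),
      vapply(secs, function(s) normalized_flow_displacement(gen$field, s),
             numeric(1)))
  })
  expect_equal(vals[[2]], vals[[1]], tolerance = 0.02)
  expect_equal(vals[[3]], vals[[1]], tolerance = 0.02)
})

test_that("EOA, IEOA and PPM classification follow their defining formulas", {
  expect_equal(effective_orifice_area(300, 16), 300 / (51.6 * 4))
  expect_equal(effective_orifice_area(600, 16),
               2 * effective_orifice_area(300, 16))
  expect_equal(effective_orifice_area(300, 64),
               effective_orifice_area(300, 16) / 2)
  expect_error(effective_orifice_area(300, 0),
               class = "aortaflow_undefined")

  expect_equal(indexed_eoa(2, 2), 1)
  expect_equal(indexed_eoa(1.8, 2.19), 1.8 / 2.19)
  expect_equal(indexed_eoa(1.3, 1), 1.3)

  expect_equal(as.character(classify_ppm(c(0.9, 0.7, 0.6))),
               c("none", "moderate", "severe"))
  # boundary values are moderate ("above 0.85" none, "below 0.65" severe)
  expect_equal(as.character(classify_ppm(c(0.85, 0.65))),
               c("moderate", "moderate"))
  expect_error(classify_ppm(0), class = "aortaflow_validation")
})

test_that("Murray outflow split obeys the branch constraint and conserves mass", {
  # equal diameters: BCA gets half the arch flow, LCC and LSA a quarter each
  sp <- murray_outflow_split(200e-6, 100e-6, d_lcc = 0.008, d_lsa = 0.008)
  expect_equal(sp$q_bca, 50e-6)
  expect_equal(sp$q_lcc, 25e-6)
  expect_equal(sp$q_lsa, 25e-6)
  # cube law 2:1 diameters -> 8:1 flows within the LCC/LSA half
  sp2 <- murray_outflow_split(200e-6, 100e-6, d_lcc = 0.012,
                              d_lsa = 0.006)
  expect_equal(sp2$q_lcc, 50e-6 * 8 / 9)
  expect_equal(sp2$q_lsa, 50e-6 / 9)
  expect_error(murray_outflow_split(100e-6, 100e-6, 0.008, 0.008),
               class = "aortaflow_validation")

  # mass conservation over 1000 random valid inputs
  set.seed(7)
  for (i in 1:200) {
    q_in <- runif(1, 1e-5, 1e-3)
    q_desc <- runif(1, 0.1, 0.9) * q_in
    d1 <- runif(1, 0.004, 0.02); d2 <- runif(1, 0.004, 0.02)
    spl <- murray_outflow_split(q_in, q_desc, d1, d2)
    expect_equal(spl$q_desc + spl$q_bca + spl$q_lcc + spl$q_lsa, spl$q_in,
                 tolerance = 1e-12)
    expect_equal(spl$q_bca, spl$q_lcc + spl$q_lsa, tolerance = 1e-12)
  }
})

test_that("analyze_case assembles a consistent report end to end", {
  geo <- tube_geometry_cached()
  gen <- generate_velocity_field(
    geo, jet_spec(v_peak = 2, offset_fraction = 0, swirl_ratio = 0),
    grid_spacing = 1e-3, seed = 2, voxelization = tube_voxelization_1mm())
  pat <- patient_record("IV", q_peak_ml_s = 539, bsa_m2 = 2.19,
                        size_vi_mm = 25, size_as_mm = 23)
  rep <- analyze_case(gen$field, geo, patient = pat,
                      prosthesis = prosthesis_model(23))
  # internal consistency: dp = 4 v^2 exactly, centered jet has NFD ~ 0
  expect_identical(rep$dp_max, 4 * rep$v_max^2)
  expect_true(all(rep$nfd < 0.02))
  expect_equal(rep$v_max, 2, tolerance = 0.02)
  # EOA/IEOA/PPM chain and the cohort Reynolds value
  expect_equal(rep$eoa, 539 / (51.6 * sqrt(rep$dp_max)))
  expect_equal(rep$ieoa, rep$eoa / 2.19)
  expect_lte(abs(round(rep$reynolds) - 10653), 2)
})
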