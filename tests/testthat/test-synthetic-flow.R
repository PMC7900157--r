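test_that("centered jets have zero displacement and swirl-free sections", {
  geo <- tube_geometry_cached()
  gen <- generate_velocity_field(
    geo, jet_spec(v_peak = 2, offset_fraction = 0, swirl_ratio = 0),
    grid_spacing = 1e-3, seed = 1,
    voxelization = tube_voxelization_1mm())
  expect_equal(unname(gen$truth$true_nfd), rep(0, 3))
  expect_equal(unname(gen$truth$true_sfd), rep(0, 3))
  expect_equal(gen$truth$true_v_max, 2)
  # field invariants: zero outside mask, finite inside
  vm <- matrix(gen$field$velocity, ncol = 3)
  expect_true(all(vm[!as.vector(gen$field$mask), ] == 0))
  expect_true(all(is.finite(vm[as.vector(gen$field$mask), ])))
})

test_that("offset-jet ground truth equals the uniform-disc centroid displacement", {
  # offset 0.3 of a 1.5 cm lumen -> displacement 4.5 mm; D_h = 30 mm
  geo <- tube_geometry_cached()
  gen <- generate_velocity_field(
    geo, jet_spec(offset_fraction = 0.3, jet_radius_fraction = 1 / 3),
    grid_spacing = 1e-3, seed = 1, voxelization = tube_voxelization_1mm())
  expect_equal(unname(gen$truth$true_nfd), rep(4.5 / 30, 3))
})

test_that("closed-form SFD ground truth matches a quadrature oracle", {
  # independent oracle: radial quadrature of the analytic profiles
  for (p in c(2, 4, 7)) for (sr in c(0.2, 0.5)) {
    num <- integrate(function(x) sr * x * x, 0, 1)$value
    den <- integrate(function(x) (1 - x^p) * x, 0, 1)$value
    geo <- tube_geometry_cached()
    gen <- generate_velocity_field(
      geo, jet_spec(swirl_ratio = sr, profile_exponent = p,
                    offset_fraction = 0.1),
      grid_spacing = 2e-3, seed = 1)
    expect_equal(unname(gen$truth$true_sfd), rep(num / den, 3),
                 tolerance = 1e-10)
  }
})

test_that("jet decay shrinks the offset downstream and keeps the jet in the lumen", {
  geo <- tube_geometry_cached()  # sections at s = 0.02, 0.05, 0.08
  gen <- generate_velocity_field(
    geo, jet_spec(offset_fraction = 0.3, decay_length = 0.05),
    grid_spacing = 2e-3, seed = 1)
  nfd <- gen$truth$true_nfd
  expect_true(all(diff(nfd) < 0))
  expect_equal(unname(nfd),
               0.3 * exp(-c(0.02, 0.05, 0.08) / 0.05) / 2,
               tolerance = 1e-10)
})

test_that("jets that would leave the lumen are rejected", {
  expect_error(jet_spec(offset_fraction = 0.5, jet_radius_fraction = 0.6),
               class = "aortaflow_validation")
})

test_that("degradation is identity at source spacing and preserves constants", {
  geo <- tube_geometry_cached()
  gen <- generate_velocity_field(geo, jet_spec(), grid_spacing = 2e-3,
                                 seed = 1)
  same <- degrade_to_mri(gen$field,
                         noise_spec(target_spacing = gen$field$spacing,
                                    noise_sd = 0))
  expect_identical(same$velocity, gen$field$velocity)
  expect_identical(same$mask, gen$field$mask)

  # a constant field with a full-grid mask stays constant under coarsening
  dims <- c(12L, 12L, 12L)
  vel <- array(0, dim = c(dims, 3)); vel[, , , 3] <- 1
  full <- velocity_field(c(0, 0, 0), rep(1e-3, 3), vel,
                         array(TRUE, dim = dims))
  coarse <- degrade_to_mri(full, noise_spec(target_spacing = rep(3e-3, 3),
                                            noise_sd = 0))
  expect_equal(as.vector(coarse$velocity[, , , 3]),
               rep(1, prod(coarse$dims)), tolerance = 1e-12)
  expect_equal(as.vector(coarse$velocity[, , , 1]),
               rep(0, prod(coarse$dims)))

  # refining is not allowed
  expect_error(degrade_to_mri(full, noise_spec(target_spacing = rep(5e-4, 3))),
               class = "aortaflow_validation")
})

test_that("degradation is deterministic per seed and box averaging never raises the peak speed", {
  geo <- tube_geometry_cached()
  gen <- generate_velocity_field(geo, jet_spec(offset_fraction = 0.2),
                                 grid_spacing = 1e-3, seed = 3,
                                 voxelization = tube_voxelization_1mm())
  ns <- noise_spec(noise_sd = 0.1, seed = 42)
  a <- degrade_to_mri(gen$field, ns)
  b <- degrade_to_mri(gen$field, ns)
  expect_identical(a$velocity, b$velocity)
  c2 <- degrade_to_mri(gen$field, noise_spec(noise_sd = 0.1, seed = 43))
  expect_false(identical(a$velocity, c2$velocity))

  # one-sided partial-volume bias at zero noise
  clean <- degrade_to_mri(gen$field, noise_spec(noise_sd = 0))
  expect_lte(max_velocity(clean), max_velocity(gen$field) + 1e-9)
})

test_that("Poiseuille reference has peak twice the mean and integrates to its flow rate", {
  R <- 0.01
  p <- poiseuille_reference(R, q = 0.5 * pi * R^2)  # mean 0.5 m/s
  expect_equal(p$v_mean, 0.5)
  expect_equal(p$v_peak, 1.0)
  expect_equal(p$velocity(R), 0)
  # area integral of the profile equals q (numeric quadrature)
  qnum <- integrate(function(r) p$velocity(r) * 2 * pi * r, 0, R,
                    rel.tol = 1e-9)$value
  expect_equal(qnum, p$q, tolerance = 1e-3)
})

test_that("voxel estimates converge toward the analytic ground truth with resolution", {
  geo <- tube_geometry_cached()
  jet <- jet_spec(v_peak = 2, offset_fraction = 0.25,
                  jet_radius_fraction = 0.5, swirl_ratio = 0.4,
                  profile_exponent = 2)
  secs <- tube_sections()
  err <- sapply(c(4e-3, 1e-3), function(h) {
    gen <- suppressWarnings(  # the 4 mm grid under-resolves on purpose
      generate_velocity_field(geo, jet, grid_spacing = h, seed = 1,
        voxelization = if (h == 1e-3) tube_voxelization_1mm() else NULL))
    sfd <- vapply(secs, function(s) secondary_flow_degree(gen$field, s),
                  numeric(1))
    nfd <- vapply(secs, function(s)
      normalized_flow_displacement(gen$field, s), numeric(1))
    c(sfd = max(abs(sfd - gen$truth$true_sfd)),
      nfd = max(abs(nfd - gen$truth$true_nfd)))
  })
  # 4x finer grid reduces the worst-section error for both statistics
  expect_lt(err["sfd", 2], err["sfd", 1])
  expect_lt(err["nfd", 2], err["nfd", 1])
  expect_lt(err["nfd", 2], 0.02)
  expect_lt(err["sfd", 2], 0.05)
})
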