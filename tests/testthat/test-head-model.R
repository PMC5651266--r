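# Head-model and dipole constructors: defaults, validation, unit handling.

test_that("default model reproduces the standard four-shell parameters", {
  m <- four_sphere()
  expect_equal(m$radii, c(0.079, 0.080, 0.085, 0.090))
  expect_equal(m$conductivities, c(0.33, 1.65, 0.0165, 0.33))
  m40 <- four_sphere(skull_divisor = 40)
  expect_equal(m40$conductivities[3], 0.33 / 40)
  expect_equal(four_sphere(skull_divisor = 80)$conductivities[3], 0.33 / 80)
})

test_that("radii and conductivities are validated", {
  expect_error(four_sphere(radii = c(8.0, 7.9, 8.5, 9.0)),
               class = "foursphere_geometry_error")
  expect_error(four_sphere(radii = c(7.9, 7.9, 8.5, 9.0)),
               class = "foursphere_geometry_error")
  expect_error(four_sphere(conductivities = c(0.33, 0, 0.0165, 0.33)),
               class = "foursphere_parameter_error")
  expect_error(four_sphere(conductivities = c(0.33, -1, 0.0165, 0.33)),
               class = "foursphere_parameter_error")
  # homogeneous control configuration is valid
  hom <- four_sphere(conductivities = rep(0.33, 4))
  expect_true(summary(hom)$homogeneous)
})

test_that("lengths may be given in metres or centimetres", {
  a <- four_sphere(radii = c(7.9, 8.0, 8.5, 9.0), units = "cm")
  b <- four_sphere(radii = c(0.079, 0.080, 0.085, 0.090), units = "m")
  expect_identical(a$radii, b$radii)
  d1 <- dipole(c(0, 0, 7.8), c(0, 0, 1e-7), units = "cm")
  d2 <- dipole(c(0, 0, 0.078), c(0, 0, 1e-7), units = "m")
  expect_identical(d1$position, d2$position)
  expect_identical(d1$r_z, 0.078)
})

test_that("dipole at the exact centre is rejected, zero moment is allowed", {
  expect_error(dipole(c(0, 0, 0), c(0, 0, 1e-7)),
               class = "foursphere_undecomposable_error")
  d0 <- dipole(c(0, 0, 0.05), c(0, 0, 0))
  expect_identical(d0$moment, c(0, 0, 0))
})

test_that("series control rejects nonsense and keeps valid settings", {
  expect_error(series_control(n_max = 0), class = "foursphere_parameter_error")
  expect_error(series_control(rel_tol = -1), class = "foursphere_parameter_error")
  expect_error(series_control(consecutive_small = 0),
               class = "foursphere_parameter_error")
  ctrl <- series_control(n_max = 123, rel_tol = 1e-9, consecutive_small = 3)
  expect_identical(ctrl$n_max, 123L)
})

test_that("random model draws respect the documented ranges and seed", {
  for (s in 1:10) {
    m <- random_head_model(seed = s)
    expect_true(all(m$radii >= 0.05 & m$radii <= 0.12))
    expect_true(all(diff(m$radii) >= 0.001))
    expect_true(all(m$conductivities >= 0.004 & m$conductivities <= 2))
  }
  expect_identical(random_head_model(seed = 7), random_head_model(seed = 7))
})
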