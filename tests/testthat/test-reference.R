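# Closed-form controls: homogeneous single sphere and infinite medium.

test_that("single-sphere formula approaches the central-dipole limit", {
  sigma <- 0.33; r4 <- 0.09; p <- 1e-7
  f <- 1e-4
  theta <- seq(0, pi, length.out = 91)
  closed <- potential_single_sphere(r4, sigma, f * r4, p, theta)
  central <- 3 * p * cos(theta) / (4 * pi * sigma * r4^2)
  expect_lt(max(abs(closed - central)) / max(abs(central)), 1e-3)
  # antisymmetry of the central-dipole limit
  expect_lt(max(abs(closed + rev(closed))) / max(abs(closed)), 1e-3)
})

test_that("first term of the closed form vanishes where cos(theta) = f", {
  f <- 0.01; r4 <- 0.09
  theta <- acos(f)
  d <- 1 + f^2 - 2 * f * cos(theta)
  expect_equal(2 * (cos(theta) - f) / d^1.5, 0)
})

test_that("single-sphere preconditions are enforced", {
  expect_error(potential_single_sphere(0.09, 0.33, 0.09, 1e-7, 0),
               class = "foursphere_parameter_error")  # f = 1
  expect_error(potential_single_sphere(0.09, 0.33, 0.10, 1e-7, 0),
               class = "foursphere_parameter_error")  # f > 1
  expect_error(potential_single_sphere(-1, 0.33, 0.01, 1e-7, 0),
               class = "foursphere_parameter_error")
})

test_that("equal-sigma four-sphere series reproduces the closed form", {
  m <- four_sphere(conductivities = rep(0.33, 4))
  theta <- seq(0, pi, length.out = 180)
  series <- potential_radial(m, RZ, 1e-7, r = m$radii[4], theta = theta)$value
  closed <- potential_single_sphere(m$radii[4], 0.33, RZ, 1e-7, theta)
  expect_lt(rel_dev(series, closed), 1e-8)
  # scaling sigma scales both solutions identically
  m10 <- four_sphere(conductivities = rep(3.3, 4))
  series10 <- potential_radial(m10, RZ, 1e-7, r = m$radii[4], theta = theta)$value
  expect_lt(rel_dev(series10, closed / 10), 1e-8)
})

test_that("infinite-medium dipole has the textbook structure", {
  d <- dipole(c(0, 0, 0.01), c(0, 0, 1e-7))
  # moment perpendicular to displacement: zero
  expect_equal(potential_infinite_medium(0.33, d, c(0.05, 0, 0.01)), 0)
  # inverse-square decay along a fixed direction
  v1 <- potential_infinite_medium(0.33, d, c(0, 0, 0.03))
  v2 <- potential_infinite_medium(0.33, d, c(0, 0, 0.05))
  expect_equal(v1 / v2, (0.04 / 0.02)^2, tolerance = 1e-12)
  expect_error(potential_infinite_medium(0.33, d, c(0, 0, 0.01)),
               class = "foursphere_singularity_error")
})

test_that("scaled-up equal-sigma model converges to the infinite medium", {
  m <- four_sphere(conductivities = rep(0.33, 4))
  d <- obl_dipole()
  rep_ <- check_infinite_limit(m, d, scales = c(10, 100, 1000))
  dev <- attr(rep_, "detail")$deviation
  expect_true(all(diff(dev) < 0))      # monotone convergence
  expect_lt(dev[3], 0.01)
  expect_true(rep_$pass)
})
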