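# Series potential evaluation: independently frozen anchors, symmetries,
# superposition, derivatives, boundary behaviour and surface statistics.

# Frozen with an independent pipeline (per-harmonic boundary-condition linear
# solve + Legendre summation implemented outside this package) for the
# standard model (K = 20), p = 1e-7 A m, r_z = 7.8 cm.
ANCHORS <- list(
  list(kind = "radial",     r = 0.090,  theta = 0,   phi = 0,      value = 9.658880284611937e-05),
  list(kind = "tangential", r = 0.090,  theta = 1.0, phi = pi / 2, value = 1.0635266712958442e-05),
  list(kind = "radial",     r = 0.0825, theta = 0.7, phi = 0,      value = 8.177054769693119e-07),
  list(kind = "tangential", r = 0.0825, theta = 0.7, phi = 2.2,    value = 1.4252763967158037e-05))

test_that("potentials match the independent linear-system pipeline anchors", {
  m <- t1_model()
  for (a in ANCHORS) {
    fn <- if (a$kind == "radial") potential_radial else potential_tangential
    got <- fn(m, RZ, 1e-7, r = a$r, theta = a$theta, phi = a$phi)$value
    expect_equal(got, a$value, tolerance = 1e-9)
  }
  # scalp magnitude lands in the tens-of-microvolts decade typical of EEG
  peak <- potential_radial(m, RZ, 1e-7, r = 0.090, theta = 0)$value
  expect_gt(abs(peak), 1e-5)
  expect_lt(abs(peak), 1e-4)
})

test_that("radial solution is azimuth-independent and linear in p", {
  m <- t1_model()
  v <- potential_radial(m, RZ, 1e-7, r = 0.09, theta = 1, phi = c(0, 2, 4.5))$value
  expect_lt(diff(range(v)) / abs(v[1]), 1e-14)
  expect_identical(potential_radial(m, RZ, 0, r = 0.09, theta = 1)$value, 0)
  v2 <- potential_radial(m, RZ, 2e-7, r = 0.09, theta = 1)$value
  expect_equal(v2, 2 * v[1], tolerance = 1e-14)
})

test_that("tangential solution is odd in phi and vanishes on the axis", {
  m <- t1_model()
  expect_identical(potential_tangential(m, RZ, 1e-7, 0.09, 1, phi = 0)$value, 0)
  vp <- potential_tangential(m, RZ, 1e-7, 0.09, 1, phi = 0.8)$value
  vm <- potential_tangential(m, RZ, 1e-7, 0.09, 1, phi = -0.8)$value
  expect_equal(vp, -vm, tolerance = 1e-14)
  # P_n^1(+/-1) = 0: exactly zero on the symmetry axis
  expect_equal(potential_tangential(m, RZ, 1e-7, 0.09, 0, phi = 1)$value, 0)
  expect_equal(potential_tangential(m, RZ, 1e-7, 0.09, pi, phi = 1)$value, 0)
})

test_that("oblique dipole equals the weighted sum of pure solutions", {
  m <- t1_model()
  pts <- fibonacci_sphere(50, 0.09)
  v45 <- potential_dipole(m, obl_dipole(), pts)
  vr <- potential_dipole(m, rad_dipole(1e-7 / sqrt(2)), pts)
  vt <- potential_dipole(m, tan_dipole(1e-7 / sqrt(2)), pts)
  expect_lt(rel_dev(v45, vr + vt), 1e-12)
})

test_that("potentials are covariant under joint rotation", {
  set.seed(11)
  m <- t1_model()
  d <- obl_dipole()
  pts <- fibonacci_sphere(20, 0.09)
  base <- potential_dipole(m, d, pts)
  for (i in 1:5) {
    R <- random_rotation()
    rot <- potential_dipole(m, rotate_dipole(d, R), pts %*% t(R))
    expect_lt(rel_dev(rot, base), 1e-10)
  }
})

test_that("potential and current are continuous across every interface", {
  m <- t1_model()
  th <- seq(0.1, pi - 0.1, length.out = 10)
  for (kind in c("radial", "tangential")) {
    fn <- if (kind == "radial") potential_radial else potential_tangential
    for (s in 1:3) {
      ri <- m$radii[s]
      # interface radius is assigned to the inner shell; a point epsilon
      # above uses the outer shell: continuity makes the values agree
      vin <- fn(m, RZ, 1e-7, ri, th, phi = 1.1)
      vout <- fn(m, RZ, 1e-7, ri * (1 + 1e-11), th, phi = 1.1)
      expect_identical(unique(vin$shell), s)
      expect_identical(unique(vout$shell), s + 1L)
      expect_lt(rel_dev(vin$value, vout$value), 1e-8)
      # sigma-weighted radial current continuity
      din <- radial_derivative(m, RZ, 1e-7, ri, th, phi = 1.1, kind = kind)
      dout <- radial_derivative(m, RZ, 1e-7, ri * (1 + 1e-11), th, phi = 1.1,
                                kind = kind)
      expect_lt(rel_dev(m$conductivities[s] * din$value,
                        m$conductivities[s + 1] * dout$value), 1e-8)
    }
  }
})

test_that("no radial current leaves the scalp surface", {
  m <- t1_model()
  th <- seq(0.1, pi - 0.1, length.out = 10)
  for (kind in c("radial", "tangential")) {
    dn <- radial_derivative(m, RZ, 1e-7, m$radii[4], th, phi = 1.1, kind = kind)
    dint <- radial_derivative(m, RZ, 1e-7, mean(m$radii[3:4]), th, phi = 1.1,
                              kind = kind)
    expect_lt(max(abs(dn$value)) / max(abs(dint$value)), 1e-10)
  }
})

test_that("analytic radial derivative matches finite differences", {
  m <- t1_model()
  h <- 1e-6
  for (kind in c("radial", "tangential")) {
    fn <- if (kind == "radial") potential_radial else potential_tangential
    for (r0 in c(0.0787, 0.0825, 0.0875)) {
      an <- radial_derivative(m, RZ, 1e-7, r0, 0.6, phi = 1, kind = kind)$value
      fd <- (fn(m, RZ, 1e-7, r0 + h, 0.6, phi = 1)$value -
             fn(m, RZ, 1e-7, r0 - h, 0.6, phi = 1)$value) / (2 * h)
      expect_equal(fd, an, tolerance = 1e-6)
    }
  }
})

test_that("the field is harmonic away from the source and interfaces", {
  # 7-point finite-difference Laplacian in the skull shell; with step
  # h = 1e-4 m and potential variation on the ~5 mm shell scale the
  # truncation residual is O((h/L)^2) ~ 1e-3 of the second-derivative scale.
  m <- t1_model()
  d <- obl_dipole()
  ctr <- c(0.02, 0.01, 0.078)                   # |ctr| = 0.0812, inside skull
  h <- 1e-4
  offs <- rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0), c(0, -h, 0),
                c(0, 0, h), c(0, 0, -h))
  pts <- rbind(ctr, sweep(offs, 2, ctr, "+"))
  v <- potential_dipole(m, d, pts)
  second <- c(v[2] + v[3], v[4] + v[5], v[6] + v[7]) - 2 * v[1]
  lap <- sum(second) / h^2
  scale <- max(abs(second)) / h^2
  expect_lt(abs(lap) / scale, 1e-2)
})

test_that("scalp surface mean vanishes (no monopole term)", {
  m <- t1_model()
  sm <- scalp_surface_mean(m, obl_dipole(), n_gauss = 120, n_phi = 48)
  expect_lt(sm$ratio, 1e-10)
})

test_that("validity region is enforced", {
  m <- t1_model()
  expect_error(potential_radial(m, RZ, 1e-7, r = 0.05, theta = 0),
               class = "foursphere_validity_region_error")
  expect_error(potential_radial(m, RZ, 1e-7, r = 0.10, theta = 0),
               class = "foursphere_outside_head_error")
  expect_error(potential_dipole(m, dipole(c(0, 0, 0.085), c(0, 0, 1e-7)),
                                c(0, 0, 0.09)),
               class = "foursphere_parameter_error")
})

test_that("zero-moment dipole yields zero potential", {
  m <- t1_model()
  v <- potential_dipole(m, dipole(c(0, 0, 0.078), c(0, 0, 0)),
                        fibonacci_sphere(5, 0.09))
  expect_identical(as.numeric(v), rep(0, 5))
})
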