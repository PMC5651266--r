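# Expansion coefficients: linkage identities, agreement between the
# closed-form recursion and the boundary-condition linear system, residual
# diagnostics, and numerical robustness in the equal-conductivity limit.

test_that("linkage identities hold to round-off", {
  m <- t1_model()
  co <- compute_coefficients(m, RZ, 1:200)
  n <- co$n
  expect_lt(max(rel_each(co$B4, n / (n + 1) * co$A4)), 1e-15)
  expect_lt(max(rel_each(co$B2, co$Y * co$A2)), 1e-12)
  expect_lt(max(rel_each(co$B3, co$V * co$A3)), 1e-12)
  # per-term scalp insulation identity, the algebraic form of the Neumann row
  expect_lt(max(rel_each(n * co$A4, (n + 1) * co$B4)), 1e-15)
})

test_that("recursion and linear-system oracle agree on the standard model", {
  m <- t1_model()
  a <- compute_coefficients(m, RZ, 1)
  b <- solve_coefficients_linear(m, RZ, 1)
  expect_lt(max(rel_each(as.matrix(a[, 2:8]), as.matrix(b[, 2:8]))), 1e-10)
  # deep harmonics stay finite and in agreement
  deep <- compute_coefficients(m, RZ, c(500L, 1000L))
  expect_true(all(is.finite(as.matrix(deep[, 2:8]))))
  deepl <- solve_coefficients_linear(m, RZ, c(500L, 1000L))
  expect_lt(max(rel_each(as.matrix(deep[, 2:8]), as.matrix(deepl[, 2:8]))), 1e-9)
})

test_that("oracle equivalence holds across random valid models", {
  ns <- c(1:50, 100, 500, 1000)
  for (s in 1:5) {
    m <- random_head_model(seed = 100 + s)
    r_z <- 7.8 / 7.9 * m$radii[1]
    a <- as.matrix(compute_coefficients(m, r_z, ns)[, 2:8])
    b <- as.matrix(solve_coefficients_linear(m, r_z, ns)[, 2:8])
    expect_lt(max(rel_each(a, b)), 1e-9)
  }
})

test_that("boundary residuals are at round-off and detect perturbations", {
  m <- t1_model()
  co <- compute_coefficients(m, RZ, 1:100)
  res <- coefficient_residuals(co, m)
  expect_lt(max(res), 1e-10)

  # Neumann residual responds linearly to a 1% perturbation of A4
  bad <- co
  bad$A4 <- bad$A4 * 1.01
  res_bad <- coefficient_residuals(bad, m)
  expect_gt(min(res_bad[, "neumann_r4"]), 1e-3)
  expect_lt(max(res_bad[, "neumann_r4"]), 1e-1)

  # residuals computed against a different model must blow up
  m80 <- t1_model(K = 80)
  expect_gt(max(coefficient_residuals(co, m80)), 1e-3)
})

test_that("equal-conductivity coefficients stay finite past the V_n pole", {
  # For equal sigma the auxiliary V_n diverges once r34^(2n+1) < eps;
  # the A, B coefficients must remain finite and boundary-consistent.
  hom <- four_sphere(conductivities = rep(0.33, 4))
  co <- compute_coefficients(hom, RZ, c(1:50, 400, 1000, 2000))
  expect_true(all(is.finite(as.matrix(co[, 2:8]))))
  expect_lt(max(coefficient_residuals(co, hom)), 1e-10)
})

test_that("near-degenerate shell geometry is handled by both routes", {
  m <- four_sphere(radii = c(0.079, 0.079 + 1e-6, 0.085, 0.090),
                   conductivities = c(0.33, 1.65, 0.0165, 0.33), units = "m")
  ns <- c(1:20, 200)
  a <- as.matrix(compute_coefficients(m, RZ, ns)[, 2:8])
  b <- as.matrix(solve_coefficients_linear(m, RZ, ns)[, 2:8])
  expect_true(all(is.finite(a)))
  expect_lt(max(rel_each(a, b)), 1e-9)
})

test_that("per-term scalp contributions eventually decay geometrically", {
  m <- t1_model()
  co <- compute_coefficients(m, RZ, 1:300)
  # term magnitude at theta = 0 on the scalp: |A4 + B4| * n (P_n(1) = 1)
  tn <- abs(co$A4 + co$B4) * co$n
  ratio <- tn[-1] / tn[-length(tn)]
  expect_true(all(ratio[100:299 - 1] < 1))
  expect_lt(mean(ratio[200:298]), 0.95)
})

test_that("argument validation matches the stated preconditions", {
  m <- t1_model()
  expect_error(compute_coefficients(m, 0.09, 1),   # r_z >= r1
               class = "foursphere_parameter_error")
  expect_error(compute_coefficients(m, 0, 1), class = "foursphere_parameter_error")
  expect_error(compute_coefficients(m, RZ, 0), class = "foursphere_parameter_error")
  expect_error(compute_coefficients(m, RZ, 1.5), class = "foursphere_parameter_error")
})
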