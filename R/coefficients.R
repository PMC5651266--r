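## Per-harmonic expansion coefficients of the four-sphere series solution.
##
## Two independent routes to the same numbers:
##   * compute_coefficients(): the closed-form recursion V_n -> Y_n -> Z_n ->
##     A_n^1 ... B_n^4, evaluated in a numerically hardened form;
##   * solve_coefficients_linear(): a 7x7 linear system assembled directly
##     from the boundary conditions, used as the in-package oracle.
##
## Numerical form of the recursion: each auxiliary is a ratio whose numerator
## and denominator mix decaying (r_34^n) and growing (r_43^{n+1}) powers.  All
## ratios are first rewritten so only DECAYING powers r_ij^{2n+1} (inner over
## outer) appear, and the auxiliaries V, Y, Z are then carried as
## numerator/denominator pairs that are folded straight into the A, B
## coefficients.  The pairs matter: for equal conductivities (the homogeneous
## control) V_n diverges once r_34^{2n+1} drops below machine epsilon, and a
## naive evaluation produces 0 * Inf; the pair form keeps every A, B finite.

.coef_names <- c("n", "A1", "A2", "B2", "A3", "B3", "A4", "B4", "V", "Y", "Z")

.pair_norm <- function(num, den) {
  m <- pmax(abs(num), abs(den))
  m[m == 0] <- 1
  list(num = num / m, den = den / m)
}

.coef_recursive <- function(model, r_z, n) {
  r <- model$radii; s <- model$conductivities
  n <- as.numeric(n)
  r12 <- r[1] / r[2]; r23 <- r[2] / r[3]; r34 <- r[3] / r[4]
  s12 <- s[1] / s[2]; s23 <- s[2] / s[3]; s34 <- s[3] / s[4]
  rz1 <- r_z / r[1]
  np1 <- n + 1
  f <- np1 / n              # (n+1)/n
  g <- n / np1              # n/(n+1)

  ## V = [g*s34 - rc] / [s34 + rc],  rc = (t - 1) / (f*t + 1),  t = r34^(2n+1)
  t <- r34^(2 * n + 1)
  v <- .pair_norm(g * s34 * (f * t + 1) - (t - 1),
                  s34 * (f * t + 1) + (t - 1))
  ## Y = [g*s23 - rc2] / [s23 + rc2],  rc2 = (g*u*Dv - Nv) / (u*Dv + Nv)
  u <- r23^(2 * n + 1)
  p2 <- .pair_norm(g * u * v$den - v$num, u * v$den + v$num)
  y <- .pair_norm(g * s23 * p2$den - p2$num, s23 * p2$den + p2$num)
  ## Z = (w*Dy - f*Ny) / (w*Dy + Ny),  w = r12^(2n+1)
  w <- r12^(2 * n + 1)
  z <- .pair_norm(w * y$den - f * y$num, w * y$den + y$num)

  src <- rz1^np1                        # (r_z/r_1)^(n+1), the source term
  A1 <- src * (f * s12 * z$den + z$num) / (s12 * z$den - z$num)
  den2 <- w * y$den + y$num
  A2 <- (A1 + src) * r12^np1 * y$den / den2
  B2 <- (A1 + src) * r12^np1 * y$num / den2
  den3 <- u * v$den + v$num
  A3 <- (A2 + B2) * r23^np1 * v$den / den3
  B3 <- (A2 + B2) * r23^np1 * v$num / den3
  A4 <- f * (A3 + B3) * r34^np1 / (f * r34^(2 * n + 1) + 1)
  B4 <- g * A4

  out <- cbind(n = n, A1 = A1, A2 = A2, B2 = B2, A3 = A3, B3 = B3,
               A4 = A4, B4 = B4,
               V = v$num / v$den, Y = y$num / y$den, Z = z$num / z$den)
  out
}

.coef_linear <- function(model, r_z, n) {
  r <- model$radii; s <- model$conductivities
  r12 <- r[1] / r[2]; r23 <- r[2] / r[3]; r34 <- r[3] / r[4]
  rz1 <- r_z / r[1]
  out <- matrix(NA_real_, length(n), 11,
                dimnames = list(NULL, .coef_names))
  for (i in seq_along(n)) {
    k <- as.numeric(n[i]); k1 <- k + 1
    ## Unknowns x = (A1, A2, B2', A3, B3', A4, B4') in an inner-anchored
    ## B-basis, B_s = B_s' (r_{s-1}/r_s)^{n+1}: every matrix entry is a
    ## bounded (decaying) power, so the system never overflows at large n.
    q2 <- r12^k1; q3 <- r23^k1; q4 <- r34^k1
    M <- matrix(0, 7, 7); b <- numeric(7)
    M[1, 1:3] <- c(1, -r12^k, -1);           b[1] <- -rz1^k1
    M[2, 1:3] <- c(s[1] * k, -s[2] * k * r12^k, s[2] * k1)
    b[2] <- s[1] * k1 * rz1^k1
    M[3, 2:5] <- c(1, q2, -r23^k, -1)
    M[4, 2:5] <- c(s[2] * k, -s[2] * k1 * q2, -s[3] * k * r23^k, s[3] * k1)
    M[5, 4:7] <- c(1, q3, -r34^k, -1)
    M[6, 4:7] <- c(s[3] * k, -s[3] * k1 * q3, -s[4] * k * r34^k, s[4] * k1)
    M[7, 6:7] <- c(k, -k1 * q4)
    sc <- apply(abs(M), 1, max)
    x <- tryCatch(solve(M / sc, b / sc),
                  error = function(e)
                    .fs_error(sprintf("boundary-condition system is singular at n = %d", n[i]),
                              "foursphere_degenerate_parameters_error"))
    A1 <- x[1]; A2 <- x[2]; B2 <- x[3] * q2
    A3 <- x[4]; B3 <- x[5] * q3; A4 <- x[6]; B4 <- x[7] * q4
    out[i, ] <- c(k, A1, A2, B2, A3, B3, A4, B4,
                  V = if (A3 != 0) B3 / A3 else NA_real_,
                  Y = if (A2 != 0) B2 / A2 else NA_real_,
                  Z = NA_real_)
  }
  out
}

.check_coef_args <- function(model, r_z, n) {
  stopifnot(inherits(model, "four_sphere"))
  if (!is.finite(r_z) || r_z <= 0 || r_z >= model$radii[1])
    .fs_error("dipole radius r_z must satisfy 0 < r_z < r1 (source strictly inside the brain shell)",
              "foursphere_parameter_error")
  if (length(n) < 1L || any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    .fs_error("harmonic index n must be a positive integer", "foursphere_parameter_error")
}

.check_coef_finite <- function(out, n) {
  ab <- out[, c("A1", "A2", "B2", "A3", "B3", "A4", "B4"), drop = FALSE]
  bad <- !is.finite(ab)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    .fs_error(sprintf("expansion coefficients left the double-precision range at n = %d",
                      as.integer(n[i])), "foursphere_series_range_error")
  }
}

#' Expansion coefficients of the four-sphere series (closed form)
#'
#' Computes, per harmonic `n`, the expansion coefficients
#' \eqn{A_n^1..A_n^4, B_n^2..B_n^4} and the auxiliaries \eqn{V_n, Y_n, Z_n}
#' of the corrected four-sphere solution.  The coefficients depend only on
#' the shell geometry, the conductivity ratios and the dipole radius `r_z` --
#' not on the evaluation point -- and satisfy the linkage identities
#' \eqn{B_n^2 = Y_n A_n^2}, \eqn{B_n^3 = V_n A_n^3},
#' \eqn{B_n^4 = \frac{n}{n+1} A_n^4}.
#'
#' In the equal-conductivity (homogeneous) limit the auxiliary \eqn{V_n}
#' diverges at large `n` while the A, B coefficients stay finite; the
#' implementation carries the auxiliaries as numerator/denominator pairs so
#' the coefficients are unaffected (\eqn{V_n} itself is then reported as
#' `Inf`).
#'
#' @param model a [four_sphere()].
#' @param r_z dipole radial position in metres, `0 < r_z < r1`.
#' @param n vector of positive integer harmonic indices.
#' @param method `"recursive"` for the closed-form recursion (default) or
#'   `"linear"` for the boundary-condition linear solve (the oracle).
#' @return A `data.frame` of class `"coefficient_set"` with columns `n`,
#'   `A1`, `A2`, `B2`, `A3`, `B3`, `A4`, `B4`, `V`, `Y`, `Z`.
#' @seealso [solve_coefficients_linear()], [coefficient_residuals()]
#' @examples
#' co <- compute_coefficients(four_sphere(), r_z = 0.078, n = 1:5)
#' all.equal(co$B4, co$n / (co$n + 1) * co$A4)
#' @export
compute_coefficients <- function(model, r_z, n,
                                 method = c("recursive", "linear")) {
  method <- match.arg(method)
  .check_coef_args(model, r_z, n)
  out <- if (method == "recursive") .coef_recursive(model, r_z, n)
         else .coef_linear(model, r_z, n)
  .check_coef_finite(out, n)
  df <- as.data.frame(out)
  attr(df, "method") <- method
  attr(df, "r_z") <- r_z
  class(df) <- c("coefficient_set", "data.frame")
  df
}

#' Expansion coefficients from the boundary-condition linear system (oracle)
#'
#' Independent route to the same coefficients as [compute_coefficients()]:
#' per harmonic, a 7x7 linear system in
#' \eqn{(A_n^1, A_n^2, B_n^2, A_n^3, B_n^3, A_n^4, B_n^4)} expressing
#' potential continuity at the three internal interfaces, current continuity
#' (\eqn{\sigma}-weighted radial derivative) there, and the zero-current
#' Neumann condition at the scalp surface, with the known source term
#' \eqn{(r_z/r)^{n+1}} on the right-hand side.  The same shell-anchored basis
#' normalisation as the series is used, so coefficients are directly
#' comparable.
#'
#' @inheritParams compute_coefficients
#' @return A `"coefficient_set"` (see [compute_coefficients()]); the `Z`
#'   auxiliary is not defined by this route and is returned as `NA`.
#' @export
solve_coefficients_linear <- function(model, r_z, n) {
  compute_coefficients(model, r_z, n, method = "linear")
}

#' Boundary-condition residuals of a coefficient set
#'
#' Diagnostic: evaluates, per harmonic, the seven boundary equations
#' (potential continuity and current continuity at the brain/CSF, CSF/skull
#' and skull/scalp interfaces, and the scalp Neumann condition) and returns
#' each residual normalised by the larger magnitude of the two matched sides.
#' For a correct coefficient set all residuals are at round-off level
#' (\eqn{\le} 1e-10 by a wide margin).
#'
#' @param coeffs a `"coefficient_set"`.
#' @param model the [four_sphere()] the coefficients were computed for.
#' @param r_z dipole radius in metres; defaults to the value recorded in
#'   `coeffs`.
#' @return Numeric matrix, one row per harmonic, columns `pot_r1`, `cur_r1`,
#'   `pot_r2`, `cur_r2`, `pot_r3`, `cur_r3`, `neumann_r4`.
#' @export
coefficient_residuals <- function(coeffs, model, r_z = attr(coeffs, "r_z")) {
  stopifnot(inherits(coeffs, "coefficient_set"), inherits(model, "four_sphere"))
  r <- model$radii; s <- model$conductivities
  n <- coeffs$n; n1 <- n + 1
  r12 <- r[1] / r[2]; r21 <- r[2] / r[1]; r23 <- r[2] / r[3]
  r32 <- r[3] / r[2]; r34 <- r[3] / r[4]; r43 <- r[4] / r[3]
  rz1 <- r_z / r[1]
  rel <- function(lhs, rhs) abs(lhs - rhs) / pmax(abs(lhs), abs(rhs), 1e-300)
  with(coeffs, {
    p1 <- rel(A1 + rz1^n1, A2 * r12^n + B2 * r21^n1)
    c1 <- rel(s[1] * (n * A1 - n1 * rz1^n1),
              s[2] * (n * A2 * r12^n - n1 * B2 * r21^n1))
    p2 <- rel(A2 + B2, A3 * r23^n + B3 * r32^n1)
    c2 <- rel(s[2] * (n * A2 - n1 * B2),
              s[3] * (n * A3 * r23^n - n1 * B3 * r32^n1))
    p3 <- rel(A3 + B3, A4 * r34^n + B4 * r43^n1)
    c3 <- rel(s[3] * (n * A3 - n1 * B3),
              s[4] * (n * A4 * r34^n - n1 * B4 * r43^n1))
    nm <- abs(n * A4 - n1 * B4) / pmax(abs(n * A4), abs(n1 * B4), 1e-300)
    cbind(pot_r1 = p1, cur_r1 = c1, pot_r2 = p2, cur_r2 = c2,
          pot_r3 = p3, cur_r3 = c3, neumann_r4 = nm)
  })
}

## Cached coefficient table rows 1..n_upto (matrix), growing on demand.
.get_coefs <- function(model, r_z, n_upto, method = "recursive") {
  key <- paste(method,
               paste(format(c(model$radii, model$conductivities, r_z),
                            digits = 17), collapse = ","),
               sep = "|")
  hit <- .fs_cache[[key]]
  if (is.null(hit) || nrow(hit) < n_upto) {
    hit <- if (method == "recursive") .coef_recursive(model, r_z, seq_len(n_upto))
           else .coef_linear(model, r_z, seq_len(n_upto))
    .fs_cache[[key]] <- hit
  }
  hit
}
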