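## Executable validation suite: the model's physical controls packaged as
## reportable checks.  Tolerances are arguments (configuration), not code
## constants; every report records the tolerance it was judged against.

.vreport <- function(check, statistic, samples, tolerance, tolerance_source,
                     extra = NULL) {
  out <- data.frame(check = check, statistic = statistic, samples = samples,
                    tolerance = tolerance, pass = statistic <= tolerance,
                    tolerance_source = tolerance_source,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) attr(out, "detail") <- extra
  class(out) <- c("validation_report", "data.frame")
  out
}

.bind_reports <- function(...) {
  out <- do.call(rbind, lapply(list(...), function(x) {
    class(x) <- "data.frame"; x
  }))
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Four-sphere validation report\n")
  df <- data.frame(check = x$check,
                   statistic = signif(x$statistic, 4),
                   samples = x$samples,
                   tolerance = x$tolerance,
                   pass = ifelse(x$pass, "PASS", "FAIL"))
  print(df, row.names = FALSE)
  invisible(x)
}

## interface sample grid: `samples` (theta, phi) pairs avoiding the poles,
## where the tangential solution is trivially zero.
.angle_grid <- function(samples) {
  nt <- max(2L, ceiling(sqrt(samples)))
  np <- max(2L, ceiling(samples / nt))
  expand.grid(theta = seq(0.02, pi - 0.02, length.out = nt),
              phi = seq(0, 2 * pi, length.out = np + 1L)[seq_len(np)])
}

#' Boundary-condition check
#'
#' Verifies, on a sample of interface directions, that the evaluated series
#' satisfies the defining boundary conditions: the potential and the
#' \eqn{\sigma}-weighted radial current density are continuous across the
#' brain/CSF, CSF/skull and skull/scalp interfaces, and no current leaves the
#' scalp surface.  Both sides of each interface are evaluated with the
#' expansion of the adjoining shell; residuals are normalised by the larger
#' of the two matched sides (the Neumann residual by the interior derivative
#' scale).  Radial and tangential solutions are checked for whichever
#' components the supplied dipole carries (both for an oblique dipole).
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()].
#' @param samples number of (theta, phi) interface samples (>= 10).
#' @param ctrl a [series_control()].
#' @param tol tolerance for the continuity residuals.
#' @param neumann_tol tolerance for the scalp Neumann residual, relative to
#'   the interior radial-derivative scale.
#' @return A `"validation_report"` with one row per condition family.
#' @export
check_boundary_conditions <- function(model, d, samples = 100,
                                      ctrl = series_control(),
                                      tol = 1e-8, neumann_tol = 1e-10) {
  stopifnot(inherits(model, "four_sphere"), inherits(d, "dipole"))
  if (samples < 10) .fs_error("need at least 10 samples", "foursphere_parameter_error")
  fr <- canonical_frame(d)
  kinds <- c(if (fr$p_rad != 0) "radial", if (fr$p_tan != 0) "tangential")
  if (length(kinds) == 0L) kinds <- c("radial", "tangential")  # zero moment: check unit solutions
  g <- .angle_grid(samples)
  r_z <- fr$r_z
  pot_res <- cur_res <- 0
  neu_res <- 0
  for (kind in kinds) {
    for (s in 1:3) {
      ## both sides evaluated AT the interface radius, each with its own
      ## shell's expansion; residual normalised by the grid-wide magnitude
      ## (pointwise ratios are undefined at the potential's zero crossings).
      ri <- rep(model$radii[s], nrow(g))
      inner <- .series_eval(model, r_z, ri, g$theta, g$phi,
                            kind = kind, ctrl = ctrl, force_shell = s)
      outer_ <- .series_eval(model, r_z, ri, g$theta, g$phi,
                             kind = kind, ctrl = ctrl, force_shell = s + 1L)
      pot_res <- max(pot_res,
                     max(abs(inner$value - outer_$value)) / max(abs(inner$value)))
      di <- .series_eval(model, r_z, ri, g$theta, g$phi, kind = kind,
                         deriv = TRUE, ctrl = ctrl, force_shell = s)
      do_ <- .series_eval(model, r_z, ri, g$theta, g$phi, kind = kind,
                          deriv = TRUE, ctrl = ctrl, force_shell = s + 1L)
      ji <- model$conductivities[s] * di$value
      jo <- model$conductivities[s + 1L] * do_$value
      cur_res <- max(cur_res, max(abs(ji - jo)) / max(abs(ji)))
    }
    dn <- .series_eval(model, r_z, rep(model$radii[4], nrow(g)), g$theta,
                       g$phi, kind = kind, deriv = TRUE, ctrl = ctrl)
    dint <- .series_eval(model, r_z,
                         rep(mean(model$radii[3:4]), nrow(g)), g$theta, g$phi,
                         kind = kind, deriv = TRUE, ctrl = ctrl)
    neu_res <- max(neu_res, max(abs(dn$value)) / max(abs(dint$value)))
  }
  .bind_reports(
    .vreport("potential continuity (interfaces r1-r3)", pot_res, nrow(g) * length(kinds),
             tol, "continuity tolerance argument"),
    .vreport("current continuity (interfaces r1-r3)", cur_res, nrow(g) * length(kinds),
             tol, "continuity tolerance argument"),
    .vreport("scalp Neumann (zero radial current at r4)", neu_res,
             nrow(g) * length(kinds), neumann_tol, "neumann tolerance argument"))
}

#' Homogeneous single-sphere limit check
#'
#' With all four conductivities equal, the four-sphere scalp potential of a
#' radial dipole must coincide with the closed-form homogeneous single-sphere
#' solution ([potential_single_sphere()]) with radius `r4`.  The deviation is
#' normalised by the maximum closed-form magnitude over the grid (pointwise
#' ratios are meaningless near the potential's zero crossing).
#'
#' @param radii four shell radii in metres (only the geometry matters here).
#' @param conductivity the common conductivity (S/m).
#' @param r_z radial dipole position (m).
#' @param p moment magnitude (A m).
#' @param n_theta size of the polar-angle grid on \[0, pi\].
#' @param ctrl a [series_control()].
#' @param tol tolerance on the normalised deviation (truncation-limited).
#' @return A one-row `"validation_report"`.
#' @export
check_homogeneous_limit <- function(radii = four_sphere()$radii,
                                    conductivity = 0.33,
                                    r_z = 0.078, p = 1e-7, n_theta = 180,
                                    ctrl = series_control(), tol = 1e-6) {
  model <- four_sphere(radii = radii, conductivities = rep(conductivity, 4),
                       units = "m")
  theta <- seq(0, pi, length.out = n_theta)
  series <- potential_radial(model, r_z, p, r = model$radii[4], theta = theta,
                             ctrl = ctrl)$value
  closed <- potential_single_sphere(model$radii[4], conductivity, r_z, p, theta)
  dev <- max(abs(series - closed)) / max(abs(closed))
  .vreport("homogeneous single-sphere limit", dev, n_theta, tol,
           "truncation-limited tolerance argument")
}

#' Infinite homogeneous medium limit check
#'
#' With equal conductivities, scaling all shell radii up while keeping the
#' dipole and electrodes fixed must drive the four-sphere potential to the
#' infinite-medium dipole formula.  The check asserts a monotonically
#' decreasing deviation over the scale sequence and a final deviation within
#' `tol`.
#'
#' @param model a [four_sphere()] with equal conductivities.
#' @param d a [dipole()] inside the unscaled brain shell.
#' @param scales increasing radius multipliers.
#' @param points optional electrode matrix (m); default: 24 directions on the
#'   unscaled scalp sphere.
#' @param ctrl a [series_control()].
#' @param tol tolerance on the final (largest-scale) deviation.
#' @return A `"validation_report"`; attribute `"detail"` holds the per-scale
#'   deviations.
#' @export
check_infinite_limit <- function(model, d, scales = c(10, 100, 1000),
                                 points = NULL, ctrl = series_control(),
                                 tol = 0.01) {
  stopifnot(inherits(model, "four_sphere"), inherits(d, "dipole"))
  s <- model$conductivities
  if (max(abs(s - s[1])) > 1e-12 * s[1])
    .fs_error("infinite-medium limit requires equal conductivities in all shells",
              "foursphere_parameter_error")
  if (is.null(points)) {
    th <- seq(0.3, pi - 0.3, length.out = 8)
    ph <- c(pi / 5, pi / 2, 4 * pi / 3)
    g <- expand.grid(theta = th, phi = ph)
    r4 <- model$radii[4]
    points <- cbind(r4 * sin(g$theta) * cos(g$phi),
                    r4 * sin(g$theta) * sin(g$phi),
                    r4 * cos(g$theta))
  }
  ref <- potential_infinite_medium(s[1], d, points)
  sc_ref <- max(abs(ref))
  dev <- vapply(scales, function(k) {
    mk <- four_sphere(radii = model$radii * k, conductivities = s, units = "m")
    val <- potential_dipole(mk, d, points, ctrl = ctrl)
    max(abs(val - ref)) / sc_ref
  }, numeric(1))
  monotone <- all(diff(dev) < 0)
  rep_ <- .vreport("infinite homogeneous medium limit", dev[length(dev)],
                   nrow(points) * length(scales), tol,
                   "final-scale tolerance argument",
                   extra = data.frame(scale = scales, deviation = dev))
  rep_$pass <- rep_$pass && monotone
  rep_
}

#' Cross-check against the boundary-condition linear-system oracle
#'
#' Evaluates the potential of a dipole at a set of points twice: with the
#' closed-form coefficient recursion and with coefficients obtained by
#' solving the per-harmonic boundary-condition linear system, and reports the
#' maximum difference normalised by the maximum potential magnitude.  The two
#' routes share only the boundary conditions themselves, so agreement is a
#' strong correctness check of the coefficient algebra.
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()].
#' @param points optional electrode matrix (m); default `n_points` scalp
#'   positions on a Fibonacci lattice.
#' @param n_points number of default scalp points.
#' @param ctrl a [series_control()].
#' @param tol tolerance on the normalised maximum difference.
#' @return A one-row `"validation_report"`.
#' @export
compare_with_oracle <- function(model, d, points = NULL, n_points = 1000,
                                ctrl = series_control(), tol = 1e-9) {
  stopifnot(inherits(model, "four_sphere"), inherits(d, "dipole"))
  if (is.null(points))
    points <- fibonacci_sphere(n_points, model$radii[4])
  a <- potential_dipole(model, d, points, ctrl = ctrl, method = "recursive")
  b <- potential_dipole(model, d, points, ctrl = ctrl, method = "linear")
  dev <- max(abs(a - b)) / max(abs(a))
  .vreport("closed-form vs linear-system oracle", dev, nrow(.as_points(points)),
           tol, "oracle tolerance argument")
}

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' @param n number of points.
#' @param radius sphere radius.
#' @return n x 3 matrix.
#' @export
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(s * cos(phi), s * sin(phi), z)
}

#' Run the full validation suite
#'
#' Executes the four packaged checks -- boundary conditions, homogeneous
#' single-sphere limit, infinite-medium limit and oracle equivalence -- and
#' returns a combined report.  The homogeneous and infinite-medium checks use
#' an equal-conductivity copy of the supplied model (those limits are defined
#' for equal conductivities); the boundary and oracle checks use the model as
#' given.
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()]; the default is an oblique (45-degree) dipole 1 mm
#'   below the brain surface with \eqn{|p|} = 1e-7 A m, which exercises both
#'   the radial and the tangential solution.
#' @param ctrl a [series_control()].
#' @param samples interface samples for the boundary check.
#' @param n_points scalp points for the oracle check.
#' @param tolerances named list overriding the per-check tolerances
#'   (`boundary`, `neumann`, `homogeneous`, `infinite`, `oracle`).
#' @return A `"validation_report"` with one row per check.
#' @examples
#' \donttest{
#' run_validation(four_sphere(), samples = 25, n_points = 100)
#' }
#' @export
run_validation <- function(model = four_sphere(),
                           d = dipole(c(0, 0, 7.8),
                                      c(0, 1e-7, 1e-7) / sqrt(2), units = "cm"),
                           ctrl = series_control(), samples = 100,
                           n_points = 1000,
                           tolerances = list()) {
  tl <- utils::modifyList(list(boundary = 1e-8, neumann = 1e-10,
                               homogeneous = 1e-6, infinite = 0.01,
                               oracle = 1e-9), tolerances)
  hom_sigma <- model$conductivities[1]
  .bind_reports(
    check_boundary_conditions(model, d, samples = samples, ctrl = ctrl,
                              tol = tl$boundary, neumann_tol = tl$neumann),
    check_homogeneous_limit(radii = model$radii, conductivity = hom_sigma,
                            r_z = d$r_z, p = max(sqrt(sum(d$moment^2)), 1e-7),
                            ctrl = ctrl, tol = tl$homogeneous),
    check_infinite_limit(four_sphere(radii = model$radii,
                                     conductivities = rep(hom_sigma, 4),
                                     units = "m"),
                         d, ctrl = ctrl, tol = tl$infinite),
    compare_with_oracle(model, d, n_points = n_points, ctrl = ctrl,
                        tol = tl$oracle))
}
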