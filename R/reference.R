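## Closed-form control solutions used to validate the series machinery.

#' Scalp potential of a radial dipole in a homogeneous single sphere
#'
#' Closed-form surface potential of a radially oriented dipole inside a
#' single homogeneous conducting sphere with an insulating exterior,
#' \deqn{\Phi(\theta) = \frac{p}{4\pi\sigma r_4^2}\left\{
#'   \frac{2(\cos\theta - f)}{(1 + f^2 - 2f\cos\theta)^{3/2}}
#'   + \frac{1}{f}\left[\frac{1}{(1 + f^2 - 2f\cos\theta)^{1/2}} - 1\right]
#'   \right\}, \quad f = r_z/r_4.}
#' The equal-conductivity four-sphere model must reproduce this exactly
#' (see [check_homogeneous_limit()]); as \eqn{f \to 0} it tends to the
#' central-dipole formula \eqn{3p\cos\theta/(4\pi\sigma r_4^2)}.
#'
#' @param radius sphere radius in metres.
#' @param conductivity conductivity in S/m.
#' @param r_z dipole radial position (m), `0 < r_z < radius`.
#' @param p moment magnitude (A m).
#' @param theta polar angle(s) from the dipole axis, radians.
#' @return Potential(s) in volts at the sphere surface.
#' @export
potential_single_sphere <- function(radius, conductivity, r_z, p, theta) {
  if (!is.finite(radius) || radius <= 0 || !is.finite(conductivity) ||
      conductivity <= 0)
    .fs_error("radius and conductivity must be positive", "foursphere_parameter_error")
  f <- r_z / radius
  if (!is.finite(f) || f <= 0 || f >= 1)
    .fs_error("r_z must satisfy 0 < r_z < radius (f = r_z/r4 < 1)",
              "foursphere_parameter_error")
  ct <- cos(theta)
  d <- 1 + f^2 - 2 * f * ct
  p / (4 * pi * conductivity * radius^2) *
    (2 * (ct - f) / d^1.5 + (1 / f) * (1 / sqrt(d) - 1))
}

#' Potential of an ideal current dipole in an infinite homogeneous medium
#'
#' The textbook inverse-square dipole potential
#' \eqn{\Phi(\mathbf{r}) = \mathbf{p}\cdot(\mathbf{r}-\mathbf{r}_0) /
#' (4\pi\sigma |\mathbf{r}-\mathbf{r}_0|^3)}.  The four-sphere solution must
#' approach this when all conductivities are equal and the shell radii are
#' scaled to infinity at fixed source-electrode geometry
#' (see [check_infinite_limit()]).
#'
#' @param conductivity medium conductivity in S/m.
#' @param d a [dipole()].
#' @param points 3-vector or n x 3 matrix of field points (m).
#' @return Potential(s) in volts.
#' @export
potential_infinite_medium <- function(conductivity, d, points) {
  stopifnot(inherits(d, "dipole"))
  if (!is.finite(conductivity) || conductivity <= 0)
    .fs_error("conductivity must be positive", "foursphere_parameter_error")
  pts <- .as_points(points)
  disp <- sweep(pts, 2L, d$position)
  dist <- sqrt(rowSums(disp^2))
  if (any(dist == 0))
    .fs_error("field point coincides with the dipole position",
              "foursphere_singularity_error")
  as.numeric(disp %*% d$moment) / (4 * pi * conductivity * dist^3)
}
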