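## Canonical-frame geometry.  The series formulas assume the dipole sits on
## the +z axis with any tangential moment component along +y; an arbitrary
## problem is rotated into that frame, evaluated, and the (scalar) potentials
## need no rotation back.

#' Canonical frame of a dipole
#'
#' Builds the rotation that maps world coordinates into the frame the series
#' solution assumes: the dipole position on the +z axis and the tangential
#' part of its moment along +y.  Any dipole is thereby decomposed into a
#' radial component `p_rad` (signed, along the position vector) and a
#' tangential component `p_tan` (non-negative); the potential of the full
#' dipole is the superposition of the two pure solutions.
#'
#' @param d a [dipole()].
#' @return Object of class `"canonical_frame"`: list with `rotation` (3x3
#'   orthogonal, determinant +1, world -> canonical), `r_z` (m), `p_rad` and
#'   `p_tan` (A m).
#' @examples
#' f <- canonical_frame(dipole(c(0, 0, 0.078), c(0, 1e-7, 1e-7) / sqrt(2)))
#' f$p_rad; f$p_tan   # equal split for a 45-degree dipole
#' @export
canonical_frame <- function(d) {
  stopifnot(inherits(d, "dipole"))
  ez <- d$position / d$r_z
  p_rad <- sum(d$moment * ez)
  tan_vec <- d$moment - p_rad * ez
  p_tan <- sqrt(sum(tan_vec^2))
  if (p_tan > 1e-14 * max(sqrt(sum(d$moment^2)), 1e-300)) {
    ey <- tan_vec / p_tan
  } else {
    p_tan <- 0
    ## moment purely radial (or zero): tangential direction is free.
    ## Deterministic choice that keeps the frame world-aligned for a dipole
    ## on +z (so ey -> world y): ey = ez x h, h the world axis least aligned
    ## with ez.
    k <- which.min(abs(ez))
    h <- numeric(3); h[k] <- 1
    ey <- c(ez[2] * h[3] - ez[3] * h[2],
            ez[3] * h[1] - ez[1] * h[3],
            ez[1] * h[2] - ez[2] * h[1])
    ey <- ey / sqrt(sum(ey^2))
  }
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  rot <- rbind(ex, ey, ez, deparse.level = 0)
  structure(list(rotation = rot, r_z = d$r_z, p_rad = p_rad, p_tan = p_tan),
            class = "canonical_frame")
}

#' @export
print.canonical_frame <- function(x, ...) {
  cat(sprintf("Canonical dipole frame: r_z = %.4g m, p_rad = %.3g A m, p_tan = %.3g A m\n",
              x$r_z, x$p_rad, x$p_tan))
  invisible(x)
}

#' Cartesian points to canonical spherical coordinates
#'
#' Maps world-frame Cartesian points into the spherical coordinates
#' \eqn{(r, \theta, \varphi)} of a dipole's canonical frame: \eqn{\theta} is
#' the angle from the dipole position axis and \eqn{\varphi} the azimuth from
#' the canonical +x axis (so the tangential moment lies at
#' \eqn{\varphi = \pi/2}).
#'
#' @param points numeric 3-vector or an n x 3 matrix of points in metres.
#' @param frame a [canonical_frame()].
#' @param model optional [four_sphere()]; when supplied, points outside the
#'   scalp radius raise an error.
#' @param tol relative slack on the outside-head test; points within it
#'   (e.g. scalp electrodes whose file coordinates were rounded) are clamped
#'   onto the scalp surface.
#' @return `data.frame` with columns `r` (m), `theta`, `phi` (radians).
#' @export
to_spherical <- function(points, frame, model = NULL, tol = 1e-4) {
  stopifnot(inherits(frame, "canonical_frame"))
  pts <- .as_points(points)
  q <- pts %*% t(frame$rotation)
  r <- sqrt(rowSums(q^2))
  if (!is.null(model)) {
    r4 <- model$radii[4]
    if (any(r > r4 * (1 + tol)))
      .fs_error(sprintf("point at r = %.6g m lies outside the head (r4 = %.6g m)",
                        max(r), r4),
                "foursphere_outside_head_error")
    r <- pmin(r, r4)
  }
  ct <- ifelse(r > 0, q[, 3] / r, 1)
  data.frame(r = r,
             theta = acos(pmin(1, pmax(-1, ct))),
             phi = atan2(q[, 2], q[, 1]))
}

.as_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      .fs_error("'points' must be a 3-vector or an n x 3 matrix",
                "foursphere_parameter_error")
    points <- matrix(points, nrow = 1L)
  }
  storage.mode(points) <- "double"
  if (ncol(points) != 3L || !all(is.finite(points)))
    .fs_error("'points' must be finite with 3 columns", "foursphere_parameter_error")
  points
}
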