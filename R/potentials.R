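## Series evaluation of the potential (and its radial derivative) in every
## shell, for radial and tangential dipoles, plus the superposed potential of
## an arbitrarily oriented dipole.
##
## Angular bases are generated by upward recurrence per evaluation point:
##   P_n(x):    (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
##   P_n^1(x):  n P_{n+1}^1 = (2n+1) x P_n^1 - (n+1) P_{n-1}^1
## with the Condon-Shortley-free start P_1^1(cos t) = sin t >= 0.  With that
## convention the tangential prefactor is +p sin(phi)/(4 pi sigma_1 r_z^2)
## for a moment along canonical +y; the sign is pinned by requiring agreement
## with the infinite-homogeneous-medium dipole formula (and is algebraically
## identical to the conventional -sin(phi) form written with Condon-Shortley
## phased associated Legendre functions).

## Core: adaptive block summation over harmonics.
## r, theta, phi: equal-length vectors (canonical frame, SI).
## kind: "radial" | "tangential"; deriv: d/dr instead of value.
## Returns list(value, terms_used, converged, shell).
.series_eval <- function(model, r_z, r, theta, phi, kind = "radial",
                         deriv = FALSE, ctrl = series_control(),
                         method = "recursive", p = 1, force_shell = NULL) {
  m <- length(r)
  shell <- if (is.null(force_shell)) .shell_index(model, r)
           else rep_len(as.integer(force_shell), m)
  if (any(r <= r_z))
    .fs_error("evaluation points must lie strictly outside the dipole radius r_z (the interior expansion is not implemented)",
              "foursphere_validity_region_error")
  x <- cos(theta)
  prefac <- p / (4 * pi * model$conductivities[1] * r_z^2)
  ang_scale <- if (kind == "tangential") sin(phi) else rep(1, m)
  rs <- model$radii[shell]
  log_up <- log(r / rs)                               # A-basis exponent rate
  log_dn <- ifelse(shell == 1L, log(r_z / r), log(rs / r))  # B/source basis

  acc <- numeric(m)
  small_run <- integer(m)
  terms_used <- rep(NA_integer_, m)
  active <- rep(TRUE, m)

  ## Legendre recurrence state (value at current n, previous n)
  p_prev <- rep(1, m); p_curr <- x                    # P_0, P_1
  q_prev <- rep(0, m); q_curr <- sqrt(pmax(0, 1 - x^2))  # P_0^1, P_1^1

  block <- 256L
  n_done <- 0L
  groups <- split(seq_len(m), shell)
  repeat {
    hi <- min(n_done + block, ctrl$n_max)
    nn <- (n_done + 1L):hi
    nb <- length(nn)
    co <- .get_coefs(model, r_z, hi, method)

    ## angular factors for the block (scalar loop over n, vector over points)
    ang <- matrix(0, nb, m)
    for (k in seq_len(nb)) {
      nk <- nn[k]
      ang[k, ] <- if (kind == "radial") nk * p_curr else ang_scale * q_curr
      p_next <- ((2 * nk + 1) * x * p_curr - nk * p_prev) / (nk + 1)
      p_prev <- p_curr; p_curr <- p_next
      q_next <- ((2 * nk + 1) * x * q_curr - (nk + 1) * q_prev) / nk
      q_prev <- q_curr; q_curr <- q_next
    }

    ## radial factors per shell group (vectorised over n and points)
    term <- matrix(0, nb, m)
    for (g in names(groups)) {
      idx <- groups[[g]]
      si <- as.integer(g)
      a_col <- co[nn, paste0("A", si)]
      c_col <- if (si == 1L) rep(1, nb) else co[nn, paste0("B", si)]
      up <- exp(outer(nn, log_up[idx]))
      dn <- exp(outer(nn + 1, log_dn[idx]))
      if (deriv) {
        rad <- (a_col * nn) * up - (c_col * (nn + 1)) * dn
        rad <- sweep(rad, 2L, r[idx], "/")
      } else {
        rad <- a_col * up + c_col * dn
      }
      term[, idx] <- rad
    }
    term <- term * ang
    if (any(!is.finite(term))) {
      bad <- which(!is.finite(term), arr.ind = TRUE)[1L, 1L]
      .fs_error(sprintf("series term left the double-precision range at n = %d",
                        nn[bad]), "foursphere_series_range_error")
    }

    for (k in seq_len(nb)) {
      acc <- acc + term[k, ]
      ok <- abs(term[k, ]) <= ctrl$rel_tol * abs(acc)
      small_run <- ifelse(ok, small_run + 1L, 0L)
      done <- active & small_run >= ctrl$consecutive_small
      terms_used[done] <- nn[k]
      active[done] <- FALSE
    }
    n_done <- hi
    if (!any(active) || n_done >= ctrl$n_max) break
  }
  converged <- !active
  if (any(active)) {
    terms_used[active] <- ctrl$n_max
    warning(sprintf("series not converged to rel_tol = %g within n_max = %d for %d point(s)",
                    ctrl$rel_tol, ctrl$n_max, sum(active)))
  }
  list(value = prefac * acc, terms_used = terms_used,
       converged = converged, shell = shell)
}

.recycle3 <- function(r, theta, phi) {
  m <- max(length(r), length(theta), length(phi))
  list(r = rep_len(as.numeric(r), m), theta = rep_len(as.numeric(theta), m),
       phi = rep_len(as.numeric(phi), m))
}

.potential_kind <- function(model, r_z, p, r, theta, phi, kind, ctrl, deriv = FALSE,
                            method = "recursive") {
  stopifnot(inherits(model, "four_sphere"))
  .check_coef_args(model, r_z, 1L)
  if (!is.finite(p)) .fs_error("moment magnitude must be finite", "foursphere_parameter_error")
  g <- .recycle3(r, theta, phi)
  if (p == 0) {    # linearity: zero source, zero field; skip summation
    sh <- .shell_index(model, g$r)
    return(data.frame(r = g$r, theta = g$theta, phi = g$phi, shell = sh,
                      value = 0, terms_used = 0L))
  }
  ev <- .series_eval(model, r_z, g$r, g$theta, g$phi, kind = kind,
                     deriv = deriv, ctrl = ctrl, method = method, p = p)
  data.frame(r = g$r, theta = g$theta, phi = g$phi, shell = ev$shell,
             value = ev$value, terms_used = ev$terms_used)
}

#' Potential of a radial dipole
#'
#' Series potential of a dipole whose moment points along its position vector
#' (canonical frame: on the +z axis).  The solution is azimuth-independent;
#' `phi` is accepted for interface symmetry but does not affect the value.
#'
#' @param model a [four_sphere()].
#' @param r_z dipole radial position (m), `0 < r_z < r1`.
#' @param p signed moment magnitude (A m).
#' @param r,theta,phi evaluation coordinates in the canonical frame (m,
#'   radians); recycled to a common length.  Valid region:
#'   `r_z < r <= r4`.
#' @param ctrl a [series_control()].
#' @return `data.frame` with columns `r`, `theta`, `phi`, `shell` (1-4,
#'   interface radii assigned to the inner shell), `value` (volts) and
#'   `terms_used` (harmonics at truncation).
#' @examples
#' m <- four_sphere()
#' potential_radial(m, r_z = 0.078, p = 1e-7, r = 0.09, theta = 0)
#' @export
potential_radial <- function(model, r_z, p, r, theta, phi = 0,
                             ctrl = series_control()) {
  .potential_kind(model, r_z, p, r, theta, phi, "radial", ctrl)
}

#' Potential of a tangential dipole
#'
#' Series potential of a dipole whose moment is perpendicular to its position
#' vector (canonical frame: moment along +y, azimuth measured from +x so the
#' value is proportional to \eqn{\sin\varphi}).  Uses the same expansion
#' coefficients as the radial solution; the angular basis is the first-order
#' associated Legendre function and there is no extra factor `n` in the sum.
#' On the symmetry axis (\eqn{\theta} = 0 or \eqn{\pi}) the potential is
#' exactly zero.
#'
#' @inheritParams potential_radial
#' @return As [potential_radial()].
#' @export
potential_tangential <- function(model, r_z, p, r, theta, phi = 0,
                                 ctrl = series_control()) {
  .potential_kind(model, r_z, p, r, theta, phi, "tangential", ctrl)
}

#' Radial derivative of the series potential
#'
#' Term-by-term analytic differentiation of the shell basis in `r`.  Used to
#' verify the current-continuity and scalp Neumann boundary conditions: at
#' `r = r4` the per-term derivative cancels identically because
#' \eqn{B_n^4 = \frac{n}{n+1} A_n^4}.
#'
#' @inheritParams potential_radial
#' @param kind `"radial"` or `"tangential"` dipole solution.
#' @return `data.frame` as [potential_radial()], `value` in V/m.
#' @export
radial_derivative <- function(model, r_z, p, r, theta, phi = 0,
                              kind = c("radial", "tangential"),
                              ctrl = series_control()) {
  kind <- match.arg(kind)
  .potential_kind(model, r_z, p, r, theta, phi, kind, ctrl, deriv = TRUE)
}

#' Potential of an arbitrarily oriented dipole
#'
#' Decomposes the dipole into its radial and tangential components
#' ([canonical_frame()]), evaluates the two pure solutions with a shared
#' coefficient table, and superposes them.  Points are world-frame Cartesian
#' coordinates relative to the sphere centre.
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()]; its position must lie strictly inside the brain
#'   shell.
#' @param points 3-vector or n x 3 matrix of evaluation points (m).  Every
#'   point must satisfy `r_z < |point| <= r4`.
#' @param ctrl a [series_control()].
#' @param method coefficient route, `"recursive"` (default) or `"linear"`
#'   (boundary-condition oracle; used for cross-checking).
#' @return Numeric vector of potentials in volts, with attribute
#'   `"terms_used"` (max harmonics over the component evaluations).
#' @examples
#' m <- four_sphere()
#' d <- dipole(c(0, 0, 7.8), c(0, 0, 1e-7), units = "cm")
#' potential_dipole(m, d, c(0, 0, 0.09))
#' @export
potential_dipole <- function(model, d, points, ctrl = series_control(),
                             method = c("recursive", "linear")) {
  stopifnot(inherits(model, "four_sphere"), inherits(d, "dipole"))
  method <- match.arg(method)
  if (d$r_z >= model$radii[1])
    .fs_error("dipole must lie strictly inside the brain shell (r_z < r1)",
              "foursphere_parameter_error")
  fr <- canonical_frame(d)
  sph <- to_spherical(points, fr, model = model)
  if (all(d$moment == 0)) {
    out <- rep(0, nrow(sph)); attr(out, "terms_used") <- 0L
    return(out)
  }
  val <- numeric(nrow(sph))
  terms <- 0L
  if (fr$p_rad != 0) {
    ev <- .series_eval(model, d$r_z, sph$r, sph$theta, sph$phi,
                       kind = "radial", ctrl = ctrl, method = method,
                       p = fr$p_rad)
    val <- val + ev$value
    terms <- max(terms, ev$terms_used)
  }
  if (fr$p_tan != 0) {
    ev <- .series_eval(model, d$r_z, sph$r, sph$theta, sph$phi,
                       kind = "tangential", ctrl = ctrl, method = method,
                       p = fr$p_tan)
    val <- val + ev$value
    terms <- max(terms, ev$terms_used)
  }
  attr(val, "terms_used") <- terms
  val
}

#' Predict electrode potentials from a head model
#'
#' `predict` method for `"four_sphere"`: potentials of a dipole at a set of
#' electrode positions.
#'
#' @param object a [four_sphere()].
#' @param d a [dipole()].
#' @param electrodes a `data.frame` with columns `label`, `x`, `y`, `z` (as
#'   returned by [read_electrodes()]) or an n x 3 matrix of positions in
#'   metres.
#' @param ctrl a [series_control()].
#' @param units output units, `"V"` (default) or `"uV"`.
#' @param ... unused.
#' @return `data.frame` with the electrode positions and a `potential_V`
#'   (or `potential_uV`) column.
#' @export
predict.four_sphere <- function(object, d, electrodes,
                                ctrl = series_control(),
                                units = c("V", "uV"), ...) {
  units <- match.arg(units)
  if (is.data.frame(electrodes)) {
    lab <- if ("label" %in% names(electrodes)) as.character(electrodes$label)
           else as.character(seq_len(nrow(electrodes)))
    pts <- as.matrix(electrodes[, c("x", "y", "z")])
  } else {
    pts <- .as_points(electrodes)
    lab <- as.character(seq_len(nrow(pts)))
  }
  if (nrow(pts) == 0L) {
    out <- data.frame(label = character(), x = double(), y = double(),
                      z = double())
    out[[paste0("potential_", units)]] <- double()
    return(out)
  }
  val <- potential_dipole(object, d, pts, ctrl = ctrl)
  out <- data.frame(label = lab, x = pts[, 1], y = pts[, 2], z = pts[, 3])
  out[[paste0("potential_", units)]] <-
    if (units == "uV") as.numeric(val) * 1e6 else as.numeric(val)
  attr(out, "terms_used") <- attr(val, "terms_used")
  out
}

#' @rdname compute_coefficients
#' @param object a `"four_sphere"` model (for the `coef` method).
#' @param ... unused.
#' @export
coef.four_sphere <- function(object, r_z, n = 1:50,
                             method = c("recursive", "linear"), ...) {
  compute_coefficients(object, r_z, n, method = match.arg(method))
}

#' @rdname coefficient_residuals
#' @param object a `"four_sphere"` model (for the `residuals` method).
#' @param n harmonic indices (for the `residuals` method).
#' @param ... unused.
#' @export
residuals.four_sphere <- function(object, r_z, n = 1:50, ...) {
  coefficient_residuals(compute_coefficients(object, r_z, n), object, r_z)
}
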