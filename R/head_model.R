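## Domain objects: head model, dipole, series control.  Constructors validate
## eagerly and convert units at the boundary; everything downstream is SI.

.fs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "foursphere_error", "error")))
}

.to_metres <- function(x, units) {
  switch(units, m = x, cm = x / 100,
         .fs_error(sprintf("unknown length unit '%s' (use 'm' or 'cm')", units),
                   "foursphere_parameter_error"))
}

#' Four-sphere head model
#'
#' Constructs a concentric four-shell volume-conductor model of the head.
#' Shells 1--4 are brain, cerebrospinal fluid (CSF), skull and scalp; each has
#' an outer radius and a homogeneous, isotropic, frequency-independent
#' conductivity.
#'
#' The defaults reproduce the standard geometry used throughout the EEG
#' literature: radii 7.9, 8.0, 8.5 and 9.0 cm with
#' \eqn{\sigma_{CSF} = 5\sigma_{brain}}, \eqn{\sigma_{skull} =
#' \sigma_{brain}/K} and \eqn{\sigma_{scalp} = \sigma_{brain}}, with
#' \eqn{\sigma_{brain} = 0.33} S/m.  The skull divisor `K` is not settled in
#' the literature; 20, 40 and 80 are the commonly used presets.
#'
#' @param radii outer radii of the four shells, strictly increasing.
#' @param conductivities optional vector of four conductivities in S/m; when
#'   `NULL` they are derived from `sigma_brain` and `skull_divisor` as above.
#' @param sigma_brain brain conductivity in S/m (used when `conductivities`
#'   is `NULL`).
#' @param skull_divisor the ratio \eqn{\sigma_{brain}/\sigma_{skull}} (used
#'   when `conductivities` is `NULL`).
#' @param units unit of `radii`: `"cm"` (default, matching how head geometry
#'   is conventionally quoted) or `"m"`.
#'
#' @return An object of class `"four_sphere"`: a list with elements `radii`
#'   (metres) and `conductivities` (S/m), shells ordered brain, CSF, skull,
#'   scalp.
#'
#' @examples
#' m <- four_sphere()                  # standard model, K = 20
#' m80 <- four_sphere(skull_divisor = 80)
#' hom <- four_sphere(conductivities = rep(0.33, 4))  # homogeneous control
#' @export
four_sphere <- function(radii = c(7.9, 8.0, 8.5, 9.0),
                        conductivities = NULL,
                        sigma_brain = 0.33,
                        skull_divisor = 20,
                        units = c("cm", "m")) {
  units <- match.arg(units)
  if (length(radii) != 4L || !is.numeric(radii) || !all(is.finite(radii)))
    .fs_error("'radii' must be four finite numbers", "foursphere_geometry_error")
  if (is.null(conductivities)) {
    if (!is.finite(sigma_brain) || sigma_brain <= 0)
      .fs_error("'sigma_brain' must be positive", "foursphere_parameter_error")
    if (!is.finite(skull_divisor) || skull_divisor <= 0)
      .fs_error("'skull_divisor' must be positive", "foursphere_parameter_error")
    conductivities <- sigma_brain * c(1, 5, 1 / skull_divisor, 1)
  }
  if (length(conductivities) != 4L || !is.numeric(conductivities) ||
      !all(is.finite(conductivities)))
    .fs_error("'conductivities' must be four finite numbers",
              "foursphere_parameter_error")
  r <- .to_metres(as.numeric(radii), units)
  if (any(r <= 0) || any(diff(r) <= 0))
    .fs_error("shell radii must satisfy 0 < r1 < r2 < r3 < r4",
              "foursphere_geometry_error")
  if (any(conductivities <= 0))
    .fs_error("all conductivities must be strictly positive",
              "foursphere_parameter_error")
  structure(
    list(radii = r, conductivities = as.numeric(conductivities)),
    class = "four_sphere")
}

#' @export
print.four_sphere <- function(x, ...) {
  cat("Four-sphere head model (concentric shells)\n")
  df <- data.frame(
    shell = c("brain", "CSF", "skull", "scalp"),
    radius_cm = x$radii * 100,
    sigma_S_per_m = x$conductivities)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.four_sphere <- function(object, ...) {
  s <- object$conductivities
  out <- list(
    model = object,
    sigma_ratios = c(sigma12 = s[1] / s[2], sigma23 = s[2] / s[3],
                     sigma34 = s[3] / s[4]),
    skull_divisor = s[1] / s[3],
    homogeneous = isTRUE(all.equal(rep(s[1], 4), s)))
  class(out) <- "summary.four_sphere"
  out
}

#' @export
print.summary.four_sphere <- function(x, ...) {
  print(x$model)
  cat(sprintf("sigma_brain/sigma_skull (K): %.4g\n", x$skull_divisor))
  cat(sprintf("interface conductivity ratios: s12 = %.4g, s23 = %.4g, s34 = %.4g\n",
              x$sigma_ratios[1], x$sigma_ratios[2], x$sigma_ratios[3]))
  if (x$homogeneous)
    cat("conductivities are equal: homogeneous (single-sphere) control case\n")
  invisible(x)
}

#' @export
plot.four_sphere <- function(x, ...) {
  r <- x$radii * 100
  graphics::plot(NA, xlim = c(-r[4], r[4]) * 1.05, ylim = c(-r[4], r[4]) * 1.05,
                 asp = 1, xlab = "x (cm)", ylab = "z (cm)",
                 main = "Four-sphere head model (cross-section)", ...)
  cols <- c("#fdd49e", "#a6bddb", "#d9d9d9", "#fcbba1")
  th <- seq(0, 2 * pi, length.out = 361)
  for (s in 4:1)
    graphics::polygon(r[s] * cos(th), r[s] * sin(th), col = cols[s],
                      border = "grey30")
  graphics::legend("topright", legend = c("brain", "CSF", "skull", "scalp"),
                   fill = cols, bty = "n", cex = 0.8)
  invisible(x)
}

#' Current dipole source
#'
#' An ideal current dipole: a point source/sink pair with infinitesimal
#' separation, characterised by a position vector and a moment vector.  The
#' standard source model for the neural generators of EEG.
#'
#' The position must be strictly off-centre: the series solution carries a
#' \eqn{1/r_z^2} prefactor and is indeterminate for a dipole exactly at the
#' sphere centre.  Use a small offset (e.g. 1 mm) if a central source is
#' needed.  A zero moment is allowed and yields zero potential everywhere.
#'
#' @param position 3-vector, dipole location relative to the sphere centre.
#' @param moment 3-vector, dipole moment in ampere-metres.
#' @param units unit of `position`: `"m"` (default) or `"cm"`.
#' @return Object of class `"dipole"`: list with `position` (m), `moment`
#'   (A m) and `r_z` (radial distance of the source, m).
#' @examples
#' d <- dipole(c(0, 0, 7.8), c(0, 0, 1e-7), units = "cm")  # radial dipole
#' @export
dipole <- function(position, moment, units = c("m", "cm")) {
  units <- match.arg(units)
  if (length(position) != 3L || !all(is.finite(position)))
    .fs_error("'position' must be a finite 3-vector", "foursphere_parameter_error")
  if (length(moment) != 3L || !all(is.finite(moment)))
    .fs_error("'moment' must be a finite 3-vector", "foursphere_parameter_error")
  pos <- .to_metres(as.numeric(position), units)
  r_z <- sqrt(sum(pos^2))
  if (r_z == 0)
    .fs_error("dipole exactly at the sphere centre is not representable; use a small offset",
              "foursphere_undecomposable_error")
  structure(list(position = pos, moment = as.numeric(moment), r_z = r_z),
            class = "dipole")
}

#' @export
print.dipole <- function(x, ...) {
  cat(sprintf("Current dipole at (%.4g, %.4g, %.4g) m  (r_z = %.4g cm)\n",
              x$position[1], x$position[2], x$position[3], x$r_z * 100))
  cat(sprintf("  moment (%.3g, %.3g, %.3g) A m, |p| = %.3g A m\n",
              x$moment[1], x$moment[2], x$moment[3], sqrt(sum(x$moment^2))))
  invisible(x)
}

#' Series truncation control
#'
#' The Legendre expansions are infinite sums; evaluation truncates adaptively.
#' Summation stops once `consecutive_small` successive terms each contribute
#' less than `rel_tol` of the running sum, or at the hard cap `n_max`.
#'
#' The defaults are sized for the hardest routine case, evaluation just above
#' the dipole on the brain surface, where the term ratio is
#' \eqn{r_z/r_1 \approx 0.987} and roughly 2000 harmonics are needed for a
#' 1e-12 tail.  Scalp-surface evaluation typically converges within a few
#' hundred terms.
#'
#' @param n_max hard cap on the harmonic index (default 5000).
#' @param rel_tol relative tail tolerance (default 1e-12).
#' @param consecutive_small number of successive negligible terms required
#'   before stopping (default 10; guards against odd/even term cancellation
#'   patterns on the symmetry axis).
#' @return Object of class `"series_control"`.
#' @export
series_control <- function(n_max = 5000L, rel_tol = 1e-12,
                           consecutive_small = 10L) {
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L)
    .fs_error("'n_max' must be a positive integer", "foursphere_parameter_error")
  if (!is.finite(rel_tol) || rel_tol <= 0)
    .fs_error("'rel_tol' must be positive", "foursphere_parameter_error")
  consecutive_small <- as.integer(consecutive_small)
  if (is.na(consecutive_small) || consecutive_small < 1L)
    .fs_error("'consecutive_small' must be a positive integer",
              "foursphere_parameter_error")
  structure(list(n_max = n_max, rel_tol = rel_tol,
                 consecutive_small = consecutive_small),
            class = "series_control")
}

## shell index of radius r: 1..4, interface radii assigned to the inner shell
## (the continuity condition makes either assignment equivalent to tolerance).
.shell_index <- function(model, r, tol = 1e-12) {
  rs <- model$radii
  out <- 4L - (r <= rs[3] * (1 + tol)) - (r <= rs[2] * (1 + tol)) -
    (r <= rs[1] * (1 + tol))
  out <- pmax(out, 1L)
  if (any(r > rs[4] * (1 + tol)))
    .fs_error(sprintf("evaluation point at r = %.6g m lies outside the scalp (r4 = %.6g m)",
                      max(r), rs[4]), "foursphere_outside_head_error")
  as.integer(out)
}

#' Random valid head model (for property testing)
#'
#' Draws a geometrically valid four-sphere model: radii strictly increasing in
#' \[5, 12\] cm with at least 1 mm between consecutive interfaces, and
#' conductivities log-uniform in \[0.004, 2\] S/m (log-uniform because
#' interface conductivity *ratios* are what the physics responds to).
#'
#' @param seed optional integer seed, applied locally via a private RNG stream
#'   so the caller's RNG state is untouched.
#' @return A `"four_sphere"` object.
#' @export
random_head_model <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  repeat {
    r <- sort(stats::runif(4, 5, 12))
    if (all(diff(r) >= 0.1)) break
  }
  sig <- exp(stats::runif(4, log(0.004), log(2)))
  four_sphere(radii = r, conductivities = sig, units = "cm")
}
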