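## Scalp-surface potential maps: gridding, export, surface statistics.

#' Gridded scalp potential map
#'
#' Evaluates the potential of a dipole on a regular
#' \eqn{(\theta, \varphi)} grid over the scalp surface `r = r4`.  Angles are
#' world-frame spherical coordinates about the +z axis (not the dipole's
#' canonical frame), so maps for differently oriented dipoles share a grid.
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()].
#' @param n_theta,n_phi grid resolution; theta covers \[0, pi\], phi covers
#'   \[0, 2 pi).
#' @param ctrl a [series_control()].
#' @return Object of class `"scalp_map"`: list with `theta`, `phi` (grid
#'   vectors), `values` (`n_theta` x `n_phi` matrix, volts) and metadata
#'   (`model`, `dipole`, `ctrl`, `version`).
#' @examples
#' \donttest{
#' m <- scalp_map(four_sphere(), dipole(c(0, 0, 7.8), c(0, 0, 1e-7), "cm"),
#'                n_theta = 31, n_phi = 60)
#' plot(m)
#' }
#' @export
scalp_map <- function(model, d, n_theta = 90, n_phi = 180,
                      ctrl = series_control()) {
  stopifnot(inherits(model, "four_sphere"), inherits(d, "dipole"))
  if (n_theta < 2 || n_phi < 2)
    .fs_error("grid resolution must be at least 2 per axis",
              "foursphere_parameter_error")
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[seq_len(n_phi)]
  g <- expand.grid(theta = theta, phi = phi)
  r4 <- model$radii[4]
  pts <- cbind(r4 * sin(g$theta) * cos(g$phi),
               r4 * sin(g$theta) * sin(g$phi),
               r4 * cos(g$theta))
  val <- potential_dipole(model, d, pts, ctrl = ctrl)
  structure(list(theta = theta, phi = phi,
                 values = matrix(as.numeric(val), n_theta, n_phi),
                 model = model, dipole = d, ctrl = ctrl,
                 version = as.character(utils::packageVersion("foursphere"))),
            class = "scalp_map")
}

#' @export
print.scalp_map <- function(x, ...) {
  cat(sprintf("Scalp potential map: %d x %d (theta x phi) grid at r4 = %.3g cm\n",
              length(x$theta), length(x$phi), x$model$radii[4] * 100))
  cat(sprintf("  range [%.4g, %.4g] uV\n",
              min(x$values) * 1e6, max(x$values) * 1e6))
  invisible(x)
}

#' @export
as.data.frame.scalp_map <- function(x, ...) {
  g <- expand.grid(theta_rad = x$theta, phi_rad = x$phi)
  g$potential_V <- as.vector(x$values)
  g
}

#' Write a scalp map as long-format CSV
#'
#' Columns `theta_rad`, `phi_rad`, `potential_V` (or `potential_uV`).
#'
#' @param map a [scalp_map()].
#' @param path output file.
#' @param units `"V"` or `"uV"`.
#' @return `path`, invisibly.
#' @export
write_scalp_map <- function(map, path, units = c("V", "uV")) {
  units <- match.arg(units)
  df <- as.data.frame(map)
  if (units == "uV") {
    df$potential_V <- df$potential_V * 1e6
    names(df)[names(df) == "potential_V"] <- "potential_uV"
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.scalp_map <- function(x, ...) {
  v <- x$values * 1e6
  lim <- max(abs(v))
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  graphics::image(x$phi, x$theta, t(v), col = pal,
                  zlim = c(-lim, lim), xlab = expression(phi ~ "(rad)"),
                  ylab = expression(theta ~ "(rad)"), useRaster = TRUE,
                  main = "Scalp potential (uV)", ...)
  graphics::contour(x$phi, x$theta, t(v), add = TRUE, col = "grey30",
                    nlevels = 8)
  invisible(x)
}

#' Area-weighted mean potential over the scalp sphere
#'
#' Surface average computed with Gauss-Legendre quadrature in
#' \eqn{\cos\theta} and a uniform azimuthal grid.  The expansion contains no
#' monopole term (all source current returns within the head), so the mean
#' must vanish to truncation tolerance; returned alongside the peak magnitude
#' for normalisation.
#'
#' @param model a [four_sphere()].
#' @param d a [dipole()].
#' @param n_gauss Gauss-Legendre node count (exact for harmonics up to
#'   `2 n_gauss - 1`).
#' @param n_phi azimuthal grid size.
#' @param ctrl a [series_control()].
#' @return List with `mean` (V), `peak` (V) and `ratio` (`|mean|/peak`).
#' @export
scalp_surface_mean <- function(model, d, n_gauss = 200, n_phi = 90,
                               ctrl = series_control()) {
  gl <- pracma::gaussLegendre(n_gauss, -1, 1)
  theta <- acos(gl$x)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[seq_len(n_phi)]
  g <- expand.grid(theta = theta, phi = phi)
  r4 <- model$radii[4]
  pts <- cbind(r4 * sin(g$theta) * cos(g$phi),
               r4 * sin(g$theta) * sin(g$phi),
               r4 * cos(g$theta))
  val <- matrix(potential_dipole(model, d, pts, ctrl = ctrl),
                n_gauss, n_phi)
  mn <- sum(gl$w * rowMeans(val)) / 2     # weights sum to 2 over cos(theta)
  list(mean = mn, peak = max(abs(val)), ratio = abs(mn) / max(abs(val)))
}
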