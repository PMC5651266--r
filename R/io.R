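## Configuration and electrode file handling, and the three operations behind
## the command-line interface (inst/exec/foursphere): compute, map, validate.
## Progress/log lines go to stderr via message(); results go to files.

#' Read a model configuration file
#'
#' YAML or JSON (chosen by file extension).  Recognised structure:
#' \preformatted{
#' model:
#'   radii: [7.9, 8.0, 8.5, 9.0]
#'   units: cm            # or m
#'   sigma_brain: 0.33    # Table-style spec: CSF = 5*brain, skull = brain/K,
#'   skull_divisor: 20    # scalp = brain ...
#'   conductivities: [...]  # ... or all four explicitly (S/m)
#' series: {n_max: 5000, rel_tol: 1e-12, consecutive_small: 10}
#' dipole:  {position: [0, 0, 7.8], moment: [0, 0, 1e-7]}  # position in model units
#' output:  {units: V}    # or uV
#' }
#' All keys except `model` are optional.
#'
#' @param path configuration file path.
#' @return List with `model` ([four_sphere()]), `ctrl` ([series_control()]),
#'   `dipole` ([dipole()] or `NULL`), `units` (length unit of the file) and
#'   `output_units`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    .fs_error(sprintf("configuration file '%s' not found", path),
              "foursphere_io_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  mc <- cfg$model
  if (is.null(mc)) .fs_error("configuration lacks a 'model' section",
                             "foursphere_config_error")
  units <- if (is.null(mc$units)) "cm" else match.arg(mc$units, c("cm", "m"))
  args <- list(units = units)
  if (!is.null(mc$radii)) args$radii <- as.numeric(mc$radii)
  if (!is.null(mc$conductivities)) {
    args$conductivities <- as.numeric(mc$conductivities)
  } else {
    if (!is.null(mc$sigma_brain)) args$sigma_brain <- as.numeric(mc$sigma_brain)
    if (!is.null(mc$skull_divisor)) args$skull_divisor <- as.numeric(mc$skull_divisor)
  }
  model <- do.call(four_sphere, args)
  sargs <- cfg$series[intersect(names(cfg$series),
                                c("n_max", "rel_tol", "consecutive_small"))]
  ctrl <- do.call(series_control, if (is.null(sargs)) list() else as.list(sargs))
  dip <- NULL
  if (!is.null(cfg$dipole))
    dip <- dipole(as.numeric(cfg$dipole$position),
                  as.numeric(cfg$dipole$moment), units = units)
  out_units <- if (is.null(cfg$output$units)) "V"
               else match.arg(cfg$output$units, c("V", "uV"))
  list(model = model, ctrl = ctrl, dipole = dip, units = units,
       output_units = out_units)
}

#' Read an electrode position file
#'
#' CSV with header `label,x,y,z`.  Coordinates are interpreted in `units`
#' (typically the configuration file's unit) and returned in metres.
#' Malformed rows raise an error naming the offending line.
#'
#' @param path CSV file path.
#' @param units length unit of the coordinates, `"m"` or `"cm"`.
#' @return `data.frame` with columns `label`, `x`, `y`, `z` (metres).
#' @export
read_electrodes <- function(path, units = c("m", "cm")) {
  units <- match.arg(units)
  if (!file.exists(path))
    .fs_error(sprintf("electrode file '%s' not found", path), "foursphere_io_error")
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(raw)))
    .fs_error("electrode file must have header 'label,x,y,z'",
              "foursphere_io_error")
  if (nrow(raw) == 0L)
    return(data.frame(label = character(), x = double(), y = double(),
                      z = double()))
  xyz <- suppressWarnings(
    vapply(c("x", "y", "z"), function(cn) as.numeric(raw[[cn]]),
           numeric(nrow(raw))))
  xyz <- matrix(xyz, nrow = nrow(raw))
  bad <- which(rowSums(!is.finite(xyz)) > 0)
  if (length(bad))
    .fs_error(sprintf("malformed electrode row at line %d of '%s'",
                      bad[1] + 1L, path), "foursphere_io_error")
  data.frame(label = raw$label,
             x = .to_metres(xyz[, 1], units),
             y = .to_metres(xyz[, 2], units),
             z = .to_metres(xyz[, 3], units))
}

#' Compute electrode potentials from configuration files
#'
#' Reads a configuration (which must include a `dipole` section) and an
#' electrode CSV, computes the potential at every electrode, and writes a CSV
#' `label,x,y,z,potential_V` (coordinates echoed in metres).  An electrode
#' outside the scalp raises an error naming its label.
#'
#' @param config_path configuration file (see [read_config()]).
#' @param electrodes_path electrode CSV (see [read_electrodes()]).
#' @param output_path output CSV path.
#' @param units output unit override (`"V"` or `"uV"`); default from the
#'   configuration.
#' @return The output `data.frame`, invisibly.
#' @export
run_compute <- function(config_path, electrodes_path, output_path,
                        units = NULL) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- read_config(config_path)
  if (is.null(cfg$dipole))
    .fs_error("configuration must contain a 'dipole' section for compute",
              "foursphere_config_error")
  units <- if (is.null(units)) cfg$output_units else match.arg(units, c("V", "uV"))
  el <- read_electrodes(electrodes_path, units = cfg$units)
  r4 <- cfg$model$radii[4]
  if (nrow(el)) {
    rr <- sqrt(el$x^2 + el$y^2 + el$z^2)
    out_of_head <- which(rr > r4 * (1 + 1e-4))
    if (length(out_of_head))
      .fs_error(sprintf("electrode '%s' at r = %.4g cm lies outside the scalp (r4 = %.4g cm)",
                        el$label[out_of_head[1]], rr[out_of_head[1]] * 100, r4 * 100),
                "foursphere_outside_head_error")
  } else {
    warning("electrode file is empty; writing header-only output")
  }
  res <- predict(cfg$model, cfg$dipole, el, ctrl = cfg$ctrl, units = units)
  utils::write.csv(res, output_path, row.names = FALSE, quote = FALSE)
  message(sprintf("foursphere compute: %d electrode(s), %s harmonic(s), %.2f s",
                  nrow(res),
                  if (nrow(res)) max(attr(res, "terms_used")) else 0L,
                  proc.time()[["elapsed"]] - t0))
  invisible(res)
}

#' Compute and export a scalp potential map
#'
#' Grids the scalp potential of the configured dipole
#' (see [scalp_map()]) and writes it as long-format CSV
#' (`theta_rad,phi_rad,potential_V`); optionally renders a PNG image.
#'
#' @param config_path configuration file with a `dipole` section.
#' @param output_path output CSV path.
#' @param n_theta,n_phi grid resolution (>= 2 each).
#' @param image_path optional PNG output.
#' @param units output unit override.
#' @return The `"scalp_map"`, invisibly.
#' @export
run_map <- function(config_path, output_path, n_theta = 90, n_phi = 180,
                    image_path = NULL, units = NULL) {
  cfg <- read_config(config_path)
  if (is.null(cfg$dipole))
    .fs_error("configuration must contain a 'dipole' section for map",
              "foursphere_config_error")
  units <- if (is.null(units)) cfg$output_units else match.arg(units, c("V", "uV"))
  mp <- scalp_map(cfg$model, cfg$dipole, n_theta = n_theta, n_phi = n_phi,
                  ctrl = cfg$ctrl)
  write_scalp_map(mp, output_path, units = units)
  if (!is.null(image_path)) {
    grDevices::png(image_path, width = 900, height = 500)
    plot(mp)
    grDevices::dev.off()
  }
  message(sprintf("foursphere map: %d x %d grid written to %s",
                  n_theta, n_phi, output_path))
  invisible(mp)
}

#' Run the validation suite from a configuration file
#'
#' Executes [run_validation()] on the configured model (and dipole, if one is
#' given) and writes a machine-readable JSON report; the human-readable table
#' goes to stderr.
#'
#' @param config_path configuration file.
#' @param report_path output JSON path.
#' @param samples,n_points check sizes, see [run_validation()].
#' @return `TRUE` if every check passed, invisibly.
#' @export
run_validate <- function(config_path, report_path, samples = 100,
                         n_points = 1000) {
  cfg <- read_config(config_path)
  args <- list(model = cfg$model, ctrl = cfg$ctrl, samples = samples,
               n_points = n_points)
  if (!is.null(cfg$dipole)) args$d <- cfg$dipole
  rep_ <- do.call(run_validation, args)
  jsonlite::write_json(
    list(checks = as.data.frame(unclass(rep_)),
         all_pass = all(rep_$pass),
         package_version = as.character(utils::packageVersion("foursphere"))),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(paste(utils::capture.output(print(rep_)), collapse = "\n"))
  invisible(all(rep_$pass))
}
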