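# Scan/reconstruction configuration with validation and defaults.

#' Scan and reconstruction configuration
#'
#' Collects the acquisition schedule and all solver settings.  Defaults
#' follow the experimental regime the method was designed for: 57
#' wavelengths spanning 430-1200 nm, upsampling factor 4, and 500-pixel
#' tiles with at least 50 pixels of overlap for full-field processing.
#'
#' @param wavelengths wavelength schedule in um; sorted ascending (an
#'   unsorted schedule is sorted with a warning).
#' @param n_m medium refractive index.
#' @param z_D defocus (sample-to-sensor) distance in um.
#' @param sensor_pitch sensor pixel pitch in um.
#' @param upsample integer pixel super-resolution factor s >= 1.
#' @param alpha relaxation factor of the intensity constraint, in [0, 1].
#' @param passes outer iterations over the full schedule.
#' @param nz,dz axial voxel count and pitch (um) of the reconstruction grid.
#' @param reg list of regularization settings: \code{passes},
#'   \code{tv_weight} (NULL: 0.02 x max contrast at first pass),
#'   \code{tv_iters}, \code{nonneg}, \code{interleave} (0: final-stage only).
#' @param tile,min_overlap tile size and minimum overlap (pixels) for
#'   full-field processing.
#' @param seed integer seed driving every stochastic component.
#' @param noise simulation-only noise settings: \code{enabled},
#'   \code{photons}, \code{read_sd}.
#' @return Object of class \code{scan_config}.
#' @export
scan_config <- function(wavelengths = scan_schedule(0.43, 1.20, 57),
                        n_m = 1.33, z_D = 414, sensor_pitch = 1.67,
                        upsample = 4L, alpha = 0.5, passes = 3L,
                        nz = 64L, dz = NULL,
                        reg = list(), tile = 500L, min_overlap = 50L,
                        seed = 1L,
                        noise = list(enabled = FALSE, photons = 1e4,
                                     read_sd = 2)) {
  if (is.unsorted(wavelengths)) {
    warning("wavelength schedule was not sorted; sorting ascending")
    wavelengths <- sort(wavelengths)
  }
  reg_def <- list(passes = 20L, tv_weight = NULL, tv_iters = 10L,
                  nonneg = TRUE, interleave = 0L)
  reg <- utils::modifyList(reg_def, reg)
  noise_def <- list(enabled = FALSE, photons = 1e4, read_sd = 2)
  noise <- utils::modifyList(noise_def, noise)
  if (is.null(dz)) dz <- sensor_pitch / upsample
  cfg <- structure(list(
    wavelengths = as.numeric(wavelengths), n_m = n_m, z_D = z_D,
    sensor_pitch = sensor_pitch, upsample = as.integer(upsample),
    alpha = alpha, passes = as.integer(passes),
    nz = as.integer(nz), dz = dz, reg = reg,
    tile = as.integer(tile), min_overlap = as.integer(min_overlap),
    seed = as.integer(seed), noise = noise), class = "scan_config")
  validate_scan_config(cfg)
  cfg
}

#' Validate a scan configuration
#'
#' Checks every \code{\link{scan_config}} invariant and reports all
#' violations at once.
#'
#' @param cfg a \code{scan_config} (possibly hand-edited).
#' @return The configuration, invisibly, if valid; otherwise an error
#'   aggregating the violations.
#' @export
validate_scan_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(cfg$wavelengths) >= 1 && all(cfg$wavelengths > 0),
      "wavelengths must be positive")
  chk(!is.unsorted(cfg$wavelengths), "wavelengths must be sorted ascending")
  chk(cfg$n_m >= 1, "n_m must be >= 1")
  chk(is.finite(cfg$z_D), "z_D must be finite")
  chk(cfg$sensor_pitch > 0, "sensor_pitch must be positive")
  chk(cfg$upsample >= 1L, "upsample must be >= 1")
  chk(cfg$alpha >= 0 && cfg$alpha <= 1, "alpha must lie in [0, 1]")
  chk(cfg$passes >= 1L, "passes must be >= 1")
  chk(cfg$nz >= 2L && cfg$dz > 0, "axial grid must have nz >= 2, dz > 0")
  chk(cfg$reg$passes >= 0L, "reg$passes must be >= 0")
  chk(cfg$tile >= 1L && cfg$min_overlap >= 0L && cfg$min_overlap < cfg$tile,
      "tiling requires 0 <= min_overlap < tile")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    paste0("Scan config: %d wavelengths %.3g-%.3g um, n_m %.4g, z_D %.4g um,\n",
           "  sensor pitch %.4g um, upsample %d, alpha %.2g, passes %d, ",
           "grid z: %d x %.4g um\n"),
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    x$n_m, x$z_D, x$sensor_pitch, x$upsample, x$alpha, x$passes, x$nz, x$dz))
  cat(sprintf("  regularization: %d passes, tv_weight %s, %d TV iters, nonneg %s\n",
              x$reg$passes,
              if (is.null(x$reg$tv_weight)) "auto" else signif(x$reg$tv_weight, 3),
              x$reg$tv_iters, x$reg$nonneg))
  invisible(x)
}

#' Load a configuration file
#'
#' Reads a YAML or JSON configuration, fills defaults (see
#' \code{\link{scan_config}}), validates, and echoes the effective
#' configuration.  A schedule may be given either as \code{wavelengths_nm}
#' (converted to um) or as \code{wavelengths} (um).
#'
#' @param path file path; extension selects the parser (.yaml/.yml or .json).
#' @param quiet suppress the configuration echo.
#' @return A validated \code{scan_config}.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$wavelengths_nm)) {
    raw$wavelengths <- as.numeric(raw$wavelengths_nm) / 1000
    raw$wavelengths_nm <- NULL
  }
  known <- names(formals(scan_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown configuration keys: ",
            paste(unknown, collapse = ", "))
  cfg <- do.call(scan_config, raw[intersect(names(raw), known)])
  if (!quiet) print(cfg)
  cfg
}
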