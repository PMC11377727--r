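# Forward simulation of the lens-free measurement: scattering potential,
# first-order scattered field on the Ewald shell, Rytov intensity at the
# defocused detector plane, pixel binning to the sensor pitch, and the
# per-wavelength scan simulator.

#' Complex field at a plane
#'
#' A 2D complex envelope field U(r_T; z), i.e. the total field divided by the
#' on-axis plane-wave carrier, so U = 0 means "no sample" in the Rytov
#' exponent representation and U = 1 for the plain field representation.
#'
#' @param field 2D complex matrix.
#' @param pitch lateral pitch in um.
#' @param z plane coordinate in um.
#' @param lambda wavelength in um.
#' @return Object of class \code{complex_field}.
#' @export
complex_field <- function(field, pitch, z, lambda) {
  if (!is.matrix(field)) stop("'field' must be a matrix")
  if (any(!is.finite(Re(field))) || any(!is.finite(Im(field))))
    stop("field entries must be finite")
  structure(list(field = field, pitch = pitch, z = z, lambda = lambda),
            class = "complex_field")
}

#' Measured/simulated intensity frame
#'
#' One non-negative 2D intensity image with its wavelength, defocus distance
#' and pixel pitch.  After normalization the background level is 1.
#'
#' @param I non-negative 2D matrix.
#' @param lambda wavelength (um).
#' @param z_D defocus distance (um).
#' @param pitch pixel pitch (um).
#' @param bit_depth informational tag, e.g. 16.
#' @return Object of class \code{intensity_frame}.
#' @export
intensity_frame <- function(I, lambda, z_D, pitch, bit_depth = NA) {
  if (!is.matrix(I)) stop("'I' must be a matrix")
  if (min(I) < 0) stop("intensity must be non-negative")
  structure(list(I = I, lambda = lambda, z_D = z_D, pitch = pitch,
                 bit_depth = bit_depth),
            class = "intensity_frame")
}

#' @export
print.intensity_frame <- function(x, ...) {
  cat(sprintf(
    "Intensity frame: %d x %d px, pitch %.4g um, lambda %.4g um, z_D %.4g um, range [%.4g, %.4g]\n",
    nrow(x$I), ncol(x$I), x$pitch, x$lambda, x$z_D, min(x$I), max(x$I)))
  invisible(x)
}

#' Scattering potential of a volume
#'
#' Wolf's object function for wavelength \code{lambda}:
#' \deqn{V(r) = (2\pi/\lambda)^2 \, (n(r)^2 - n_m^2)} in um^-2.  It vanishes
#' where the index equals the medium and scales as \eqn{\lambda^{-2}} at
#' fixed contrast, which is what makes the inter-wavelength spectrum
#' transition factor \eqn{(\lambda_i/\lambda_{i+1})^2} exact.
#'
#' @param vol an \code{\link{ri_volume}}.
#' @param lambda wavelength in um.
#' @return 3D array (complex when the volume carries absorption).
#' @export
scattering_potential <- function(vol, lambda) {
  stopifnot(inherits(vol, "ri_volume"))
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive")
  (2 * pi / lambda)^2 * (vol$n^2 - vol$n_m^2)
}

#' Potential spectrum of a volume
#'
#' Centered 3D Fourier transform of the scattering potential, wrapped as a
#' \code{\link{potential_spectrum}} whose fill-weight mask is marked as fully
#' measured (the spectrum is exact, not iteratively filled).
#'
#' @param vol an \code{\link{ri_volume}}.
#' @param lambda wavelength in um.
#' @return A \code{potential_spectrum}.
#' @export
potential_spectrum_of <- function(vol, lambda) {
  V <- scattering_potential(vol, lambda)
  grid <- frequency_grid(dim(vol$n), vol$pitch)
  vhat <- ft_nd(V, vol$pitch)
  potential_spectrum(vhat, grid, lambda,
                     weight = array(1, dim(vol$n)))
}

#' First-order scattered field from a potential spectrum
#'
#' Reads the 3D spectrum on the discretized Ewald shell, applies the
#' diffraction prefactor (see \code{\link{build_shell}}), and inverse
#' transforms the resulting 2D lateral spectrum to the scattered-field
#' envelope \eqn{U_{s1}(r_T; z_D)} (zeros outside the shell support).
#'
#' @param spec a \code{\link{potential_spectrum}}.
#' @param shell an \code{\link{build_shell}} result on the same grid.
#' @return A \code{\link{complex_field}} at the high-resolution pitch.
#' @export
first_order_field <- function(spec, shell) {
  stopifnot(inherits(spec, "potential_spectrum"), inherits(shell, "ewald_shell"))
  if (!identical(spec$grid$shape, shell$grid$shape) ||
      max(abs(spec$grid$pitch - shell$grid$pitch)) > 1e-12)
    stop("shell and spectrum were built on different grids")
  nx <- spec$grid$shape[1]; ny <- spec$grid$shape[2]
  Uhat <- matrix(0i, nx, ny)
  Uhat[cbind(shell$ix, shell$iy)] <- shell$prefactor * spec$vhat[shell$target]
  U <- ift_nd(Uhat, spec$grid$pitch[1:2])
  complex_field(U, spec$grid$pitch[1], shell$z_D, shell$lambda)
}

#' Rytov intensity of a scattered-field envelope
#'
#' Under the Rytov approximation the total field is
#' \eqn{U = U_{in} \exp(U_{s1})} with a unit-amplitude incident wave, so the
#' measured intensity is \eqn{I = |\exp(U_{s1})|^2 = \exp(2\,\mathrm{Re}\,U_{s1})}.
#'
#' @param U_s1 a \code{\link{complex_field}} holding the Rytov exponent.
#' @return An \code{\link{intensity_frame}} at the same (high-resolution) pitch.
#' @export
rytov_intensity <- function(U_s1) {
  stopifnot(inherits(U_s1, "complex_field"))
  I <- exp(2 * Re(U_s1$field))
  intensity_frame(I, U_s1$lambda, U_s1$z, U_s1$pitch)
}

# mean over non-overlapping s x s blocks
#' @noRd
block_mean <- function(x, s) {
  nx <- nrow(x); ny <- ncol(x)
  a <- array(x, c(s, nx %/% s, ny))
  m <- colSums(a) / s                       # (nx/s, ny)
  a2 <- array(t(m), c(s, ny %/% s, nx %/% s))
  t(colSums(a2) / s)                        # (nx/s, ny/s)
}

# upsample by block replication
#' @noRd
block_replicate <- function(x, s) {
  x[rep(seq_len(nrow(x)), each = s), rep(seq_len(ncol(x)), each = s)]
}

#' Bin an intensity frame to the sensor pitch
#'
#' Models the sensor pixel as the mean of its \code{s} x \code{s} block of
#' high-resolution pixels (mean, not sum, so a unit background stays at 1
#' across scales).  Output pitch is \code{s} times the input pitch; the mean
#' intensity is preserved exactly.
#'
#' @param I_hr high-resolution \code{\link{intensity_frame}}.
#' @param s integer upsampling factor (>= 1); both frame dimensions must be
#'   divisible by \code{s}.
#' @return \code{intensity_frame} at the sensor pitch.
#' @export
bin_pixels <- function(I_hr, s) {
  stopifnot(inherits(I_hr, "intensity_frame"))
  s <- as.integer(s)
  if (s < 1L) stop("'s' must be a positive integer")
  if (s == 1L) return(I_hr)
  if (nrow(I_hr$I) %% s != 0L || ncol(I_hr$I) %% s != 0L)
    stop("frame dimensions must be divisible by s; pad symmetrically first")
  intensity_frame(block_mean(I_hr$I, s), I_hr$lambda, I_hr$z_D,
                  I_hr$pitch * s, I_hr$bit_depth)
}

#' Simulate a wavelength-scanning acquisition
#'
#' Composes, per scheduled wavelength: scattering potential, 3D transform,
#' shell extraction, Rytov intensity at the defocus plane, and pixel binning
#' to the sensor pitch.  Optional shot + read noise is applied to the binned
#' frame before normalization (Poisson at \code{cfg$noise$photons} photons
#' per unit intensity, Gaussian read noise of sd \code{cfg$noise$read_sd}
#' photons), then the frame is rescaled back to a unit background.
#'
#' @param vol an \code{\link{ri_volume}}; its lateral extent must equal the
#'   sensor geometry times the upsampling factor.
#' @param cfg a \code{\link{scan_config}}.
#' @return List with \code{frames} (list of sensor-pitch
#'   \code{\link{intensity_frame}}s, schedule order) and \code{truth}
#'   (the phantom annotation plus the configuration).
#' @export
simulate_scan <- function(vol, cfg) {
  stopifnot(inherits(vol, "ri_volume"), inherits(cfg, "scan_config"))
  shape <- dim(vol$n)
  if (any(shape[1:2] %% cfg$upsample != 0L))
    stop("volume lateral extent must be divisible by the upsampling factor")
  if (max(abs(vol$pitch[1] * cfg$upsample - cfg$sensor_pitch)) > 1e-9)
    stop("volume lateral pitch times upsampling factor must equal the sensor pitch")
  grid <- frequency_grid(shape, vol$pitch)
  # dispersion-free sample: one 3D transform, rescaled per wavelength
  f <- vol$n^2 - vol$n_m^2
  fhat <- ft_nd(f, vol$pitch)
  noise_on <- isTRUE(cfg$noise$enabled)
  if (noise_on) set.seed(cfg$seed)
  frames <- vector("list", length(cfg$wavelengths))
  for (i in seq_along(cfg$wavelengths)) {
    lam <- cfg$wavelengths[i]
    vhat <- (2 * pi / lam)^2 * fhat
    spec <- potential_spectrum(vhat, grid, lam)
    shell <- build_shell(grid, lam, cfg$n_m, cfg$z_D)
    Us1 <- first_order_field(spec, shell)
    I_hr <- rytov_intensity(Us1)
    fr <- bin_pixels(I_hr, cfg$upsample)
    if (noise_on) {
      ph <- cfg$noise$photons
      counts <- stats::rpois(length(fr$I), fr$I * ph) +
        stats::rnorm(length(fr$I), 0, cfg$noise$read_sd)
      fr$I <- matrix(pmax(counts, 0) / ph, nrow(fr$I), ncol(fr$I))
    }
    frames[[i]] <- fr
  }
  list(frames = frames,
       truth = list(annotation = vol$annotation, n_m = vol$n_m,
                    pitch = vol$pitch, config = cfg))
}
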