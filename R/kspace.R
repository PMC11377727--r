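# Frequency-space bookkeeping: Cartesian frequency grids, Ewald-sphere radii,
# the lateral-to-axial frequency map, and discretized Ewald-shell voxel maps
# shared by the forward simulator and the inverse solver.

#' Cartesian frequency grid
#'
#' Describes the 3D sampling shared by a real-space volume and its spectrum:
#' voxel counts, voxel pitch (micrometres) and the implied frequency spacing
#' \eqn{\Delta k = 1/(N \Delta x)} (cycles/um) per axis.  Zero frequency sits
#' at 0-based index \code{N \%/\% 2} of each axis, i.e. the coordinate of
#' index \eqn{i} is \eqn{(i - N\%/\%2)\,\Delta k}.
#'
#' @param shape integer vector (Nx, Ny, Nz), each >= 2.
#' @param pitch numeric vector (dx, dy, dz) in micrometres, strictly positive;
#'   the two lateral pitches must be equal.
#' @return An object of class \code{frequency_grid} with fields \code{shape},
#'   \code{pitch} and \code{dk}.
#' @examples
#' g <- frequency_grid(c(64, 64, 32), c(0.25, 0.25, 0.5))
#' g$dk
#' @export
frequency_grid <- function(shape, pitch) {
  shape <- as.integer(shape)
  pitch <- as.numeric(pitch)
  if (length(shape) != 3L || any(shape < 2L))
    stop("'shape' must be three voxel counts, each >= 2")
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stop("'pitch' must be three strictly positive voxel pitches (um)")
  if (abs(pitch[1] - pitch[2]) > 1e-12 * pitch[1])
    stop("lateral pitches must be equal (dx == dy)")
  structure(list(shape = shape, pitch = pitch, dk = 1 / (shape * pitch)),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat("Frequency grid:", paste(x$shape, collapse = " x "),
      "voxels, pitch", paste(signif(x$pitch, 4), collapse = "/"),
      "um, dk", paste(signif(x$dk, 4), collapse = "/"), "cycles/um\n")
  invisible(x)
}

#' Ewald-sphere radius
#'
#' Radius of the Ewald sphere for illumination wavelength \code{lambda} in a
#' medium of refractive index \code{n_m}, in reduced frequency units:
#' \eqn{k_m = n_m/\lambda} (cycles/um).
#'
#' @param lambda wavelength in micrometres (> 0).
#' @param n_m medium refractive index (>= 1).
#' @return Shell radius in cycles/um.
#' @examples
#' ewald_radius(0.43, 1.33)
#' @export
ewald_radius <- function(lambda, n_m) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be positive")
  if (any(!is.finite(n_m)) || any(n_m < 1))
    stop("'n_m' must be >= 1")
  n_m / lambda
}

#' Axial frequency on the Ewald sphere
#'
#' Maps a lateral frequency magnitude to its axial frequency on the sphere of
#' radius \code{k_m}: \eqn{k_z = \sqrt{k_m^2 - k_T^2}}.  Samples at or beyond
#' the shell radius are evanescent and flagged with \code{NA} rather than an
#' error; callers drop them.
#'
#' @param k_T lateral frequency magnitude (cycles/um, >= 0); vectorized.
#' @param k_m shell radius (cycles/um).
#' @return \eqn{k_z} in cycles/um, or \code{NA} where \code{k_T >= k_m}.
#' @examples
#' axial_frequency(3, 5)  # 3-4-5 triangle
#' @export
axial_frequency <- function(k_T, k_m) {
  if (any(k_T < 0)) stop("'k_T' must be non-negative")
  kz <- suppressWarnings(sqrt(k_m^2 - k_T^2))
  kz[k_T >= k_m] <- NA_real_
  kz
}

#' Build the discretized Ewald shell for one wavelength
#'
#' Precomputes, for every lateral frequency voxel strictly inside the disk
#' \eqn{|k_T| < k_m}, the exact axial frequency \eqn{k_z}, the 3D voxel index
#' nearest to the shifted point \eqn{(k_x, k_y, k_z - k_m)} (on-axis
#' incidence shifts the cap by \eqn{k_{in} = (0,0,k_m)}), and the complex
#' diffraction prefactor at defocus \code{z_D}.  The prefactor is the
#' first-order (Born/Rytov) weight in the envelope convention with the
#' incident carrier removed:
#' \deqn{P(k_T) = \frac{i}{4\pi k_z} \exp\{2\pi i (k_z - k_m) z_D\}.}
#' The exact \eqn{k_z} enters the prefactor; rounding applies only to the
#' target voxel index.  Lateral samples whose shifted axial index falls
#' outside the grid are dropped with a warning.
#'
#' @param grid a \code{\link{frequency_grid}}.
#' @param lambda wavelength (um).
#' @param n_m medium refractive index.
#' @param z_D defocus (sample-to-sensor) distance in um.
#' @return An object of class \code{ewald_shell}: parallel vectors \code{ix},
#'   \code{iy} (1-based lateral voxel indices), \code{kx}, \code{ky},
#'   \code{kz}, linear 3D target indices \code{target}, complex
#'   \code{prefactor}, plus the deduplicated target set \code{uidx} with the
#'   sample-to-unique map \code{gidx} and per-target multiplicities
#'   \code{counts} used for fill-weight accounting.
#' @export
build_shell <- function(grid, lambda, n_m, z_D) {
  stopifnot(inherits(grid, "frequency_grid"))
  km <- ewald_radius(lambda, n_m)
  dk <- grid$dk
  if (km <= max(dk[1:2]))
    stop("empty shell support: k_m = ", signif(km, 4),
         " does not exceed the lateral frequency spacing")
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  kx <- centered_coords(nx, dk[1])
  ky <- centered_coords(ny, dk[2])
  kxg <- matrix(kx, nx, ny)
  kyg <- matrix(ky, nx, ny, byrow = TRUE)
  kT <- sqrt(kxg^2 + kyg^2)
  keep <- kT < km
  ij <- which(keep, arr.ind = TRUE)
  kxv <- kxg[keep]; kyv <- kyg[keep]; kTv <- kT[keep]
  kzv <- sqrt(km^2 - kTv^2)
  # shifted axial coordinate (always <= 0) -> nearest axial voxel
  izc <- as.integer(round((kzv - km) / dk[3]))          # centered offset
  iz <- izc + nz %/% 2L + 1L                            # 1-based index
  inside <- iz >= 1L & iz <= nz
  if (!all(inside)) {
    warning("Ewald cap truncated: ", sum(!inside),
            " lateral samples fall outside the axial frequency extent")
    ij <- ij[inside, , drop = FALSE]
    kxv <- kxv[inside]; kyv <- kyv[inside]; kTv <- kTv[inside]
    kzv <- kzv[inside]; iz <- iz[inside]
  }
  target <- ij[, 1] + (ij[, 2] - 1L) * nx + (iz - 1L) * nx * ny
  pref <- (1i / (4 * pi * kzv)) * exp(2i * pi * (kzv - km) * z_D)
  u <- sort(unique(target))
  g <- match(target, u)
  structure(list(
    lambda = lambda, n_m = n_m, k_m = km, z_D = z_D,
    grid = grid,
    ix = ij[, 1], iy = ij[, 2],
    kx = kxv, ky = kyv, kT = kTv, kz = kzv,
    target = target, prefactor = pref,
    uidx = u, gidx = g, counts = tabulate(g, length(u))
  ), class = "ewald_shell")
}

#' @export
print.ewald_shell <- function(x, ...) {
  cat(sprintf(
    "Ewald shell: lambda = %.4g um, n_m = %.4g, k_m = %.4g cycles/um, z_D = %.4g um\n",
    x$lambda, x$n_m, x$k_m, x$z_D))
  cat(sprintf("  %d lateral samples -> %d spectrum voxels\n",
              length(x$target), length(x$uidx)))
  invisible(x)
}

#' Wavelength scan schedule
#'
#' Uniformly spaced, ascending, inclusive wavelength schedule emulating an
#' acousto-optic tunable filter sweep.
#'
#' @param lambda_min,lambda_max range endpoints in um (min < max).
#' @param count number of wavelengths (>= 2).
#' @return Numeric vector of length \code{count}.
#' @examples
#' scan_schedule(0.43, 1.20, 57)
#' @export
scan_schedule <- function(lambda_min, lambda_max, count) {
  if (!is.finite(lambda_min) || !is.finite(lambda_max) || lambda_min <= 0)
    stop("wavelengths must be positive and finite")
  if (lambda_min >= lambda_max)
    stop("'lambda_min' must be smaller than 'lambda_max'")
  count <- as.integer(count)
  if (is.na(count) || count < 2L) stop("'count' must be at least 2")
  seq(lambda_min, lambda_max, length.out = count)
}
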