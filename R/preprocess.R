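# Raw-stack conditioning: background normalization and autofocus estimation
# of the defocus distance.

# median of the frame's border ring (robust background estimate: lens-free
# frames have object-free margins)
#' @noRd
border_median <- function(I, width = 8L) {
  nx <- nrow(I); ny <- ncol(I)
  w <- min(width, max(1L, min(nx, ny) %/% 4L))
  ring <- c(I[seq_len(w), ], I[nx - seq_len(w) + 1L, ],
            I[, seq_len(w)], I[, ny - seq_len(w) + 1L])
  stats::median(ring)
}

#' Normalize an intensity frame to a unit background
#'
#' Divides the frame by the median of its 8-pixel border ring so that the
#' (object-free) background level becomes 1.  Idempotent.
#'
#' @param frame an \code{\link{intensity_frame}} with positive mean.
#' @return Normalized \code{\link{intensity_frame}}.
#' @export
normalize_intensity <- function(frame) {
  stopifnot(inherits(frame, "intensity_frame"))
  if (mean(frame$I) <= 0) stop("frame has non-positive mean; cannot normalize")
  bg <- border_median(frame$I)
  if (bg <= 0) stop("background estimate is non-positive; cannot normalize")
  frame$I <- frame$I / bg
  frame
}

# envelope angular-spectrum propagation of a 2D complex field by distance dz
# (um); carrier removed, kernel exp(2i*pi*(k_z - k_m)*dz), evanescent
# components decay
#' @noRd
angular_spectrum_env <- function(U, pitch, lambda, n_m, dz) {
  nx <- nrow(U); ny <- ncol(U)
  km <- n_m / lambda
  kx <- centered_coords(nx, 1 / (nx * pitch))
  ky <- centered_coords(ny, 1 / (ny * pitch))
  kT2 <- outer(kx^2, ky^2, `+`)
  arg <- km^2 - kT2
  kz <- sqrt(as.complex(arg))          # imaginary for evanescent waves
  H <- exp(2i * pi * (kz - km) * dz)
  H[Re(arg) < 0] <- H[Re(arg) < 0] * (abs(H[Re(arg) < 0]) <= 1)  # kill growth
  ift_nd(ft_nd(U, c(pitch, pitch)) * H, c(pitch, pitch))
}

# Tamura coefficient (sd/mean) of the gradient magnitude of |A|: an
# edge-sparsity sharpness score, invariant to global intensity scaling
#' @noRd
tamura_of_gradient <- function(A) {
  a <- abs(A)
  gx <- a[c(2:nrow(a), nrow(a)), ] - a
  gy <- a[, c(2:ncol(a), ncol(a))] - a
  g <- sqrt(gx^2 + gy^2)
  m <- mean(g)
  if (m == 0) return(0)
  stats::sd(g) / m
}

#' Autofocus: estimate the defocus distance
#'
#' Back-propagates the contrast hologram \eqn{\sqrt{I/I_{bg}} - 1} (the
#' amplitude deviation from the unit background, with \eqn{I_{bg}} the
#' border-ring median) by the angular spectrum to each candidate distance
#' and scores the result by the Tamura coefficient of the gradient magnitude
#' of the field modulus.  The scattered field refocuses into its sharpest,
#' sparsest form at the acquisition distance, so the score is maximized at
#' focus; the internal background division makes the estimate invariant to
#' global intensity scaling.  Ties break toward smaller z.
#'
#' @param frame an \code{\link{intensity_frame}}.
#' @param lambda wavelength in um (defaults to the frame's).
#' @param n_m medium refractive index.
#' @param z_range numeric vector (z_lo, z_hi, step) in um.
#' @return List with \code{z_D} (the estimate), \code{z} (candidates) and
#'   \code{score} (criterion values).
#' @export
autofocus <- function(frame, lambda = frame$lambda, n_m, z_range) {
  stopifnot(inherits(frame, "intensity_frame"))
  if (length(z_range) != 3L || z_range[1] >= z_range[2] || z_range[3] <= 0)
    stop("'z_range' must be (z_lo, z_hi, step) with z_lo < z_hi, step > 0")
  if (stats::sd(frame$I) < 1e-12 * mean(frame$I))
    stop("no focus structure: frame is (nearly) constant")
  bg <- border_median(frame$I)
  if (bg <= 0) stop("background estimate is non-positive; cannot focus")
  zs <- seq(z_range[1], z_range[2], by = z_range[3])
  A0 <- sqrt(frame$I / bg) - 1
  score <- vapply(zs, function(z) {
    A <- angular_spectrum_env(A0 + 0i, frame$pitch, lambda, n_m, -z)
    tamura_of_gradient(A)
  }, 0)
  pick <- which.max(score)
  list(z_D = zs[pick], z = zs, score = score)
}
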