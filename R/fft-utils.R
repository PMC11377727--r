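# Centered discrete Fourier transforms.
#
# All spectra in this package live on "centered" grids: the zero-frequency
# voxel of an axis of length N sits at 0-based index N %/% 2, i.e. the
# coordinate of index i is (i - N %/% 2) * dk.  Real-space arrays use the
# same centering ((i - N %/% 2) * dx), so that the transform pair below
# approximates the continuous Fourier integral with kernel exp(-2i*pi*k*r)
# (forward) on unshifted coordinates.  Reduced frequencies (cycles/um) are
# used everywhere; there is no 2*pi in the exponent bookkeeping.

#' @noRd
shift_perm <- function(n, shift) {
  ((seq_len(n) - 1L - shift) %% n) + 1L
}

#' Move the centered origin to index 0 (pre-FFT shift)
#' @noRd
ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) shift_perm(n, -(n %/% 2L)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Move index 0 to the centered origin (post-FFT shift)
#' @noRd
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) shift_perm(n, n %/% 2L))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Forward transform of a centered real-space array, scaled by the voxel
# volume so the result approximates the continuous transform.
#' @noRd
ft_nd <- function(x, pitch) {
  fftshift(fft(ifftshift(x))) * prod(pitch)
}

# Inverse of ft_nd on a centered spectrum.
#' @noRd
ift_nd <- function(X, pitch) {
  d <- dim(X)
  if (is.null(d)) d <- length(X)
  fftshift(fft(ifftshift(X), inverse = TRUE)) / (prod(d) * prod(pitch))
}

# Centered frequency (or space) coordinates of an axis.
#' @noRd
centered_coords <- function(n, step) {
  ((seq_len(n) - 1L) - n %/% 2L) * step
}
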