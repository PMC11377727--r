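# The iterative wavelength-scanning inverse solver: spectrum initialization,
# per-wavelength sub-spectrum extraction, pixel-super-resolved intensity
# constraint, Ewald-shell remapping, inter-wavelength spectrum transition,
# and the outer loop tying them together.

#' Scattering-potential spectrum container
#'
#' The object the solver iteratively fills: a complex 3D spectrum on a
#' centered frequency grid, a non-negative fill-weight mask counting
#' measured insertions per voxel (0 = never touched by any shell), and the
#' reference wavelength whose \eqn{\lambda^{-2}} scaling the stored values
#' currently carry.
#'
#' @param vhat complex 3D array (centered frequency layout).
#' @param grid the \code{\link{frequency_grid}}.
#' @param lambda_ref reference wavelength in um.
#' @param weight fill-weight array (defaults to all-zero).
#' @return Object of class \code{potential_spectrum}.
#' @export
potential_spectrum <- function(vhat, grid, lambda_ref, weight = NULL) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (!identical(dim(vhat), as.integer(grid$shape)))
    stop("spectrum shape does not match the grid")
  if (is.null(weight)) weight <- array(0, grid$shape)
  structure(list(vhat = vhat, grid = grid, lambda_ref = lambda_ref,
                 weight = weight),
            class = "potential_spectrum")
}

#' @export
print.potential_spectrum <- function(x, ...) {
  cat(sprintf(
    "Potential spectrum: %s voxels, lambda_ref %.4g um, %.3g%% measured\n",
    paste(x$grid$shape, collapse = " x "), x$lambda_ref,
    100 * mean(x$weight > 0)))
  invisible(x)
}

#' Initialize the potential spectrum
#'
#' The sample space is filled with the medium index, i.e. zero contrast, so
#' the initial spectrum is identically zero and nothing is marked measured.
#'
#' @param grid a \code{\link{frequency_grid}}.
#' @param n_m medium refractive index (kept for the record; the initial
#'   contrast is zero regardless).
#' @param lambda_ref reference wavelength tag in um.
#' @return A \code{\link{potential_spectrum}}.
#' @export
init_spectrum <- function(grid, n_m, lambda_ref) {
  potential_spectrum(array(0i, grid$shape), grid, lambda_ref)
}

#' Pixel-super-resolved intensity constraint
#'
#' Replaces the modeled amplitude with the measured one under the
#' pixel-binning model.  With \eqn{U = \exp(U_{s1})} and
#' \eqn{I_{hr} = |U|^2}, the measured sensor-pitch frame constrains each
#' s x s block multiplicatively,
#' \deqn{I_{change} = I_{hr} \cdot \mathrm{rep}\{ I_{meas} / (\mathrm{bin}(I_{hr}) + \epsilon) \},}
#' preserving intra-block high-frequency structure while matching block
#' means, and the relaxed update is
#' \deqn{\bar U_{s1} = \ln\{\alpha \sqrt{I_{change}}\, e^{i \arg U} + (1-\alpha) U\}.}
#' The logarithm takes the branch closest to the current iterate: the
#' \eqn{2\pi} offset minimizing \eqn{|\bar U_{s1} - U_{s1}|} is added to the
#' principal value, preventing wrap artifacts for optically thicker samples.
#'
#' @param U_s1 current Rytov exponent (\code{\link{complex_field}}, high-res).
#' @param I_meas measured \code{\link{intensity_frame}} at the sensor pitch.
#' @param s integer upsampling factor relating the two pitches.
#' @param alpha relaxation factor in [0, 1]; 0 leaves the field unchanged.
#' @return Updated \code{\link{complex_field}}.
#' @export
intensity_constraint <- function(U_s1, I_meas, s, alpha) {
  stopifnot(inherits(U_s1, "complex_field"), inherits(I_meas, "intensity_frame"))
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  s <- as.integer(s)
  if (!identical(dim(U_s1$field), as.integer(dim(I_meas$I) * s)))
    stop("field and measured frame shapes are not related by s")
  if (alpha == 0) return(U_s1)
  U <- exp(U_s1$field)
  I_hr <- Re(U * Conj(U))
  if (s == 1L) {
    ratio <- I_meas$I / (I_hr + 1e-9 * mean(I_meas$I))
  } else {
    ratio <- block_replicate(
      I_meas$I / (block_mean(I_hr, s) + 1e-9 * mean(I_meas$I)), s)
  }
  I_change <- I_hr * ratio
  mix <- alpha * sqrt(I_change) * exp(1i * Arg(U)) + (1 - alpha) * U
  L <- log(mix)
  k <- round((Im(U_s1$field) - Im(L)) / (2 * pi))
  complex_field(L + 2i * pi * k, U_s1$pitch, U_s1$z, U_s1$lambda)
}

#' Remap an updated field onto the Ewald shell
#'
#' Forward 2D transform of the updated Rytov exponent; each shell sample is
#' divided by its diffraction prefactor and written back to its shifted 3D
#' spectrum voxel.  Values are replaced (not blended) on measured voxels;
#' several lateral samples rounding to one voxel are averaged.  The
#' fill-weight mask is incremented by the insertion multiplicity; voxels
#' outside the shell are untouched.
#'
#' @param U_s1 updated \code{\link{complex_field}} (high-resolution pitch).
#' @param shell the \code{\link{build_shell}} used for extraction.
#' @param spec the \code{\link{potential_spectrum}} to update.
#' @return Updated \code{\link{potential_spectrum}}.
#' @export
remap_to_shell <- function(U_s1, shell, spec) {
  stopifnot(inherits(U_s1, "complex_field"), inherits(shell, "ewald_shell"),
            inherits(spec, "potential_spectrum"))
  if (!identical(spec$grid$shape, shell$grid$shape))
    stop("shell and spectrum were built on different grids")
  Uhat <- ft_nd(U_s1$field, spec$grid$pitch[1:2])
  vals <- Uhat[cbind(shell$ix, shell$iy)] / shell$prefactor
  sums <- rowsum(cbind(Re(vals), Im(vals)), shell$gidx, reorder = TRUE)
  avg <- complex(real = sums[, 1], imaginary = sums[, 2]) / shell$counts
  spec$vhat[shell$uidx] <- avg
  spec$weight[shell$uidx] <- spec$weight[shell$uidx] + shell$counts
  spec
}

#' Inter-wavelength spectrum transition
#'
#' Converts a spectrum expressed at wavelength \code{lambda_i} into the
#' initial value for \code{lambda_next} by scaling every voxel by
#' \eqn{(\lambda_i/\lambda_{next})^2}; the underlying physical contrast
#' spectrum (potential divided by \eqn{\lambda^{-2}}) is preserved exactly.
#'
#' @param spec a \code{\link{potential_spectrum}}.
#' @param lambda_i,lambda_next wavelengths in um (both positive).
#' @return Spectrum rescaled and retagged to \code{lambda_next}.
#' @export
wavelength_transition <- function(spec, lambda_i, lambda_next) {
  stopifnot(inherits(spec, "potential_spectrum"))
  if (lambda_i <= 0 || lambda_next <= 0) stop("wavelengths must be positive")
  spec$vhat <- (lambda_i / lambda_next)^2 * spec$vhat
  spec$lambda_ref <- lambda_next
  spec
}

# contrast volume (n^2 - n_m^2) from a spectrum; real and imaginary parts
#' @noRd
spectrum_to_contrast <- function(spec) {
  V <- ift_nd(spec$vhat, spec$grid$pitch)
  (spec$lambda_ref / (2 * pi))^2 * V
}

# inverse of spectrum_to_contrast on a (possibly complex) contrast array
#' @noRd
contrast_to_spectrum <- function(f, spec) {
  spec$vhat <- ft_nd((2 * pi / spec$lambda_ref)^2 * f, spec$grid$pitch)
  spec
}

#' Reconstruct a 3D refractive-index volume from a wavelength scan
#'
#' The full inverse solver.  Starting from a zero-contrast spectrum, each
#' outer pass loops over the wavelength schedule performing: sub-spectrum
#' extraction on the wavelength's Ewald shell
#' (\code{\link{first_order_field}}), the pixel-super-resolved intensity
#' constraint (\code{\link{intensity_constraint}}), shell remapping
#' (\code{\link{remap_to_shell}}), and the spectrum transition to the next
#' wavelength (\code{\link{wavelength_transition}}).  After the final pass
#' the hybrid missing-cone regularization (\code{\link{hybrid_fill}}) is
#' applied, and the recovered potential is converted to a refractive index
#' via \eqn{n(r) = \sqrt{n_m^2 + V(r) (\lambda_{ref}/2\pi)^2}} (real part;
#' negative radicands are clipped to the medium index).
#'
#' Frames are matched to the schedule by their recorded wavelength, so the
#' input order of \code{frames} is irrelevant.  Per-wavelength residuals
#' \eqn{\|\sqrt{I_{model}} - \sqrt{I_{meas}}\|_2 / \|\sqrt{I_{meas}}\|_2}
#' (at the sensor pitch, before each update) are recorded per pass; passes
#' stop early when the median residual improves by less than 1e-3
#' relatively.
#'
#' @param frames list of normalized \code{\link{intensity_frame}}s, one per
#'   scheduled wavelength, sharing one defocus distance.
#' @param cfg a \code{\link{scan_config}}; \code{cfg$nz} and \code{cfg$dz}
#'   fix the axial reconstruction grid, the lateral grid is the sensor frame
#'   times \code{cfg$upsample}.
#' @param regularize apply the hybrid missing-cone completion (default TRUE;
#'   FALSE is useful for before/after comparisons).
#' @return Object of class \code{wsfpdt}: the recovered
#'   \code{\link{ri_volume}} (\code{$volume}), the final
#'   \code{\link{potential_spectrum}} (\code{$spectrum}), the residual
#'   matrix (\code{$residuals}, passes x wavelengths), the imaginary-part
#'   diagnostic \code{$im_ratio}, and the configuration.
#' @seealso \code{\link{simulate_scan}} for generating synthetic input,
#'   \code{\link{cell_morphology}} for downstream analysis.
#' @export
wsfpdt <- function(frames, cfg, regularize = TRUE) {
  stopifnot(inherits(cfg, "scan_config"))
  if (length(frames) != length(cfg$wavelengths))
    stop("need exactly one frame per scheduled wavelength (",
         length(cfg$wavelengths), "), got ", length(frames))
  lam_f <- vapply(frames, function(f) f$lambda, 0)
  ord <- match(round(cfg$wavelengths, 9), round(lam_f, 9))
  if (any(is.na(ord)))
    stop("frame wavelengths do not match the configured schedule")
  frames <- frames[ord]
  sdim <- dim(frames[[1]]$I)
  s <- cfg$upsample
  grid <- frequency_grid(c(sdim * s, cfg$nz),
                         c(rep(cfg$sensor_pitch / s, 2), cfg$dz))
  shells <- lapply(cfg$wavelengths, function(l)
    build_shell(grid, l, cfg$n_m, cfg$z_D))
  nlam <- length(cfg$wavelengths)
  spec <- init_spectrum(grid, cfg$n_m, cfg$wavelengths[1])
  resid <- matrix(NA_real_, cfg$passes, nlam)
  med_prev <- Inf
  npass <- 0L
  for (p in seq_len(cfg$passes)) {
    for (i in seq_len(nlam)) {
      Us1 <- first_order_field(spec, shells[[i]])
      I_model <- bin_pixels(rytov_intensity(Us1), s)
      num <- sqrt(sum((sqrt(I_model$I) - sqrt(frames[[i]]$I))^2))
      den <- sqrt(sum(frames[[i]]$I))
      resid[p, i] <- num / den
      if (!is.finite(resid[p, i]))
        stop("solver diverged: non-finite residual at pass ", p,
             ", wavelength ", signif(cfg$wavelengths[i], 4), " um")
      Ub <- intensity_constraint(Us1, frames[[i]], s, cfg$alpha)
      spec <- remap_to_shell(Ub, shells[[i]], spec)
      lam_next <- if (i < nlam) cfg$wavelengths[i + 1] else cfg$wavelengths[1]
      spec <- wavelength_transition(spec, cfg$wavelengths[i], lam_next)
    }
    npass <- p
    med <- stats::median(resid[p, ])
    if (is.finite(med_prev) && (med_prev - med) < 1e-3 * med_prev) break
    med_prev <- med
  }
  if (regularize && cfg$reg$passes > 0L)
    spec <- hybrid_fill(spec, passes = cfg$reg$passes,
                        tv_weight = cfg$reg$tv_weight,
                        tv_iters = cfg$reg$tv_iters,
                        nonneg = cfg$reg$nonneg)
  f <- spectrum_to_contrast(spec)
  im_ratio <- if (max(abs(Re(f))) > 0) max(abs(Im(f))) / max(abs(Re(f))) else 0
  rad <- cfg$n_m^2 + Re(f)
  n <- sqrt(pmax(rad, cfg$n_m^2 * 0))   # clip negative radicand
  n[rad < 0] <- cfg$n_m
  n <- pmax(n, 1)
  vol <- ri_volume(array(n, grid$shape), grid$pitch, cfg$n_m)
  structure(list(volume = vol, spectrum = spec,
                 residuals = resid[seq_len(npass), , drop = FALSE],
                 passes_run = npass, im_ratio = im_ratio,
                 regularized = regularize && cfg$reg$passes > 0L,
                 config = cfg),
            class = "wsfpdt")
}

#' @export
print.wsfpdt <- function(x, ...) {
  cat("Wavelength-scanning diffraction tomography reconstruction\n")
  cat(sprintf("  grid: %s voxels (%s um pitch)\n",
              paste(dim(x$volume$n), collapse = " x "),
              paste(signif(x$volume$pitch, 4), collapse = "/")))
  cat(sprintf("  %d wavelengths, %d pass(es), final median residual %.4g\n",
              length(x$config$wavelengths), x$passes_run,
              stats::median(x$residuals[x$passes_run, ])))
  cat(sprintf("  regularized: %s; Im/Re diagnostic: %.3g\n",
              x$regularized, x$im_ratio))
  invisible(x)
}

#' @export
summary.wsfpdt <- function(object, ...) {
  ctr <- Re(object$volume$n) - object$config$n_m
  out <- list(
    grid = dim(object$volume$n),
    pitch = object$volume$pitch,
    passes_run = object$passes_run,
    residual_median_by_pass = apply(object$residuals, 1, stats::median),
    contrast_range = range(ctr),
    im_ratio = object$im_ratio,
    regularized = object$regularized)
  class(out) <- "summary.wsfpdt"
  out
}

#' @export
print.summary.wsfpdt <- function(x, ...) {
  cat("wsFPDT reconstruction summary\n")
  cat("  grid:", paste(x$grid, collapse = " x "),
      "| pitch (um):", paste(signif(x$pitch, 4), collapse = "/"), "\n")
  cat("  median residual by pass:",
      paste(signif(x$residual_median_by_pass, 4), collapse = ", "), "\n")
  cat(sprintf("  recovered contrast range: [%.4g, %.4g]\n",
              x$contrast_range[1], x$contrast_range[2]))
  cat(sprintf("  Im/Re diagnostic: %.3g | regularized: %s\n",
              x$im_ratio, x$regularized))
  invisible(x)
}

#' @export
residuals.wsfpdt <- function(object, ...) object$residuals

#' @export
fitted.wsfpdt <- function(object, ...) object$volume

#' Plot a reconstruction
#'
#' Left: central lateral slice of the recovered refractive index; right:
#' per-pass residual trend (median with per-wavelength spread).
#'
#' @param x a \code{wsfpdt} object.
#' @param z_index axial slice to display (default: central slice).
#' @param ... unused.
#' @export
plot.wsfpdt <- function(x, z_index = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  d <- dim(x$volume$n)
  if (is.null(z_index)) z_index <- d[3] %/% 2L + 1L
  sl <- Re(x$volume$n[, , z_index])
  graphics::image(seq_len(d[1]) * x$volume$pitch[1],
                  seq_len(d[2]) * x$volume$pitch[2], sl,
                  col = grDevices::gray.colors(128), useRaster = TRUE,
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("RI slice z = %d", z_index))
  med <- apply(x$residuals, 1, stats::median)
  graphics::matplot(seq_len(nrow(x$residuals)), x$residuals, type = "p",
                    pch = 1, col = "grey70", xlab = "pass",
                    ylab = "relative amplitude residual", main = "convergence")
  graphics::lines(seq_along(med), med, lwd = 2)
  invisible(x)
}

#' Simulate frames from a fitted reconstruction
#'
#' Runs the forward model on the recovered volume under the fitted
#' configuration, producing synthetic sensor-pitch frames; useful for
#' posterior predictive checks against the measured stack.
#'
#' @param object a \code{wsfpdt} object.
#' @param nsim number of replicate stacks (noise draws; 1 if noiseless).
#' @param seed optional seed overriding the configuration seed.
#' @param ... unused.
#' @return A list of \code{nsim} frame lists.
#' @export
simulate.wsfpdt <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    if (isTRUE(cfg$noise$enabled)) cfg$seed <- cfg$seed + r - 1L
    out[[r]] <- simulate_scan(object$volume, cfg)$frames
  }
  out
}
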