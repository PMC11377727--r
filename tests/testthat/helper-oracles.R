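# Test-suite-only oracles and shared fixtures.  The oracles deliberately
# avoid the package's internal FFT helpers: they implement the centered
# transforms from scratch (even-sized grids only, where the half-length
# circular shift is its own inverse).

rms <- function(x) sqrt(mean(abs(x)^2))

# half-length circular shift of a matrix (its own inverse for even dims)
half_shift <- function(x) {
  n <- nrow(x); m <- ncol(x)
  stopifnot(n %% 2 == 0, m %% 2 == 0)
  x[c((n / 2 + 1):n, 1:(n / 2)), c((m / 2 + 1):m, 1:(m / 2))]
}

# independent angular-spectrum propagation of a 2D complex envelope field
# over distance dist (um); carrier removed, evanescent components dropped
oracle_propagate <- function(U0, pitch, lambda, n_m, dist) {
  n <- nrow(U0); m <- ncol(U0)
  km <- n_m / lambda
  kx <- ((0:(n - 1)) - n %/% 2) / (n * pitch)
  ky <- ((0:(m - 1)) - m %/% 2) / (m * pitch)
  kT2 <- outer(kx^2, ky^2, `+`)
  kz <- sqrt(as.complex(km^2 - kT2))
  H <- exp(2i * pi * (kz - km) * dist)
  H[Re(km^2 - kT2) < 0] <- 0
  Uhat <- half_shift(stats::fft(half_shift(U0)))
  half_shift(stats::fft(half_shift(Uhat * H), inverse = TRUE)) / (n * m)
}

# brute-force sample-by-sample first-order scattered field: one explicit
# loop over the shell samples, then a from-scratch centered 2D inverse
# transform matching the continuous-integral normalization
oracle_first_order <- function(vhat, shell, pitch2) {
  nx <- shell$grid$shape[1]; ny <- shell$grid$shape[2]
  Uhat <- matrix(0i, nx, ny)
  for (m in seq_along(shell$target)) {
    Uhat[shell$ix[m], shell$iy[m]] <-
      shell$prefactor[m] * vhat[shell$target[m]]
  }
  half_shift(stats::fft(half_shift(Uhat), inverse = TRUE)) /
    (nx * ny * prod(pitch2))
}

# weighted second-moment axial elongation of a non-negative contrast array:
# sqrt of axial variance over mean lateral variance
moment_elongation <- function(w) {
  idx <- which(w > 0, arr.ind = TRUE)
  ww <- w[w > 0]
  mu <- colSums(idx * ww) / sum(ww)
  v <- colSums(sweep(idx, 2, mu)^2 * ww) / sum(ww)
  sqrt(v[3] / mean(v[1:2]))
}

# local maxima of a profile above frac of its maximum
peak_positions <- function(profile, frac = 0.3) {
  lm <- which(diff(sign(diff(profile))) == -2) + 1
  lm[profile[lm] > frac * max(profile)]
}

# --- shared expensive fixtures (computed once per test run) ----------------

# noiseless 5 um bead at the acceptance scale: 96^3 grid, 19 wavelengths
# spanning 0.43-1.2 um, s = 2, 3 outer passes, solved with and without the
# hybrid regularization
bead_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scan_config(
        wavelengths = scan_schedule(0.43, 1.2, 19), n_m = 1.58,
        z_D = 414, sensor_pitch = 0.5, upsample = 2L,
        alpha = 0.5, passes = 3L, nz = 96L, dz = 0.25,
        reg = list(passes = 10L, tv_iters = 10L), seed = 7L)
      vol <- bead_phantom(
        c(96L, 96L, 96L), c(0.25, 0.25, 0.25),
        list(list(center = c(0, 0, 0), diameter = 5, ri = 1.594)),
        n_m = 1.58)
      suppressWarnings({
        sim <- simulate_scan(vol, cfg)
        fit_nr <- wsfpdt(sim$frames, cfg, regularize = FALSE)
        fit_rg <- wsfpdt(sim$frames, cfg, regularize = TRUE)
      })
      cache <<- list(cfg = cfg, vol = vol, sim = sim,
                     nr = fit_nr, rg = fit_rg)
    }
    cache
  }
})

# pixel-super-resolution bar pair: two bars 0.96 um wide with centers
# 1.2 sensor pitches apart, simulated on the s = 4 grid and reconstructed
# at s = 1 and s = 4 from the same sensor-pitch frames
psr_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p_sens <- 1.6; s <- 4L
      bar_w <- 0.6 * p_sens
      sep <- 1.2 * p_sens
      nx_hr <- 128L; nz <- 32L; dxy <- p_sens / s
      n_m <- 1.33
      cc <- (seq_len(nx_hr) - 1 - nx_hr %/% 2) * dxy
      xg <- matrix(cc, nx_hr, nx_hr); yg <- t(xg)
      inbar <- (abs(xg - sep / 2) < bar_w / 2 |
                  abs(xg + sep / 2) < bar_w / 2) & abs(yg) < 6
      n <- array(n_m, c(nx_hr, nx_hr, nz))
      n[, , nz %/% 2 + 1][inbar] <- n_m + 0.02
      vol <- ri_volume(n, c(dxy, dxy, dxy), n_m)
      lams <- scan_schedule(0.43, 1.2, 9)
      mkcfg <- function(s_use) scan_config(
        wavelengths = lams, n_m = n_m, z_D = 100, sensor_pitch = p_sens,
        upsample = s_use, passes = 3L, nz = nz, dz = dxy, seed = 3L)
      suppressWarnings({
        sim <- simulate_scan(vol, mkcfg(s))
        fits <- lapply(c(1L, 4L), function(s_use)
          wsfpdt(sim$frames, mkcfg(s_use), regularize = FALSE))
      })
      cache <<- list(p_sens = p_sens, sep = sep, nz = nz,
                     s1 = fits[[1]], s4 = fits[[2]])
    }
    cache
  }
})

# line profile across the PSR bar pair: positive contrast averaged over the
# bar length at the bar plane, restricted to a window around the pair
psr_profile <- function(fit, p_sens, sep, nz) {
  s_use <- fit$config$upsample
  ctr <- pmax(Re(fit$volume$n) - fit$config$n_m, 0)
  nxr <- dim(ctr)[1]
  xr <- (seq_len(nxr) - 1 - nxr %/% 2) * (p_sens / s_use)
  ymid <- which(abs(xr) < 4)
  prof <- rowMeans(ctr[, ymid, nz %/% 2 + 1])
  win <- which(abs(xr) < 2 * sep)
  list(x = xr[win], p = prof[win])
}
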