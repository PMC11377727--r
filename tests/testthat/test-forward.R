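test_that("scattering_potential follows Wolf's object function", {
  v0 <- ri_volume(array(1.33, c(4, 4, 4)), c(1, 1, 1), 1.33)
  expect_true(all(scattering_potential(v0, 0.5) == 0))
  v1 <- ri_volume(array(1.594, c(2, 2, 2)), c(1, 1, 1), 1.58)
  V <- scattering_potential(v1, 0.483)
  expect_equal(Re(V[1]), (2 * pi / 0.483)^2 * (1.594^2 - 1.58^2))
  expect_equal(round(Re(V[1]), 4), 7.5197)
  # doubling lambda quarters the potential
  expect_equal(scattering_potential(v1, 0.966), V / 4)
})

test_that("first_order_field is linear and vanishes on a zero spectrum", {
  g <- frequency_grid(c(16, 16, 16), c(0.5, 0.5, 0.5))
  sh <- build_shell(g, 0.5, 1.33, 100)
  z <- potential_spectrum(array(0i, c(16, 16, 16)), g, 0.5)
  expect_true(all(first_order_field(z, sh)$field == 0))
  set.seed(1)
  va <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)), rep(16, 3))
  vb <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)), rep(16, 3))
  fa <- first_order_field(potential_spectrum(va, g, 0.5), sh)$field
  fb <- first_order_field(potential_spectrum(vb, g, 0.5), sh)$field
  fab <- first_order_field(potential_spectrum(2 * va + vb, g, 0.5), sh)$field
  expect_equal(fab, 2 * fa + fb, tolerance = 1e-12)
})

test_that("a DC impulse produces the flat envelope i/(4 pi k_m)", {
  g <- frequency_grid(c(16, 16, 16), c(0.5, 0.5, 0.5))
  sh <- build_shell(g, 0.5, 1.33, 100)
  vh <- array(0i, c(16, 16, 16))
  vh[sh$target[which(sh$kT == 0)]] <- 1
  U <- first_order_field(potential_spectrum(vh, g, 0.5), sh)
  # envelope convention: exp(2 pi i (k_z - k_m) z_D) = 1 at DC, so the
  # lateral spectrum holds i/(4 pi k_m) at k_T = 0 and zero elsewhere;
  # transform the field back with the from-scratch oracle FFT to check
  Uhat <- half_shift(stats::fft(half_shift(U$field))) * prod(g$pitch[1:2])
  expect_equal(Uhat[9, 9], 1i / (4 * pi * sh$k_m), tolerance = 1e-12)
  expect_lt(max(abs(Uhat[-(9 + 8 * 16)])), 1e-12)
})

test_that("first_order_field equals the brute-force Eq.-by-sample oracle", {
  g <- frequency_grid(c(16, 16, 16), c(0.5, 0.5, 0.5))
  sh <- build_shell(g, 0.5, 1.33, 100)
  set.seed(42)
  vh <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)), rep(16, 3))
  U <- first_order_field(potential_spectrum(vh, g, 0.5), sh)$field
  U_bf <- oracle_first_order(vh, sh, g$pitch[1:2])
  expect_lt(max(abs(U - U_bf)) / max(abs(U_bf)), 1e-10)
})

test_that("rytov_intensity exposes only the real part of the exponent", {
  z <- complex_field(matrix(0i, 4, 4), 0.5, 100, 0.5)
  expect_true(all(rytov_intensity(z)$I == 1))
  ph <- complex_field(matrix(0.3i, 4, 4), 0.5, 100, 0.5)
  expect_equal(rytov_intensity(ph)$I, matrix(1, 4, 4))   # phase invisibility
  re <- complex_field(matrix(0.1 + 0i, 4, 4), 0.5, 100, 0.5)
  expect_equal(rytov_intensity(re)$I, matrix(exp(0.2), 4, 4))
})

test_that("bin_pixels is the block mean with a unit-preserving contract", {
  f <- intensity_frame(matrix(1, 4, 4), 0.5, 100, 0.25)
  expect_equal(bin_pixels(f, 2)$I, matrix(1, 2, 2))
  expect_equal(bin_pixels(f, 2)$pitch, 0.5)
  g <- intensity_frame(matrix(c(0, 4, 2, 6), 2, 2), 0.5, 100, 0.25)
  expect_equal(bin_pixels(g, 2)$I, matrix(3, 1, 1))
  expect_identical(bin_pixels(f, 1), f)
  expect_error(bin_pixels(f, 3), "divisible")
  # bin -> replicate -> bin is idempotent
  set.seed(2)
  h <- intensity_frame(matrix(runif(64), 8, 8), 0.5, 100, 0.25)
  b1 <- bin_pixels(h, 2)$I
  up <- intensity_frame(b1[rep(1:4, each = 2), rep(1:4, each = 2)],
                        0.5, 100, 0.25)
  expect_equal(bin_pixels(up, 2)$I, b1, tolerance = 1e-14)
})

test_that("simulate_scan on an empty sample yields unit frames", {
  cfg <- scan_config(wavelengths = scan_schedule(0.5, 1.0, 3), n_m = 1.33,
                     z_D = 50, sensor_pitch = 1.0, upsample = 2L,
                     nz = 8L, dz = 0.5)
  vol <- ri_volume(array(1.33, c(32, 32, 8)), c(0.5, 0.5, 0.5), 1.33)
  sim <- simulate_scan(vol, cfg)
  for (f in sim$frames) expect_equal(f$I, matrix(1, 16, 16), tolerance = 1e-12)
})

test_that("simulate_scan shows wavelength diversity and seeded noise determinism", {
  cfg <- scan_config(wavelengths = scan_schedule(0.43, 1.2, 5), n_m = 1.58,
                     z_D = 100, sensor_pitch = 1.0, upsample = 2L,
                     nz = 16L, dz = 0.5, seed = 11L)
  vol <- bead_phantom(c(64, 64, 16), c(0.5, 0.5, 0.5),
                      list(list(center = c(0, 0, 0), diameter = 5,
                                ri = 1.594)), n_m = 1.58)
  suppressWarnings(sim <- simulate_scan(vol, cfg))
  d <- vapply(2:5, function(i) rms(sim$frames[[i]]$I - sim$frames[[1]]$I), 0)
  expect_true(all(d > 0))
  cfgN <- cfg; cfgN$noise$enabled <- TRUE
  suppressWarnings({
    n1 <- simulate_scan(vol, cfgN)
    n2 <- simulate_scan(vol, cfgN)
  })
  for (i in 1:5) expect_identical(n1$frames[[i]]$I, n2$frames[[i]]$I)
  expect_false(identical(n1$frames[[1]]$I, sim$frames[[1]]$I))
})

test_that("simulate_scan validates the volume-to-sensor geometry", {
  cfg <- scan_config(wavelengths = scan_schedule(0.5, 1.0, 2), n_m = 1.33,
                     z_D = 50, sensor_pitch = 1.0, upsample = 2L,
                     nz = 8L, dz = 0.5)
  bad_pitch <- ri_volume(array(1.33, c(32, 32, 8)), c(0.4, 0.4, 0.5), 1.33)
  expect_error(simulate_scan(bad_pitch, cfg), "sensor pitch")
  odd <- ri_volume(array(1.33, c(31, 31, 8)), c(0.5, 0.5, 0.5), 1.33)
  expect_error(simulate_scan(odd, cfg), "divisible")
})

test_that("weak-object intensity matches an independent propagation oracle", {
  # thin low-contrast slab with a smooth lateral pattern; the projected-phase
  # oracle is only valid for band-limited patterns (the diffraction model
  # carries the high-NA obliquity factor a sharp edge would excite)
  nx <- 64; nz <- 32
  pitch <- c(0.3, 0.3, 0.3)
  n_m <- 1.33; lam <- 0.5; dn <- 0.004; z_D <- 400
  cc <- ((seq_len(nx) - 1) - nx %/% 2) * pitch[1]
  xg <- matrix(cc, nx, nx); yg <- t(xg)
  pat <- exp(-((xg + 2)^2 + yg^2) / (2 * 2^2)) +
    0.7 * exp(-((xg - 3)^2 + (yg - 2)^2) / (2 * 1.5^2))
  n <- array(n_m, c(nx, nx, nz))
  n[, , nz %/% 2 + 1] <- n_m + dn * pat
  vol <- ri_volume(n, pitch, n_m)
  spec <- potential_spectrum_of(vol, lam)
  g <- frequency_grid(c(nx, nx, nz), pitch)
  sh <- build_shell(g, lam, n_m, z_D)
  I_model <- rytov_intensity(first_order_field(spec, sh))$I
  phi <- 2 * pi / lam * dn * pitch[3] * pat
  I_oracle <- Mod(oracle_propagate(exp(1i * phi), pitch[1], lam, n_m, z_D))^2
  expect_lt(rms(I_model - I_oracle) / rms(I_oracle - 1), 0.02)
})
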