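test_that("fwhm handles exact and near-exact peak shapes", {
  tri <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)
  expect_equal(fwhm(tri, 1), 4.0)
  expect_equal(fwhm(tri, 0.5), 2.0)
  xs <- seq(-15, 15)
  gau <- exp(-xs^2 / (2 * 2^2))
  expect_lt(abs(fwhm(gau, 1) - 2 * 2 * sqrt(2 * log(2))), 0.05)
  expect_error(fwhm(seq(0, 1, 0.1), 1), "peak")
  expect_error(fwhm(c(1, 2), 1), "short")
})

test_that("throughput_numbers reproduces the headline platform figures", {
  tp <- throughput_numbers(3872, 2764, 1.67, 0.775, 5.43, 200)
  expect_equal(round(tp$fov_mm2, 2), 29.85)
  expect_equal(round(tp$nyquist_ratio, 2), 2.15)
  expect_equal(round(tp$voxel_um3, 2), 3.26)
  expect_equal(round(tp$volume_mm3, 2), 5.97)
  expect_equal(signif(tp$effective_voxels, 3), 1.83e9)
})

test_that("throughput_numbers unit case and linearity", {
  tp <- throughput_numbers(1000, 1000, 1.0, 1.0, 1.0, 1000)
  expect_equal(unlist(tp[c("fov_mm2", "nyquist_ratio", "voxel_um3",
                           "volume_mm3")]),
               c(fov_mm2 = 1, nyquist_ratio = 1, voxel_um3 = 1,
                 volume_mm3 = 1))
  expect_equal(tp$effective_voxels, 1e9)
  half <- throughput_numbers(1000, 1000, 1.0, 1.0, 1.0, 500)
  expect_equal(half$volume_mm3, tp$volume_mm3 / 2)
  expect_equal(half$effective_voxels, tp$effective_voxels / 2)
  expect_error(throughput_numbers(0, 1, 1, 1, 1, 1), "positive")
})

make_ball <- function(r, nside, n_m = 1.33, dn = 0.05) {
  cc <- ((seq_len(nside) - 1) - nside %/% 2)
  r2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  n <- array(n_m, rep(nside, 3))
  n[r2 < r^2] <- n_m + dn
  ri_volume(n, c(1, 1, 1), n_m)
}

test_that("cell_morphology measures a digital ball with the documented bias", {
  m <- cell_morphology(make_ball(10, 28), threshold = 0.02)
  expect_identical(m$summary$n_objects, 1L)
  ob <- m$objects
  expect_lt(abs(ob$volume_um3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.03)
  # face counting overestimates a sphere's area by ~1.5x, so the measured
  # sphericity of a well-resolved ball sits near 2/3, not near 1
  expect_gt(ob$sphericity, 0.60)
  expect_lt(ob$sphericity, 0.72)
  expect_identical(ob$stage, "I")
  # spreading area: the widest z slice of a ball is its equator
  expect_lt(abs(ob$spreading_area_um2 - pi * 100) / (pi * 100), 0.05)
})

test_that("a single voxel has the closed-form cube sphericity", {
  n <- array(1.33, c(5, 5, 5)); n[3, 3, 3] <- 1.4
  m <- cell_morphology(ri_volume(n, c(1, 1, 1), 1.33), threshold = 0.02)
  expect_equal(m$objects$volume_um3, 1)
  expect_equal(m$objects$surface_area_um2, 6)
  expect_equal(m$objects$sphericity, pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
})

test_that("disjoint objects are labeled separately with additive stats", {
  n <- array(1.33, c(40, 24, 24))
  cc1 <- ((seq_len(24) - 1) - 12)
  r2a <- outer(outer((((seq_len(40) - 1) - 10))^2, cc1^2, `+`), cc1^2, `+`)
  r2b <- outer(outer((((seq_len(40) - 1) - 30))^2, cc1^2, `+`), cc1^2, `+`)
  n[r2a < 6^2] <- 1.38
  n[r2b < 6^2] <- 1.38
  m <- cell_morphology(ri_volume(n, c(1, 1, 1), 1.33), threshold = 0.02)
  expect_identical(m$summary$n_objects, 2L)
  single <- cell_morphology(make_ball(6, 16), threshold = 0.02)
  expect_equal(sort(m$objects$volume_um3),
               rep(single$objects$volume_um3, 2))
  expect_equal(sort(m$objects$sphericity),
               rep(single$objects$sphericity, 2), tolerance = 1e-12)
})

test_that("cell_morphology recovers phantom annotation volumes within 5%", {
  cp <- cell_phantom(c(96, 96, 64), rep(0.5, 3), n_cells = 2,
                     stage_mix = c(1, 0, 0), n_m = 1.33, dn = 0.03,
                     radius = 5, seed = 4)
  m <- cell_morphology(cp, threshold = 0.015)
  expect_identical(m$summary$n_objects, 2L)
  got <- sort(m$objects$volume_um3)
  want <- sort(vapply(cp$annotation$cells, `[[`, 0, "volume_analytic"))
  expect_true(all(abs(got - want) / want < 0.05))
  expect_true(all(m$objects$stage == "I"))
})

test_that("the axial correction rescales the axial pitch", {
  m1 <- cell_morphology(make_ball(8, 24), threshold = 0.02)
  m2 <- cell_morphology(make_ball(8, 24), threshold = 0.02,
                        axial_correction = 2)
  expect_equal(m2$objects$volume_um3, m1$objects$volume_um3 / 2)
  expect_error(cell_morphology(make_ball(8, 24), threshold = 0), "> 0")
  expect_error(cell_morphology(make_ball(8, 24), threshold = 0.02,
                               axial_correction = -1), "> 0")
})

test_that("an empty mask yields an empty (not failing) report", {
  v <- ri_volume(array(1.33, c(8, 8, 8)), c(1, 1, 1), 1.33)
  m <- cell_morphology(v, threshold = 0.01)
  expect_identical(m$summary$n_objects, 0L)
  expect_identical(nrow(m$objects), 0L)
})

test_that("morphology reports print and serialize", {
  m <- cell_morphology(make_ball(6, 16), threshold = 0.02)
  expect_output(print(m), "object")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_morphology(m, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$volume_um3, m$objects$volume_um3)
  s <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(s$n_objects, 1L)
  expect_equal(s$stage_counts$I, 1L)
})
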