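## Render a noiseless total-A map of one vertical vessel on a voxel grid,
## directly from the circle-chord law (the quantity the projection of a
## cylinder produces), for calibration round-trip tests.
render_vessel_map <- function(s0 = 50, dbar = 4, nx = 41, ny = 20,
                              dx = 0.55, dy = 0.55, x0 = (nx - 1) / 2 * dx) {
  x <- (seq_len(nx) - 1) * dx
  chord <- ifelse(abs(x - x0) <= dbar / 2,
                  sqrt(pmax(dbar^2 - 4 * (x - x0)^2, 0)), 0)
  matrix(rep(s0 * dx * dy * chord, ny), nx, ny)
}

test_that("total_A_map sums per-artery maps voxelwise", {
  a <- array(0.4, c(2, 2, 1)); b <- array(0.6, c(2, 2, 1))
  expect_equal(total_A_map(list(a)), a)               # single artery: identity
  expect_equal(total_A_map(list(a, b)),
               array(1.0, c(2, 2, 1)))
  expect_equal(total_A_map(list(a * 0, b * 0)), array(0, c(2, 2, 1)))
  ## NA (unfitted in one artery) treated as zero contribution
  a[1, 1, 1] <- NA
  expect_equal(total_A_map(list(a, b))[1, 1, 1], 0.6)
  expect_error(total_A_map(list(a, array(1, c(3, 2, 1)))), "shape")
})

test_that("profile extraction interpolates bilinearly in physical mm", {
  m <- matrix(7, 30, 30)
  ln <- profile_line(anchor = c(8, 8), direction = c(1, 0),
                     half_length = 4, spacing = 0.5)
  smp <- extract_profile(m, ln, c(0.55, 0.55))
  expect_true(all(smp$value == 7))                    # constant map
  expect_equal(range(smp$d), c(-4, 4))
  ## a linear ramp is reproduced exactly by bilinear interpolation
  ramp <- outer(seq_len(30), rep(1, 30)) * 1.0
  smp2 <- extract_profile(ramp, ln, c(1, 1))
  expect_equal(smp2$value, 8 + smp2$d + 1, tolerance = 1e-12)
  ## leaving the image names the offending sample
  ln_out <- profile_line(c(1, 8), c(1, 0), half_length = 5, spacing = 0.5)
  expect_error(extract_profile(m, ln_out, c(0.55, 0.55)), "outside")
  expect_error(profile_line(c(1, 1), c(0, 0), 1, 0.5), "direction")
  expect_error(profile_line(c(1, 1), c(1, 0), 1, 0), "spacing")
})

test_that("circle-chord profile fit recovers (S0, diameter, center)", {
  d <- seq(-4.4, 4.4, by = 0.275)
  vd <- c(0.55, 0.55)
  a <- ifelse(abs(d) <= 2, 50 * 0.55 * 0.55 * sqrt(pmax(16 - 4 * d^2, 0)), 0)
  f <- fit_profile(data.frame(d = d, value = a), vd)
  expect_equal(f$s0, 50, tolerance = 1e-3)
  expect_equal(f$diameter, 4, tolerance = 1e-3)
  expect_equal(f$center, 0, tolerance = 1e-3)
  ## the fitted model is zero beyond the vessel edge and satisfies the
  ## peak identity A(d0) = S0 dx dy dbar
  expect_equal(angioflow:::profile_model(3, f$s0, f$diameter, f$center,
                                         0.55, 0.55), 0)
  expect_equal(angioflow:::profile_model(f$center, f$s0, f$diameter,
                                         f$center, 0.55, 0.55),
               f$s0 * 0.55 * 0.55 * f$diameter, tolerance = 1e-9)
  expect_error(fit_profile(data.frame(d = d, value = 0 * a), vd), "signal")
  expect_error(fit_profile(data.frame(d = d[1:5], value = a[1:5]), vd),
               "7")
})

test_that("profile fits are scale-equivariant in the map amplitude", {
  d <- seq(-4.4, 4.4, by = 0.275)
  vd <- c(0.55, 0.55)
  a <- ifelse(abs(d - 0.3) <= 1.5,
              35 * 0.55 * 0.55 * sqrt(pmax(9 - 4 * (d - 0.3)^2, 0)), 0)
  f1 <- fit_profile(data.frame(d = d, value = a), vd)
  f2 <- fit_profile(data.frame(d = d, value = 3 * a), vd)
  expect_equal(f2$s0 / f1$s0, 3, tolerance = 1e-6)
  expect_equal(f2$diameter, f1$diameter, tolerance = 1e-6)
  expect_equal(f2$center, f1$center, tolerance = 1e-6)
})

test_that("2D calibration averages profiles and reports the SE of the mean", {
  vd <- c(0.55, 0.55)
  ## three stacked vessel maps with S0 = 48, 50, 52 in different row bands
  m <- cbind(render_vessel_map(48, ny = 6), render_vessel_map(50, ny = 6),
             render_vessel_map(52, ny = 6))
  ## samples fall exactly on voxel centers, so no interpolation smoothing
  mk_line <- function(j) profile_line(anchor = c(11, (j - 1) * 0.55),
                                      direction = c(1, 0),
                                      half_length = 4.4, spacing = 0.55)
  cal <- calibrate_2d(m, lapply(c(3, 9, 15), mk_line), vd, sample_width = 0)
  expect_equal(cal$s0_mean, 50, tolerance = 1e-3)
  expect_equal(cal$s0_se, sd(c(48, 50, 52)) / sqrt(3), tolerance = 1e-3)
  ## identical profiles: zero spread
  cal2 <- calibrate_2d(m, lapply(c(2, 3, 4), mk_line), vd, sample_width = 0)
  expect_equal(cal2$s0_se, 0, tolerance = 1e-6)
  expect_equal(cal2$s0_mean, 48, tolerance = 1e-3)
  ## fewer than two usable profiles is an error
  expect_error(calibrate_2d(m * 0 + 1e-9, lapply(c(3, 9), mk_line), vd),
               "usable")
})

test_that("3D calibration divides A by the voxel volume", {
  cal <- calibrate_3d(5, c(0.5, 0.5, 0.5))
  expect_equal(cal$s0_mean, 40)                       # 5 / 0.125 mm^3
  cal2 <- calibrate_3d(c(4.9, 5.0, 5.1), c(1, 1, 1))
  expect_equal(cal2$s0_mean, 5)
  expect_equal(cal2$s0_se, sd(c(4.9, 5, 5.1)) / sqrt(3), tolerance = 1e-9)
  expect_equal(cal2$s0_se, 0.0577, tolerance = 1e-3)
  expect_warning(calibrate_3d(c(5, 0), c(1, 1, 1)), "implausible")
  expect_error(calibrate_3d(numeric(0), c(1, 1, 1)), "voxels")
})

test_that("2D and 3D self-calibration agree on a 3D phantom", {
  cfg <- phantom_config(
    segments = tube_segment(c(8, 0, 6), c(8, 19, 6), diameter = 6,
                            flow = 1.0, artery = "tube", name = "tube"),
    acq = default_acq_twin(voxel_dims = c(0.5, 0.5, 0.5)),
    fov_mm = c(16, 19.5, 12), s0_true = 50, noise_sd = 0,
    mode = "3d", supersample = 4)
  ras <- angioflow:::rasterize_phantom(cfg)
  A <- ras$truth$tube$A
  vol <- ras$volume
  ## 3D method: voxels entirely inside the vessel
  pure <- which(vol > 0.999 * prod(cfg$acq$voxel_dims))
  expect_gt(length(pure), 50)
  cal3 <- calibrate_3d(A[pure], cfg$acq$voxel_dims)
  expect_equal(cal3$s0_mean, 50, tolerance = 0.01)
  ## 2D method on the slab projection of the same phantom
  A0 <- A; A0[is.na(A0)] <- 0
  proj <- apply(A0, c(1, 2), sum)
  lines <- auto_profile_lines(proj, cfg$acq$voxel_dims, n = 8)
  cal2 <- calibrate_2d(proj, lines, cfg$acq$voxel_dims)
  expect_lt(abs(cal2$s0_mean - cal3$s0_mean) / cal3$s0_mean, 0.02)
})

test_that("calibration report writes text and CSV", {
  vd <- c(0.55, 0.55)
  m <- render_vessel_map(50, ny = 8)
  lines <- lapply(c(3, 5), function(j)
    profile_line(c(11, (j - 1) * 0.55), c(1, 0), 4.4, 0.275))
  cal <- calibrate_2d(m, lines, vd)
  tf <- tempfile(); cf <- tempfile(fileext = ".csv")
  tab <- write_calibration(cal, tf, cf)
  expect_true(file.exists(tf) && file.exists(cf))
  expect_equal(nrow(utils::read.csv(cf)), 2)
  expect_match(readLines(tf)[1], "2d")
})
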