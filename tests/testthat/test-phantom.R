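test_that("plug-flow velocity follows from flow and diameter", {
  ## 0.30 ml/s through a 4 mm tube: 0.3 cm^3/s / (pi * 0.2^2 cm^2)
  v <- velocity_from_flow(0.30, 4)
  expect_equal(v / 10, 2.387, tolerance = 1e-3)     # cm/s
  expect_equal(velocity_from_flow(0.6, 4), 2 * v)
  expect_error(velocity_from_flow(0.3, 0), "diameter")
})

test_that("arrival times follow plug-flow kinematics along the tree", {
  segs <- list(
    tube_segment(c(5, 0), c(5, 20), diameter = 4, flow = 0.3,
                 artery = "a", name = "root"),
    tube_segment(c(5, 20), c(5, 40), diameter = 4, flow = 0.3,
                 parent = "root", name = "child"))
  pts <- rbind(c(5, 10, 0), c(5, 20, 0), c(5, 30, 0))
  at <- arrival_time(segs, pts)
  v <- velocity_from_flow(0.3, 4)
  expect_equal(at$transit, c(10, 20, 30) / v, tolerance = 1e-9)
  ## continuity across the junction: child start equals root end
  at_end <- arrival_time(segs, rbind(c(5, 19.999, 0)))
  at_start <- arrival_time(segs, rbind(c(5, 20.001, 0)))
  expect_equal(at_start$transit, at_end$transit, tolerance = 1e-3)
  ## doubling the flow halves every transit time
  segs2 <- lapply(segs, function(s) { s$flow <- s$flow * 2
    s$velocity <- velocity_from_flow(s$flow, s$diameter); s })
  at2 <- arrival_time(segs2, pts)
  expect_equal(at2$transit, at$transit / 2, tolerance = 1e-9)
  ## points outside all tubes carry NA
  expect_true(is.na(arrival_time(segs, rbind(c(20, 10, 0)))$segment))
})

test_that("kernel origin compensates the accrued kernel-mean delay", {
  segs <- list(tube_segment(c(5, 0), c(5, 40), diameter = 4, flow = 0.3,
                            artery = "a", name = "root"))
  disp <- dispersion_accrual()
  at <- arrival_time(segs, rbind(c(5, 25, 0)), disp)
  ## mean arrival = dt + kernel mean (1/s + p) = transit + baseline mean
  mean_arrival <- at$dt + 1 / at$s + at$p
  expect_equal(mean_arrival, at$transit + disp$inv_s0 + disp$p0,
               tolerance = 1e-9)
})

test_that("flow conservation is enforced at junctions", {
  bad <- list(
    tube_segment(c(5, 0), c(5, 20), 4, flow = 1.0, artery = "a",
                 name = "root"),
    tube_segment(c(5, 20), c(2, 40), 3, flow = 0.5, parent = "root",
                 name = "d1"),
    tube_segment(c(5, 20), c(8, 40), 3, flow = 0.3, parent = "root",
                 name = "d2"))
  expect_error(angioflow:::resolve_tree(bad), "sum to")
  ok <- bad
  ok[[3]] <- tube_segment(c(5, 20), c(8, 40), 3, flow = 0.5,
                          parent = "root", name = "d2")
  expect_silent(angioflow:::resolve_tree(ok))
})

test_that("generated phantoms are seeded and reproducible", {
  cfg <- coarse_tube_config(flow = 1.0, seed = 3)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$cycles, p2$cycles)
  p3 <- generate_phantom(coarse_tube_config(flow = 1.0, seed = 4))
  expect_false(identical(p1$cycles, p3$cycles))
  ## generation does not disturb the caller's RNG stream
  set.seed(10); before <- rnorm(1)
  set.seed(10); invisible(generate_phantom(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a tube outside the field of view is rejected", {
  seg <- tube_segment(c(-10, 0), c(-10, 30), 4, 1, name = "out")
  cfg <- phantom_config(list(seg), acq = default_acq_twin(),
                        fov_mm = c(30, 40), noise_sd = 0)
  expect_error(generate_phantom(cfg), "field of view")
})

test_that("noiseless voxel time courses equal the forward model of their truth", {
  ph <- generate_phantom(coarse_tube_config(flow = 1.0, noise_sd = 0))
  tr <- ph$truth[[ph$config$arteries[1]]]
  comp <- ph$clean$components[[1]]
  idx <- which(!is.na(tr$A) & tr$A > 0.5 * max(tr$A, na.rm = TRUE))
  i <- idx[ceiling(length(idx) / 2)]
  d <- dim(tr$A)
  ijk <- arrayInd(i, d)
  y <- comp[ijk[1], ijk[2], ijk[3], ]
  want <- forward_signal(list(A = tr$A[i], dt = tr$dt[i], s = tr$s[i],
                              p = tr$p[i]), ph$acq)
  expect_equal(y, want, tolerance = 1e-12)
})

test_that("projected noiseless A profile matches the circle-chord law", {
  ph <- generate_phantom(tube_phantom_config(flow = 1.0, noise_sd = 0))
  tr <- ph$truth$tube$A
  a <- tr[, , 1]; a[is.na(a)] <- 0
  j <- round(dim(a)[2] / 2)
  v <- a[, j]
  dx <- ph$acq$voxel_dims[1]
  x <- (seq_along(v) - 1) * dx
  x0 <- sum(x * v) / sum(v)
  ## compare against the voxel-footprint-averaged chord model
  want <- angioflow:::profile_model(x, ph$truth$s0_true, 4, x0, dx,
                                    ph$acq$voxel_dims[2], sample_width = dx)
  expect_lt(max(abs(v - want)) / max(want), 0.02)
  ## total projected blood volume in the row: pi r^2 dy
  expect_equal(sum(v) / ph$truth$s0_true, pi * 2^2 * ph$acq$voxel_dims[2],
               tolerance = 0.01)
})

test_that("mixing tree carries flow-proportional components at the outlet", {
  ph <- generate_phantom(mixing_tree_config(
    flow_total = 1.0, split = c(0.7, 0.3), seed = 1, noise_sd = 0,
    acq = default_acq_twin(voxel_dims = c(1.1, 1.1, 50)),
    fov_mm = c(35.2, 52.8), junction_y = 12, inlet_half_sep = 8))
  labs <- ph$mask$labels
  out_lab <- unname(ph$mask$table[["outlet"]])
  out <- labs == out_lab
  AR <- ph$truth$right$A; AL <- ph$truth$left$A
  sR <- sum(AR[out], na.rm = TRUE); sL <- sum(AL[out], na.rm = TRUE)
  expect_equal(sR / (sR + sL), 0.7, tolerance = 1e-2)
  ## equal split gives equal components by symmetry
  ph2 <- generate_phantom(mixing_tree_config(
    flow_total = 1.0, split = c(0.5, 0.5), seed = 1, noise_sd = 0,
    acq = default_acq_twin(voxel_dims = c(1.1, 1.1, 50)),
    fov_mm = c(35.2, 52.8), junction_y = 12, inlet_half_sep = 8))
  out2 <- ph2$mask$labels == unname(ph2$mask$table[["outlet"]])
  s1 <- sum(ph2$truth$right$A[out2], na.rm = TRUE)
  s2 <- sum(ph2$truth$left$A[out2], na.rm = TRUE)
  expect_equal(s1 / s2, 1, tolerance = 1e-3)
  expect_error(mixing_tree_config(split = c(0.7, 0.4)), "sum")
})
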