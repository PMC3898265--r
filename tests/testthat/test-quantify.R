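## Minimal hand-built kinetic_maps (one or a few voxels) for unit tests.
toy_maps <- function(pars_list, acq = test_acq(), cov = NULL) {
  n <- length(pars_list)
  d <- c(n, 1, 1)
  g <- function(field) array(vapply(pars_list, `[[`, numeric(1), field), d)
  covarr <- array(0, c(d, 10L))
  if (!is.null(cov)) {
    lt <- lower.tri(matrix(0, 4, 4), diag = TRUE)
    for (i in seq_len(n)) covarr[i, 1, 1, ] <- cov[[i]][lt]
  }
  structure(list(A = g("A"), dt = g("dt"), s = g("s"), p = g("p"),
                 rss = array(0, d), fitted = array(TRUE, d), cov = covarr,
                 acq = acq),
            class = "kinetic_maps")
}

test_that("short-bolus signal has unit kernel mass and causal support", {
  acq <- test_acq()
  maps <- toy_maps(list(list(A = 2, dt = 0.2, s = 10, p = 0.3)), acq)
  cfg <- short_bolus_config(tau_prime = 0.001,
                            sim_times = seq(0, 4, by = 0.002))
  sim <- simulate_short_bolus(maps, cfg)
  sp <- sim$sprime[1, ]
  expect_true(all(sp >= 0))
  expect_true(all(sp[sim$times < 0.2] == 0))          # t < dt
  ## temporal integral equals A * tau'
  expect_equal(sum(sp) * 0.002, 2 * 0.001, tolerance = 1e-4)
  ## value at t = 0.5 against a brute-force quadrature oracle
  oracle <- 2 * integrate(dispersion_kernel, 0.5 - 0.2 - 0.001, 0.5 - 0.2,
                          s = 10, p = 0.3, rel.tol = 1e-12)$value
  got <- sp[which.min(abs(sim$times - 0.5))]
  expect_lt(abs(got - oracle) / oracle, 0.001)
  expect_error(simulate_short_bolus(maps, cfg, voxels = integer(0)),
               "no fitted voxels")
})

test_that("mask flow curve calibrates, scales and handles empty overlap", {
  acq <- test_acq()
  maps <- toy_maps(list(list(A = 100, dt = 0.1, s = 20, p = 0.05),
                        list(A = 50, dt = 0.3, s = 20, p = 0.05)), acq)
  mask <- array(TRUE, c(2, 1, 1))
  cfg <- short_bolus_config()
  c1 <- mask_flow_curve(maps, mask, s0 = 50, cfg)
  c2 <- mask_flow_curve(maps, mask, s0 = 100, cfg)
  expect_equal(c2$flow, c1$flow / 2, tolerance = 1e-12)  # doubling S0 halves
  ## mask voxels without fits contribute zero flow
  maps2 <- maps; maps2$fitted[] <- FALSE
  c0 <- mask_flow_curve(maps2, mask, 50, cfg)
  expect_true(all(c0$flow == 0))
  expect_equal(c0$n_voxels, 0L)
  expect_error(mask_flow_curve(maps, array(FALSE, c(2, 1, 1)), 50, cfg),
               "empty")
  expect_error(mask_flow_curve(maps, mask, -1, cfg), "positive")
  ## unit bookkeeping: a single voxel of unit-mass bolus fully inside the
  ## window integrates to A/S0/1000 ml
  dense <- short_bolus_config(sim_times = seq(0, 4, by = 0.002))
  cd <- mask_flow_curve(maps, mask, 50, dense)
  expect_equal(sum(cd$flow) * 0.002, (100 + 50) / 50 / 1000,
               tolerance = 1e-4)
})

test_that("plateau detection reproduces the hand-worked example", {
  curve <- c(0, 1, 4, 5, 5, 5, 4, 1, 0)
  pl <- detect_plateau(curve, times = 0:8)
  ## 20% of max = 1.0; strictly above -> [4,5,5,5,4]; median 5;
  ## at-or-above median -> samples 4..6 (0-based 3..5)
  expect_equal(pl$median, 5)
  expect_equal(pl$idx, 4:6)
  expect_equal(pl$flow_mean, 5)
  expect_equal(pl$flow_sd, 0)
  expect_false(pl$no_plateau)
  ## constant positive curve: plateau spans everything, SD 0, no flag
  plc <- detect_plateau(rep(2.5, 11), times = seq(0, 1, 0.1))
  expect_equal(plc$idx, 1:11)
  expect_equal(plc$flow_sd, 0)
  expect_false(plc$no_plateau)
  ## strictly increasing curve: bolus never contained, flagged
  pli <- detect_plateau(seq(0.1, 2, length.out = 20), times = 1:20)
  expect_true(pli$no_plateau)
  expect_error(detect_plateau(rep(0, 5)), "no plateau")
})

test_that("sigma-point uncertainty propagation behaves linearly in Var(A)", {
  acq <- test_acq()
  base_cov <- diag(c(0.25, 0, 0, 0))
  m1 <- toy_maps(list(list(A = 10, dt = 0.2, s = 10, p = 0.1)), acq,
                 cov = list(base_cov))
  m2 <- toy_maps(list(list(A = 10, dt = 0.2, s = 10, p = 0.1)), acq,
                 cov = list(2 * base_cov))
  mask <- array(TRUE, c(1, 1, 1))
  cfg <- short_bolus_config(sim_times = seq(0, 1.5, by = 0.01))
  p1 <- propagate_uncertainty(m1, mask, 50, cfg)
  p2 <- propagate_uncertainty(m2, mask, 50, cfg)
  nz <- p1$flow_sd > 1e-12
  expect_equal(p2$flow_sd[nz]^2 / p1$flow_sd[nz]^2,
               rep(2, sum(nz)), tolerance = 1e-6)
  ## zero covariance and zero S0 SE give exactly zero propagated SD
  m0 <- toy_maps(list(list(A = 10, dt = 0.2, s = 10, p = 0.1)), acq)
  p0 <- propagate_uncertainty(m0, mask, 50, cfg)
  expect_true(all(p0$flow_sd == 0))
})

test_that("sigma-point mean matches Monte Carlo over the Laplace posterior", {
  acq <- test_acq()
  mu <- c(A = 10, dt = 0.3, s = 12, p = 0.08)
  sds <- c(0.5, 0.02, 1.2, 0.008)
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.3; R[3, 4] <- R[4, 3] <- -0.2
  Sg <- diag(sds) %*% R %*% diag(sds)
  m <- toy_maps(list(as.list(mu)), acq, cov = list(Sg))
  mask <- array(TRUE, c(1, 1, 1))
  tq <- 0.5
  cfg <- short_bolus_config(sim_times = c(0, tq))
  pu <- propagate_uncertainty(m, mask, 50, cfg)
  ## Monte Carlo oracle with 1e5 draws of S'(0.5)
  set.seed(99)
  L <- t(chol(Sg))
  draws <- t(mu + L %*% matrix(rnorm(4e5), 4))
  draws[, 1] <- pmax(draws[, 1], 0); draws[, 3] <- pmax(draws[, 3], 1e-6)
  draws[, 4] <- pmax(draws[, 4], 0)
  sp <- draws[, 1] *
    (pgamma(tq - draws[, 2], 1 + draws[, 3] * draws[, 4], draws[, 3]) -
     pgamma(tq - 0.001 - draws[, 2], 1 + draws[, 3] * draws[, 4],
            draws[, 3]))
  mc_flow <- mean(sp) / 50 / 1000 / 0.001
  expect_lt(abs(pu$flow[2] - mc_flow) / mc_flow, 0.01)
})

test_that("vessel quantification decomposes by artery and stays calibrated", {
  acq <- test_acq()
  mk <- function(f) toy_maps(list(list(A = 100 * f, dt = 0.1, s = 25,
                                       p = 0.03),
                                  list(A = 90 * f, dt = 0.25, s = 25,
                                       p = 0.03)), acq)
  maps <- list(right = mk(0.7), left = mk(0.3))
  mask <- array(TRUE, c(2, 1, 1))
  est <- quantify_vessel(maps, mask, s0 = 50, uncertainty = FALSE)
  expect_s3_class(est, "flow_estimate")
  expect_equal(sum(est$per_artery), est$flow_mean, tolerance = 1e-6)
  expect_equal(unname(est$per_artery["right"] / est$flow_mean), 0.7,
               tolerance = 1e-6)
  ## flow is invariant under joint rescaling of signal and calibration
  maps_k <- list(right = mk(0.7 * 3), left = mk(0.3 * 3))
  est_k <- quantify_vessel(maps_k, mask, s0 = 150, uncertainty = FALSE)
  expect_equal(est_k$flow_mean, est$flow_mean, tolerance = 1e-9)
})

test_that("summed-A fractions are exact on noiseless maps", {
  acq <- test_acq()
  maps <- list(a1 = toy_maps(list(list(A = 7, dt = 0.1, s = 10, p = 0.1)),
                             acq),
               a2 = toy_maps(list(list(A = 3, dt = 0.1, s = 10, p = 0.1)),
                             acq))
  mask <- array(TRUE, c(1, 1, 1))
  fr <- relative_flow_by_A(maps, mask)
  expect_equal(unname(fr), c(0.7, 0.3))
  expect_equal(sum(fr), 1)
  expect_equal(unname(relative_flow_by_A(maps["a1"], mask)), 1)
  maps0 <- list(a1 = toy_maps(list(list(A = 0, dt = 0.1, s = 10, p = 0.1)),
                              acq))
  expect_error(relative_flow_by_A(maps0, mask), "zero")
})

test_that("shrinking the mask below full containment only lowers the flow", {
  ph <- generate_phantom(coarse_tube_config(flow = 1.0, noise_sd = 0))
  maps <- truth_maps(ph)
  full <- whole_mask(ph)
  est_full <- quantify_vessel(maps, full, ph$truth$s0_true,
                              uncertainty = FALSE)
  ## keep only a short proximal stretch: the bolus is never fully inside
  labs <- ph$mask$labels
  short <- array(0L, dim(labs))
  ny <- dim(labs)[2]
  short[, seq_len(floor(ny / 8)), ] <- labs[, seq_len(floor(ny / 8)), ]
  est_short <- quantify_vessel(maps, vessel_mask(short),
                               s0 = ph$truth$s0_true, uncertainty = FALSE)
  expect_lt(est_short$flow_mean, est_full$flow_mean * 1.02)
})
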