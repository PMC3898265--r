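test_that("labeled input function is a half-open rect of duration tau", {
  expect_identical(input_function(0.5, 1.0), 1)
  expect_identical(input_function(-0.1, 1.0), 0)
  expect_identical(input_function(1.0, 1.0), 0)   # t = tau excluded
  expect_identical(input_function(0, 1.0), 1)     # t = 0 included
  expect_equal(input_function(c(-1, 0.2, 0.9, 1.5), 1),
               c(0, 1, 1, 0))
  expect_error(input_function(0.5, 0), "tau")
  expect_error(input_function(0.5, -1), "tau")
})

test_that("dispersion kernel is a causal unit-mass density with mode p", {
  for (s in c(1, 10, 100)) {
    for (p in c(0, 0.3, 1)) {
      I <- integrate(dispersion_kernel, 0, Inf, s = s, p = p,
                     rel.tol = 1e-10)$value
      expect_lt(abs(I - 1), 1e-6)
    }
  }
  ## mode at p (gamma mode = (shape-1)/rate = p)
  tp <- seq(0, 2, by = 1e-4)
  d <- dispersion_kernel(tp, s = 10, p = 0.3)
  expect_equal(tp[which.max(d)], 0.3, tolerance = 1e-3)
  expect_identical(dispersion_kernel(-0.01, 10, 0.3), 0)
  expect_error(dispersion_kernel(0.1, s = 0, p = 0.1), "'s'")
  expect_error(dispersion_kernel(0.1, s = 10, p = -0.1), "'p'")
})

test_that("T1 decay follows exp(-elapsed/T1) and is monotone", {
  expect_equal(t1_attenuation(0, 1.65), 1)
  expect_equal(t1_attenuation(1.65, 1.65), exp(-1), tolerance = 1e-12)
  el <- seq(0, 3, by = 0.1)
  expect_true(all(diff(t1_attenuation(el, 1.65)) <= 0))
  expect_error(t1_attenuation(-0.1, 1.65), "elapsed")
  expect_error(t1_attenuation(1, 0), "t1_blood")
})

test_that("RF attenuation counts pulses after arrival in the imaging region", {
  ## no pulses before blood arrives
  expect_equal(rf_attenuation(c(0, 0.1, 0.2), dt_min = 0.2,
                              pulse_interval = 0.01, flip_angle = 30),
               c(1, 1, 1))
  ## zero flip angle leaves the signal untouched
  expect_equal(rf_attenuation(seq(0, 2, 0.25), 0, 0.01, flip_angle = 0),
               rep(1, 9))
  ## two pulses at 30 degrees: cos^2(30) = 0.75
  expect_equal(rf_attenuation(0.025, dt_min = 0, pulse_interval = 0.01,
                              flip_angle = 30), cos(pi / 6)^2)
  expect_equal(rf_attenuation(0.025, 0, 0.01, 30), 0.75)
  ## pulse counting referenced to max(dt_min, imaging_start)
  expect_equal(rf_attenuation(1.02, dt_min = 0, pulse_interval = 0.01,
                              flip_angle = 30, imaging_start = 1),
               cos(pi / 6)^2)
  expect_error(rf_attenuation(1, 0, 0, 30), "pulse_interval")
})

test_that("forward signal is causal, linear in A and reduced by attenuation", {
  acq <- test_acq()
  pars <- list(A = 2, dt = 0.4, s = 10, p = 0.1)
  t <- seq(0, 2, by = 0.05)
  s1 <- forward_signal(pars, acq, t, attenuation = FALSE)
  expect_true(all(s1[t < pars$dt] == 0))
  ## linearity in A, exact
  s2 <- forward_signal(modifyList(pars, list(A = 4)), acq, t,
                       attenuation = FALSE)
  expect_identical(s2, 2 * s1)
  ## attenuation can only reduce the signal
  sa <- forward_signal(pars, acq, t, attenuation = TRUE)
  expect_true(all(sa <= s1 + 1e-15))
  expect_error(forward_signal(list(A = 1, dt = NA, s = 10, p = 1), acq, t),
               "finite")
  expect_error(forward_signal(list(A = 1, dt = 0, s = -1, p = 1), acq, t),
               "'s'")
})

test_that("transit time shifts the unattenuated signal rigidly", {
  acq <- test_acq()
  t <- seq(0, 3, by = 0.01)
  base <- forward_signal(list(A = 1, dt = 0.2, s = 8, p = 0.1), acq, t,
                         attenuation = FALSE)
  delta <- 0.25
  shifted <- forward_signal(list(A = 1, dt = 0.2 + delta, s = 8, p = 0.1),
                            acq, t + delta, attenuation = FALSE)
  expect_equal(shifted, base, tolerance = 1e-10)
})

test_that("in the sharp-kernel limit the signal approaches the shifted rect", {
  acq <- test_acq()
  pars <- list(A = 1.7, dt = 0.2, s = 1e4, p = 0)
  ## stay 10/s away from the rect edges
  t <- c(0.21, 0.5, 0.9, 1.19, 1.3, 1.5)
  s <- forward_signal(pars, acq, t, attenuation = FALSE)
  expected <- pars$A * input_function(t - pars$dt, acq$tau)
  expect_equal(s, expected, tolerance = 0.01)
})

test_that("closed-form convolution matches the brute-force Riemann oracle", {
  acq <- test_acq()
  pars <- list(A = 1, dt = 0.2, s = 10, p = 0.3)
  t <- acq$frame_times
  got <- forward_signal(pars, acq, t, attenuation = FALSE)
  want <- oracle_forward(pars, acq, t)
  expect_lt(max(abs(got - want)) / max(want), 0.001)
  ## with attenuation terms switched on
  got_a <- forward_signal(pars, acq, t)
  want_a <- oracle_forward(pars, acq, t, attenuation = TRUE)
  expect_lt(max(abs(got_a - want_a)) / max(want_a), 0.001)
})

test_that("acquisition and kinetic parameter containers validate inputs", {
  expect_error(acq_params(tau = -1, frame_times = 1:3 / 10,
                          pulse_interval = 0.01, flip_angle = 30), "tau")
  expect_error(acq_params(tau = 1, frame_times = c(0.2, 0.1),
                          pulse_interval = 0.01, flip_angle = 30),
               "increasing")
  expect_error(acq_params(tau = 1, frame_times = 1:3 / 10,
                          pulse_interval = 0.01, flip_angle = 95),
               "flip_angle")
  expect_error(kinetic_params(-1, 0, 1, 0), "'A'")
  expect_error(kinetic_params(1, 0, 1, 0,
                              covariance = matrix(c(1, 2, 3, 4, rep(0, 12)),
                                                  4, 4)),
               "symmetric")
  p <- kinetic_params(1, 0.2, 8, 0.1, covariance = diag(4) * 0.01)
  expect_s3_class(p, "kinetic_params")
  ## dynamic series frame-count contract
  acq <- test_acq()
  expect_error(dynamic_series(array(0, c(2, 2, 1, 5)), acq), "frame count")
})
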