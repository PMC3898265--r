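## Shared fixtures, built in code.

## Default acquisition used in unit tests (the phantom twin).
test_acq <- function(...) default_acq_twin(...)

## Coarse, small phantom for fast integration tests: 1.1 mm voxels (no
## interpolation), reduced field of view, clean SNR. At this resolution the
## vessel spans only ~3.6 voxels, so study-condition noise would make the
## profile calibration edge-limited; these fixtures exercise the pipeline
## mechanics, not the study conditions.
coarse_tube_config <- function(flow = 1.0, seed = 0, peak_snr = 60, ...) {
  tube_phantom_config(
    flow = flow, seed = seed, peak_snr = peak_snr,
    acq = default_acq_twin(voxel_dims = c(1.1, 1.1, 50)),
    fov_mm = c(35.2, 52.8), ...)
}

## Wrap ground-truth per-artery parameter maps as a kinetic_maps object
## (zero covariance), for quantification tests that bypass fitting.
truth_maps <- function(phantom, artery = NULL) {
  if (is.null(artery)) artery <- phantom$config$arteries[1]
  tr <- phantom$truth[[artery]]
  structure(list(A = tr$A, dt = tr$dt, s = tr$s, p = tr$p,
                 rss = tr$A * 0, fitted = !is.na(tr$A),
                 cov = array(0, c(dim(tr$A), 10L)),
                 acq = phantom$acq),
            class = "kinetic_maps")
}

## Whole-network mask for a phantom.
whole_mask <- function(phantom) {
  labs <- phantom$mask$labels
  vessel_mask(array(as.integer(labs > 0), dim(labs)),
              stats::setNames(1L, "whole_tree"))
}

## Brute-force Riemann-sum oracle for the single-voxel forward model
## (0.1 ms grid), independent of the closed-form implementation.
oracle_forward <- function(pars, acq, t, attenuation = FALSE,
                           step = 1e-4, horizon = 6) {
  tp <- seq(0, horizon, by = step)
  D <- dispersion_kernel(tp, pars$s, pars$p)
  vapply(t, function(tt) {
    cin <- input_function(tt - tp - pars$dt, acq$tau)
    v <- pars$A * sum(cin * D) * step
    if (attenuation)
      v <- v * t1_attenuation(max(tt, 0), acq$t1_blood) *
        rf_attenuation(tt, acq$dt_min, acq$pulse_interval, acq$flip_angle,
                       acq$imaging_start)
    v
  }, numeric(1))
}
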