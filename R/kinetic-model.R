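#' Labeled-bolus input function
#'
#' Relative concentration of labeled blood in the proximal vessel for a
#' CASL/PCASL-style preparation: a rect function equal to 1 while labeling is
#' on and 0 otherwise, with the half-open convention `1` on `[0, tau)`.
#'
#' @param t Time(s) since the start of labeling (s); vectorised.
#' @param tau Labeling duration (s), `> 0`.
#' @return Numeric vector of 0/1 relative concentrations.
#' @export
input_function <- function(t, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive, finite scalar")
  as.numeric(t >= 0 & t < tau)
}

#' Gamma-variate dispersion kernel
#'
#' Probability density of the additional transit delay caused by bolus
#' dispersion, parameterised by sharpness `s` (1/s) and time-to-peak `p` (s):
#' a gamma density with shape `1 + s*p` and rate `s`, which integrates to 1
#' and has its mode at `p`.
#'
#' @param t_prime Delay (s); the kernel is causal (zero for `t_prime < 0`).
#' @param s Sharpness (1/s), `> 0`.
#' @param p Time-to-peak (s), `>= 0`.
#' @return Kernel density values (1/s).
#' @export
dispersion_kernel <- function(t_prime, s, p) {
  if (!is.finite(s) || s <= 0) stop("dispersion sharpness 's' must be > 0")
  if (!is.finite(p) || p < 0) stop("dispersion time-to-peak 'p' must be >= 0")
  out <- numeric(length(t_prime))
  pos <- t_prime >= 0
  out[pos] <- stats::dgamma(t_prime[pos], shape = 1 + s * p, rate = s)
  out
}

## Integral of the dispersion kernel over (-Inf, x]: the gamma CDF.
dispersion_cdf <- function(x, s, p) {
  stats::pgamma(pmax(x, 0), shape = 1 + s * p, rate = s)
}

#' T1 decay of the label
#'
#' Attenuation of the labeled-blood signal due to longitudinal relaxation:
#' `exp(-elapsed / t1_blood)`, where `elapsed` is the total time since the
#' blood element was labeled.
#'
#' @param elapsed Time since labeling of the blood element (s), `>= 0`;
#'   vectorised.
#' @param t1_blood T1 of labeled blood (s), `> 0`.
#' @return Attenuation factors in `(0, 1]`.
#' @export
t1_attenuation <- function(elapsed, t1_blood) {
  if (!is.finite(t1_blood) || t1_blood <= 0) stop("'t1_blood' must be > 0")
  if (any(!is.finite(elapsed)) || any(elapsed < 0))
    stop("'elapsed' must be finite and non-negative")
  exp(-elapsed / t1_blood)
}

#' RF attenuation from imaging excitation pulses
#'
#' Each imaging excitation tips away part of the labeled longitudinal
#' magnetization, leaving a factor `cos(flip_angle)` per pulse. Pulses accrue
#' once blood is inside the imaging region and imaging has begun, so the
#' number of pulses experienced by observation time `t` is
#' `n = max(0, floor((t - max(dt_min, imaging_start)) / pulse_interval))`
#' and the attenuation is `cos(flip_angle)^n` (1 before any pulse).
#'
#' @param t Observation time(s) since the start of labeling (s); vectorised.
#' @param dt_min Earliest arrival of labeled blood in the imaging region (s).
#' @param pulse_interval Time between successive excitation pulses (s).
#' @param flip_angle Excitation flip angle (degrees).
#' @param imaging_start Time at which imaging pulses begin (s).
#' @return Attenuation factors in `(0, 1]`.
#' @export
rf_attenuation <- function(t, dt_min, pulse_interval, flip_angle,
                           imaging_start = 0) {
  if (!is.finite(pulse_interval) || pulse_interval <= 0)
    stop("'pulse_interval' must be > 0")
  if (!is.finite(flip_angle) || flip_angle < 0 || flip_angle >= 90)
    stop("'flip_angle' must lie in [0, 90) degrees")
  if (!is.finite(dt_min) || dt_min < 0) stop("'dt_min' must be >= 0")
  t0 <- max(dt_min, imaging_start)
  n <- pmax(0, floor((t - t0) / pulse_interval))
  cos(flip_angle * pi / 180)^n
}

#' Single-voxel forward signal model
#'
#' Predicted angiographic signal in one voxel: the labeled input function,
#' delayed by the transit time `dt` and convolved with the gamma-variate
#' dispersion kernel, scaled by `A` and attenuated by T1 decay and imaging RF
#' pulses,
#' \deqn{S(t) = A \, T(t)\, \Psi(t) \int c_{in}(t - t' - \Delta t)\, D(t')\, dt'.}
#' With the rect input the convolution integral is the difference of two
#' gamma CDFs and is evaluated in closed form. The T1 term uses the full time
#' since labeling and the RF term the pulse count since
#' `max(dt_min, imaging_start)`; both are independent of the dispersion delay
#' and factor out of the integral.
#'
#' Setting `attenuation = FALSE` gives the unattenuated signal
#' (`T = Psi = 1`), as used when simulating the idealised short-bolus
#' experiment.
#'
#' @param params A [kinetic_params()] object or a list with elements
#'   `A`, `dt`, `s`, `p`.
#' @param acq An [acq_params()] object.
#' @param t Times at which to evaluate the signal (s); defaults to the
#'   acquisition frame times.
#' @param attenuation Apply the T1 and RF attenuation terms? Default `TRUE`.
#' @return Numeric vector of predicted signal values at `t`.
#' @export
forward_signal <- function(params, acq, t = acq$frame_times,
                           attenuation = TRUE) {
  if (!inherits(acq, "acq_params")) stop("'acq' must be an acq_params object")
  A <- params$A; dt <- params$dt; s <- params$s; p <- params$p
  if (any(!is.finite(c(A, dt, s, p))))
    stop("kinetic parameters must be finite")
  if (s <= 0) stop("'s' must be positive")
  x <- t - dt
  bolus <- dispersion_cdf(x, s, p) - dispersion_cdf(x - acq$tau, s, p)
  sig <- A * bolus
  if (attenuation) {
    sig <- sig * exp(-pmax(t, 0) / acq$t1_blood) *
      rf_attenuation(t, acq$dt_min, acq$pulse_interval, acq$flip_angle,
                     acq$imaging_start)
  }
  sig
}
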