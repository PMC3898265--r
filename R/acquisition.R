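#' Acquisition parameters for a dynamic angiography experiment
#'
#' Bundles the sequence and geometry constants needed by the kinetic model:
#' the labeling duration, the frame acquisition times, the interval between
#' successive imaging excitation pulses, the excitation flip angle, the
#' longitudinal relaxation time of labeled blood, the earliest arrival time of
#' labeled blood in the imaging region and the voxel dimensions.
#'
#' All times are in seconds, the flip angle in degrees and voxel dimensions in
#' millimetres. Frame times are measured relative to the start of labeling.
#'
#' @param tau Labeling duration (s), `> 0`.
#' @param frame_times Strictly increasing acquisition times of each frame (s).
#' @param pulse_interval Time between successive imaging excitation pulses (s).
#' @param flip_angle Imaging excitation flip angle (degrees), in `(0, 90)`.
#' @param t1_blood Longitudinal relaxation time of labeled arterial blood (s).
#'   Default 1.65 s, appropriate for arterial blood at 3 T.
#' @param dt_min Earliest arrival time of labeled blood in the imaging
#'   region (s), `>= 0`.
#' @param voxel_dims Numeric length-3 vector `(dx, dy, dz)` in mm.
#' @param imaging_start Time at which imaging excitation pulses begin (s).
#'   RF attenuation is referenced to `max(dt_min, imaging_start)`.
#'
#' @return An object of class `"acq_params"`.
#' @export
acq_params <- function(tau, frame_times, pulse_interval, flip_angle,
                       t1_blood = 1.65, dt_min = 0,
                       voxel_dims = c(1, 1, 1), imaging_start = 0) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' (labeling duration) must be a positive, finite number")
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) < 1L || anyNA(frame_times) ||
      any(diff(frame_times) <= 0))
    stop("'frame_times' must be strictly increasing and non-empty")
  if (!is.finite(pulse_interval) || pulse_interval <= 0)
    stop("'pulse_interval' must be positive")
  if (!is.finite(flip_angle) || flip_angle <= 0 || flip_angle >= 90)
    stop("'flip_angle' must lie strictly between 0 and 90 degrees")
  if (!is.finite(t1_blood) || t1_blood <= 0)
    stop("'t1_blood' must be positive")
  if (!is.finite(dt_min) || dt_min < 0)
    stop("'dt_min' must be non-negative")
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) ||
      any(voxel_dims <= 0))
    stop("'voxel_dims' must be three positive numbers (mm)")
  if (!is.finite(imaging_start) || imaging_start < 0)
    stop("'imaging_start' must be non-negative")
  structure(list(
    tau            = as.numeric(tau),
    frame_times    = frame_times,
    pulse_interval = as.numeric(pulse_interval),
    flip_angle     = as.numeric(flip_angle),
    t1_blood       = as.numeric(t1_blood),
    dt_min         = as.numeric(dt_min),
    voxel_dims     = voxel_dims,
    imaging_start  = as.numeric(imaging_start)
  ), class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Dynamic angiography acquisition parameters\n")
  cat(sprintf("  labeling duration tau : %.3f s\n", x$tau))
  cat(sprintf("  frames                : %d, t = %.3f ... %.3f s\n",
              length(x$frame_times), min(x$frame_times), max(x$frame_times)))
  cat(sprintf("  pulse interval        : %.1f ms, flip angle %.1f deg\n",
              1e3 * x$pulse_interval, x$flip_angle))
  cat(sprintf("  T1 blood              : %.2f s\n", x$t1_blood))
  cat(sprintf("  dt_min / imaging start: %.3f / %.3f s\n",
              x$dt_min, x$imaging_start))
  cat(sprintf("  voxel dims            : %.2f x %.2f x %.2f mm\n",
              x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]))
  invisible(x)
}

#' Per-voxel kinetic model parameters
#'
#' Container for the four free parameters of the single-voxel kinetic model:
#' the scaling factor `A` (signal units, proportional to labeled blood
#' volume, `A = S0 * v`), the transit time `dt` (s), the dispersion sharpness
#' `s` (1/s) and the dispersion time-to-peak `p` (s), optionally with a 4x4
#' covariance matrix over `(A, dt, s, p)`.
#'
#' @param A Scaling factor, `>= 0`.
#' @param dt Transit time from the labeling plane to the voxel (s), `>= 0`.
#' @param s Dispersion sharpness (1/s), `> 0`.
#' @param p Dispersion time-to-peak (s), `>= 0`.
#' @param covariance Optional 4x4 symmetric positive semi-definite matrix.
#' @return An object of class `"kinetic_params"`.
#' @export
kinetic_params <- function(A, dt, s, p, covariance = NULL) {
  vals <- c(A = A, dt = dt, s = s, p = p)
  if (any(!is.finite(vals)))
    stop("kinetic parameters must be finite")
  if (A < 0) stop("'A' must be non-negative")
  if (dt < 0) stop("'dt' must be non-negative")
  if (s <= 0) stop("'s' must be positive")
  if (p < 0) stop("'p' must be non-negative")
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    if (!all(dim(covariance) == c(4L, 4L)))
      stop("'covariance' must be a 4x4 matrix")
    if (max(abs(covariance - t(covariance))) >
        1e-8 * max(1, max(abs(covariance))))
      stop("'covariance' must be symmetric")
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev))))
      stop("'covariance' must be positive semi-definite")
    dimnames(covariance) <- list(names(vals), names(vals))
  }
  structure(list(A = as.numeric(A), dt = as.numeric(dt),
                 s = as.numeric(s), p = as.numeric(p),
                 covariance = covariance),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: A = %.4g, dt = %.4g s, s = %.4g 1/s, p = %.4g s\n",
    x$A, x$dt, x$s, x$p))
  if (!is.null(x$covariance)) {
    cat("  marginal SDs:",
        paste(sprintf("%.3g", sqrt(pmax(0, diag(x$covariance)))),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' 4D dynamic angiographic series
#'
#' Wraps a 4D signal array indexed `(x, y, z, frame)` together with its
#' acquisition parameters, and optionally a named list of per-feeding-artery
#' component series of the same shape (as produced by [decode_components()]).
#'
#' @param data 4D numeric array, fourth axis = time frame.
#' @param acq An [acq_params()] object; the frame count must match
#'   `length(acq$frame_times)`.
#' @param components Optional named list of 4D arrays (same shape as `data`),
#'   one per feeding artery.
#' @return An object of class `"dynamic_series"`.
#' @export
dynamic_series <- function(data, acq, components = NULL) {
  if (!inherits(acq, "acq_params")) stop("'acq' must be an acq_params object")
  data <- as.array(data)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, frame)")
  if (dim(data)[4] != length(acq$frame_times))
    stop(sprintf("frame count (%d) does not match length(frame_times) (%d)",
                 dim(data)[4], length(acq$frame_times)))
  if (!is.null(components)) {
    if (is.null(names(components)) || any(!nzchar(names(components))))
      stop("'components' must be a named list")
    for (nm in names(components)) {
      if (!all(dim(as.array(components[[nm]])) == dim(data)))
        stop("component '", nm, "' does not match the series dimensions")
    }
  }
  structure(list(data = data, acq = acq, components = components),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic series: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  if (!is.null(x$components))
    cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  invisible(x)
}
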