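#' Read a 4D dynamic series from a NIfTI-1 file
#'
#' Frame times are attached from the supplied acquisition parameters, not
#' the file header. The header voxel dimensions are checked against the
#' acquisition (a discrepancy above 1% triggers a warning).
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param acq An [acq_params()] object.
#' @return A [dynamic_series()].
#' @export
read_series <- function(path, acq) {
  img <- RNifti::readNifti(path)
  arr <- nifti_array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("'%s' is %dD; a 4D series (x, y, z, frame) was expected",
                 path, length(dim(arr))))
  pd <- attr(img, "pixdim")
  if (!is.null(pd) && length(pd) >= 3) {
    rel <- abs(pd[1:3] - acq$voxel_dims) / acq$voxel_dims
    if (any(rel > 0.01, na.rm = TRUE))
      warning(sprintf(
        "header pixdim (%s) differs from configured voxel_dims (%s) by >1%%",
        paste(signif(pd[1:3], 4), collapse = "x"),
        paste(signif(acq$voxel_dims, 4), collapse = "x")))
  }
  dynamic_series(arr, acq)
}

#' Write an array or dynamic series to NIfTI-1
#'
#' Data are stored as float64, so a write/read round trip reproduces the
#' array bit-exactly. Voxel dimensions are recorded in the header.
#'
#' @param x A [dynamic_series()] or numeric array (3D or 4D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_dims Voxel dimensions in mm (taken from the series if given).
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path, voxel_dims = NULL) {
  if (inherits(x, "dynamic_series")) {
    if (is.null(voxel_dims)) voxel_dims <- x$acq$voxel_dims
    x <- x$data
  }
  x <- as.array(x)
  if (!is.null(voxel_dims))
    attr(x, "pixdim") <- as.numeric(voxel_dims[1:min(3L, length(voxel_dims))])
  nii <- RNifti::asNifti(x, datatype = "double")
  RNifti::writeNifti(nii, path)
  invisible(path)
}

## plain numeric array from a NIfTI image (header attributes stripped)
nifti_array <- function(img) {
  a <- as.array(img)
  structure(as.vector(a), dim = dim(a))
}

#' Write fitted kinetic parameter maps to NIfTI files
#'
#' One 3D NIfTI per parameter (`A`, `dt`, `s`, `p`) plus the residual map
#' and a 4D NIfTI holding the 10 lower-triangle covariance elements per
#' voxel. A `<prefix>_fitted.nii` mask marks fitted voxels.
#'
#' @param maps A `"kinetic_maps"` object.
#' @param prefix Output path prefix (directory must exist).
#' @return Named character vector of the files written, invisibly.
#' @export
write_param_maps <- function(maps, prefix) {
  vd <- maps$acq$voxel_dims
  na0 <- function(a) { a[is.na(a)] <- 0; a }
  files <- c(A = paste0(prefix, "_A.nii"),
             dt = paste0(prefix, "_dt.nii"),
             s = paste0(prefix, "_s.nii"),
             p = paste0(prefix, "_p.nii"),
             rss = paste0(prefix, "_rss.nii"),
             fitted = paste0(prefix, "_fitted.nii"),
             cov = paste0(prefix, "_cov.nii"))
  write_series(na0(maps$A), files["A"], vd)
  write_series(na0(maps$dt), files["dt"], vd)
  write_series(na0(maps$s), files["s"], vd)
  write_series(na0(maps$p), files["p"], vd)
  write_series(na0(maps$rss), files["rss"], vd)
  write_series(array(as.numeric(maps$fitted), dim(maps$fitted)),
               files["fitted"], vd)
  write_series(na0(maps$cov), files["cov"], vd)
  invisible(files)
}

#' Read kinetic parameter maps written by [write_param_maps()]
#' @param prefix Path prefix used when writing.
#' @param acq An [acq_params()] object.
#' @return A `"kinetic_maps"` object.
#' @export
read_param_maps <- function(prefix, acq) {
  ## NIfTI files drop trailing singleton dimensions on read; restore them
  rd3 <- function(f) {
    a <- nifti_array(RNifti::readNifti(f))
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    a
  }
  rd <- function(f) rd3(f)
  rd4 <- function(f) {
    a <- nifti_array(RNifti::readNifti(f))
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3])
    a
  }
  fitted <- rd3(paste0(prefix, "_fitted.nii")) > 0.5
  naify <- function(a) { a[!fitted] <- NA_real_; a }
  naify4 <- function(a) {
    m <- matrix(a, nrow = length(fitted))
    m[!fitted, ] <- NA_real_
    array(m, dim(a))
  }
  maps <- list(A = naify(rd(paste0(prefix, "_A.nii"))),
               dt = naify(rd(paste0(prefix, "_dt.nii"))),
               s = naify(rd(paste0(prefix, "_s.nii"))),
               p = naify(rd(paste0(prefix, "_p.nii"))),
               rss = naify(rd(paste0(prefix, "_rss.nii"))),
               fitted = fitted,
               cov = naify4(rd4(paste0(prefix, "_cov.nii"))),
               acq = acq)
  structure(maps, class = "kinetic_maps")
}

#' Read acquisition parameters from a YAML config file
#'
#' Keys carry explicit units: `tau_s`, `frame_times_s` (or `n_frames` +
#' `frame_dt_s`), `pulse_interval_s`, `flip_angle_deg`, `t1_blood_s`,
#' `dt_min_s`, `voxel_dims_mm`, `imaging_start_s`.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return An [acq_params()] object.
#' @export
read_acq_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  ft <- cfg$frame_times_s
  if (is.null(ft)) {
    if (is.null(cfg$n_frames) || is.null(cfg$frame_dt_s))
      stop("config needs frame_times_s or n_frames + frame_dt_s")
    ft <- seq_len(cfg$n_frames) * cfg$frame_dt_s
  }
  acq_params(tau = cfg$tau_s, frame_times = as.numeric(ft),
             pulse_interval = cfg$pulse_interval_s,
             flip_angle = cfg$flip_angle_deg,
             t1_blood = if (is.null(cfg$t1_blood_s)) 1.65 else cfg$t1_blood_s,
             dt_min = if (is.null(cfg$dt_min_s)) 0 else cfg$dt_min_s,
             voxel_dims = as.numeric(cfg$voxel_dims_mm),
             imaging_start = if (is.null(cfg$imaging_start_s)) 0
               else cfg$imaging_start_s)
}

#' Build a phantom configuration from a YAML config
#'
#' A single-tube phantom is described by `flow_ml_s` and `diameter_mm`; a
#' mixing tree by `tree: {flow_total_ml_s, split, outlet_diameter_mm}`.
#' Acquisition keys are as in [read_acq_config()]; phantom keys are
#' `fov_mm`, `s0_true`, `peak_snr` or `noise_sd`, `static_level`, `seed`,
#' `supersample`.
#'
#' @param config Path to YAML or a parsed list.
#' @param seed Optional seed overriding the config value.
#' @return A `"phantom_config"`.
#' @export
read_phantom_config <- function(config, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  acq <- tryCatch(read_acq_config(cfg), error = function(e) default_acq_twin())
  args <- list(acq = acq)
  for (k in c("fov_mm", "s0_true", "peak_snr", "noise_sd", "static_level",
              "seed", "supersample"))
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  if (!is.null(seed)) args$seed <- seed
  if (!is.null(cfg$tree)) {
    tr <- cfg$tree
    do.call(mixing_tree_config,
            c(list(flow_total = tr$flow_total_ml_s,
                   split = as.numeric(tr$split),
                   outlet_diameter = if (is.null(tr$outlet_diameter_mm)) 4
                     else tr$outlet_diameter_mm), args))
  } else {
    if (is.null(cfg$flow_ml_s)) stop("config needs flow_ml_s or a tree block")
    do.call(tube_phantom_config,
            c(list(flow = cfg$flow_ml_s,
                   diameter = if (is.null(cfg$diameter_mm)) 4
                     else cfg$diameter_mm), args))
  }
}

#' Write a flow estimate table to CSV
#'
#' One row per quantified vessel: mean flow, plateau SD, plateau bounds,
#' model-based SD, per-artery columns and the no-plateau flag.
#'
#' @param estimates Named list of `"flow_estimate"` objects (or one).
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_flow_csv <- function(estimates, path) {
  if (inherits(estimates, "flow_estimate"))
    estimates <- list(vessel = estimates)
  arts <- unique(unlist(lapply(estimates, function(e) names(e$per_artery))))
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    row <- data.frame(vessel = nm, flow_ml_s = e$flow_mean,
                      sd_ml_s = e$flow_sd,
                      plateau_start_s = e$plateau$start,
                      plateau_end_s = e$plateau$end,
                      model_sd_ml_s = e$propagated_sd,
                      no_plateau_flag = e$no_plateau,
                      stringsAsFactors = FALSE)
    for (a in arts)
      row[[paste0("flow_", a, "_ml_s")]] <-
        if (!is.null(e$per_artery) && a %in% names(e$per_artery))
          e$per_artery[[a]] else NA_real_
    row
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
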