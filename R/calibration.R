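#' Total blood-volume-scaled signal map
#'
#' Voxelwise sum of the fitted scaling factor `A` across all feeding
#' arteries. `A` is proportional to the labeled blood volume in the voxel, so
#' the sum is proportional to the total blood volume, the quantity needed for
#' self-calibration.
#'
#' @param maps A list of numeric arrays of identical shape (one `A` map per
#'   feeding artery, `NA` allowed for unfitted voxels), or a single array.
#' @return Array of the same shape; `NA`s are treated as zero contribution,
#'   and voxels unfitted in every artery stay `NA`.
#' @export
total_A_map <- function(maps) {
  if (is.array(maps) || is.numeric(maps)) maps <- list(maps)
  dims <- lapply(maps, function(m) dim(as.array(m)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all A maps must share the same shape")
  tot <- array(0, dims[[1]])
  seen <- array(FALSE, dims[[1]])
  for (m in maps) {
    m <- as.array(m)
    ok <- !is.na(m)
    tot[ok] <- tot[ok] + m[ok]
    seen <- seen | ok
  }
  tot[!seen] <- NA_real_
  tot
}

#' Define a calibration profile line
#'
#' A straight sampling line in the imaging plane, perpendicular to a vessel,
#' along which the total-`A` profile is extracted for the circular
#' cross-section calibration fit. Positions are physical, in millimetres,
#' voxel-center based (index `(i, j)` maps to `((i-1)*dx, (j-1)*dy)` mm).
#'
#' @param anchor Length-2 numeric: line center `(x, y)` in mm.
#' @param direction Length-2 numeric direction (need not be normalised).
#' @param half_length Half the line length (mm), `> 0`.
#' @param spacing Sample spacing along the line (mm), `> 0`.
#' @return An object of class `"profile_line"`.
#' @export
profile_line <- function(anchor, direction, half_length, spacing) {
  anchor <- as.numeric(anchor); direction <- as.numeric(direction)
  if (length(anchor) != 2L || any(!is.finite(anchor)))
    stop("'anchor' must be two finite numbers (mm)")
  if (length(direction) != 2L || all(direction == 0) ||
      any(!is.finite(direction)))
    stop("'direction' must be a non-zero 2-vector")
  if (!is.finite(half_length) || half_length <= 0)
    stop("'half_length' must be > 0")
  if (!is.finite(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  structure(list(anchor = anchor,
                 direction = direction / sqrt(sum(direction^2)),
                 half_length = half_length, spacing = spacing),
            class = "profile_line")
}

#' Sample a map along a profile line
#'
#' Bilinear interpolation of a 2D map at uniformly spaced positions along a
#' [profile_line()]. Distances `d` are measured in mm from the line anchor
#' (negative on one side, positive on the other). Unfitted (`NA`) voxels are
#' treated as zero signal.
#'
#' @param map 2D numeric array (e.g. a projected total-`A` map).
#' @param line A [profile_line()].
#' @param voxel_dims In-plane voxel dimensions `(dx, dy)` in mm (a length-3
#'   vector is accepted; the first two entries are used).
#' @param mark_censored Add a logical `censored` column flagging samples that
#'   interpolate any unfitted (`NA`) voxel. On fitted parameter maps such
#'   samples are below the fitting mask's threshold rather than truly zero,
#'   and [fit_profile()] treats the ones bordering the vessel as missing.
#' @return A data frame with columns `d` (mm) and `value` (and `censored`
#'   when requested).
#' @export
extract_profile <- function(map, line, voxel_dims, mark_censored = FALSE) {
  map <- as.array(map)
  if (length(dim(map)) == 3L && dim(map)[3] == 1L) dim(map) <- dim(map)[1:2]
  if (length(dim(map)) != 2L) stop("'map' must be 2D")
  if (!inherits(line, "profile_line")) stop("'line' must be a profile_line")
  dx <- voxel_dims[1]; dy <- voxel_dims[2]
  d <- seq(-line$half_length, line$half_length, by = line$spacing)
  if (length(d) < 2L) stop("zero-length profile: increase half_length")
  px <- line$anchor[1] + d * line$direction[1]
  py <- line$anchor[2] + d * line$direction[2]
  ## physical mm -> (voxel-center) index coordinates
  xi <- px / dx + 1
  yi <- py / dy + 1
  nx <- dim(map)[1]; ny <- dim(map)[2]
  out_of <- xi < 1 | xi > nx | yi < 1 | yi > ny
  if (any(out_of)) {
    k <- which(out_of)[1]
    stop(sprintf(
      "profile sample %d at (%.2f, %.2f) mm lies outside the image", k,
      px[k], py[k]))
  }
  m <- map
  m[is.na(m)] <- 0
  ## pracma::interp2 interprets rows as y; supply transposed grid
  vals <- pracma::interp2(x = seq_len(nx), y = seq_len(ny), Z = t(m),
                          xp = xi, yp = yi, method = "linear")
  out <- data.frame(d = d, value = vals)
  if (mark_censored) {
    ## a sample is censored when an unfitted voxel carries nonzero weight
    ## in its interpolation (at grid nodes: when the node itself is NA)
    w <- pracma::interp2(x = seq_len(nx), y = seq_len(ny),
                         Z = t(array(as.numeric(is.na(map)), dim(map))),
                         xp = xi, yp = yi, method = "linear")
    out$censored <- w > 1e-6
  }
  out
}

## Circle-chord calibration model: projected blood signal across a circular
## vessel of diameter dbar centered at d0, per unit in-plane voxel area.
## With sample_width w > 0 the chord is box-averaged over the sample
## footprint (closed form via the chord antiderivative), matching profiles
## read off a voxel grid; w = 0 gives the ideal point-sampled chord.
profile_model <- function(d, s0, dbar, d0, dx, dy, sample_width = 0) {
  u <- d - d0
  if (sample_width <= 0) {
    q <- dbar^2 - 4 * u^2
    return(ifelse(q > 0, s0 * dx * dy * sqrt(pmax(q, 0)), 0))
  }
  G <- function(x) {
    xc <- pmin(pmax(x, -dbar / 2), dbar / 2)
    (xc / 2) * sqrt(pmax(dbar^2 - 4 * xc^2, 0)) +
      (dbar^2 / 4) * asin(pmin(pmax(2 * xc / dbar, -1), 1))
  }
  s0 * dx * dy * (G(u + sample_width / 2) - G(u - sample_width / 2)) /
    sample_width
}

#' Fit the circular cross-section calibration model to one profile
#'
#' Least-squares fit of the circle-chord model
#' \deqn{A_{tot}(d) = S_0 \Delta x \Delta y \sqrt{\bar d^2 - 4 (d-d_0)^2}}
#' (zero outside `|d - d0| > dbar/2`) to a sampled total-`A` profile,
#' estimating the calibration factor `S0` (signal per mm^3 of blood), the
#' vessel diameter `dbar` (mm) and the vessel-center offset `d0` (mm).
#'
#' Initialisation is deterministic: `d0` at the profile argmax, `dbar` from
#' the full width of the region above 10% of the peak, and `S0` from the peak
#' identity `A(d0) = S0 dx dy dbar`. Profiles whose fitted center lies within
#' `dbar/2` of a profile end are rejected (truncated vessel).
#'
#' @param samples Data frame with columns `d` and `value`
#'   (from [extract_profile()]), needing at least 7 samples.
#' @param voxel_dims In-plane voxel dimensions (mm).
#' @param sample_width Footprint width (mm) over which each sample averages
#'   the underlying profile; profiles read off a voxel grid should use the
#'   in-plane voxel size. 0 fits the ideal point-sampled chord.
#' @param max_rel_rms Reject the fit (calibration failure) when the RMS
#'   residual exceeds this fraction of the profile peak.
#' @return An object of class `"profile_fit"`: `s0`, `diameter`, `center`,
#'   `residual` (sum of squared residuals), `samples`.
#' @export
fit_profile <- function(samples, voxel_dims, sample_width = 0,
                        max_rel_rms = 0.2) {
  if (!is.null(samples$censored)) {
    ## censored samples bordering fitted ones sit just below the fitting
    ## mask's threshold: their true value is unknown (not zero), so they are
    ## excluded; censored samples deep in the background stay as zeros
    cen <- samples$censored
    nbr_fitted <- c(FALSE, !cen[-nrow(samples)]) | c(!cen[-1], FALSE)
    samples <- samples[!(cen & nbr_fitted), , drop = FALSE]
  }
  d <- samples$d; a <- samples$value
  if (length(d) < 7L) stop("need at least 7 profile samples")
  if (all(a == 0) || max(a, na.rm = TRUE) <= 0)
    stop("calibration failure: profile has no signal")
  dx <- voxel_dims[1]; dy <- voxel_dims[2]
  pk <- which.max(a)
  d0_0 <- d[pk]
  above <- which(a > 0.1 * a[pk])
  dbar_0 <- max(d[max(above)] - d[min(above)], 2 * min(diff(d)))
  s0_0 <- a[pk] / (dx * dy * dbar_0)
  obj <- function(th) {
    sum((profile_model(d, th[1], th[2], th[3], dx, dy, sample_width) - a)^2)
  }
  th0 <- c(s0_0, dbar_0, d0_0)
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  ## polish: restart once from the optimum (Nelder-Mead can stall early)
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  th <- opt$par
  if (!all(is.finite(th)) || th[1] <= 0 || th[2] <= 0)
    stop("calibration failure: profile fit did not converge")
  if (th[3] - th[2] / 2 < min(d) || th[3] + th[2] / 2 > max(d))
    stop("calibration failure: vessel truncated by the profile ends")
  if (sqrt(opt$value / length(d)) > max_rel_rms * max(a))
    stop("calibration failure: profile poorly described by the circle model")
  structure(list(s0 = th[1], diameter = th[2], center = th[3],
                 residual = opt$value, samples = samples),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf(
    "Profile fit: S0 = %.4g /mm^3, diameter = %.3f mm, center = %.3f mm (SSR %.3g)\n",
    x$s0, x$diameter, x$center, x$residual))
  invisible(x)
}

#' Self-calibration from vessel cross-section profiles (2D method)
#'
#' Fits the circle-chord model to a set of profiles drawn perpendicular to
#' vessels in a projected total-`A` map and averages the per-profile `S0`
#' estimates. The spread across profiles gives the standard error of the
#' mean, which is later propagated into the flow estimate. Profiles that fail
#' to fit (no signal, non-convergence, truncation) are skipped and counted.
#'
#' @param a_tot 2D total-`A` map (e.g. from [total_A_map()]).
#' @param lines List of [profile_line()] objects (at least 2 usable).
#' @param voxel_dims In-plane voxel dimensions (mm).
#' @param sample_width Sample footprint passed to [fit_profile()]; defaults
#'   to the in-plane voxel size, appropriate for voxel-grid profiles.
#' @param consensus_diameter When `TRUE` (default) and at least 3 profiles
#'   fit, profiles whose fitted diameter deviates from the median diameter
#'   by more than 15% are discarded: profiles drawn along the same vessel
#'   segment must agree on its diameter, and disagreement indicates a
#'   truncated or merged cross-section rather than a clean one.
#' @return An object of class `"calibration"`: `s0_mean`, `s0_se`,
#'   `per_profile` (list of `profile_fit`), `n_failed`, `method`.
#' @export
calibrate_2d <- function(a_tot, lines, voxel_dims,
                         sample_width = voxel_dims[1],
                         consensus_diameter = TRUE) {
  if (inherits(lines, "profile_line")) lines <- list(lines)
  fits <- list(); failed <- 0L
  for (ln in lines) {
    f <- tryCatch({
      smp <- extract_profile(a_tot, ln, voxel_dims, mark_censored = TRUE)
      fit_profile(smp, voxel_dims, sample_width = sample_width)
    }, error = function(e) e)
    if (inherits(f, "error")) failed <- failed + 1L else fits[[length(fits) + 1L]] <- f
  }
  if (consensus_diameter && length(fits) >= 3L) {
    ds <- vapply(fits, `[[`, numeric(1), "diameter")
    keep <- abs(ds - stats::median(ds)) <= 0.15 * stats::median(ds)
    failed <- failed + sum(!keep)
    fits <- fits[keep]
  }
  if (length(fits) < 2L)
    stop(sprintf("calibration failed: only %d usable profile(s) out of %d",
                 length(fits), length(lines)))
  s0s <- vapply(fits, `[[`, numeric(1), "s0")
  structure(list(s0_mean = mean(s0s),
                 s0_se = stats::sd(s0s) / sqrt(length(s0s)),
                 per_profile = fits, n_failed = failed, method = "2d"),
            class = "calibration")
}

#' Self-calibration from pure-blood voxels (3D method)
#'
#' For a 3D acquisition, any voxel lying entirely within an artery contains
#' blood of exactly the voxel volume, so `S0 = A_tot / (dx dy dz)` voxel by
#' voxel. The estimates are averaged and their standard error recorded.
#'
#' @param a_tot Total-`A` values in the pre-selected pure-blood voxels
#'   (numeric vector).
#' @param voxel_dims Voxel dimensions `(dx, dy, dz)` in mm.
#' @return An object of class `"calibration"` (see [calibrate_2d()]);
#'   `per_voxel` holds the per-voxel `S0` values.
#' @export
calibrate_3d <- function(a_tot, voxel_dims) {
  a_tot <- as.numeric(a_tot)
  a_tot <- a_tot[!is.na(a_tot)]
  if (length(a_tot) == 0L) stop("no pure-blood voxels supplied")
  vol <- prod(voxel_dims[1:3])
  s0s <- a_tot / vol
  if (any(s0s <= 0))
    warning("non-positive S0 in ", sum(s0s <= 0),
            " voxel(s): implausible calibration values")
  se <- if (length(s0s) > 1L) stats::sd(s0s) / sqrt(length(s0s)) else 0
  structure(list(s0_mean = mean(s0s), s0_se = se, per_voxel = s0s,
                 per_profile = NULL, n_failed = 0L, method = "3d"),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  n <- if (x$method == "2d") length(x$per_profile) else length(x$per_voxel)
  cat(sprintf(
    "Self-calibration (%s method): S0 = %.4g +/- %.2g (SE) from %d %s",
    x$method, x$s0_mean, x$s0_se, n,
    if (x$method == "2d") "profiles" else "voxels"))
  if (x$n_failed > 0) cat(sprintf(" (%d failed)", x$n_failed))
  cat("\n")
  invisible(x)
}

#' Write a calibration report
#'
#' Writes a short human-readable text report and a machine-readable CSV of
#' the per-profile calibration fits.
#'
#' @param calib A `"calibration"` object.
#' @param path_txt,path_csv Output file paths (either may be `NULL`).
#' @return Invisibly, the per-profile data frame.
#' @export
write_calibration <- function(calib, path_txt = NULL, path_csv = NULL) {
  if (calib$method == "2d") {
    tab <- data.frame(
      profile = seq_along(calib$per_profile),
      s0 = vapply(calib$per_profile, `[[`, numeric(1), "s0"),
      diameter_mm = vapply(calib$per_profile, `[[`, numeric(1), "diameter"),
      center_mm = vapply(calib$per_profile, `[[`, numeric(1), "center"),
      ssr = vapply(calib$per_profile, `[[`, numeric(1), "residual"))
  } else {
    tab <- data.frame(voxel = seq_along(calib$per_voxel),
                      s0 = calib$per_voxel)
  }
  if (!is.null(path_txt)) {
    con <- file(path_txt, "w"); on.exit(close(con))
    writeLines(c(
      sprintf("Calibration method: %s", calib$method),
      sprintf("S0 mean: %.6g", calib$s0_mean),
      sprintf("S0 standard error: %.6g", calib$s0_se),
      sprintf("Usable measurements: %d (failed: %d)", nrow(tab),
              calib$n_failed)), con)
  }
  if (!is.null(path_csv)) utils::write.csv(tab, path_csv, row.names = FALSE)
  invisible(tab)
}
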