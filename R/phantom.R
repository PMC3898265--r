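#' Mean velocity in a tube from its volume flow rate
#'
#' Plug-flow mean velocity: `flow / cross-sectional area`.
#'
#' @param flow_ml_s Volume flow rate (ml/s).
#' @param diameter_mm Inner diameter (mm).
#' @return Mean velocity in mm/s.
#' @export
velocity_from_flow <- function(flow_ml_s, diameter_mm) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive")
  area_mm2 <- pi * (diameter_mm / 2)^2
  flow_ml_s * 1000 / area_mm2
}

#' Straight tube segment of a flow phantom
#'
#' One cylindrical segment of a (possibly bifurcating) tube network. Points
#' are physical positions in mm (2 or 3 coordinates; the third defaults to
#' 0, the slab center plane). Labeled blood enters a root segment (no
#' parent) at its start, where the labeling plane sits.
#'
#' @param start,end Segment end points (mm).
#' @param diameter Inner diameter (mm), `> 0`.
#' @param flow Volume flow rate through the segment (ml/s), `> 0`.
#' @param artery Feeding-artery label carried by a root segment.
#' @param parent `NULL` for a root, otherwise the name(s) of the upstream
#'   segment(s); two parents denote a converging junction.
#' @param name Segment name (defaults to `artery` for roots).
#' @return An object of class `"tube_segment"`.
#' @export
tube_segment <- function(start, end, diameter, flow, artery = "artery_1",
                         parent = NULL, name = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) == 2L) start <- c(start, 0)
  if (length(end) == 2L) end <- c(end, 0)
  if (length(start) != 3L || length(end) != 3L)
    stop("'start' and 'end' must have 2 or 3 coordinates (mm)")
  if (!is.finite(diameter) || diameter <= 0) stop("'diameter' must be > 0")
  if (!is.finite(flow) || flow <= 0) stop("'flow' must be > 0")
  L <- sqrt(sum((end - start)^2))
  if (L <= 0) stop("segment has zero length")
  if (is.null(name)) name <- if (is.null(parent)) artery else "segment"
  structure(list(start = start, end = end, diameter = diameter,
                 flow = flow, artery = artery, parent = parent,
                 name = name, length = L,
                 velocity = velocity_from_flow(flow, diameter)),
            class = "tube_segment")
}

#' Dispersion accrual model for the phantom
#'
#' The gamma-variate dispersion parameters accrue along the flow path: the
#' inverse sharpness `1/s` and the time-to-peak `p` each grow in proportion
#' to the transit time, on top of a baseline acquired at the labeling plane.
#'
#' The mean extra delay carried by the kernel (`1/s + p`, the gamma mean)
#' therefore grows at rate `alpha + beta` per unit transit. Conservation of
#' mass requires the mean arrival time of labeled blood at a voxel to equal
#' the plug-flow transit time, so the kernel origin assigned to a voxel is
#' the kinematic transit *minus* the accrued kernel-mean growth:
#' `dt = (1 - alpha - beta) * transit`. The bolus then travels at the true
#' mean velocity while broadening, and the simulated-bolus flow estimate is
#' unbiased.
#'
#' @param inv_s0 Baseline `1/s` at the labeling plane (s).
#' @param p0 Baseline time-to-peak at the labeling plane (s).
#' @param alpha Growth of `1/s` per unit transit time (dimensionless).
#' @param beta Growth of `p` per unit transit time (dimensionless);
#'   `alpha + beta < 1` required.
#' @return A named list.
#' @export
dispersion_accrual <- function(inv_s0 = 0.015, p0 = 0.010,
                               alpha = 0.05, beta = 0.05) {
  stopifnot(inv_s0 > 0, p0 >= 0, alpha >= 0, beta >= 0, alpha + beta < 1)
  list(inv_s0 = inv_s0, p0 = p0, alpha = alpha, beta = beta)
}

## Resolve a tube tree: arrival time, dispersion state and per-artery mixing
## fractions at the start of every segment, walking parents before children.
## Checks flow conservation at both diverging and converging junctions.
resolve_tree <- function(segments, dispersion = dispersion_accrual()) {
  nm <- vapply(segments, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("segment names must be unique")
  names(segments) <- nm
  done <- stats::setNames(logical(length(segments)), nm)
  state <- list()
  remaining <- nm
  while (length(remaining) > 0L) {
    progressed <- FALSE
    for (s in remaining) {
      seg <- segments[[s]]
      if (is.null(seg$parent)) {
        state[[s]] <- list(t0 = 0, inv_s = dispersion$inv_s0,
                           p = dispersion$p0,
                           mix = stats::setNames(1, seg$artery))
        done[s] <- TRUE; progressed <- TRUE
      } else if (all(seg$parent %in% nm[done])) {
        par_states <- lapply(seg$parent, function(pn) {
          pseg <- segments[[pn]]; pst <- state[[pn]]
          transit <- pseg$length / pseg$velocity
          list(t0 = pst$t0 + transit,
               inv_s = pst$inv_s + dispersion$alpha * transit,
               p = pst$p + dispersion$beta * transit,
               mix = pst$mix, flow = pseg$flow)
        })
        w <- vapply(par_states, `[[`, numeric(1), "flow")
        w <- w / sum(w)
        mix <- list()
        for (k in seq_along(par_states)) {
          for (a in names(par_states[[k]]$mix)) {
            mix[[a]] <- (if (is.null(mix[[a]])) 0 else mix[[a]]) +
              w[k] * par_states[[k]]$mix[[a]]
          }
        }
        state[[s]] <- list(
          t0 = sum(w * vapply(par_states, `[[`, numeric(1), "t0")),
          inv_s = sum(w * vapply(par_states, `[[`, numeric(1), "inv_s")),
          p = sum(w * vapply(par_states, `[[`, numeric(1), "p")),
          mix = unlist(mix))
        done[s] <- TRUE; progressed <- TRUE
      }
    }
    remaining <- nm[!done]
    if (!progressed)
      stop("tube tree has unresolved or cyclic parent references: ",
           paste(remaining, collapse = ", "))
  }
  ## flow conservation at junctions
  for (s in nm) {
    children <- nm[vapply(segments, function(sg)
      !is.null(sg$parent) && length(sg$parent) == 1L && sg$parent == s,
      logical(1))]
    if (length(children) > 1L) {
      fsum <- sum(vapply(segments[children], `[[`, numeric(1), "flow"))
      if (abs(fsum - segments[[s]]$flow) > 1e-6 * segments[[s]]$flow)
        stop(sprintf("child flows at '%s' sum to %.4g but parent flow is %.4g",
                     s, fsum, segments[[s]]$flow))
    }
  }
  for (s in nm) {
    seg <- segments[[s]]
    if (!is.null(seg$parent) && length(seg$parent) > 1L) {
      fsum <- sum(vapply(segments[seg$parent], `[[`, numeric(1), "flow"))
      if (abs(fsum - seg$flow) > 1e-6 * seg$flow)
        stop(sprintf("parent flows into '%s' sum to %.4g but its flow is %.4g",
                     s, fsum, seg$flow))
    }
  }
  list(segments = segments, state = state)
}

#' Arrival time (and dispersion state) of labeled blood at given points
#'
#' Plug-flow kinematics: the transit time to a point is the sum over the
#' upstream path of segment length over mean velocity, linear in distance
#' within a segment. Points are assigned to the segment whose axis they are
#' closest to (largest tube thickness at that point).
#'
#' @param segments List of [tube_segment()]s.
#' @param points Matrix (n x 2 or n x 3) of positions in mm.
#' @param dispersion A [dispersion_accrual()] list.
#' @return Data frame with `transit` (kinematic transit time, s), `dt`
#'   (kernel origin for the forward model: transit minus the accrued
#'   kernel-mean delay, see [dispersion_accrual()]), `s` (1/s), `p` (s) and
#'   `segment` (name, NA outside all tubes).
#' @export
arrival_time <- function(segments, points, dispersion = dispersion_accrual()) {
  res <- resolve_tree(segments, dispersion)
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  n <- nrow(points)
  best_chord <- rep(-Inf, n)
  dt <- rep(NA_real_, n); sv <- rep(NA_real_, n); pv <- rep(NA_real_, n)
  trn <- rep(NA_real_, n)
  segname <- rep(NA_character_, n)
  for (s in names(res$segments)) {
    seg <- res$segments[[s]]; st <- res$state[[s]]
    u <- (seg$end - seg$start) / seg$length
    w <- sweep(points, 2, seg$start)
    ax <- as.vector(w %*% u)
    perp2 <- rowSums(w^2) - ax^2
    r <- seg$diameter / 2
    inside <- ax >= 0 & ax <= seg$length & perp2 < r^2
    chord <- ifelse(inside, 2 * sqrt(pmax(r^2 - perp2, 0)), -Inf)
    take <- chord > best_chord & inside
    if (any(take)) {
      local <- ax[take] / seg$velocity
      transit <- st$t0 + local
      inv_s <- st$inv_s + dispersion$alpha * local
      pp <- st$p + dispersion$beta * local
      trn[take] <- transit
      ## kernel origin: transit minus the kernel-mean delay accrued since
      ## the labeling plane, so mean arrival equals the kinematic transit
      dt[take] <- pmax(0, transit - (inv_s - dispersion$inv_s0) -
                            (pp - dispersion$p0))
      sv[take] <- 1 / inv_s
      pv[take] <- pp
      segname[take] <- s
      best_chord[take] <- chord[take]
    }
  }
  data.frame(transit = trn, dt = dt, s = sv, p = pv, segment = segname,
             stringsAsFactors = FALSE)
}

#' Default acquisition twin of the phantom experiment
#'
#' 20 frames at 55 ms temporal resolution concurrent with a 1.0 s labeling
#' period, 0.55 mm in-plane voxels (1.1 mm acquired, interpolated), 50 mm
#' slab, imaging excitations every 10 ms at 8 degrees, arterial T1 1.65 s.
#'
#' @param ... Overrides passed to [acq_params()].
#' @return An [acq_params()] object.
#' @export
default_acq_twin <- function(...) {
  args <- list(tau = 1.0, frame_times = seq_len(20) * 0.055,
               pulse_interval = 0.010, flip_angle = 8,
               t1_blood = 1.65, dt_min = 0,
               voxel_dims = c(0.55, 0.55, 50), imaging_start = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(acq_params, args)
}

#' Phantom configuration
#'
#' Full description of a synthetic flow-phantom experiment: geometry,
#' acquisition, ground-truth calibration factor, noise level and seed.
#'
#' @param segments List of [tube_segment()]s.
#' @param acq An [acq_params()] object (default [default_acq_twin()]).
#' @param fov_mm In-plane field of view `(x, y)` in mm (2D mode) or `(x, y,
#'   z)` (3D mode).
#' @param s0_true Ground-truth signal per unit blood volume (units/mm^3).
#' @param peak_snr Peak SNR of the decoded per-artery series; ignored when
#'   `noise_sd` is given.
#' @param noise_sd Additive Gaussian noise SD on each encoding cycle at the
#'   acquired resolution (signal units); `NULL` to derive from `peak_snr`.
#' @param acquired_voxel_mm In-plane resolution at which the data are
#'   acquired (mm), default 1.1: noise is generated white at this
#'   resolution and bilinearly interpolated onto the reconstruction grid,
#'   reproducing the spatial noise correlation of images acquired coarse
#'   and interpolated fine. Set equal to the voxel size for white noise.
#' @param static_level Static (unlabeled) water signal as a multiple of
#'   `s0_true` per unit volume.
#' @param seed Integer RNG seed for the noise.
#' @param supersample Rasterisation supersampling factor per axis.
#' @param mode `"2d"` (projection along the slab axis) or `"3d"`.
#' @param dispersion A [dispersion_accrual()] list.
#' @param scheme An [encoding_scheme()]; default chosen from the number of
#'   distinct arteries (tag/control for one, four-cycle for two).
#' @return An object of class `"phantom_config"`.
#' @export
phantom_config <- function(segments, acq = default_acq_twin(),
                           fov_mm = c(48.4, 63.8), s0_true = 50,
                           peak_snr = 20, noise_sd = NULL,
                           static_level = 1, seed = 0,
                           supersample = 4, mode = c("2d", "3d"),
                           dispersion = dispersion_accrual(),
                           scheme = NULL, acquired_voxel_mm = 1.1) {
  mode <- match.arg(mode)
  if (inherits(segments, "tube_segment")) segments <- list(segments)
  if (!is.finite(s0_true) || s0_true <= 0) stop("'s0_true' must be > 0")
  if (!is.null(noise_sd) && noise_sd < 0) stop("'noise_sd' must be >= 0")
  arteries <- unique(unlist(lapply(resolve_tree(segments, dispersion)$state,
                                   function(st) names(st$mix))))
  if (is.null(scheme)) {
    scheme <- if (length(arteries) == 1L) encoding_single(arteries)
      else if (length(arteries) == 2L) encoding_two_tube(arteries)
      else stop("supply an encoding scheme for >2 arteries")
  }
  structure(list(segments = segments, acq = acq, fov_mm = fov_mm,
                 s0_true = s0_true, peak_snr = peak_snr,
                 noise_sd = noise_sd, static_level = static_level,
                 seed = as.integer(seed), supersample = supersample,
                 mode = mode, dispersion = dispersion, scheme = scheme,
                 arteries = arteries,
                 acquired_voxel_mm = acquired_voxel_mm),
            class = "phantom_config")
}

#' Single straight-tube phantom configuration
#'
#' Convenience wrapper mirroring the physical flow phantom: one straight
#' tube of given diameter running the length of the field of view, labeled
#' at its entry edge. The default field of view is 10 cm along the tube --
#' the experiment used a long tube, and the vessel mask must be able to
#' contain the dispersed simulated bolus even at the highest flow rates.
#'
#' @param flow Volume flow rate (ml/s).
#' @param diameter Inner diameter (mm), default 4.
#' @param ... Passed to [phantom_config()].
#' @return A `"phantom_config"`.
#' @export
tube_phantom_config <- function(flow, diameter = 4, ...) {
  cfg_args <- list(...)
  fov <- if (!is.null(cfg_args$fov_mm)) cfg_args$fov_mm else c(48.4, 101.2)
  cfg_args$fov_mm <- fov
  xc <- fov[1] / 2
  seg <- tube_segment(c(xc, 0), c(xc, fov[2]), diameter = diameter,
                      flow = flow, artery = "tube", name = "tube")
  do.call(phantom_config, c(list(segments = list(seg)), cfg_args))
}

#' Two-inlet mixing-tree phantom configuration
#'
#' Two inlet tubes carrying separately-labeled blood converge at a junction
#' into a single outlet in which the two components are fully mixed in
#' proportion to their flows. Inlet diameters scale with the square root of
#' the flow split so all segments share the same mean velocity (hence equal
#' arrival and dispersion states at the junction).
#'
#' @param flow_total Outlet volume flow rate (ml/s).
#' @param split Length-2 positive fractions summing to 1.
#' @param outlet_diameter Outlet inner diameter (mm).
#' @param junction_y Distance from the inlet entry edge to the junction (mm).
#' @param inlet_half_sep Half the horizontal separation of the inlet entry
#'   points (mm).
#' @param ... Passed to [phantom_config()].
#' @return A `"phantom_config"` with arteries `right` and `left`.
#' @export
mixing_tree_config <- function(flow_total = 1.0, split = c(0.7, 0.3),
                               outlet_diameter = 4, junction_y = 16,
                               inlet_half_sep = 10, ...) {
  if (length(split) != 2L || any(split <= 0) || abs(sum(split) - 1) > 1e-9)
    stop("'split' must be two positive fractions summing to 1")
  cfg_args <- list(...)
  fov <- if (!is.null(cfg_args$fov_mm)) cfg_args$fov_mm else c(48.4, 63.8)
  xc <- fov[1] / 2
  d_in <- outlet_diameter * sqrt(split)
  segs <- list(
    tube_segment(c(xc + inlet_half_sep, 0), c(xc, junction_y),
                 diameter = d_in[1], flow = flow_total * split[1],
                 artery = "right", name = "inlet_right"),
    tube_segment(c(xc - inlet_half_sep, 0), c(xc, junction_y),
                 diameter = d_in[2], flow = flow_total * split[2],
                 artery = "left", name = "inlet_left"),
    tube_segment(c(xc, junction_y), c(xc, fov[2]),
                 diameter = outlet_diameter, flow = flow_total,
                 parent = c("inlet_right", "inlet_left"), name = "outlet"))
  do.call(phantom_config, c(list(segments = segs), cfg_args))
}

## Rasterise the tube tree onto the voxel grid with supersampling.
## 2D mode: the projected blood volume in an in-plane voxel is the tube
## thickness along the slab axis (circle chord) integrated over the voxel
## footprint; kinetic parameters are volume-weighted voxel means.
rasterize_phantom <- function(config) {
  acq <- config$acq
  dx <- acq$voxel_dims[1]; dy <- acq$voxel_dims[2]
  ss <- config$supersample
  fov <- config$fov_mm
  nx <- max(2L, round(fov[1] / dx)); ny <- max(2L, round(fov[2] / dy))
  res <- resolve_tree(config$segments, config$dispersion)
  ## FOV containment check (segment endpoints inside the box)
  for (seg in res$segments) {
    ends <- rbind(seg$start, seg$end)
    if (any(ends[, 1] < -dx / 2) || any(ends[, 1] > fov[1] + dx / 2) ||
        any(ends[, 2] < -dy / 2) || any(ends[, 2] > fov[2] + dy / 2))
      stop(sprintf("segment '%s' lies outside the field of view", seg$name))
  }
  if (config$mode == "3d") return(rasterize_phantom_3d(config, res, nx, ny))

  fine_step_x <- dx / ss; fine_step_y <- dy / ss
  fx <- (seq_len(nx * ss) - 0.5) * fine_step_x - dx / 2
  fy <- (seq_len(ny * ss) - 0.5) * fine_step_y - dy / 2
  pts <- cbind(rep(fx, times = length(fy)),
               rep(fy, each = length(fx)), 0)
  att <- arrival_time(config$segments, pts, config$dispersion)
  seg_of <- att$segment
  r_of <- vapply(res$segments, `[[`, numeric(1), "diameter") / 2
  ## recompute chord thickness for the owning segment
  chord <- numeric(nrow(pts))
  seg_id <- match(seg_of, names(res$segments))
  for (k in seq_along(res$segments)) {
    sel <- which(seg_id == k)
    if (!length(sel)) next
    seg <- res$segments[[k]]
    u <- (seg$end - seg$start) / seg$length
    w <- sweep(pts[sel, , drop = FALSE], 2, seg$start)
    ax <- as.vector(w %*% u)
    perp2 <- pmax(rowSums(w^2) - ax^2, 0)
    chord[sel] <- 2 * sqrt(pmax(r_of[k]^2 - perp2, 0))
  }
  vol_fine <- chord * fine_step_x * fine_step_y   # mm^3 per fine point

  agg <- function(v) {  # sum fine values into coarse voxels
    a <- array(v, c(ss, nx, ss, ny))
    colSums(aperm(a, c(1, 3, 2, 4)), dims = 2L)
  }
  vol_vox <- agg(vol_fine)
  zero <- function(x) ifelse(is.na(x), 0, x)
  wmean <- function(v) {
    m <- agg(zero(v) * vol_fine) / ifelse(vol_vox > 0, vol_vox, 1)
    m[vol_vox <= 0] <- NA_real_
    m
  }
  dt_vox <- wmean(att$dt)
  s_vox <- wmean(att$s)
  p_vox <- wmean(att$p)

  ## majority-vote segment label per voxel
  lab_vox <- array(0L, c(nx, ny))
  for (k in seq_along(res$segments)) {
    vk <- agg(vol_fine * as.numeric(zero(seg_id == k)))
    lab_vox[vk > 0.5 * vol_vox & vol_vox > 0] <- k
  }

  ## per-artery volumes via the owning segment's mixing fractions
  arteries <- config$arteries
  vol_art <- lapply(arteries, function(a) {
    fa <- vapply(seq_along(res$segments), function(k) {
      mx <- res$state[[k]]$mix
      if (a %in% names(mx)) mx[[a]] else 0
    }, numeric(1))
    w <- rep(0, nrow(pts))
    ok <- !is.na(seg_id)
    w[ok] <- fa[seg_id[ok]]
    agg(vol_fine * w)
  })
  names(vol_art) <- arteries

  to3d <- function(m) array(m, c(nx, ny, 1L))
  truth <- lapply(arteries, function(a) {
    A <- config$s0_true * vol_art[[a]]
    A[A == 0] <- NA_real_
    list(A = to3d(A), dt = to3d(dt_vox), s = to3d(s_vox), p = to3d(p_vox))
  })
  names(truth) <- arteries
  list(truth = truth,
       volume = to3d(vol_vox),
       labels = to3d(lab_vox),
       segment_names = names(res$segments),
       state = res$state, nx = nx, ny = ny, nz = 1L)
}

## 3D rasterisation: per-voxel blood volume fraction by supersampling.
rasterize_phantom_3d <- function(config, res, nx, ny) {
  acq <- config$acq
  dz <- acq$voxel_dims[3]
  nz <- max(1L, round(config$fov_mm[3] / dz))
  ss <- config$supersample
  dx <- acq$voxel_dims[1]; dy <- acq$voxel_dims[2]
  fx <- (seq_len(nx * ss) - 0.5) * dx / ss - dx / 2
  fy <- (seq_len(ny * ss) - 0.5) * dy / ss - dy / 2
  fz <- (seq_len(nz * ss) - 0.5) * dz / ss - dz / 2
  vol_vox <- array(0, c(nx, ny, nz))
  dt_sum <- array(0, c(nx, ny, nz)); s_sum <- dt_sum; p_sum <- dt_sum
  lab_best <- array(0L, c(nx, ny, nz)); lab_vol <- array(0, c(nx, ny, nz))
  fine_vol <- (dx / ss) * (dy / ss) * (dz / ss)
  ## slice by z to bound memory
  for (kz in seq_along(fz)) {
    pts <- cbind(rep(fx, times = length(fy)),
                 rep(fy, each = length(fx)), fz[kz])
    att <- arrival_time(config$segments, pts, config$dispersion)
    inside <- !is.na(att$segment)
    if (!any(inside)) next
    vz <- ((kz - 1L) %/% ss) + 1L
    agg2 <- function(v) {
      a <- array(v, c(ss, nx, ss, ny))
      colSums(aperm(a, c(1, 3, 2, 4)), dims = 2L)
    }
    w <- as.numeric(inside) * fine_vol
    vol_vox[, , vz] <- vol_vox[, , vz] + agg2(w)
    zero <- function(x) ifelse(is.na(x), 0, x)
    dt_sum[, , vz] <- dt_sum[, , vz] + agg2(zero(att$dt) * w)
    s_sum[, , vz] <- s_sum[, , vz] + agg2(zero(att$s) * w)
    p_sum[, , vz] <- p_sum[, , vz] + agg2(zero(att$p) * w)
    seg_id <- match(att$segment, names(res$segments))
    for (k in seq_along(res$segments)) {
      lv <- agg2(as.numeric(zero(seg_id == k)) * fine_vol)
      upd <- lv > lab_vol[, , vz]
      lb <- lab_best[, , vz]; lb[upd] <- k
      lab_best[, , vz] <- lb
      lvv <- lab_vol[, , vz]; lvv[upd] <- lv[upd]
      lab_vol[, , vz] <- lvv
    }
  }
  has <- vol_vox > 0
  dt_vox <- ifelse(has, dt_sum / pmax(vol_vox, 1e-30), NA_real_)
  s_vox <- ifelse(has, s_sum / pmax(vol_vox, 1e-30), NA_real_)
  p_vox <- ifelse(has, p_sum / pmax(vol_vox, 1e-30), NA_real_)
  lab_best[!has] <- 0L
  arteries <- config$arteries
  truth <- lapply(arteries, function(a) {
    fa <- vapply(seq_along(res$segments), function(k) {
      mx <- res$state[[k]]$mix
      if (a %in% names(mx)) mx[[a]] else 0
    }, numeric(1))
    fmap <- array(0, dim(vol_vox))
    fmap[has] <- fa[lab_best[has]]
    A <- config$s0_true * vol_vox * fmap
    A[A == 0] <- NA_real_
    list(A = A, dt = dt_vox, s = s_vox, p = p_vox)
  })
  names(truth) <- arteries
  list(truth = truth, volume = vol_vox, labels = lab_best,
       segment_names = names(res$segments), state = res$state,
       nx = nx, ny = ny, nz = dim(vol_vox)[3])
}

## Gaussian noise for a (x, y, z, frame) block: white at the acquired
## resolution (block factor f in-plane), bilinearly interpolated onto the
## reconstruction grid, mimicking coarse acquisition + fine reconstruction.
phantom_noise <- function(d, sd, f = 1L) {
  if (f <= 1L) return(array(stats::rnorm(prod(d), sd = sd), d))
  nxc <- ceiling(d[1] / f) + 1L
  nyc <- ceiling(d[2] / f) + 1L
  xc <- (seq_len(nxc) - 1) * f + 1
  yc <- (seq_len(nyc) - 1) * f + 1
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    for (t in seq_len(d[4])) {
      coarse <- matrix(stats::rnorm(nxc * nyc, sd = sd), nxc, nyc)
      out[, , z, t] <- pracma::interp2(x = xc, y = yc, Z = t(coarse),
                                       xp = rep(seq_len(d[1]), d[2]),
                                       yp = rep(seq_len(d[2]),
                                                each = d[1]),
                                       method = "linear")
    }
  }
  out
}

#' Generate a synthetic flow-phantom acquisition
#'
#' Rasterises the tube network onto the voxel grid (partial volume by
#' supersampling; 2D mode projects along the slab axis), assigns each voxel
#' its ground-truth kinetic parameters (`A = s0_true *` blood volume,
#' transit time and accrued dispersion from plug-flow kinematics),
#' synthesises the per-artery frame signals with the forward model, combines
#' them into encoding-cycle images with a static component, and adds seeded
#' Gaussian noise. The full ground truth is returned alongside.
#'
#' @param config A [phantom_config()].
#' @return An object of class `"angio_phantom"`: `cycles` (list of 4D
#'   arrays), `scheme`, `acq`, `truth` (per-artery ground-truth parameter
#'   maps plus `s0_true`, blood `volume` map, segment `labels` and flows),
#'   `mask` (a [vessel_mask()] labeled by segment), `clean` (noiseless
#'   decoded per-artery series), `noise_sd`, `config`.
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop("'config' must be a phantom_config")
  acq <- config$acq
  ras <- rasterize_phantom(config)
  nt <- length(acq$frame_times)
  dims <- c(ras$nx, ras$ny, ras$nz)

  ## per-artery noiseless signals
  comp <- lapply(config$arteries, function(a) {
    tr <- ras$truth[[a]]
    arr <- array(0, c(dims, nt))
    idx <- which(!is.na(tr$A) & tr$A > 0)
    flat <- matrix(arr, nrow = prod(dims), ncol = nt)
    for (i in idx) {
      flat[i, ] <- forward_signal(list(A = tr$A[i], dt = tr$dt[i],
                                       s = tr$s[i], p = tr$p[i]), acq)
    }
    array(flat, c(dims, nt))
  })
  names(comp) <- config$arteries

  ## static (unlabeled water) component: proportional to water volume
  static_vox <- config$static_level * config$s0_true * ras$volume
  static_arr <- array(rep(as.vector(static_vox), nt), c(dims, nt))

  ## cycle images per the encoding scheme
  E <- config$scheme$matrix
  comps_all <- c(list(static_arr), comp)
  cycles <- lapply(seq_len(nrow(E)), function(cy) {
    Reduce(`+`, Map(function(w, a) w * a, E[cy, ], comps_all))
  })

  ## noise level from the requested decoded-series peak SNR
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    peak <- max(vapply(comp, max, numeric(1)))
    g <- sqrt(max(diag(solve(crossprod(E)))[-1]))
    noise_sd <- if (is.finite(peak) && peak > 0)
      peak / (config$peak_snr * g) else 0
  }
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
    f <- max(1, round(config$acquired_voxel_mm / acq$voxel_dims[1]))
    cycles <- lapply(cycles, function(a)
      a + phantom_noise(dim(a), noise_sd, f))
  }

  labs <- ras$labels
  mask <- vessel_mask(labs, stats::setNames(seq_along(ras$segment_names),
                                            ras$segment_names))
  flows <- data.frame(
    segment = vapply(config$segments, `[[`, character(1), "name"),
    flow_ml_s = vapply(config$segments, `[[`, numeric(1), "flow"),
    diameter_mm = vapply(config$segments, `[[`, numeric(1), "diameter"),
    stringsAsFactors = FALSE)

  structure(list(cycles = cycles, scheme = config$scheme, acq = acq,
                 truth = c(ras$truth,
                           list(s0_true = config$s0_true,
                                volume = ras$volume, labels = labs,
                                flows = flows, state = ras$state)),
                 mask = mask,
                 clean = dynamic_series(static_arr, acq, components = comp),
                 noise_sd = noise_sd, config = config),
            class = "angio_phantom")
}

#' @export
print.angio_phantom <- function(x, ...) {
  d <- dim(x$cycles[[1]])
  cat(sprintf(
    "Synthetic flow phantom: %d cycle(s) of %d x %d x %d voxels x %d frames\n",
    length(x$cycles), d[1], d[2], d[3], d[4]))
  cat(sprintf("  arteries: %s; noise SD %.4g; S0_true %.4g\n",
              paste(x$config$arteries, collapse = ", "), x$noise_sd,
              x$truth$s0_true))
  print(x$truth$flows)
  invisible(x)
}
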