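#' Vessel-encoding scheme
#'
#' Linear model mapping component amplitudes (static water plus one labeled
#' component per feeding artery) to the signal measured in each encoding
#' cycle. Row `c` of the matrix gives the coefficients of
#' `(static, artery_1, ..., artery_K)` in cycle `c`: the static column is 1
#' in every cycle and an artery column is 1 in cycles where that artery is
#' tagged and 0 where it is controlled.
#'
#' @param matrix Numeric matrix, rows = encoding cycles (>= columns), full
#'   column rank; first column = static.
#' @param cycle_names Optional row labels.
#' @param artery_names Optional names for the artery columns.
#' @return An object of class `"encoding_scheme"`.
#' @export
encoding_scheme <- function(matrix, cycle_names = NULL, artery_names = NULL) {
  E <- as.matrix(matrix)
  if (nrow(E) < ncol(E))
    stop("encoding scheme needs at least as many cycles as components")
  if (qr(E)$rank < ncol(E))
    stop("encoding scheme matrix is rank deficient")
  if (is.null(artery_names))
    artery_names <- paste0("artery_", seq_len(ncol(E) - 1L))
  colnames(E) <- c("static", artery_names)
  if (!is.null(cycle_names)) rownames(E) <- cycle_names
  structure(list(matrix = E, arteries = artery_names),
            class = "encoding_scheme")
}

#' Four-cycle scheme for a two-tube (two-artery) experiment
#'
#' Non-selective tag, non-selective control, tag right whilst controlling
#' left, and tag left whilst controlling right.
#'
#' @param artery_names Names for the two arteries.
#' @return An [encoding_scheme()] with 4 cycles and 3 components.
#' @export
encoding_two_tube <- function(artery_names = c("right", "left")) {
  encoding_scheme(rbind(c(1, 1, 1),   # non-selective tag
                        c(1, 0, 0),   # non-selective control
                        c(1, 1, 0),   # tag right / control left
                        c(1, 0, 1)),  # tag left  / control right
                  cycle_names = c("ns_tag", "ns_control",
                                  "tag_right", "tag_left"),
                  artery_names = artery_names)
}

#' Two-cycle tag/control scheme for a single artery
#' @param artery_name Name of the artery.
#' @return An [encoding_scheme()] with 2 cycles and 2 components.
#' @export
encoding_single <- function(artery_name = "artery_1") {
  encoding_scheme(rbind(c(1, 1), c(1, 0)),
                  cycle_names = c("tag", "control"),
                  artery_names = artery_name)
}

#' Decode encoding cycles into per-artery components
#'
#' Per voxel and frame, solves the encoding linear model in the least-squares
#' sense for the component amplitudes. With as many cycles as components and
#' no noise the decomposition is exact, and re-encoding the components
#' reproduces the cycle data.
#'
#' @param cycles List of 4D arrays (one per encoding cycle, identical shape),
#'   or a 5D array with the cycle as the fifth axis.
#' @param scheme An [encoding_scheme()]; `nrow(scheme$matrix)` must equal the
#'   number of cycles.
#' @param acq An [acq_params()] object for the decoded series.
#' @return A [dynamic_series()] whose `data` is the static component and
#'   whose `components` are the per-artery labeled series.
#' @export
decode_components <- function(cycles, scheme, acq) {
  if (!inherits(scheme, "encoding_scheme"))
    stop("'scheme' must be an encoding_scheme")
  E <- scheme$matrix
  if (is.array(cycles) && length(dim(cycles)) == 5L) {
    cycles <- lapply(seq_len(dim(cycles)[5]),
                     function(c5) cycles[, , , , c5])
  }
  if (length(cycles) != nrow(E))
    stop(sprintf("got %d cycles but the scheme has %d rows",
                 length(cycles), nrow(E)))
  d <- dim(as.array(cycles[[1]]))
  if (length(d) == 3L) d <- c(d[1:2], 1L, d[3])
  Y <- vapply(cycles, function(a) {
    a <- as.array(a)
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3])
    if (!all(dim(a) == d)) stop("cycle arrays differ in shape")
    as.vector(a)
  }, numeric(prod(d)))
  ## Y: (voxel*frame) x cycles; solve E X = t(Y) in least squares
  X <- t(qr.coef(qr(E), t(Y)))
  static <- array(X[, 1], d)
  comps <- lapply(seq_along(scheme$arteries),
                  function(j) array(X[, j + 1L], d))
  names(comps) <- scheme$arteries
  dynamic_series(static, acq, components = comps)
}

#' Re-encode decoded components into cycle data
#'
#' Inverse of [decode_components()] for checking round trips: applies the
#' encoding matrix to the static + per-artery components.
#'
#' @param series A [dynamic_series()] with components.
#' @param scheme An [encoding_scheme()].
#' @return List of per-cycle 4D arrays.
#' @export
encode_components <- function(series, scheme) {
  E <- scheme$matrix
  comps <- c(list(series$data), unname(series$components))
  lapply(seq_len(nrow(E)), function(cy) {
    Reduce(`+`, Map(function(w, a) w * a, E[cy, ], comps))
  })
}

#' High-signal mask for kinetic model fitting
#'
#' Restricts fitting to voxels carrying real vascular signal. Two masks are
#' built -- one from the temporal mean and one from the temporal maximum of
#' the series -- and their intersection is used. The maximum-based criterion
#' retains proximal voxels where blood washes out so rapidly that the mean
#' signal is low.
#'
#' Each statistic is thresholded at `median(map) + k * 1.4826 * mad(map)`,
#' a robust z-score against that statistic's own (background-dominated)
#' distribution; scaling each threshold to its statistic's noise level is
#' what lets a high-max/low-mean washout voxel clear the mean criterion. A
#' `"quantile"` mode thresholding each statistic at a quantile of its values
#' over above-noise voxels is also available.
#'
#' @param series A [dynamic_series()] or 4D array.
#' @param k_mean,k_max Robust z-score thresholds (method `"mad"`), default 4:
#'   permissive enough to retain partial-volume vessel edges (whose exclusion
#'   directly underestimates blood volume and hence flow) while keeping the
#'   false-positive rate of the background temporal-max statistic negligible.
#' @param method `"mad"` (default) or `"quantile"`.
#' @param q_mean,q_max Quantiles used by method `"quantile"` (default 0.9),
#'   applied to each statistic over voxels exceeding 5x the robust noise SD.
#' @return An object of class `"high_signal_mask"`: logical `mask` plus the
#'   thresholds used.
#' @export
high_signal_mask <- function(series, k_mean = 4, k_max = 4,
                             method = c("mad", "quantile"),
                             q_mean = 0.9, q_max = 0.9) {
  method <- match.arg(method)
  data <- if (inherits(series, "dynamic_series")) series$data else as.array(series)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  d <- dim(data)
  nvox <- prod(d[1:3])
  mat <- matrix(data, nrow = nvox, ncol = d[4])
  mean_map <- rowMeans(mat)
  max_map <- apply(mat, 1L, max)
  if (max(mean_map) == min(mean_map) && max(max_map) == min(max_map))
    stop("degenerate series: all voxels identical")
  thr_of <- function(map, k, q) {
    if (method == "mad") {
      stats::median(map) + k * stats::mad(map)
    } else {
      sig <- stats::mad(as.vector(mat))
      cand <- map[map > 5 * sig]
      if (length(cand) == 0L) cand <- map
      stats::quantile(cand, q, names = FALSE)
    }
  }
  thr_mean <- thr_of(mean_map, k_mean, q_mean)
  thr_max <- thr_of(max_map, k_max, q_max)
  mask <- array(mean_map > thr_mean & max_map > thr_max, d[1:3])
  structure(list(mask = mask,
                 thresholds = c(mean = thr_mean, max = thr_max),
                 method = method),
            class = "high_signal_mask")
}

#' @export
print.high_signal_mask <- function(x, ...) {
  cat(sprintf(
    "High-signal mask: %d voxels (mean thr %.4g, max thr %.4g, %s rule)\n",
    sum(x$mask), x$thresholds["mean"], x$thresholds["max"], x$method))
  invisible(x)
}

#' Estimate the earliest arrival time of labeled blood
#'
#' Simple data-driven estimate of `dt_min`: the earliest frame time at which
#' any voxel rises above a noise-scaled threshold, minus one frame interval
#' (arrival occurred between that frame and the previous one).
#'
#' @param series A [dynamic_series()] or 4D array.
#' @param k Robust z threshold (default 5).
#' @return Estimated `dt_min` in seconds (`>= 0`).
#' @export
estimate_dt_min <- function(series, k = 5) {
  data <- if (inherits(series, "dynamic_series")) series$data else as.array(series)
  ft <- if (inherits(series, "dynamic_series")) series$acq$frame_times else
    seq_len(dim(data)[length(dim(data))])
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  nvox <- prod(dim(data)[1:3])
  mat <- matrix(data, nrow = nvox)
  thr <- stats::median(mat) + k * stats::mad(as.vector(mat))
  hit <- which(apply(mat, 2L, max) > thr)
  if (length(hit) == 0L) return(0)
  df <- if (length(ft) > 1) stats::median(diff(ft)) else 0
  max(0, ft[min(hit)] - df)
}
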