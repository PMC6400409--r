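#' Ground truth for a synthetic joint-motion experiment
#'
#' Bundles everything the synthetic-data generator needs to produce a
#' flexion gesture about a planted screw axis, together with the values a
#' recovery test must reproduce: the axis (point + unit direction), the
#' flexion-angle profile over time, the axial (medial-lateral) translation
#' profile as a function of flexion angle, and the two noise levels of the
#' emulated instruments (marker tracking and surface digitization).
#'
#' Defaults emulate the in vitro protocol the package validates against:
#' a smooth flexion ramp 0 to 91 degrees over 40 s sampled at 100 Hz
#' (`dt = 0.01` s), marker noise 0.012 mm, surface noise 0.02 mm.
#'
#' @param axis_point 3-vector (mm): a point on the planted flexion axis.
#' @param axis_direction 3-vector: axis direction, normalized internally.
#' @param angle_profile Function of time (s) returning flexion in degrees;
#'   must be monotone non-decreasing over `[0, duration]`.
#' @param axial_translation_profile Function of flexion angle (degrees)
#'   returning translation along the axis in mm.
#' @param marker_noise_sigma Marker coordinate noise SD, mm.
#' @param surface_noise_sigma Surface digitization noise SD, mm.
#' @param dt Sampling interval, s.
#' @param duration Gesture duration, s.
#' @param seed Integer seed associated with the scenario.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(axis_point = c(30, -20, 15),
                         axis_direction = c(0.15, -0.08, 0.98),
                         angle_profile = smoothstep_profile(0, 91, 40),
                         axial_translation_profile = function(theta_deg) rep(0, length(theta_deg)),
                         marker_noise_sigma = 0.012,
                         surface_noise_sigma = 0.02,
                         dt = 0.01,
                         duration = 40,
                         seed = 1L) {
  stopifnot(is.function(angle_profile), is.function(axial_translation_profile))
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (!(duration > 0)) stop("duration must be positive", call. = FALSE)
  if (marker_noise_sigma < 0 || surface_noise_sigma < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  n <- unitize(vec3(axis_direction))
  truth <- structure(list(
    axis_point = vec3(axis_point),
    axis_direction = n,
    angle_profile = angle_profile,
    axial_translation_profile = axial_translation_profile,
    marker_noise_sigma = marker_noise_sigma,
    surface_noise_sigma = surface_noise_sigma,
    dt = dt,
    duration = duration,
    seed = as.integer(seed)
  ), class = "ground_truth")
  check_monotone_profile(truth)
  truth
}

# The angle profile must be monotone non-decreasing: a flexion gesture,
# not an oscillation. Checked on the sampling grid actually used.
check_monotone_profile <- function(truth) {
  t <- truth_times(truth)
  th <- truth$angle_profile(t)
  if (length(th) != length(t) || anyNA(th)) {
    stop("angle_profile must be vectorized over time and return finite values",
         call. = FALSE)
  }
  if (any(diff(th) < -1e-9)) {
    stop("invalid scenario: angle_profile must be monotone non-decreasing",
         call. = FALSE)
  }
  invisible(truth)
}

truth_times <- function(truth) {
  seq(0, truth$duration, by = truth$dt)
}

#' @export
print.ground_truth <- function(x, ...) {
  t <- truth_times(x)
  th <- x$angle_profile(t)
  cat("Synthetic joint-motion ground truth\n")
  cat(sprintf("  frames: %d (dt = %g s, duration = %g s)\n", length(t), x$dt, x$duration))
  cat(sprintf("  flexion: %.2f to %.2f deg\n", th[1L], th[length(t)]))
  cat(sprintf("  axis through (%.2f, %.2f, %.2f), direction (%.4f, %.4f, %.4f)\n",
              x$axis_point[1L], x$axis_point[2L], x$axis_point[3L],
              x$axis_direction[1L], x$axis_direction[2L], x$axis_direction[3L]))
  cat(sprintf("  noise: markers %g mm, surfaces %g mm\n",
              x$marker_noise_sigma, x$surface_noise_sigma))
  invisible(x)
}

#' Smooth monotone ramp profile
#'
#' C1 "smoothstep" ramp from `from` to `to` degrees over `duration` seconds:
#' \eqn{\theta(t) = \theta_0 + \Delta\theta\,(3u^2 - 2u^3)} with
#' \eqn{u = t/T} clamped to `[0, 1]`. Starts and ends with zero angular
#' velocity, emulating a smooth manual actuation.
#'
#' @param from,to Start and end angles, degrees.
#' @param duration Ramp duration, s.
#' @return A vectorized function of time (s) returning degrees.
#' @export
smoothstep_profile <- function(from, to, duration) {
  force(from); force(to); force(duration)
  function(t) {
    u <- clamp(t / duration, 0, 1)
    from + (to - from) * (3 * u^2 - 2 * u^3)
  }
}

#' Piecewise-cubic profile with planted extrema
#'
#' Cubic Hermite interpolant through `(x, y)` knots with zero slope at every
#' knot, so the curve attains its extrema exactly at the knots and stays
#' within the knot value range on each interval. Used to plant displacement
#' profiles whose printed endpoint/extreme values must be recovered exactly.
#'
#' @param x Strictly increasing knot abscissae.
#' @param y Knot values.
#' @return A vectorized function; constant extrapolation outside the knots.
#' @export
hermite_profile <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, all(diff(x) > 0))
  force(x); force(y)
  function(q) {
    q <- clamp(q, x[1L], x[length(x)])
    i <- findInterval(q, x, rightmost.closed = TRUE)
    u <- (q - x[i]) / (x[i + 1L] - x[i])
    s <- 3 * u^2 - 2 * u^3
    y[i] + (y[i + 1L] - y[i]) * s
  }
}

#' Marker-cluster geometry
#'
#' Body-frame offsets of the optical markers of one tracking cluster.
#' At least three non-collinear markers are required for a rigid pose fit.
#'
#' @param offsets Numeric M x 3 matrix of marker offsets (mm) in the body
#'   frame, rows named with marker names (names generated if absent).
#' @return An object of class `cluster_geometry` (an M x 3 matrix).
#' @export
cluster_geometry <- function(offsets) {
  offsets <- as.matrix(offsets)
  storage.mode(offsets) <- "double"
  if (ncol(offsets) != 3L) stop("offsets must be an M x 3 matrix", call. = FALSE)
  if (nrow(offsets) < 3L) stop("a cluster needs at least 3 markers", call. = FALSE)
  centred <- sweep(offsets, 2L, colMeans(offsets))
  sv <- svd(centred, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9) stop("degenerate geometry: cluster markers are collinear", call. = FALSE)
  if (is.null(rownames(offsets))) {
    rownames(offsets) <- paste0("m", seq_len(nrow(offsets)))
  }
  structure(offsets, class = c("cluster_geometry", "matrix", "array"))
}
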