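# Decomposition of the measured joint motion into the six displacement
# components expressed in the anatomical frame, and aggregation of
# multi-trial displacement-vs-flexion curves with Student-t error bars.

identity_pose <- function() list(R = diag(3), O = c(0, 0, 0))

# Generalized cumulative product W_i = R_i %*% t(Rref), vectorized.
relative_rotations_rows <- function(R9, Rref) {
  C <- matrix(0, nrow(R9), 9L)
  for (a in 1:3) for (b in 1:3) {
    C[, e9(a, b)] <- R9[, e9(a, 1L)] * Rref[b, 1L] +
      R9[, e9(a, 2L)] * Rref[b, 2L] +
      R9[, e9(a, 3L)] * Rref[b, 3L]
  }
  C
}

# Conjugation D_i = t(U) %*% W_i %*% U per row, vectorized.
conjugate_rows <- function(W9, U) {
  WU <- matrix(0, nrow(W9), 9L)
  for (a in 1:3) for (b in 1:3) {
    WU[, e9(a, b)] <- W9[, e9(a, 1L)] * U[1L, b] +
      W9[, e9(a, 2L)] * U[2L, b] +
      W9[, e9(a, 3L)] * U[3L, b]
  }
  D <- matrix(0, nrow(W9), 9L)
  for (a in 1:3) for (b in 1:3) {
    D[, e9(a, b)] <- U[1L, a] * WU[, e9(1L, b)] +
      U[2L, a] * WU[, e9(2L, b)] +
      U[3L, a] * WU[, e9(3L, b)]
  }
  D
}

#' Express a pose displacement in the anatomical joint frame
#'
#' Forms the world displacement relative to the reference pose,
#' \eqn{W = P\,P_{ref}^{-1}}, and changes basis into the joint frame:
#' \eqn{D = G^{-1} W G} with `G` the joint frame (axes `U`, origin
#' `O_beta`). The result is the rigid displacement of the moving bone as
#' seen on the joint axes: its rotation feeds the Tait-Bryan decomposition
#' and its translation is the origin displacement on (U_X, U_Y, U_Z).
#'
#' @param pose List with `R` (3 x 3) and `O` (3-vector, mm): the pose of the
#'   moving bone in the fixed-bone frame.
#' @param frame An `anatomical_frame`.
#' @param reference_pose Reference (maximum-extension) pose, same structure;
#'   default the identity pose.
#' @return List with `R` (3 x 3) and `t` (3-vector, mm), the displacement
#'   in joint-frame coordinates.
#' @export
pose_in_joint_frame <- function(pose, frame, reference_pose = identity_pose()) {
  stopifnot(inherits(frame, "anatomical_frame"))
  Rw <- pose$R %*% t(reference_pose$R)
  tw <- pose$O - Rw %*% reference_pose$O
  U <- frame$U
  Ob <- frame$origin
  list(R = t(U) %*% Rw %*% U,
       t = as.vector(t(U) %*% (Rw %*% Ob + tw - Ob)))
}

#' Tait-Bryan decomposition of a joint-frame displacement
#'
#' Factors the displacement rotation as an intrinsic Z-Y-X cascade,
#' \eqn{R = Rot_Z(R_Z)\,Rot_Y(R_Y)\,Rot_X(R_X)}, so that the first
#' extracted angle is the flexion rotation about `U_Z`; the translations
#' are the components of the displacement translation on the joint axes.
#' Near gimbal lock (`|R_Y|` > 89.9 degrees) the sample is flagged.
#'
#' @param disp List with `R` and `t` as returned by
#'   [pose_in_joint_frame()].
#' @return Named numeric vector `R_Z`, `R_Y`, `R_X` (degrees), `T_X`,
#'   `T_Y`, `T_Z` (mm); attribute `gimbal` TRUE near the singularity.
#' @export
decompose_tait_bryan <- function(disp) {
  R <- disp$R
  ry <- asin(clamp(-R[3L, 1L], -1, 1))
  out <- c(R_Z = rad2deg(atan2(R[2L, 1L], R[1L, 1L])),
           R_Y = rad2deg(ry),
           R_X = rad2deg(atan2(R[3L, 2L], R[3L, 3L])),
           T_X = disp$t[1L], T_Y = disp$t[2L], T_Z = disp$t[3L])
  attr(out, "gimbal") <- abs(rad2deg(ry)) > 89.9
  out
}

#' Instantaneous flexion angle from the carpal centre
#'
#' Tracks the carpal centre through the joint displacement and measures the
#' signed angle, in the U_X U_Y plane, between the projected vector from
#' `O_beta` to the displaced carpal centre and the zero-flexion reference
#' direction (by default, the projected direction at the reference pose).
#'
#' @param disp Joint-frame displacement (list `R`, `t`).
#' @param C_W_joint Carpal centre at the reference pose, in joint-frame
#'   coordinates (mm): `t(U) %*% (C_W - O_beta)`.
#' @param zero_direction Optional in-plane 2-vector defining zero flexion;
#'   default the projection of `C_W_joint`.
#' @return Flexion angle, degrees, increasing with flexion.
#' @export
flexion_angle <- function(disp, C_W_joint, zero_direction = NULL) {
  C_W_joint <- vec3(C_W_joint)
  p0 <- if (is.null(zero_direction)) C_W_joint[1:2] else as.numeric(zero_direction)[1:2]
  ct <- disp$R %*% C_W_joint + disp$t
  p <- ct[1:2]
  if (sqrt(sum(p0^2)) < 1e-6 || sqrt(sum(p^2)) < 1e-6) {
    stop("degenerate projection: forearm vector has no U_X U_Y component",
         call. = FALSE)
  }
  rad2deg(atan2(p0[1L] * p[2L] - p0[2L] * p[1L], sum(p0 * p)))
}

#' Per-frame six-DoF displacement samples of a pose series
#'
#' Vectorized pipeline stage: expresses every pose of a series in the joint
#' frame relative to the reference pose, decomposes it into the six
#' displacement components and the instantaneous flexion angle (tracked via
#' the carpal centre).
#'
#' @param poses A `pose_series`.
#' @param frame An `anatomical_frame`.
#' @param C_W Carpal centre at the reference configuration, fixed-frame
#'   coordinates (mm); a `carpal_centre` object is also accepted.
#' @param reference_pose Reference pose (default identity).
#' @param trial_id Identifier stored in the `trial` column.
#' @return Data frame of class `dof_samples`: `trial`, `time`,
#'   `flexion_deg`, `R_Z`, `R_Y`, `R_X` (degrees), `T_X`, `T_Y`, `T_Z`
#'   (mm), `gimbal`.
#' @export
dof_samples <- function(poses, frame, C_W, reference_pose = identity_pose(),
                        trial_id = 1L) {
  stopifnot(inherits(poses, "pose_series"), inherits(frame, "anatomical_frame"))
  if (inherits(C_W, "carpal_centre")) C_W <- C_W$C_W
  C_W <- vec3(C_W)
  U <- frame$U
  Ob <- frame$origin
  N <- length(poses$times)

  R9 <- rot_to_rows(poses$rotations)
  W9 <- relative_rotations_rows(R9, reference_pose$R)
  D9 <- conjugate_rows(W9, U)

  # translations: t_d = U^T (W O_beta + t_w - O_beta), t_w = O - W O_ref
  WOb <- t(apply_rotations(array(t(W9), c(3L, 3L, N)), Ob - reference_pose$O))
  v <- WOb + poses$origins - matrix(Ob, N, 3L, byrow = TRUE)
  td <- v %*% U

  ry <- asin(clamp(-D9[, e9(3L, 1L)], -1, 1))
  rz <- atan2(D9[, e9(2L, 1L)], D9[, e9(1L, 1L)])
  rx <- atan2(D9[, e9(3L, 2L)], D9[, e9(3L, 3L)])

  # carpal-centre track for the instantaneous flexion angle
  c0 <- as.vector(t(U) %*% (C_W - Ob))
  ct <- t(apply_rotations(array(t(D9), c(3L, 3L, N)), c0)) + td
  p0 <- c0[1:2]
  if (sqrt(sum(p0^2)) < 1e-6) {
    stop("degenerate projection: carpal centre lies on the flexion axis",
         call. = FALSE)
  }
  flex <- rad2deg(atan2(p0[1L] * ct[, 2L] - p0[2L] * ct[, 1L],
                        ct[, 1L] * p0[1L] + ct[, 2L] * p0[2L]))

  out <- data.frame(trial = trial_id,
                    time = poses$times,
                    flexion_deg = flex,
                    R_Z = rad2deg(rz), R_Y = rad2deg(ry), R_X = rad2deg(rx),
                    T_X = td[, 1L], T_Y = td[, 2L], T_Z = td[, 3L],
                    gimbal = abs(rad2deg(ry)) > 89.9)
  class(out) <- c("dof_samples", "data.frame")
  out
}

dof_names <- c("R_X", "R_Y", "T_X", "T_Y", "T_Z")

#' Student-t critical value
#'
#' Two-tailed critical value \eqn{t_{1-\alpha/2,\,df}} of the Student-t
#' distribution, as used for the error bars of the displacement curves
#' (e.g. 2.064 for 24 degrees of freedom at the 5% level).
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical value.
#' @export
t_critical <- function(df, alpha = 0.05) {
  if (!(is.numeric(df) && length(df) == 1L && df >= 1)) {
    stop("df must be a single value >= 1", call. = FALSE)
  }
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  stats::qt(1 - alpha / 2, df)
}

#' Aggregate multi-trial displacement curves on a flexion grid
#'
#' Interpolates each trial's displacement-vs-flexion samples onto a common
#' flexion grid and computes, per grid point and per DoF, the across-trial
#' mean and the confidence half-width \eqn{t_{1-\alpha/2,\,n-1}\, s/\sqrt n}
#' (with `s` the across-trial standard deviation and `n` the number of
#' trials covering that grid point). Trials are aligned by flexion angle,
#' not time, so differing actuation speeds are comparable. Grid points
#' outside a trial's flexion range exclude that trial there; the counts are
#' reported.
#'
#' @param samples A `dof_samples` data frame (multiple trials stacked).
#' @param grid Flexion grid in degrees; default a 1-degree grid over the
#'   range common to all trials.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A list of class `dof_curves`: `flexion_grid`, `mean` and
#'   `half_width` (G x 5 matrices, columns `R_X`, `R_Y`, `T_X`, `T_Y`,
#'   `T_Z`), `n_trials`, `n_used` (per grid point), `t_critical`, `alpha`.
#' @export
aggregate_curves <- function(samples, grid = NULL, alpha = 0.05) {
  trials <- unique(samples$trial)
  n <- length(trials)
  if (n < 2L) stop("need at least 2 trials to aggregate", call. = FALSE)
  rng <- vapply(trials, function(tr) {
    f <- samples$flexion_deg[samples$trial == tr]
    c(min(f), max(f))
  }, numeric(2L))
  if (is.null(grid)) {
    lo <- ceiling(max(rng[1L, ]))
    hi <- floor(min(rng[2L, ]))
    if (hi <= lo) stop("trials share no common flexion range", call. = FALSE)
    grid <- seq(lo, hi, by = 1)
  }
  G <- length(grid)
  vals <- array(NA_real_, c(G, length(dof_names), n),
                dimnames = list(NULL, dof_names, NULL))
  for (j in seq_len(n)) {
    tr <- samples[samples$trial == trials[j], ]
    ord <- order(tr$flexion_deg)
    f <- tr$flexion_deg[ord]
    for (dof in dof_names) {
      vals[, dof, j] <- stats::approx(f, tr[[dof]][ord], xout = grid,
                                      ties = mean, rule = 1)$y
    }
  }
  n_used <- apply(!is.na(vals[, 1L, , drop = FALSE]), 1L, sum)
  mu <- apply(vals, c(1L, 2L), mean, na.rm = TRUE)
  sd_ <- apply(vals, c(1L, 2L), stats::sd, na.rm = TRUE)
  tcrit <- t_critical(n - 1L, alpha)
  hw <- sd_ / sqrt(pmax(n_used, 1))
  for (dof in dof_names) {
    hw[, dof] <- ifelse(n_used >= 2L,
                        t_critical_vec(n_used - 1L, alpha) * hw[, dof],
                        NA_real_)
  }
  structure(list(flexion_grid = grid, mean = mu, half_width = hw,
                 n_trials = n, n_used = n_used,
                 n_excluded = sum(n - n_used),
                 t_critical = tcrit, alpha = alpha),
            class = "dof_curves")
}

t_critical_vec <- function(df, alpha) stats::qt(1 - alpha / 2, df)

#' @export
print.dof_curves <- function(x, ...) {
  cat(sprintf("DoF curves: %d grid points (%g to %g deg flexion), %d trials, t = %.3f (alpha = %g)\n",
              length(x$flexion_grid), min(x$flexion_grid), max(x$flexion_grid),
              x$n_trials, x$t_critical, x$alpha))
  rng <- apply(x$mean, 2L, range)
  for (dof in colnames(x$mean)) {
    unit <- if (startsWith(dof, "T")) "mm" else "deg"
    cat(sprintf("  %s: %.4g to %.4g %s\n", dof, rng[1L, dof], rng[2L, dof], unit))
  }
  invisible(x)
}

#' Screen DoF curves against measurement uncertainty
#'
#' A DoF is flagged significant when the lower edge of its confidence band,
#' `|mean| - half_width`, exceeds the measurement uncertainty of its family
#' somewhere on the flexion grid. Translations are compared against the
#' marker-tracking uncertainty (default 0.012 mm); rotations against its
#' angular equivalent over the marker-cluster span,
#' \eqn{\sigma / r_{rms}} radians with \eqn{r_{rms}} the RMS marker
#' distance from the cluster centroid (see [rotation_uncertainty_deg()]).
#'
#' @param curves A `dof_curves`.
#' @param translation_uncertainty_mm Uncertainty for T_X, T_Y, T_Z (mm).
#' @param rotation_uncertainty_deg Uncertainty for R_X, R_Y (degrees);
#'   default assumes sigma = 0.012 mm over a 10 mm RMS cluster radius.
#' @return Named logical vector over `R_X`, `R_Y`, `T_X`, `T_Y`, `T_Z`.
#' @export
significance_screen <- function(curves,
                                translation_uncertainty_mm = 0.012,
                                rotation_uncertainty_deg = NULL) {
  stopifnot(inherits(curves, "dof_curves"))
  if (is.null(rotation_uncertainty_deg)) {
    rotation_uncertainty_deg <- rad2deg(translation_uncertainty_mm / 10)
  }
  unc <- c(R_X = rotation_uncertainty_deg, R_Y = rotation_uncertainty_deg,
           T_X = translation_uncertainty_mm, T_Y = translation_uncertainty_mm,
           T_Z = translation_uncertainty_mm)
  out <- logical(length(dof_names))
  names(out) <- dof_names
  for (dof in dof_names) {
    lower <- abs(curves$mean[, dof]) - curves$half_width[, dof]
    out[dof] <- any(lower > unc[dof], na.rm = TRUE)
  }
  out
}

#' Angular equivalent of the marker-tracking uncertainty
#'
#' Propagates the marker coordinate uncertainty to an orientation
#' uncertainty over a cluster: an uncertainty `sigma_mm` across the RMS
#' marker radius `r_rms` subtends `sigma_mm / r_rms` radians.
#'
#' @param sigma_mm Marker coordinate uncertainty, mm.
#' @param geom Optional `cluster_geometry`; its RMS centroid distance is
#'   used for `r_rms`.
#' @param r_rms RMS marker distance from the cluster centroid, mm (used
#'   when `geom` is missing).
#' @return Uncertainty in degrees.
#' @export
rotation_uncertainty_deg <- function(sigma_mm, geom = NULL, r_rms = 10) {
  if (!is.null(geom)) {
    g <- sweep(unclass(geom), 2L, colMeans(unclass(geom)))
    r_rms <- sqrt(mean(rowSums(g * g)))
  }
  rad2deg(sigma_mm / r_rms)
}

#' Write DoF curves to CSV
#'
#' Columns: `flexion_deg`, then `<dof>_mean` and `<dof>_half_width` for
#' each of R_X, R_Y, T_X, T_Y, T_Z, plus `n_trials_used`.
#'
#' @param curves A `dof_curves`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dof_curves_csv <- function(curves, path) {
  out <- data.frame(flexion_deg = curves$flexion_grid)
  for (dof in colnames(curves$mean)) {
    out[[paste0(dof, "_mean")]] <- curves$mean[, dof]
    out[[paste0(dof, "_half_width")]] <- curves$half_width[, dof]
  }
  out$n_trials_used <- curves$n_used
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a flexion-to-DoF coupling table
#'
#' Downsamples a DoF mean curve to evenly spaced knots suitable as a
#' coupling (spline) table for musculoskeletal modelling tools: flexion
#' angle in degrees against the coupled displacement.
#'
#' @param curves A `dof_curves`.
#' @param path Output CSV path.
#' @param dof Which DoF to export (default `"T_Z"`, the medial-lateral
#'   translation).
#' @param n_knots Number of knots (default 10).
#' @return The knot data frame, invisibly.
#' @export
export_coupling_table <- function(curves, path, dof = "T_Z", n_knots = 10L) {
  stopifnot(dof %in% colnames(curves$mean))
  idx <- unique(round(seq(1L, length(curves$flexion_grid), length.out = n_knots)))
  knots <- data.frame(flexion_deg = curves$flexion_grid[idx],
                      value = curves$mean[idx, dof])
  names(knots)[2L] <- dof
  utils::write.csv(knots, path, row.names = FALSE)
  invisible(knots)
}
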