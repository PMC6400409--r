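# Forward models: rigid pose series of a screw joint (and, more generally,
# of a 6-DoF joint-frame displacement program). These are the generators the
# analysis pipeline is validated against by parameter recovery.

# 3 x 3 x N rotation array about one fixed unit axis, vectorized over angles.
rotations_about_axis <- function(n, phis) {
  n <- unitize(vec3(n))
  cp <- cos(phis); sp <- sin(phis); vp <- 1 - cp
  N <- length(phis)
  R <- array(0, c(3L, 3L, N))
  R[1L, 1L, ] <- cp + vp * n[1L]^2
  R[2L, 1L, ] <- vp * n[1L] * n[2L] + sp * n[3L]
  R[3L, 1L, ] <- vp * n[1L] * n[3L] - sp * n[2L]
  R[1L, 2L, ] <- vp * n[1L] * n[2L] - sp * n[3L]
  R[2L, 2L, ] <- cp + vp * n[2L]^2
  R[3L, 2L, ] <- vp * n[2L] * n[3L] + sp * n[1L]
  R[1L, 3L, ] <- vp * n[1L] * n[3L] + sp * n[2L]
  R[2L, 3L, ] <- vp * n[2L] * n[3L] - sp * n[1L]
  R[3L, 3L, ] <- cp + vp * n[3L]^2
  R
}

# Intrinsic Z-Y-X (Tait-Bryan) rotation array, vectorized over angle vectors
# (radians): R = Rz(a) %*% Ry(b) %*% Rx(c) per frame.
rotations_zyx <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b); cc <- cos(c); sc <- sin(c)
  N <- length(a)
  R <- array(0, c(3L, 3L, N))
  R[1L, 1L, ] <- ca * cb
  R[2L, 1L, ] <- sa * cb
  R[3L, 1L, ] <- -sb
  R[1L, 2L, ] <- ca * sb * sc - sa * cc
  R[2L, 2L, ] <- sa * sb * sc + ca * cc
  R[3L, 2L, ] <- cb * sc
  R[1L, 3L, ] <- ca * sb * cc + sa * sc
  R[2L, 3L, ] <- sa * sb * cc - ca * sc
  R[3L, 3L, ] <- cb * cc
  R
}

#' Generate the pose series of a screw-joint flexion gesture
#'
#' Forward model of a screw joint: at each sample time the moving bone frame
#' is rotated about the planted fixed axis by the flexion-angle profile and
#' translated along the same axis by the axial translation profile evaluated
#' at the current flexion angle. The moving body frame coincides with the
#' fixed (global) frame in the unrotated, untranslated configuration.
#'
#' @param truth A [ground_truth()] object.
#' @return A `pose_series` over `seq(0, duration, by = dt)`.
#' @export
make_screw_motion <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  check_monotone_profile(truth)
  t <- truth_times(truth)
  theta_deg <- truth$angle_profile(t)
  phi <- deg2rad(theta_deg)
  tau <- truth$axial_translation_profile(theta_deg)
  stopifnot(length(tau) == length(t))
  n <- truth$axis_direction
  C <- truth$axis_point
  R <- rotations_about_axis(n, phi)
  # origin of the moving frame: O(t) = C - R(t) C + tau(t) n
  RC <- t(apply_rotations(R, C))  # N x 3
  O <- matrix(C, length(t), 3L, byrow = TRUE) - RC + outer(tau, n)
  pose_series(t, R, O, validate = FALSE)
}

# Apply a 3 x 3 x N rotation array to one 3-vector -> 3 x N matrix.
apply_rotations <- function(R, v) {
  rbind(R[1L, 1L, ] * v[1L] + R[1L, 2L, ] * v[2L] + R[1L, 3L, ] * v[3L],
        R[2L, 1L, ] * v[1L] + R[2L, 2L, ] * v[2L] + R[2L, 3L, ] * v[3L],
        R[3L, 1L, ] * v[1L] + R[3L, 2L, ] * v[2L] + R[3L, 3L, ] * v[3L])
}

#' Generate a pose series from joint-frame displacement profiles
#'
#' Generalizes [make_screw_motion()] to all six degrees of freedom: given an
#' anatomical joint frame (orthonormal triad `B` with columns U_X, U_Y, U_Z
#' and origin `O_beta`) and displacement profiles as functions of flexion
#' angle, builds per-frame joint displacements
#' \eqn{D = Rot_Z(\theta) Rot_Y(R_Y) Rot_X(R_X)} plus translation
#' `(T_X, T_Y, T_Z)` expressed in the joint frame, and conjugates them into
#' the global frame. With all non-flexion profiles zero and `O_beta` on the
#' axis this reduces exactly to the screw-joint model.
#'
#' @param truth A [ground_truth()] object (supplies times, flexion profile,
#'   and the T_Z profile via `axial_translation_profile`).
#' @param B 3 x 3 matrix, columns U_X, U_Y, U_Z; `U_Z` must equal the truth
#'   axis direction.
#' @param O_beta Joint-frame origin (must lie on the planted axis for the
#'   flexion DoF to be a rotation about that axis), mm.
#' @param rx_deg,ry_deg Functions of flexion (deg) returning degrees;
#'   default zero.
#' @param tx,ty Functions of flexion (deg) returning mm; default zero.
#' @return A `pose_series`.
#' @export
make_joint_motion <- function(truth, B, O_beta,
                              rx_deg = NULL, ry_deg = NULL,
                              tx = NULL, ty = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  zerofun <- function(theta) rep(0, length(theta))
  if (is.null(rx_deg)) rx_deg <- zerofun
  if (is.null(ry_deg)) ry_deg <- zerofun
  if (is.null(tx)) tx <- zerofun
  if (is.null(ty)) ty <- zerofun
  if (max(abs(B[, 3L] - truth$axis_direction)) > 1e-9) {
    stop("third column of B must equal the planted axis direction", call. = FALSE)
  }
  t <- truth_times(truth)
  theta <- truth$angle_profile(t)
  Rj <- rotations_zyx(deg2rad(theta), deg2rad(ry_deg(theta)), deg2rad(rx_deg(theta)))
  td <- cbind(tx(theta), ty(theta), truth$axial_translation_profile(theta))
  N <- length(t)
  Rw <- array(0, c(3L, 3L, N))
  O <- matrix(0, N, 3L)
  Bt <- t(B)
  for (i in seq_len(N)) {
    Ri <- B %*% Rj[, , i] %*% Bt
    Rw[, , i] <- Ri
    O[i, ] <- O_beta - Ri %*% O_beta + B %*% td[i, ]
  }
  pose_series(t, Rw, O, validate = FALSE)
}
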