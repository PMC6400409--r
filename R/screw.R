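# Instantaneous helical (screw) axis extraction from a rigid pose series.
#
# Per sampling step the incremental rotation between consecutive frames is
# expressed through its Rodrigues parameters (the unit-quaternion components
# S, L, M, N), giving the step rotation angle phi and axis direction n.
# The axis location A is obtained from the angular velocity and the origin
# velocity, both estimated with the five-point central-difference stencil.

# --- vectorized rotation-array helpers (internal) -------------------------

# 3 x 3 x N array -> N x 9 row-per-frame matrix, column-major element order.
rot_to_rows <- function(R) {
  t(matrix(R, 9L, dim(R)[3L]))
}

e9 <- function(a, b) a + 3L * (b - 1L)

# Step products R_i = R_{i+1} %*% t(R_i) for i = 1..N-1, vectorized.
step_rotations_rows <- function(R9) {
  N <- nrow(R9)
  A <- R9[-1L, , drop = FALSE]   # frame i+1
  B <- R9[-N, , drop = FALSE]    # frame i
  C <- matrix(0, N - 1L, 9L)
  for (a in 1:3) for (b in 1:3) {
    C[, e9(a, b)] <- A[, e9(a, 1L)] * B[, e9(b, 1L)] +
      A[, e9(a, 2L)] * B[, e9(b, 2L)] +
      A[, e9(a, 3L)] * B[, e9(b, 3L)]
  }
  C
}

# Cumulative products R_i %*% t(R_1), vectorized over frames.
cumulative_rotations_rows <- function(R9) {
  N <- nrow(R9)
  R1 <- R9[1L, ]
  C <- matrix(0, N, 9L)
  for (a in 1:3) for (b in 1:3) {
    C[, e9(a, b)] <- R9[, e9(a, 1L)] * R1[e9(b, 1L)] +
      R9[, e9(a, 2L)] * R1[e9(b, 2L)] +
      R9[, e9(a, 3L)] * R1[e9(b, 3L)]
  }
  C
}

# Rodrigues parameters per row of an N x 9 rotation matrix block.
# Rows with S below s_min are re-extracted with the largest-diagonal branch.
rodrigues_rows <- function(R9, s_min = 1e-4) {
  tr <- R9[, 1L] + R9[, 5L] + R9[, 9L]
  S <- 0.5 * sqrt(pmax(1 + tr, 0))
  L <- M <- N <- numeric(nrow(R9))
  ok <- S >= s_min
  L[ok] <- (R9[ok, e9(3L, 2L)] - R9[ok, e9(2L, 3L)]) / (4 * S[ok])
  M[ok] <- (R9[ok, e9(1L, 3L)] - R9[ok, e9(3L, 1L)]) / (4 * S[ok])
  N[ok] <- (R9[ok, e9(2L, 1L)] - R9[ok, e9(1L, 2L)]) / (4 * S[ok])
  for (i in which(!ok)) {
    q <- rodrigues_params(matrix(R9[i, ], 3L, 3L), s_min = s_min)
    S[i] <- q[1L]; L[i] <- q[2L]; M[i] <- q[3L]; N[i] <- q[4L]
  }
  cbind(S = S, L = L, M = M, N = N, near_pi = as.numeric(!ok))
}

# --- exported elementary operations ---------------------------------------

#' Incremental rotation between consecutive frames
#'
#' Returns the proper rotation carrying the moving-frame orientation at
#' frame `i` to that at frame `i + 1`, expressed in the fixed (global)
#' frame: \eqn{R_i = R(t_{i+1}) R(t_i)^T}.
#'
#' @param poses A `pose_series`.
#' @param i Frame index, `1 <= i < length(poses)`.
#' @return A 3 x 3 rotation matrix.
#' @export
incremental_rotation <- function(poses, i) {
  n <- length(poses$times)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1L && i < n)) {
    stop(sprintf("index i must satisfy 1 <= i < %d", n), call. = FALSE)
  }
  poses$rotations[, , i + 1L] %*% t(poses$rotations[, , i])
}

#' Rodrigues parameters of a rotation matrix
#'
#' Extracts the unit-quaternion components `(S, L, M, N)` of a proper
#' rotation matrix: \eqn{S = \frac{1}{2}\sqrt{1 + a_{11} + a_{22} + a_{33}}},
#' \eqn{L = (a_{32}-a_{23})/(4S)}, \eqn{M = (a_{13}-a_{31})/(4S)},
#' \eqn{N = (a_{21}-a_{12})/(4S)}. Near a half-turn (rotation angle near
#' \eqn{\pi}) `S` vanishes and this division is ill-conditioned; the
#' extraction then switches to the standard largest-diagonal quaternion
#' branch and flags the result (attribute `near_pi`).
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param s_min Threshold on `S` below which the alternate branch is used.
#' @return Numeric 4-vector `c(S, L, M, N)` with `S >= 0`; attribute
#'   `near_pi` is TRUE when the alternate branch was used.
#' @export
rodrigues_params <- function(R, s_min = 1e-4) {
  stopifnot_rotation(R)
  S <- 0.5 * sqrt(max(1 + R[1L, 1L] + R[2L, 2L] + R[3L, 3L], 0))
  if (S >= s_min) {
    q <- c(S,
           (R[3L, 2L] - R[2L, 3L]) / (4 * S),
           (R[1L, 3L] - R[3L, 1L]) / (4 * S),
           (R[2L, 1L] - R[1L, 2L]) / (4 * S))
    attr(q, "near_pi") <- FALSE
    return(q)
  }
  # Largest-diagonal branch: stable for rotations near pi.
  d <- c(R[1L, 1L], R[2L, 2L], R[3L, 3L])
  k <- which.max(d)
  if (k == 1L) {
    x <- 0.5 * sqrt(max(1 + d[1L] - d[2L] - d[3L], 0))
    q <- c(S = (R[3L, 2L] - R[2L, 3L]) / (4 * x),
           L = x,
           M = (R[1L, 2L] + R[2L, 1L]) / (4 * x),
           N = (R[1L, 3L] + R[3L, 1L]) / (4 * x))
  } else if (k == 2L) {
    y <- 0.5 * sqrt(max(1 - d[1L] + d[2L] - d[3L], 0))
    q <- c(S = (R[1L, 3L] - R[3L, 1L]) / (4 * y),
           L = (R[1L, 2L] + R[2L, 1L]) / (4 * y),
           M = y,
           N = (R[2L, 3L] + R[3L, 2L]) / (4 * y))
  } else {
    z <- 0.5 * sqrt(max(1 - d[1L] - d[2L] + d[3L], 0))
    q <- c(S = (R[2L, 1L] - R[1L, 2L]) / (4 * z),
           L = (R[1L, 3L] + R[3L, 1L]) / (4 * z),
           M = (R[2L, 3L] + R[3L, 2L]) / (4 * z),
           N = z)
  }
  if (q[1L] < 0) q <- -q  # canonical S >= 0
  q <- unname(q)
  attr(q, "near_pi") <- TRUE
  q
}

#' Rotation angle and screw-axis direction from Rodrigues parameters
#'
#' \eqn{\phi = 2\arccos(S)} (argument clamped to `[-1, 1]`) and
#' \eqn{n = (L, M, N)/\sin(\phi/2)}. For rotations smaller than `phi_min`
#' the direction is numerically undefined: `n` is returned as `NA` with
#' attribute `axis_defined = FALSE`, `phi` is still returned.
#'
#' @param q Numeric 4-vector `(S, L, M, N)`, unit quaternion within 1e-6.
#' @param phi_min Smallest rotation (rad) with a defined axis.
#' @return List with `phi` (rad), `n` (unit 3-vector or `NA`), and logical
#'   `axis_defined`.
#' @export
axis_angle <- function(q, phi_min = 1e-6) {
  q <- as.numeric(q)
  stopifnot(length(q) == 4L)
  if (abs(sum(q^2) - 1) > 1e-6) {
    stop("Rodrigues parameters do not satisfy the unit-quaternion constraint",
         call. = FALSE)
  }
  # phi = 2 arccos(S), evaluated as 2 atan2(||(L,M,N)||, S) which is the
  # same quantity but keeps full precision for small rotations
  sinhalf <- sqrt(sum(q[2:4]^2))
  phi <- 2 * atan2(sinhalf, clamp(q[1L], -1, 1))
  if (phi < phi_min) {
    return(list(phi = phi, n = rep(NA_real_, 3L), axis_defined = FALSE))
  }
  list(phi = phi, n = q[2:4] / sinhalf, axis_defined = TRUE)
}

#' Five-point central-difference derivative
#'
#' Applies the stencil
#' \eqn{\dot x_i = \frac{1}{12\,dt}(x_{i-2} - 8x_{i-1} + 8x_{i+1} - x_{i+2})}
#' to each column of a uniformly sampled series. The stencil is exact for
#' polynomials up to degree 4. The first two and last two samples have no
#' full stencil support and are returned as `NA`; downstream screw
#' computations exclude them.
#'
#' @param series Numeric vector or N x k matrix, N >= 5.
#' @param dt Sampling interval.
#' @return Derivative of the same shape, `NA` on the two boundary rows at
#'   each end.
#' @export
five_point_derivative <- function(series, dt) {
  vec <- is.null(dim(series))
  X <- as.matrix(series)
  N <- nrow(X)
  if (N < 5L) stop("five-point stencil needs at least 5 frames", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  D <- matrix(NA_real_, N, ncol(X))
  i <- 3:(N - 2L)
  D[i, ] <- (X[i - 2L, , drop = FALSE] - 8 * X[i - 1L, , drop = FALSE] +
               8 * X[i + 1L, , drop = FALSE] - X[i + 2L, , drop = FALSE]) / (12 * dt)
  if (vec) D[, 1L] else D
}

# Exact conversion from a rotation-vector rate to the spatial angular
# velocity (differential of the exponential map):
# omega = rho_dot + (1-cos a)/a^2 (rho x rho_dot)
#         + (a - sin a)/a^3 rho x (rho x rho_dot),  a = |rho|.
# Reduces to omega = rho_dot for fixed-axis motion (rho parallel rho_dot).
rotvec_rate_to_omega <- function(rho, rho_dot) {
  a2 <- rowSums(rho * rho)
  a <- sqrt(a2)
  c1 <- ifelse(a > 1e-8, (1 - cos(a)) / a2, 0.5)
  c2 <- ifelse(a > 1e-8, (a - sin(a)) / (a2 * a), 1 / 6)
  cr <- cross3_rows(rho, rho_dot)
  rho_dot + c1 * cr + c2 * cross3_rows(rho, cr)
}

# Unwrapped rotation-vector series rho_i = phi_i * n_i of the cumulative
# orientation R(t_i) R(t_1)^T. Quaternion sign continuity is enforced so
# the series is continuous for gestures staying below a half-turn.
rotation_vectors <- function(poses) {
  R9 <- rot_to_rows(poses$rotations)
  C9 <- cumulative_rotations_rows(R9)
  q <- rodrigues_rows(C9)
  # sign continuity
  sgn <- rep(1, nrow(q))
  for (i in 2:nrow(q)) {
    if (sum(q[i, 1:4] * q[i - 1L, 1:4] * sgn[i - 1L]) < 0) sgn[i] <- -sgn[i - 1L] else sgn[i] <- sgn[i - 1L]
  }
  q[, 1:4] <- q[, 1:4] * sgn
  S <- clamp(q[, 1L], -1, 1)
  sinhalf <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  phi <- 2 * atan2(sinhalf, S)
  fac <- ifelse(sinhalf > 1e-12, phi / sinhalf, 2)
  q[, 2:4] * fac
}

#' Instantaneous helical axis point
#'
#' Locates the point of the instantaneous screw axis closest to the moving
#' frame origin: \eqn{A_i = O_i + (\omega_i \times V_i)/(\omega_i\cdot\omega_i)},
#' the orthogonal projection of \eqn{O_i} onto the axis.
#'
#' @param O_i Moving-frame origin, mm.
#' @param omega_i Angular velocity vector, rad/s.
#' @param V_i Origin velocity, mm/s.
#' @param omega_min Validity threshold on `||omega||` (rad/s).
#' @return 3-vector `A_i` (mm), or `NA` vector with attribute
#'   `valid = FALSE` when the angular velocity is below `omega_min`.
#' @export
iha_point <- function(O_i, omega_i, V_i, omega_min = 1e-8) {
  O_i <- vec3(O_i); V_i <- vec3(V_i)
  omega_i <- as.numeric(omega_i)
  w2 <- sum(omega_i^2)
  if (!is.finite(w2) || sqrt(w2) < omega_min) {
    out <- rep(NA_real_, 3L)
    attr(out, "valid") <- FALSE
    return(out)
  }
  out <- O_i + cross3(omega_i, V_i) / w2
  attr(out, "valid") <- TRUE
  out
}

#' Translation along the screw axis over one step
#'
#' Signed projection of the origin displacement onto the screw-axis
#' direction of the following step: \eqn{d_i = (O_{i+1} - O_i)\cdot n_{i+1}}.
#'
#' @param O_i,O_iplus1 Origin positions at frames i and i+1, mm.
#' @param n_next Unit axis direction at step i+1.
#' @return Signed scalar, mm.
#' @export
translation_along_axis <- function(O_i, O_iplus1, n_next) {
  if (anyNA(n_next)) stop("axis direction undefined at step i+1", call. = FALSE)
  sum((vec3(O_iplus1) - vec3(O_i)) * unitize(vec3(n_next)))
}

# --- full series extraction ----------------------------------------------

#' Extract per-step screw parameters from a pose series
#'
#' Runs the complete helical-axis chain on a rigid pose series: incremental
#' rotations between consecutive frames, Rodrigues parameters, step angle
#' `phi` and axis direction `n`, origin velocity `V` and angular velocity
#' `omega` by five-point differentiation, axis point `A`, and the axial
#' translation increment `d`.
#'
#' Angular velocity is obtained by applying the five-point stencil to the
#' unwrapped rotation-vector series of the cumulative orientation
#' (`omega_method = "rotation_vector"`, dimensionally consistent with the
#' axis-point formula). The alternative `"scalar"` method differentiates the
#' per-step scalar angles and assigns direction from the step axis.
#'
#' Steps are flagged invalid when the step rotation is below `phi_min`,
#' the angular velocity is below `omega_min`, or the frame lies in the
#' two-sample stencil boundary; invalid steps are retained in the output
#' with their flags, never silently dropped.
#'
#' @param poses A `pose_series` (>= 5 frames).
#' @param phi_min Smallest step rotation (rad) with a defined axis.
#' @param omega_min Validity threshold on `||omega||` (rad/s).
#' @param s_min Rodrigues branch-switch threshold.
#' @param omega_method `"rotation_vector"` (default) or `"scalar"`.
#' @return A data frame of class `screw_series` with one row per step
#'   (frames i to i+1): `time`, `phi` (rad), `S`, `L`, `M`, `N`, `n_x`,
#'   `n_y`, `n_z`, `A_x`, `A_y`, `A_z`, `d`, `V_*`, `omega_*`,
#'   `axis_defined`, `valid`.
#' @export
screw_series <- function(poses, phi_min = 1e-6, omega_min = 1e-8,
                         s_min = 1e-4, omega_method = c("rotation_vector", "scalar")) {
  stopifnot(inherits(poses, "pose_series"))
  omega_method <- match.arg(omega_method)
  N <- length(poses$times)
  if (N < 5L) stop("screw extraction needs at least 5 frames", call. = FALSE)
  dt <- diff(poses$times[1:2])

  R9 <- rot_to_rows(poses$rotations)
  St9 <- step_rotations_rows(R9)          # (N-1) x 9
  q <- rodrigues_rows(St9, s_min = s_min) # S, L, M, N per step
  S <- clamp(q[, 1L], -1, 1)
  sinhalf <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  phi <- 2 * atan2(sinhalf, S)
  axis_defined <- phi >= phi_min
  n <- matrix(NA_real_, N - 1L, 3L)
  n[axis_defined, ] <- q[axis_defined, 2:4, drop = FALSE] / sinhalf[axis_defined]

  O <- poses$origins
  V <- five_point_derivative(O, dt)       # per frame
  if (omega_method == "rotation_vector") {
    rho <- rotation_vectors(poses)
    rho_dot <- five_point_derivative(rho, dt)
    omega <- rotvec_rate_to_omega(rho, rho_dot)
  } else {
    # scalar variant: differentiate the accumulated step angles, orient
    # along the step axis
    wmag <- five_point_derivative(cumsum(c(0, phi)), dt)
    omega <- n[c(seq_len(N - 1L), N - 1L), , drop = FALSE] * wmag
  }
  w2 <- rowSums(omega^2)
  omega_valid <- is.finite(w2) & sqrt(w2) >= omega_min
  A <- matrix(NA_real_, N, 3L)
  ok <- which(omega_valid)
  A[ok, ] <- O[ok, , drop = FALSE] +
    cross3_rows(omega[ok, , drop = FALSE], V[ok, , drop = FALSE]) / w2[ok]

  # d_i = (O_{i+1} - O_i) . n_{i+1} per the printed step convention
  d <- rep(NA_real_, N - 1L)
  i <- seq_len(N - 2L)
  use <- axis_defined[i + 1L]
  dO <- O[i + 1L, , drop = FALSE] - O[i, , drop = FALSE]
  d[i[use]] <- rowSums(dO[use, , drop = FALSE] * n[i[use] + 1L, , drop = FALSE])

  steps <- seq_len(N - 1L)
  interior <- steps >= 3L & steps <= N - 2L
  out <- data.frame(
    step = steps,
    time = poses$times[steps],
    phi = phi,
    S = q[, 1L], L = q[, 2L], M = q[, 3L], N = q[, 4L],
    n_x = n[, 1L], n_y = n[, 2L], n_z = n[, 3L],
    A_x = A[steps, 1L], A_y = A[steps, 2L], A_z = A[steps, 3L],
    d = d,
    V_x = V[steps, 1L], V_y = V[steps, 2L], V_z = V[steps, 3L],
    omega_x = omega[steps, 1L], omega_y = omega[steps, 2L], omega_z = omega[steps, 3L],
    axis_defined = axis_defined,
    near_pi = q[, 5L] > 0,
    valid = axis_defined & omega_valid[steps] & interior
  )
  attr(out, "dt") <- dt
  attr(out, "phi_min") <- phi_min
  attr(out, "omega_min") <- omega_min
  class(out) <- c("screw_series", "data.frame")
  out
}

#' Mean flexion axis from a screw series
#'
#' Averages the valid per-step axis directions after aligning them to a
#' common hemisphere (each direction is sign-flipped when its dot product
#' with the running mean is negative), renormalizes, and averages the valid
#' axis points.
#'
#' By default the direction average is weighted by the step rotation angle
#' `phi` and the point average by the squared angular-velocity magnitude.
#' Because step increments at a high sampling rate can be smaller than the
#' per-frame orientation noise, the unweighted averages (`weights =
#' "none"`) are noise-dominated there, while the angle weighting telescopes
#' the increments so interior noise cancels; both options are available.
#'
#' @param steps A `screw_series` (or data frame with the same columns).
#' @param phi_min Optional stricter angle threshold; steps below it are
#'   ignored in the direction average.
#' @param weights `"angle"` (default: phi-weighted directions,
#'   omega-squared-weighted points) or `"none"` (plain means).
#' @return A list of class `mean_axis`: `n_m` (unit direction), `A_m`
#'   (mm), `n_steps_used`.
#' @export
mean_flexion_axis <- function(steps, phi_min = NULL,
                              weights = c("angle", "none")) {
  weights <- match.arg(weights)
  use <- steps$valid
  if (!is.null(phi_min)) use <- use & steps$phi >= phi_min
  if (!any(use)) stop("no valid screw steps to average", call. = FALSE)
  n <- as.matrix(steps[use, c("n_x", "n_y", "n_z")])
  if (weights == "angle") {
    # signed sum of step rotation vectors phi_i * n_i: consecutive-step
    # noise telescopes, so no per-step sign flipping is applied
    n_m <- unitize(colSums(n * steps$phi[use]))
  } else {
    ref <- n[1L, ]
    for (i in seq_len(nrow(n))) {
      if (sum(n[i, ] * ref) < 0) n[i, ] <- -n[i, ]
      ref <- ref + (n[i, ] - ref) / i  # running mean as hemisphere reference
    }
    n_m <- unitize(colMeans(n))
  }
  A <- as.matrix(steps[use, c("A_x", "A_y", "A_z")])
  wA <- if (weights == "angle") {
    rowSums(as.matrix(steps[use, c("omega_x", "omega_y", "omega_z")])^2)
  } else {
    rep(1, sum(use))
  }
  keep <- stats::complete.cases(A)
  A_m <- unname(colSums(A[keep, , drop = FALSE] * wA[keep]) / sum(wA[keep]))
  structure(list(n_m = unname(n_m), A_m = A_m, n_steps_used = sum(use)),
            class = "mean_axis")
}

#' Finite helical axis of the displacement between two frames
#'
#' Screw decomposition of the total rigid displacement from frame `from` to
#' frame `to`: rotation angle and axis from the Rodrigues parameters of
#' \eqn{R_{to} R_{from}^T}, axial translation `d`, and the axis location
#' solved from \eqn{(I - R)A = t - d\,n} in the plane orthogonal to the
#' axis. Because the baseline spans the whole gesture rather than one
#' sampling step, the axis location is far less sensitive to marker noise
#' than any single-step estimate.
#'
#' @param poses A `pose_series`.
#' @param from,to Frame indices (defaults: first and last).
#' @return A list: `phi` (rad), `n` (unit direction), `point` (a point on
#'   the axis with no offset along `n` from the plane of the frame-`from`
#'   origin), `d` (mm, translation along the axis).
#' @export
finite_helical_axis <- function(poses, from = 1L, to = length(poses$times)) {
  N <- length(poses$times)
  stopifnot(from >= 1L, to <= N, from < to)
  R <- poses$rotations[, , to] %*% t(poses$rotations[, , from])
  t_ <- poses$origins[to, ] - as.vector(R %*% poses$origins[from, ])
  q <- rodrigues_params(R)
  aa <- axis_angle(q)
  if (!aa$axis_defined) {
    stop("displacement between the chosen frames is too small to define an axis",
         call. = FALSE)
  }
  n <- aa$n
  d <- sum(t_ * n)
  u <- orthonormal_to(n)
  v <- cross3(n, u)
  ImR <- diag(3) - R
  Mx <- cbind(ImR %*% u, ImR %*% v)
  a <- qr.solve(Mx, t_ - d * n)
  list(phi = aa$phi, n = n, point = a[1L] * u + a[2L] * v, d = d)
}

#' Least-squares axis point from many large-baseline displacements
#'
#' Global estimate of the flexion-axis location: every frame pair
#' `(i, i + lag)` contributes the screw-axis constraint
#' \eqn{(I - R_{pair}) A = t_{pair} - (n\cdot t_{pair})\,n}, restricted to
#' the plane orthogonal to the axis direction `n`, and the stacked system
#' is solved in least squares. Pair displacements span a large fraction of
#' the gesture, so each constraint is well conditioned and the pair errors
#' are nearly independent; the estimate improves like the square root of
#' the pair count, unlike single-step axis points whose error is amplified
#' by the inverse step rotation.
#'
#' @param poses A `pose_series`.
#' @param n Unit axis direction (e.g. from [mean_flexion_axis()]).
#' @param lag Frame lag between pair members; default half the series.
#' @return A 3-vector: the axis point in the plane through the origin
#'   orthogonal to `n`.
#' @export
fit_axis_point <- function(poses, n, lag = NULL) {
  N <- length(poses$times)
  n <- unitize(vec3(n))
  if (is.null(lag)) lag <- max(1L, N %/% 2L)
  if (lag >= N) stop("lag must be smaller than the number of frames", call. = FALSE)
  R9 <- rot_to_rows(poses$rotations)
  A9 <- R9[(lag + 1L):N, , drop = FALSE]
  B9 <- R9[seq_len(N - lag), , drop = FALSE]
  P9 <- matrix(0, N - lag, 9L)
  for (a in 1:3) for (b in 1:3) {
    P9[, e9(a, b)] <- A9[, e9(a, 1L)] * B9[, e9(b, 1L)] +
      A9[, e9(a, 2L)] * B9[, e9(b, 2L)] +
      A9[, e9(a, 3L)] * B9[, e9(b, 3L)]
  }
  O1 <- poses$origins[seq_len(N - lag), , drop = FALSE]
  O2 <- poses$origins[(lag + 1L):N, , drop = FALSE]
  RO1 <- cbind(P9[, 1L] * O1[, 1L] + P9[, 4L] * O1[, 2L] + P9[, 7L] * O1[, 3L],
               P9[, 2L] * O1[, 1L] + P9[, 5L] * O1[, 2L] + P9[, 8L] * O1[, 3L],
               P9[, 3L] * O1[, 1L] + P9[, 6L] * O1[, 2L] + P9[, 9L] * O1[, 3L])
  tp <- O2 - RO1
  b3 <- tp - outer(as.vector(tp %*% n), n)  # component orthogonal to n
  u <- orthonormal_to(n)
  v <- cross3(n, u)
  # columns of M per pair: (I - R) u and (I - R) v
  Ru <- cbind(P9[, 1L] * u[1L] + P9[, 4L] * u[2L] + P9[, 7L] * u[3L],
              P9[, 2L] * u[1L] + P9[, 5L] * u[2L] + P9[, 8L] * u[3L],
              P9[, 3L] * u[1L] + P9[, 6L] * u[2L] + P9[, 9L] * u[3L])
  Rv <- cbind(P9[, 1L] * v[1L] + P9[, 4L] * v[2L] + P9[, 7L] * v[3L],
              P9[, 2L] * v[1L] + P9[, 5L] * v[2L] + P9[, 8L] * v[3L],
              P9[, 3L] * v[1L] + P9[, 6L] * v[2L] + P9[, 9L] * v[3L])
  Mu <- matrix(u, N - lag, 3L, byrow = TRUE) - Ru
  Mv <- matrix(v, N - lag, 3L, byrow = TRUE) - Rv
  # normal equations of the stacked 2-parameter least squares
  G <- matrix(c(sum(Mu * Mu), sum(Mu * Mv), sum(Mu * Mv), sum(Mv * Mv)), 2L, 2L)
  rhs <- c(sum(Mu * b3), sum(Mv * b3))
  a <- solve(G, rhs)
  a[1L] * u + a[2L] * v
}

#' @export
print.mean_axis <- function(x, ...) {
  cat(sprintf("Mean flexion axis: n_m = (%.5f, %.5f, %.5f), A_m = (%.3f, %.3f, %.3f) mm, %d steps\n",
              x$n_m[1L], x$n_m[2L], x$n_m[3L], x$A_m[1L], x$A_m[2L], x$A_m[3L],
              x$n_steps_used))
  invisible(x)
}

#' Write a screw series to CSV
#'
#' Columns: time, phi_deg, n_x, n_y, n_z, A_x, A_y, A_z, d_mm, valid.
#'
#' @param steps A `screw_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screw_csv <- function(steps, path) {
  out <- data.frame(time = steps$time,
                    phi_deg = rad2deg(steps$phi),
                    n_x = steps$n_x, n_y = steps$n_y, n_z = steps$n_z,
                    A_x = steps$A_x, A_y = steps$A_y, A_z = steps$A_z,
                    d_mm = steps$d,
                    valid = steps$valid)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
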