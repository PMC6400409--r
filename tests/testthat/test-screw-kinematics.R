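# Helical-axis extraction: Rodrigues parameters, axis-angle, stencils,
# axis points, and the mean flexion axis.

test_that("incremental rotations telescope to the total orientation change", {
  tr <- ground_truth(dt = 0.05, duration = 2)
  poses <- make_screw_motion(tr)
  N <- length(poses$times)
  expect_error(incremental_rotation(poses, 0), "index")
  expect_error(incremental_rotation(poses, N), "index")
  acc <- diag(3)
  for (i in seq_len(N - 1L)) acc <- incremental_rotation(poses, i) %*% acc
  total <- poses$rotations[, , N] %*% t(poses$rotations[, , 1L])
  expect_lt(max(abs(acc - total)), 1e-9)
  # constant orientation -> identity increments
  still <- pose_series(poses$times,
                       array(rep(diag(3), N), c(3L, 3L, N)),
                       matrix(0, N, 3L))
  expect_lt(max(abs(incremental_rotation(still, 3L) - diag(3))), 1e-15)
})

test_that("fixed-axis rotation at constant rate has constant increments", {
  w0 <- 0.8 # rad/s
  dt <- 0.01
  times <- seq(0, 1, by = dt)
  R <- array(0, c(3L, 3L, length(times)))
  for (i in seq_along(times)) R[, , i] <- rotation_about_axis(c(0, 0, 1), w0 * times[i])
  poses <- pose_series(times, R, matrix(0, length(times), 3L))
  expected <- rotation_about_axis(c(0, 0, 1), w0 * dt)
  for (i in c(1L, 50L, 100L)) {
    expect_lt(max(abs(incremental_rotation(poses, i) - expected)), 1e-12)
  }
})

test_that("Rodrigues parameters match the closed forms and the log-based oracle", {
  q0 <- rodrigues_params(diag(3))
  expect_equal(as.numeric(q0), c(1, 0, 0, 0), tolerance = 1e-15)
  q90 <- rodrigues_params(rotation_about_axis(c(0, 0, 1), pi / 2))
  expect_equal(as.numeric(q90), c(sqrt(2) / 2, 0, 0, sqrt(2) / 2),
               tolerance = 1e-12)
  set.seed(7)
  for (k in 1:1000) {
    R <- oracle_random_rotation(c(0.01, 3.0))
    q <- rodrigues_params(R)
    expect_lt(abs(sum(q^2) - 1), 1e-9)
    qo <- oracle_quat_from_matrix(R)
    expect_lt(min(max(abs(q - qo)), max(abs(q + qo))), 1e-10)
  }
})

test_that("near-half-turn rotations use the stable branch and stay exact", {
  set.seed(8)
  for (k in 1:50) {
    u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
    phi <- pi - stats::runif(1L, 0, 1e-5)
    R <- oracle_rot_from_quat(c(cos(phi / 2), sin(phi / 2) * u))
    q <- rodrigues_params(R)
    expect_true(attr(q, "near_pi"))
    qo <- oracle_quat_from_matrix(R)
    expect_lt(min(max(abs(q - qo)), max(abs(q + qo))), 1e-6)
    aa <- axis_angle(q)
    Rb <- rotation_about_axis(aa$n, aa$phi)
    expect_lt(max(abs(Rb - R)), 1e-8)
  }
})

test_that("axis-angle extraction and the Rodrigues formula are mutually inverse", {
  aa0 <- axis_angle(c(1, 0, 0, 0))
  expect_equal(aa0$phi, 0)
  expect_false(aa0$axis_defined)
  aa1 <- axis_angle(c(sqrt(2) / 2, 0, 0, sqrt(2) / 2))
  expect_equal(aa1$phi, pi / 2, tolerance = 1e-12)
  expect_equal(aa1$n, c(0, 0, 1), tolerance = 1e-12)
  expect_error(axis_angle(c(1, 1, 0, 0)), "unit-quaternion")
  set.seed(11)
  for (k in 1:1000) {
    R <- oracle_random_rotation(c(0.01, 3.0))
    aa <- axis_angle(rodrigues_params(R))
    Rb <- rotation_about_axis(aa$n, aa$phi)
    expect_lt(max(abs(Rb - R)), 1e-9)
  }
})

test_that("five-point stencil is exact through quartic polynomials", {
  dt <- 0.05
  t <- seq(0, 2, by = dt)
  expect_error(five_point_derivative(1:4, dt), "at least 5")
  expect_true(all(five_point_derivative(rep(3, 20), dt)[3:18] == 0))
  lin <- five_point_derivative(4.2 * t, dt)
  expect_lt(max(abs(lin[3:(length(t) - 2L)] - 4.2)), 1e-10)
  # degree-4 polynomial: exact; degree 5: not
  X <- cbind(t^4 - 2 * t^3, 3 * t^2 + t, t^4 + t)
  D <- five_point_derivative(X, dt)
  i <- 3:(length(t) - 2L)
  truth <- cbind(4 * t^3 - 6 * t^2, 6 * t + 1, 4 * t^3 + 1)
  expect_lt(max(abs(D[i, ] - truth[i, ]) / pmax(abs(truth[i, ]), 1)), 1e-10)
  expect_true(all(is.na(D[c(1:2, length(t) - 1L, length(t)), ])))
  d5 <- five_point_derivative(t^5, dt)
  expect_gt(max(abs(d5[i] - 5 * t[i]^4)), 1e-8)
})

test_that("angular velocity matches the matrix-log oracle on a smooth motion", {
  dt <- 0.01
  times <- seq(0, 2, by = dt)
  N <- length(times)
  # slowly precessing axis
  R <- array(0, c(3L, 3L, N))
  for (i in seq_len(N)) {
    R[, , i] <- rotation_about_axis(c(0, 0, 1), 0.1 * times[i]) %*%
      rotation_about_axis(c(1, 0, 0), 0.6 * times[i])
  }
  poses <- pose_series(times, R, matrix(0, N, 3L))
  sw <- screw_series(poses)
  # oracle: omega from skew(R-dot R^T) by central differences of R itself
  i <- seq(5L, N - 5L, by = 9L)
  for (j in i) {
    Rdot <- (R[, , j + 1L] - R[, , j - 1L]) / (2 * dt)
    W <- Rdot %*% t(R[, , j])
    w_or <- c(W[3L, 2L] - W[2L, 3L], W[1L, 3L] - W[3L, 1L],
              W[2L, 1L] - W[1L, 2L]) / 2
    w_got <- as.numeric(sw[j, c("omega_x", "omega_y", "omega_z")])
    expect_lt(max(abs(w_got - w_or)), 5e-4) # both O(dt^2)-limited
  }
  # fixed-axis constant rate: omega exactly (0, 0, w0) at interior steps
  w0 <- 0.8
  R2 <- array(0, c(3L, 3L, N))
  for (i2 in seq_len(N)) R2[, , i2] <- rotation_about_axis(c(0, 0, 1), w0 * times[i2])
  sw2 <- screw_series(pose_series(times, R2, matrix(0, N, 3L)))
  ok <- sw2$valid
  expect_lt(max(abs(sw2$omega_z[ok] - w0)), 1e-9)
  expect_lt(max(abs(sw2$omega_x[ok])), 1e-9)
})

test_that("axis points follow the velocity construction", {
  A <- iha_point(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(as.numeric(A), c(0, 0, 0), tolerance = 1e-15)
  A0 <- iha_point(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_true(all(is.na(A0)))
  expect_false(attr(A0, "valid"))
  expect_equal(translation_along_axis(c(0, 0, 0), c(0, 0, 0.1), c(0, 0, 1)), 0.1)
  expect_equal(translation_along_axis(c(1, 2, 3), c(1, 2, 3), c(0, 0, 1)), 0)
  expect_error(translation_along_axis(c(0, 0, 0), c(1, 1, 1), c(NA, NA, NA)),
               "undefined")
})

test_that("noiseless planted screw is recovered exactly on interior frames", {
  p_pitch <- 0.457 / (91 * pi / 180) # total axial translation 0.457 mm
  tr <- ground_truth(axis_point = c(30, -20, 15),
                     axis_direction = c(0.15, -0.08, 0.98),
                     angle_profile = smoothstep_profile(0, 91, 40),
                     axial_translation_profile = function(th) p_pitch * th * pi / 180,
                     dt = 0.01, duration = 40, marker_noise_sigma = 0)
  poses <- make_screw_motion(tr)
  sw <- screw_series(poses)
  ok <- sw$valid
  expect_gt(sum(ok), 3900)
  n <- tr$axis_direction
  ang_err <- acos(pmin(1, abs(sw$n_x[ok] * n[1L] + sw$n_y[ok] * n[2L] +
                                sw$n_z[ok] * n[3L])))
  expect_lt(max(ang_err), 1e-6)
  A <- as.matrix(sw[ok, c("A_x", "A_y", "A_z")])
  expect_lt(max(dist_to_line(A, tr$axis_point, n)), 1e-6)
  expect_lt(abs(sum(sw$d, na.rm = TRUE) - 0.457), 1e-6)
  # mean axis and global axis-point fit agree with the planted line
  ax <- mean_flexion_axis(sw)
  expect_lt(line_angle(ax$n_m, n), 1e-9)
  expect_lt(dist_to_line(ax$A_m, tr$axis_point, n)[1L], 1e-6)
  pt <- fit_axis_point(poses, ax$n_m)
  expect_lt(dist_to_line(pt, tr$axis_point, n)[1L], 1e-9)
  fha <- finite_helical_axis(poses)
  expect_lt(line_angle(fha$n, n), 1e-9)
  expect_lt(dist_to_line(fha$point, tr$axis_point, n)[1L], 1e-9)
  expect_equal(fha$d, 0.457, tolerance = 1e-9)
})

test_that("mean axis averaging respects hemisphere symmetry and cone geometry", {
  mk_steps <- function(n_mat, phi = rep(0.01, nrow(n_mat))) {
    data.frame(phi = phi, n_x = n_mat[, 1L], n_y = n_mat[, 2L],
               n_z = n_mat[, 3L],
               A_x = 0, A_y = 0, A_z = 0,
               omega_x = phi, omega_y = 0, omega_z = 0,
               valid = TRUE)
  }
  n_same <- matrix(rep(c(0, 0, 1), 10L), ncol = 3L, byrow = TRUE)
  expect_equal(mean_flexion_axis(mk_steps(n_same))$n_m, c(0, 0, 1),
               tolerance = 1e-12)
  # half the directions sign-flipped: unweighted mode realigns them
  set.seed(21)
  jitter <- matrix(stats::rnorm(30L, 0, 0.01), ncol = 3L)
  n_jit <- t(apply(n_same + jitter, 1L, function(v) v / sqrt(sum(v^2))))
  flip <- n_jit
  flip[seq(1L, 9L, by = 2L), ] <- -flip[seq(1L, 9L, by = 2L), ]
  a1 <- mean_flexion_axis(mk_steps(n_jit), weights = "none")
  a2 <- mean_flexion_axis(mk_steps(flip), weights = "none")
  expect_lt(line_angle(a1$n_m, a2$n_m), 1e-12)
  # 10^4 axes on a 5-degree cone around z, uniform azimuth -> mean within 0.2 deg
  set.seed(22)
  az <- stats::runif(1e4, 0, 2 * pi)
  cone <- cbind(sin(5 * pi / 180) * cos(az), sin(5 * pi / 180) * sin(az),
                rep(cos(5 * pi / 180), 1e4))
  am <- mean_flexion_axis(mk_steps(cone))
  expect_lt(line_angle(am$n_m, c(0, 0, 1)), 0.2 * pi / 180)
  expect_error(mean_flexion_axis(mk_steps(cone)[0, ]), "no valid")
})

test_that("mean axis direction improves with gesture coverage under noise", {
  # same noise level, increasing numbers of frames over the same gesture
  errs <- sapply(c(3, 10, 40), function(dur) {
    tr <- ground_truth(angle_profile = smoothstep_profile(0, 91, dur),
                       duration = dur, dt = 0.01)
    poses <- make_screw_motion(tr)
    g <- cluster_geometry(rbind(c(20, 0, 0), c(-20, 16, 0), c(0, -16, 18),
                                c(-8, 4, -20)))
    mean(sapply(1:3, function(s) {
      mk <- make_marker_trajectories(poses, g, g, sigma = 0.012, seed = s)
      rec <- relative_pose_series(mk, g, g)
      ax <- mean_flexion_axis(screw_series(rec))
      line_angle(ax$n_m, tr$axis_direction)
    }))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L], 5e-3)
})
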