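# Joint-frame displacement decomposition, flexion angle, curve aggregation
# with Student-t bands, and the significance screen.

make_frame <- function(U = diag(3), origin = c(0, 0, 0)) {
  structure(list(U = U, origin = origin, side = "right", provenance = NULL),
            class = "anatomical_frame")
}

test_that("pose changes of basis are exact and invertible", {
  set.seed(51)
  U <- build_frame_axes(c(25, 3, -2), c(1, 1, 1), c(0.2, 0.1, 0.97))
  fr <- make_frame(U, origin = c(4, -6, 2))
  ref <- list(R = oracle_random_rotation(), O = stats::rnorm(3L, 0, 10))
  pose <- list(R = oracle_random_rotation(), O = stats::rnorm(3L, 0, 10))
  # pose == reference -> identity displacement
  d0 <- pose_in_joint_frame(ref, fr, ref)
  expect_lt(max(abs(d0$R - diag(3))), 1e-12)
  expect_lt(max(abs(d0$t)), 1e-9)
  # round trip through the inverse change of basis
  d <- pose_in_joint_frame(pose, fr, ref)
  Rw <- fr$U %*% d$R %*% t(fr$U)
  tw <- as.vector(fr$U %*% d$t) - as.vector((Rw - diag(3)) %*% fr$origin)
  R_back <- Rw %*% ref$R
  O_back <- as.vector(Rw %*% ref$O + tw)
  expect_lt(max(abs(R_back - pose$R)), 1e-12)
  expect_lt(max(abs(O_back - pose$O)), 1e-9)
  # pure rotation about U_Z shows up as pure R_Z
  theta <- 0.6
  Rz_world <- fr$U %*% rotation_about_axis(c(0, 0, 1), theta) %*% t(fr$U)
  pz <- list(R = Rz_world, O = as.vector((diag(3) - Rz_world) %*% fr$origin))
  dz <- decompose_tait_bryan(pose_in_joint_frame(pz, fr))
  expect_equal(unname(dz["R_Z"]), theta * 180 / pi, tolerance = 1e-9)
  expect_lt(max(abs(dz[c("R_Y", "R_X", "T_X", "T_Y", "T_Z")])), 1e-9)
})

test_that("Tait-Bryan decomposition inverts its composition", {
  id <- decompose_tait_bryan(list(R = diag(3), t = c(0, 0, 0)))
  expect_lt(max(abs(id)), 1e-15)
  d30 <- decompose_tait_bryan(list(R = rotation_about_axis(c(0, 0, 1), pi / 6),
                                   t = c(0, 0, 0)))
  expect_equal(unname(d30["R_Z"]), 30, tolerance = 1e-12)
  expect_lt(max(abs(d30[c("R_Y", "R_X", "T_X", "T_Y", "T_Z")])), 1e-12)
  # planted cascade: flexion 40 deg, small out-of-plane angles, translation
  ang <- c(R_Z = 40, R_Y = 0.02, R_X = 0.01)
  R <- rotation_about_axis(c(0, 0, 1), ang[1L] * pi / 180) %*%
    rotation_about_axis(c(0, 1, 0), ang[2L] * pi / 180) %*%
    rotation_about_axis(c(1, 0, 0), ang[3L] * pi / 180)
  out <- decompose_tait_bryan(list(R = R, t = c(0.1, -0.2, 0.457)))
  expect_equal(unname(out[c("R_Z", "R_Y", "R_X")]), unname(ang),
               tolerance = 1e-9)
  expect_equal(unname(out[c("T_X", "T_Y", "T_Z")]), c(0.1, -0.2, 0.457),
               tolerance = 1e-12)
  expect_false(attr(out, "gimbal"))
  # decompose(compose) identity over random angles away from gimbal lock
  set.seed(52)
  for (k in 1:200) {
    a <- stats::runif(3L, -80, 80) * pi / 180
    R <- rotation_about_axis(c(0, 0, 1), a[1L]) %*%
      rotation_about_axis(c(0, 1, 0), a[2L]) %*%
      rotation_about_axis(c(1, 0, 0), a[3L])
    got <- decompose_tait_bryan(list(R = R, t = c(0, 0, 0)))
    expect_lt(max(abs(got[c("R_Z", "R_Y", "R_X")] - a * 180 / pi)), 1e-9)
  }
  near_gimbal <- decompose_tait_bryan(
    list(R = rotation_about_axis(c(0, 1, 0), 89.95 * pi / 180), t = c(0, 0, 0)))
  expect_true(attr(near_gimbal, "gimbal"))
})

test_that("the instantaneous flexion angle tracks the planted profile", {
  fr <- make_frame()
  c0 <- c(150, 0, 10)
  expect_equal(flexion_angle(list(R = diag(3), t = c(0, 0, 0)), c0), 0)
  R91 <- rotation_about_axis(c(0, 0, 1), 91 * pi / 180)
  expect_equal(flexion_angle(list(R = R91, t = c(0, 0, 0)), c0), 91,
               tolerance = 1e-9)
  expect_error(flexion_angle(list(R = diag(3), t = c(0, 0, 0)), c(0, 0, 10)),
               "degenerate")
  # full synthetic gesture: flexion matches the generator profile
  sc <- make_scenario("fresh", seed = 2, noiseless = TRUE, duration = 2)
  fr2 <- make_frame(sc$scene$B, sc$scene$O_beta)
  s <- dof_samples(sc$poses, fr2, sc$scene$C_W_true)
  th_true <- sc$truth$angle_profile(sc$poses$times)
  expect_lt(max(abs(s$flexion_deg - th_true)), 1e-6)
  # and the full six-DoF samples match the planted profiles
  expect_lt(max(abs(s$T_Z - sc$profiles$T_Z(th_true))), 1e-6)
  expect_lt(max(abs(s$T_X)), 1e-6)
  expect_lt(max(abs(s$T_Y)), 1e-6)
  expect_lt(max(abs(s$R_X)), 1e-6)
  expect_lt(max(abs(s$R_Y)), 1e-6)
  expect_lt(max(abs(s$R_Z - th_true)), 1e-6)
})

test_that("dry-scenario decomposition recovers the planted perturbations", {
  sc <- make_scenario("dry", seed = 3, noiseless = TRUE, duration = 2)
  fr <- make_frame(sc$scene$B, sc$scene$O_beta)
  s <- dof_samples(sc$poses, fr, sc$scene$C_W_true)
  th <- sc$truth$angle_profile(sc$poses$times)
  expect_lt(max(abs(s$T_Z - sc$profiles$T_Z(th))), 1e-6)
  expect_lt(max(abs(s$R_X - sc$profiles$R_X(th))), 1e-6)
  expect_lt(max(abs(s$R_Y - sc$profiles$R_Y(th))), 1e-6)
})

test_that("Student-t critical values match the distribution function", {
  expect_equal(round(t_critical(24, 0.05), 3), 2.064)
  expect_equal(t_critical(1e6, 0.05), 1.960, tolerance = 1e-3)
  expect_equal(round(t_critical(4, 0.05), 3), 2.776)
  expect_error(t_critical(0, 0.05), "df")
  expect_error(t_critical(10, 1.2), "alpha")
})

fake_samples <- function(n_trials, grid, fun = function(th) 0 * th,
                         noise = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_trials), function(j) {
    data.frame(trial = j, time = seq_along(grid), flexion_deg = grid,
               R_Z = grid,
               R_X = stats::rnorm(length(grid), 0, noise),
               R_Y = stats::rnorm(length(grid), 0, noise),
               T_X = stats::rnorm(length(grid), 0, noise),
               T_Y = stats::rnorm(length(grid), 0, noise),
               T_Z = fun(grid) + stats::rnorm(length(grid), 0, noise),
               gimbal = FALSE)
  }))
}

test_that("curve aggregation uses the t-based half-widths", {
  grid <- seq(0, 90, by = 5)
  ident <- fake_samples(25, grid, fun = function(th) 0.005 * th, noise = 0)
  cv <- aggregate_curves(ident, grid = grid)
  expect_equal(cv$n_trials, 25L)
  expect_equal(round(cv$t_critical, 3), 2.064)
  expect_lt(max(cv$half_width), 1e-12)           # identical trials
  expect_equal(unname(cv$mean[, "T_Z"]), 0.005 * grid, tolerance = 1e-12)
  expect_error(aggregate_curves(ident[ident$trial == 1L, ]), "at least 2")
  # permutation invariance in trial order
  noisy <- fake_samples(10, grid, noise = 0.01, seed = 3)
  perm <- noisy[order(-noisy$trial, noisy$flexion_deg), ]
  cv1 <- aggregate_curves(noisy, grid = grid)
  cv2 <- aggregate_curves(perm, grid = grid)
  expect_equal(cv1$mean, cv2$mean, tolerance = 1e-12)
  expect_equal(cv1$half_width, cv2$half_width, tolerance = 1e-12)
})

test_that("trials not covering a grid point are excluded with counts", {
  grid <- seq(0, 90, by = 10)
  full <- fake_samples(3, grid, noise = 0.001, seed = 4)
  short <- fake_samples(2, seq(0, 60, by = 10), noise = 0.001, seed = 5)
  short$trial <- short$trial + 3L
  cv <- aggregate_curves(rbind(full, short), grid = grid)
  expect_equal(cv$n_used[grid <= 60], rep(5L, sum(grid <= 60)))
  expect_equal(cv$n_used[grid > 60], rep(3L, sum(grid > 60)))
  expect_gt(cv$n_excluded, 0L)
})

test_that("the significance screen isolates planted displacements", {
  grid <- seq(0, 91, by = 1)
  flat <- fake_samples(25, grid, noise = 1e-6, seed = 6)
  cv0 <- aggregate_curves(flat, grid = grid)
  expect_false(any(significance_screen(cv0)))
  ramp <- fake_samples(25, grid, fun = function(th) 0.005 * th, noise = 1e-4,
                       seed = 7)
  cv1 <- aggregate_curves(ramp, grid = grid)
  sig <- significance_screen(cv1)
  expect_true(sig["T_Z"])
  expect_false(any(sig[c("R_X", "R_Y", "T_X", "T_Y")]))
  # raising the uncertainty above every curve suppresses all flags
  sig_none <- significance_screen(cv1, translation_uncertainty_mm = 10,
                                  rotation_uncertainty_deg = 10)
  expect_false(any(sig_none))
})

test_that("rotation uncertainty propagates over the cluster span", {
  g <- cluster_geometry(rbind(c(10, 0, 0), c(-10, 0, 0), c(0, 10, 0),
                              c(0, -10, 0)))
  expect_equal(rotation_uncertainty_deg(0.012, g),
               0.012 / 10 * 180 / pi, tolerance = 1e-12)
  expect_equal(rotation_uncertainty_deg(0.012, r_rms = 10),
               0.012 / 10 * 180 / pi, tolerance = 1e-12)
})
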