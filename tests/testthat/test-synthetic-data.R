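# Generators: screw-motion forward model, marker synthesis, bone surfaces,
# and the two canned experimental scenarios.

test_that("ground truth validates its invariants", {
  expect_error(ground_truth(dt = 0), "dt")
  expect_error(ground_truth(axis_direction = c(0, 0, 0)), "zero")
  expect_error(ground_truth(marker_noise_sigma = -1), "non-negative")
  expect_error(
    ground_truth(angle_profile = function(t) 45 * cos(t)),
    "monotone"
  )
  tr <- ground_truth()
  expect_lt(abs(sqrt(sum(tr$axis_direction^2)) - 1), 1e-12)
})

test_that("cluster geometry rejects degenerate marker sets", {
  expect_error(cluster_geometry(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
  expect_error(cluster_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  g <- cluster_geometry(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_s3_class(g, "cluster_geometry")
})

test_that("pure revolute motion keeps the axis fixed and stays orthonormal", {
  tr <- ground_truth(axis_point = c(0, 0, 0), axis_direction = c(0, 0, 1),
                     angle_profile = smoothstep_profile(0, 90, 2),
                     dt = 0.05, duration = 2, marker_noise_sigma = 0)
  poses <- make_screw_motion(tr)
  expect_lt(screwkin:::pose_orthonormality_error(poses$rotations), 1e-12)
  # axis points are fixed points of every pose
  for (i in c(1L, 11L, 41L)) {
    p <- c(0, 0, 5)
    moved <- poses$rotations[, , i] %*% p + poses$origins[i, ]
    expect_lt(max(abs(moved - p)), 1e-9)
  }
})

test_that("constant zero angle profile gives identity poses", {
  tr <- ground_truth(angle_profile = function(t) rep(0, length(t)),
                     dt = 0.1, duration = 1)
  poses <- make_screw_motion(tr)
  expect_lt(max(abs(poses$origins)), 1e-12)
  for (i in seq_along(poses$times)) {
    expect_lt(max(abs(poses$rotations[, , i] - diag(3))), 1e-12)
  }
})

test_that("constant-pitch screw accumulates p * Phi of axial translation", {
  p_pitch <- 2.5 # mm per rad
  tr <- ground_truth(axis_point = c(3, -2, 1),
                     axis_direction = c(1, 2, 2) / 3,
                     angle_profile = smoothstep_profile(0, 91, 4),
                     axial_translation_profile = function(th) p_pitch * th * pi / 180,
                     dt = 0.01, duration = 4)
  poses <- make_screw_motion(tr)
  N <- length(poses$times)
  # closed-form screw displacement of the final pose: rotation by Phi about
  # the axis plus translation p * Phi along it
  Phi <- 91 * pi / 180
  n <- tr$axis_direction
  probe <- c(10, 4, -7)
  R_exp <- oracle_rot_from_quat(c(cos(Phi / 2), sin(Phi / 2) * n))
  x_exp <- tr$axis_point + R_exp %*% (probe - tr$axis_point) + p_pitch * Phi * n
  x_got <- poses$rotations[, , N] %*% probe + poses$origins[N, ]
  expect_lt(max(abs(x_got - x_exp)), 1e-9)
})

test_that("noiseless marker trajectories are exactly rigid", {
  tr <- ground_truth(dt = 0.05, duration = 2)
  poses <- make_screw_motion(tr)
  g <- cluster_geometry(rbind(c(10, 0, 0), c(-10, 8, 0), c(0, -8, 9),
                              c(-4, 2, -10)))
  mk <- make_marker_trajectories(poses, g, g, sigma = 0, seed = 5)
  a <- mk$clusters$moving
  d12 <- sqrt(colSums((a[1L, , ] - a[2L, , ])^2))
  d34 <- sqrt(colSums((a[3L, , ] - a[4L, , ])^2))
  expect_lt(diff(range(d12)), 1e-12)
  expect_lt(diff(range(d34)), 1e-12)
  # noiseless moving markers equal pose-transformed offsets
  i <- 17L
  expect_equal(a[2L, , i],
               as.vector(poses$rotations[, , i] %*% g[2L, ] + poses$origins[i, ]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("marker noise has the prescribed standard deviation and is reproducible", {
  tr <- ground_truth(dt = 0.01, duration = 40)
  poses <- make_screw_motion(tr)
  g <- cluster_geometry(rbind(c(10, 0, 0), c(-10, 8, 0), c(0, -8, 9),
                              c(-4, 2, -10)))
  clean <- make_marker_trajectories(poses, g, g, sigma = 0, seed = 1)
  noisy <- make_marker_trajectories(poses, g, g, sigma = 0.012, seed = 1)
  resid <- noisy$clusters$moving - clean$clusters$moving
  expect_lt(abs(stats::sd(resid) / 0.012 - 1), 0.05)
  again <- make_marker_trajectories(poses, g, g, sigma = 0.012, seed = 1)
  expect_identical(noisy$clusters$moving, again$clusters$moving)
  other <- make_marker_trajectories(poses, g, g, sigma = 0.012, seed = 2)
  expect_false(identical(noisy$clusters$moving, other$clusters$moving))
})

test_that("synthetic surfaces lie on their primitives with the planted noise", {
  sc0 <- make_scenario("fresh", seed = 3, noiseless = TRUE, duration = 1)
  pr <- sc0$bones$truth_primitives
  d_head <- sqrt(rowSums(sweep(sc0$bones$surfaces$humeral_head, 2L,
                               pr$sphere$center)^2))
  expect_lt(max(abs(d_head - pr$sphere$radius)), 1e-9)
  d_cyl <- dist_to_line(sc0$bones$surfaces$humeral_trochlea,
                        pr$trochlea_humeral$axis_point,
                        pr$trochlea_humeral$axis_direction)
  expect_lt(max(abs(d_cyl - pr$trochlea_humeral$radius)), 1e-9)

  sc <- make_scenario("fresh", seed = 3, duration = 1)
  d_noisy <- sqrt(rowSums(sweep(sc$bones$surfaces$humeral_head, 2L,
                                pr$sphere$center)^2))
  expect_lt(abs(stats::sd(d_noisy - pr$sphere$radius) / 0.02 - 1), 0.10)
})

test_that("scenarios plant the printed displacement profiles", {
  expect_error(make_scenario("boiled"), "fresh, dry")
  fr <- make_scenario("fresh", seed = 1, noiseless = TRUE, duration = 1)
  expect_equal(fr$profiles$T_Z(0), 0.002, tolerance = 1e-12)
  expect_equal(fr$profiles$T_Z(91), 0.457, tolerance = 1e-12)
  th <- seq(0, 91, by = 0.25)
  expect_true(all(diff(fr$profiles$T_Z(th)) >= 0))

  dr <- make_scenario("dry", seed = 1, noiseless = TRUE, duration = 1)
  thd <- seq(0, 70, by = 0.1)
  tz <- dr$profiles$T_Z(thd)
  expect_equal(min(tz), -0.81, tolerance = 1e-9)
  expect_equal(max(tz), -0.017, tolerance = 1e-9)
  expect_true(any(diff(tz) > 0) && any(diff(tz) < 0)) # non-monotone
  rx <- dr$profiles$R_X(thd)
  expect_equal(range(rx), c(0, 47.5e-3), tolerance = 1e-9)
  ry <- dr$profiles$R_Y(thd)
  expect_equal(min(ry), -2.75e-3, tolerance = 1e-9)
  expect_equal(max(ry), 19.6e-3, tolerance = 1e-9)
  # dry flexion range strictly smaller than fresh
  expect_lt(max(dr$truth$angle_profile(screwkin:::truth_times(dr$truth))),
            max(fr$truth$angle_profile(screwkin:::truth_times(fr$truth))))
})

test_that("generators are pure functions of parameters and seed", {
  a <- make_scenario("dry", seed = 11, duration = 1)
  b <- make_scenario("dry", seed = 11, duration = 1)
  expect_identical(a$markers$clusters$moving, b$markers$clusters$moving)
  expect_identical(a$bones$surfaces$radial_trochlea,
                   b$bones$surfaces$radial_trochlea)
})
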