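# Canned synthetic scenarios emulating the two experimental conditions of
# the cadaveric protocol: "fresh" specimens (ligaments intact; smooth
# monotone medial-lateral translation from 0.002 mm at 0 degrees flexion to
# 0.457 mm at 91 degrees, all other non-flexion DoFs zero) and "dry"
# specimens (soft tissue removed; reduced flexion range, non-monotone
# medial-lateral translation spanning -0.81 to -0.017 mm, plus millidegree
# adduction-abduction and internal-external perturbations).

scenario_names <- c("fresh", "dry")

fresh_tz_profile <- function() hermite_profile(c(0, 91), c(0.002, 0.457))
dry_tz_profile <- function() hermite_profile(c(0, 35, 70), c(-0.017, -0.81, -0.1))
dry_rx_profile <- function() hermite_profile(c(0, 40, 70), c(0, 47.5e-3, 20e-3))
dry_ry_profile <- function() hermite_profile(c(0, 45, 70), c(-2.75e-3, 19.6e-3, 5e-3))

#' Geometric scene of a synthetic specimen
#'
#' Derives, from a planted flexion axis, a consistent anatomy: joint-frame
#' origin on the axis, humeral-head sphere off the axis, epicondyle
#' landmarks whose midpoint projects back onto the joint origin, a humeral
#' trochlea cylinder planted at a controlled in-plane offset and tilt from
#' the flexion axis, a radial trochlea cylinder at the wrist end of the
#' forearm with its styloids, and the two marker-cluster geometries.
#'
#' @param truth A [ground_truth()].
#' @param trochlea_offset_mm In-plane offset of the humeral-trochlea axis
#'   from the joint origin (default 1.31 mm).
#' @param trochlea_tilt_deg Tilt of the humeral-trochlea axis from the
#'   flexion axis (default 5.11 degrees).
#' @return A list: planted frame (`B`, `O_beta`, `C_W`), primitives,
#'   landmarks, cluster geometries.
#' @export
scenario_scene <- function(truth, trochlea_offset_mm = 1.31,
                           trochlea_tilt_deg = 5.11) {
  n <- truth$axis_direction
  u1 <- orthonormal_to(n)        # forearm direction at reference
  u2 <- cross3(n, u1)
  O_beta <- truth$axis_point + 10 * n
  C_S <- O_beta + 45 * u2 - 25 * n
  B <- build_frame_axes(C_S, O_beta, n)
  E_M <- O_beta + 19 * n + 7 * u1
  E_L <- O_beta - 19 * n + 7 * u1
  # humeral trochlea: axis through a point offset in the U_X U_Y plane,
  # tilted about U_X so both planted values are exact by construction
  P_hc <- O_beta + trochlea_offset_mm * B[, 1L]
  n_c <- as.vector(rotation_about_axis(B[, 1L], deg2rad(trochlea_tilt_deg)) %*% n)
  # radial trochlea at the wrist end of the forearm (moving-bone frame)
  W0 <- O_beta + 170 * u1
  S_r <- W0 + 14 * n + 3 * u1
  S_u <- W0 - 12 * n + 3 * u1
  lm <- landmarks(E_M, E_L, S_r, S_u)
  # tracking clusters: ~40 mm plates screwed close to the epiphyses, so the
  # lever arm from each cluster to the joint centre stays small
  spread <- rbind(c(20, 0, 0), c(-20, 16, 0), c(0, -16, 18), c(-8, 4, -20))
  geom_fixed <- cluster_geometry(sweep(spread, 2L, c(-12, 10, 14), "+"))
  geom_moving <- cluster_geometry(sweep(spread, 2L, c(10, 6, -5), "+"))
  list(B = B, O_beta = O_beta, C_S = C_S,
       sphere = list(center = C_S, radius = 16),
       trochlea_humeral = list(axis_point = P_hc, axis_direction = n_c,
                               radius = 11),
       trochlea_radial = list(axis_point = W0, axis_direction = n,
                              radius = 12),
       C_W_true = W0 + sum((((S_r + S_u) / 2) - W0) * n) * n,
       landmarks = lm,
       geom_fixed = geom_fixed,
       geom_moving = geom_moving,
       trochlea_offset_mm = trochlea_offset_mm,
       trochlea_tilt_deg = trochlea_tilt_deg)
}

#' Build a complete synthetic scenario
#'
#' Assembles ground truth, noiseless poses, noisy marker trajectories and
#' a digitized bone set for one of the two supported experimental
#' conditions. `"fresh"` is a pure screw joint: flexion 0 to 91 degrees
#' over 40 s with the medial-lateral translation ramping 0.002 to
#' 0.457 mm and every other non-flexion DoF identically zero. `"dry"` has
#' a reduced flexion range (0 to 70 degrees), a non-monotone
#' medial-lateral translation spanning -0.81 to -0.017 mm, and small
#' planted adduction-abduction / internal-external rotation profiles.
#'
#' @param name `"fresh"` or `"dry"`.
#' @param seed Integer seed; markers and surfaces use derived sub-seeds.
#' @param noiseless Zero both noise levels (for exact-recovery checks).
#' @param dt,duration Sampling interval and gesture duration, s.
#' @return A list of class `joint_scenario`: `name`, `truth`, `scene`,
#'   `poses` (noiseless), `markers`, `bones`, and `profiles` (the planted
#'   DoF profiles as functions of flexion).
#' @export
make_scenario <- function(name, seed = 1L, noiseless = FALSE,
                          dt = 0.01, duration = 40) {
  if (!is.character(name) || length(name) != 1L || !(name %in% scenario_names)) {
    stop(sprintf("unknown scenario '%s'; supported scenarios: %s",
                 as.character(name)[1L], paste(scenario_names, collapse = ", ")),
         call. = FALSE)
  }
  seed <- as.integer(seed)
  max_flex <- if (name == "fresh") 91 else 70
  tz <- if (name == "fresh") fresh_tz_profile() else dry_tz_profile()
  truth <- ground_truth(
    angle_profile = smoothstep_profile(0, max_flex, duration),
    axial_translation_profile = tz,
    marker_noise_sigma = if (noiseless) 0 else 0.012,
    surface_noise_sigma = if (noiseless) 0 else 0.02,
    dt = dt, duration = duration, seed = seed
  )
  scene <- scenario_scene(truth)
  profiles <- list(T_Z = tz,
                   R_X = if (name == "dry") dry_rx_profile(),
                   R_Y = if (name == "dry") dry_ry_profile())
  poses <- if (name == "fresh") {
    make_screw_motion(truth)
  } else {
    make_joint_motion(truth, scene$B, scene$O_beta,
                      rx_deg = profiles$R_X, ry_deg = profiles$R_Y)
  }
  markers <- make_marker_trajectories(poses, scene$geom_fixed,
                                      scene$geom_moving,
                                      sigma = truth$marker_noise_sigma,
                                      seed = seed)
  bones <- make_bone_geometry(truth, scene$sphere, scene$trochlea_humeral,
                              scene$trochlea_radial, scene$landmarks,
                              n_points = 2000L,
                              seed = seed + 1000003L)
  structure(list(name = name, truth = truth, scene = scene, poses = poses,
                 markers = markers, bones = bones, profiles = profiles),
            class = "joint_scenario")
}

#' Regenerate the marker trajectories of a scenario with a new noise draw
#'
#' Reuses the scenario's noiseless poses and cluster geometries; only the
#' marker noise is redrawn. Used to emulate repeated measurements (trials)
#' of the same specimen.
#'
#' @param scenario A `joint_scenario`.
#' @param seed Seed for the new noise draw.
#' @return A `marker_trajectories`.
#' @export
scenario_trial <- function(scenario, seed) {
  make_marker_trajectories(scenario$poses, scenario$scene$geom_fixed,
                           scenario$scene$geom_moving,
                           sigma = scenario$truth$marker_noise_sigma,
                           seed = seed)
}

#' @export
print.joint_scenario <- function(x, ...) {
  cat(sprintf("Synthetic '%s' scenario (%d frames, marker noise %g mm, surface noise %g mm)\n",
              x$name, length(x$poses$times), x$truth$marker_noise_sigma,
              x$truth$surface_noise_sigma))
  invisible(x)
}
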