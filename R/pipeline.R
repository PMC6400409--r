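# End-to-end orchestration: simulate a scenario to files on disk, and run
# the full analysis chain (pose reconstruction -> screw kinematics ->
# primitive fitting -> anatomical frame -> DoF decomposition -> axis
# comparison), either in memory or from a simulated directory.

#' Default analysis configuration
#'
#' All tunable thresholds and options of the analysis chain with their
#' defaults: `phi_min` (rad) smallest step rotation with a defined axis,
#' `omega_min` (rad/s) angular-velocity validity threshold, `s_min`
#' Rodrigues branch switch, `alpha` two-tailed significance level,
#' `grid_by` flexion-grid spacing (degrees), `side` limb side,
#' `axis_location` (`"finite"`: global large-baseline axis-point fit;
#' `"step_mean"`: weighted mean of per-step axis points),
#' `translation_uncertainty_mm` and `rotation_uncertainty_deg` for the
#' significance screen (`NULL`: derived from the moving-cluster geometry).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(phi_min = 1e-6,
       omega_min = 1e-8,
       s_min = 1e-4,
       alpha = 0.05,
       grid_by = 1,
       side = "right",
       axis_location = "finite",
       translation_uncertainty_mm = 0.012,
       rotation_uncertainty_deg = NULL)
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config options: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(base, config)
}

#' Simulate a scenario and write its files to a directory
#'
#' Writes everything a from-disk analysis needs: marker trajectories as TRC
#' and CSV, the three labelled surfaces as ascii PLY, landmarks and ground
#' truth as JSON, and the cluster geometries as JSON. Identical inputs
#' produce byte-identical outputs.
#'
#' @param name Scenario name (`"fresh"` or `"dry"`).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param noiseless Zero the noise levels.
#' @return Invisibly, the named vector of file paths written.
#' @export
simulate_experiment <- function(name, dir, seed = 1L, noiseless = FALSE) {
  sc <- make_scenario(name, seed = seed, noiseless = noiseless)
  if (sc$truth$duration < 5 * sc$truth$dt) {
    stop("duration must cover at least 5 frames (five-point stencil support)",
         call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    trc = file.path(dir, "markers.trc"),
    csv = file.path(dir, "markers.csv"),
    humeral_head = file.path(dir, "humeral_head.ply"),
    humeral_trochlea = file.path(dir, "humeral_trochlea.ply"),
    radial_trochlea = file.path(dir, "radial_trochlea.ply"),
    landmarks = file.path(dir, "landmarks.json"),
    clusters = file.path(dir, "clusters.json"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_trc(sc$markers, paths[["trc"]])
  write_marker_csv(sc$markers, paths[["csv"]])
  for (nm in names(sc$bones$surfaces)) {
    write_ply(sc$bones$surfaces[[nm]], paths[[nm]])
  }
  write_landmarks_json(sc$scene$landmarks, paths[["landmarks"]])
  jsonlite::write_json(
    list(fixed = unname(unclass(sc$scene$geom_fixed)),
         moving = unname(unclass(sc$scene$geom_moving))),
    paths[["clusters"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  t_grid <- truth_times(sc$truth)
  theta <- sc$truth$angle_profile(t_grid)
  jsonlite::write_json(
    list(scenario = name,
         seed = seed,
         axis_point = as.numeric(sc$truth$axis_point),
         axis_direction = as.numeric(sc$truth$axis_direction),
         marker_noise_sigma = sc$truth$marker_noise_sigma,
         surface_noise_sigma = sc$truth$surface_noise_sigma,
         dt = sc$truth$dt,
         duration = sc$truth$duration,
         flexion_deg = theta,
         axial_translation_mm = sc$truth$axial_translation_profile(theta)),
    paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the full analysis chain in memory
#'
#' Orchestrates every stage of the pipeline on one or more trials of the
#' same specimen: pose reconstruction from the marker clusters, screw-axis
#' extraction and mean flexion axis, sphere/cylinder fits of the labelled
#' surfaces, anatomical frame construction, per-trial DoF decomposition,
#' across-trial aggregation with Student-t error bars, the significance
#' screen, and the comparison between the surface-fit (humeral trochlea)
#' axis and the motion-derived flexion axis.
#'
#' One specimen-level flexion axis is estimated by pooling the screw steps
#' of all trials (angle-weighted direction) and averaging the per-trial
#' large-baseline axis-point fits; all trials are then decomposed in that
#' common anatomical frame, emulating repeated measurements of one mounted
#' specimen.
#'
#' @param markers A `marker_trajectories`, or a list of them (trials).
#' @param bones A `synthetic_bone_set`, or any list with `surfaces`
#'   (`humeral_head`, `humeral_trochlea`, `radial_trochlea`) and
#'   `landmarks`.
#' @param geom_fixed,geom_moving `cluster_geometry` objects.
#' @param config Optional list overriding [default_config()] entries.
#' @return A list of class `joint_analysis`: `poses` (first trial),
#'   `screw`, `mean_axis`, `sphere`, `cylinder_humeral`,
#'   `cylinder_radial`, `frame`, `carpal`, `samples`, `curves` (NULL for a
#'   single trial), `significant`, `axis_comparison`, `excluded_steps`,
#'   `config`.
#' @export
analyze_experiment <- function(markers, bones, geom_fixed, geom_moving,
                               config = NULL) {
  cfg <- merge_config(config)
  trials <- if (inherits(markers, "marker_trajectories")) list(markers) else markers
  stopifnot(length(trials) >= 1L)

  poses_all <- lapply(trials, relative_pose_series, geom_fixed, geom_moving)
  screw_all <- lapply(poses_all, screw_series, phi_min = cfg$phi_min,
                      omega_min = cfg$omega_min, s_min = cfg$s_min)
  screw <- screw_all[[1L]]

  # one specimen-level flexion axis: directions pooled over all trials,
  # location averaged over the per-trial estimates
  pooled <- do.call(rbind, lapply(screw_all, as.data.frame))
  axis <- mean_flexion_axis(pooled)
  if (cfg$axis_location == "finite") {
    pts <- vapply(poses_all, function(p) fit_axis_point(p, axis$n_m), numeric(3L))
    axis$A_m <- rowMeans(pts)
  }

  sphere <- fit_sphere(bones$surfaces$humeral_head)
  cyl_h <- fit_cylinder(bones$surfaces$humeral_trochlea)
  cyl_r <- fit_cylinder(bones$surfaces$radial_trochlea)
  lm <- bones$landmarks
  frame <- anatomical_frame(axis, sphere, lm, side = cfg$side)
  carpal <- locate_carpal_centre(cyl_r, lm$S_r, lm$S_u)

  samples <- do.call(rbind, lapply(seq_along(trials), function(j) {
    dof_samples(poses_all[[j]], frame, carpal, trial_id = j)
  }))
  class(samples) <- c("dof_samples", "data.frame")

  curves <- NULL
  significant <- NULL
  if (length(trials) >= 2L) {
    curves <- aggregate_curves(samples, alpha = cfg$alpha)
    rot_unc <- cfg$rotation_uncertainty_deg
    if (is.null(rot_unc)) {
      rot_unc <- rotation_uncertainty_deg(cfg$translation_uncertainty_mm,
                                          geom = geom_moving)
    }
    significant <- significance_screen(
      curves,
      translation_uncertainty_mm = cfg$translation_uncertainty_mm,
      rotation_uncertainty_deg = rot_unc)
  }
  comparison <- compare_axes(cyl_h, frame)

  structure(list(poses = poses_all[[1L]], screw = screw, mean_axis = axis,
                 sphere = sphere, cylinder_humeral = cyl_h,
                 cylinder_radial = cyl_r, frame = frame, carpal = carpal,
                 samples = samples, curves = curves, significant = significant,
                 axis_comparison = comparison,
                 excluded_steps = sum(!screw$valid),
                 config = cfg),
            class = "joint_analysis")
}

#' @export
print.joint_analysis <- function(x, ...) {
  cat("Joint kinematic analysis\n")
  print(x$mean_axis)
  cat(sprintf("  excluded screw steps: %d of %d\n", x$excluded_steps, nrow(x$screw)))
  print(x$axis_comparison)
  if (!is.null(x$significant)) {
    sig <- names(x$significant)[x$significant]
    cat(sprintf("  significant DoFs: %s\n",
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Run the analysis chain on a simulated directory
#'
#' Reads the files written by [simulate_experiment()] (markers TRC,
#' surfaces PLY, landmarks and cluster JSON) and runs
#' [analyze_experiment()]. The analysis is a pure function of the input
#' files and configuration: no randomness is involved.
#'
#' @param dir Directory written by [simulate_experiment()].
#' @param config Optional config overrides.
#' @param write_outputs Write result files (screw CSV, DoF curves CSV,
#'   frame and axis-comparison JSON) into `dir`.
#' @return A `joint_analysis`.
#' @export
analyze_dir <- function(dir, config = NULL, write_outputs = TRUE) {
  need <- c("markers.trc", "humeral_head.ply", "humeral_trochlea.ply",
            "radial_trochlea.ply", "landmarks.json", "clusters.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("missing input files: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  markers <- read_trc(file.path(dir, "markers.trc"))
  cl <- jsonlite::read_json(file.path(dir, "clusters.json"), simplifyVector = TRUE)
  geom_fixed <- cluster_geometry(cl$fixed)
  geom_moving <- cluster_geometry(cl$moving)
  bones <- list(
    surfaces = list(
      humeral_head = read_ply(file.path(dir, "humeral_head.ply")),
      humeral_trochlea = read_ply(file.path(dir, "humeral_trochlea.ply")),
      radial_trochlea = read_ply(file.path(dir, "radial_trochlea.ply"))
    ),
    landmarks = read_landmarks_json(file.path(dir, "landmarks.json"))
  )
  res <- analyze_experiment(markers, bones, geom_fixed, geom_moving, config)
  if (write_outputs) {
    write_screw_csv(res$screw, file.path(dir, "screw_parameters.csv"))
    write_frame_json(res$frame, file.path(dir, "anatomical_frame.json"),
                     extra_points = list(C_W = res$carpal$C_W,
                                         A_m = res$mean_axis$A_m))
    write_axis_comparison_json(list(res$axis_comparison),
                               file.path(dir, "axis_comparison.json"))
    if (!is.null(res$curves)) {
      write_dof_curves_csv(res$curves, file.path(dir, "dof_curves.csv"))
    }
  }
  res
}
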