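#' Time series of rigid poses
#'
#' Container for the pose of the moving bone frame expressed in the fixed
#' bone frame: per-frame proper rotation matrices and origin positions on a
#' uniform time base.
#'
#' @param times Strictly increasing, uniformly spaced times (s).
#' @param rotations 3 x 3 x N array of proper rotation matrices.
#' @param origins N x 3 matrix of origin positions (mm).
#' @param validate Check orthonormality of every frame (default TRUE).
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(times, rotations, origins, validate = TRUE) {
  times <- as.numeric(times)
  n <- length(times)
  origins <- as.matrix(origins)
  stopifnot(length(dim(rotations)) == 3L, all(dim(rotations)[1:2] == 3L),
            dim(rotations)[3L] == n, nrow(origins) == n, ncol(origins) == 3L)
  if (n >= 2L) {
    dts <- diff(times)
    if (any(dts <= 0) || max(abs(dts - dts[1L])) > 1e-9 * max(dts[1L], 1)) {
      stop("times must be strictly increasing and uniformly spaced", call. = FALSE)
    }
  }
  if (validate) {
    err <- pose_orthonormality_error(rotations)
    if (err > 1e-9) {
      stop(sprintf("rotations are not orthonormal (max error %.3g)", err), call. = FALSE)
    }
  }
  structure(list(times = times, rotations = rotations, origins = origins),
            class = "pose_series")
}

pose_orthonormality_error <- function(rotations) {
  n <- dim(rotations)[3L]
  err <- 0
  for (i in seq_len(n)) {
    R <- rotations[, , i]
    err <- max(err, max(abs(crossprod(R) - diag(3))), abs(det(R) - 1))
  }
  err
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("Rigid pose series: %d frames, dt = %g s\n",
              length(x$times), if (length(x$times) > 1) diff(x$times[1:2]) else NA))
  invisible(x)
}

#' @export
length.pose_series <- function(x) length(x$times)

# i-th pose as a list(R, O).
pose_at <- function(poses, i) {
  list(R = poses$rotations[, , i], O = poses$origins[i, ])
}

#' Least-squares rigid transform between two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' \eqn{\sum_k \|R p_k + t - q_k\|^2} (absolute orientation / Procrustes
#' problem), solved by centroid alignment and SVD of the cross-covariance
#' with reflection correction so that `det(R) = +1`.
#'
#' @param reference_points M x 3 matrix (body/reference frame), M >= 3,
#'   non-collinear.
#' @param observed_points M x 3 matrix of corresponding observed positions.
#' @return A list with `rotation` (3 x 3), `translation` (3-vector),
#'   `rms_residual` (mm).
#' @export
fit_rigid_transform <- function(reference_points, observed_points) {
  P <- as.matrix(reference_points)
  Q <- as.matrix(observed_points)
  if (!all(dim(P) == dim(Q))) stop("point counts differ between sets", call. = FALSE)
  if (nrow(P) < 3L || ncol(P) != 3L) stop("need at least 3 points of dimension 3", call. = FALSE)
  centred <- sweep(P, 2L, colMeans(P))
  sv <- svd(centred, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9) stop("degenerate geometry: reference points are collinear", call. = FALSE)
  fit <- cpp_rigid_fit(P, Q)
  list(rotation = fit$rotation,
       translation = as.vector(fit$translation),
       rms_residual = fit$rms)
}

#' Reconstruct the moving-in-fixed pose series from marker trajectories
#'
#' Per frame, fits the rigid pose of the fixed-bone cluster and of the
#' moving-bone cluster in lab coordinates, then composes them so that the
#' returned poses express the moving bone frame in the fixed bone frame
#' (the fixed bone defines the global frame of the analysis).
#'
#' @param markers A `marker_trajectories` object with (at least) the two
#'   named clusters.
#' @param geom_fixed,geom_moving `cluster_geometry` objects giving the
#'   body-frame marker offsets of the two clusters.
#' @param fixed,moving Cluster names in `markers` (defaults `"fixed"`,
#'   `"moving"`).
#' @return A `pose_series`; attribute `rms` holds the per-frame fit
#'   residuals of both clusters.
#' @export
relative_pose_series <- function(markers, geom_fixed, geom_moving,
                                 fixed = "fixed", moving = "moving") {
  for (nm in c(fixed, moving)) {
    if (is.null(markers$clusters[[nm]])) {
      stop(sprintf("cluster '%s' not present in marker trajectories", nm), call. = FALSE)
    }
  }
  obs_f <- markers$clusters[[fixed]]
  obs_m <- markers$clusters[[moving]]
  check_cluster_obs(obs_f, geom_fixed, fixed)
  check_cluster_obs(obs_m, geom_moving, moving)
  fit <- cpp_relative_pose_series(unclass(geom_fixed), obs_f,
                                  unclass(geom_moving), obs_m)
  out <- pose_series(markers$times, fit$rotations, fit$origins, validate = FALSE)
  attr(out, "rms") <- cbind(fixed = fit$rms_fixed, moving = fit$rms_moving)
  out
}

check_cluster_obs <- function(obs, geom, name) {
  if (length(dim(obs)) != 3L || dim(obs)[2L] != 3L) {
    stop(sprintf("cluster '%s': observations must be an M x 3 x N array", name),
         call. = FALSE)
  }
  if (dim(obs)[1L] != nrow(geom)) {
    stop(sprintf("cluster '%s': %d observed markers but %d in geometry",
                 name, dim(obs)[1L], nrow(geom)), call. = FALSE)
  }
  bad <- which(apply(is.na(obs) | !is.finite(obs), 3L, any))
  if (length(bad)) {
    stop(sprintf("cluster '%s': fewer than %d tracked markers at frame %d",
                 name, nrow(geom), bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}
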