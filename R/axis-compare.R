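# Geometric comparison between the surface-derived flexion axis (best-fit
# cylinder of the humeral trochlea) and the motion-derived mean flexion
# axis, measured in the U_X U_Y plane of the anatomical frame.

#' Compare a fitted cylinder axis with the motion-derived flexion axis
#'
#' Intersects the cylinder axis with the U_X U_Y plane through `O_beta`
#' (the plane normal to the mean flexion axis) and reports the in-plane
#' distance between that intersection point and `O_beta`, together with the
#' angle between the two axis directions,
#' \eqn{\arccos(|d_{cyl}\cdot n_m|)} in `[0, 90]` degrees (unsigned, so the
#' comparison is invariant to either axis' orientation convention).
#'
#' @param cyl A `fitted_cylinder` (humeral trochlea).
#' @param frame An `anatomical_frame` (carries `n_m` as U_Z and `O_beta`).
#' @return A list of class `axis_comparison`: `in_plane_distance` (mm),
#'   `angular_difference` (degrees), `point_cylinder`, `point_motion`
#'   (the two in-plane points, mm).
#' @export
compare_axes <- function(cyl, frame) {
  stopifnot(inherits(cyl, "fitted_cylinder"), inherits(frame, "anatomical_frame"))
  n_m <- frame$U[, 3L]
  Ob <- frame$origin
  d <- unitize(cyl$axis_direction)
  dn <- sum(d * n_m)
  if (abs(dn) < 1e-6) {
    stop("cylinder axis is parallel to the U_X U_Y plane: no intersection",
         call. = FALSE)
  }
  s <- sum((Ob - cyl$axis_point) * n_m) / dn
  P <- cyl$axis_point + s * d
  structure(list(in_plane_distance = vnorm(P - Ob),
                 angular_difference = rad2deg(acos(clamp(abs(dn), 0, 1))),
                 point_cylinder = P,
                 point_motion = Ob),
            class = "axis_comparison")
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf("Axis comparison: in-plane offset %.3f mm, angular difference %.3f deg\n",
              x$in_plane_distance, x$angular_difference))
  invisible(x)
}

#' Summarize axis comparisons over specimens
#'
#' Means and two-tailed Student-t confidence half-widths (df = n - 1) of
#' the in-plane distance and the angular difference over a set of specimen
#' comparisons.
#'
#' @param comparisons List of `axis_comparison` objects (>= 2).
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A list: `n`, `mean_distance`, `distance_half_width`,
#'   `mean_angle`, `angle_half_width`, `alpha`.
#' @export
multi_specimen_summary <- function(comparisons, alpha = 0.05) {
  if (length(comparisons) < 2L) {
    stop("need at least 2 specimen comparisons", call. = FALSE)
  }
  d <- vapply(comparisons, function(x) x$in_plane_distance, 0)
  a <- vapply(comparisons, function(x) x$angular_difference, 0)
  n <- length(comparisons)
  tc <- t_critical(n - 1L, alpha)
  list(n = n,
       mean_distance = mean(d),
       distance_half_width = tc * stats::sd(d) / sqrt(n),
       mean_angle = mean(a),
       angle_half_width = tc * stats::sd(a) / sqrt(n),
       alpha = alpha)
}

#' Write axis comparisons and their summary as JSON
#'
#' @param comparisons List of `axis_comparison` objects.
#' @param path Output path.
#' @param alpha Significance level for the summary (when >= 2 comparisons).
#' @return `path`, invisibly.
#' @export
write_axis_comparison_json <- function(comparisons, path, alpha = 0.05) {
  if (inherits(comparisons, "axis_comparison")) comparisons <- list(comparisons)
  obj <- list(
    comparisons = lapply(comparisons, function(x) {
      list(in_plane_distance_mm = x$in_plane_distance,
           angular_difference_deg = x$angular_difference,
           point_cylinder = as.numeric(x$point_cylinder),
           point_motion = as.numeric(x$point_motion))
    })
  )
  if (length(comparisons) >= 2L) {
    obj$summary <- multi_specimen_summary(comparisons, alpha)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
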