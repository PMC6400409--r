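# Anatomical joint-frame construction. The flexion axis measured from the
# motion (mean helical axis) is combined with fitted articular geometry and
# palpated landmarks to build the joint frame in which displacements are
# decomposed.

#' Landmarks of the elbow construction
#'
#' Medial/lateral humeral epicondyles (fixed bone) and radial/ulnar styloids
#' (moving bone), each a 3-vector in its bone's frame (mm).
#'
#' @param E_M,E_L Humeral epicondyle points.
#' @param S_r,S_u Radial and ulnar styloid points.
#' @return A list of class `landmarks`.
#' @export
landmarks <- function(E_M, E_L, S_r, S_u) {
  E_M <- vec3(E_M); E_L <- vec3(E_L); S_r <- vec3(S_r); S_u <- vec3(S_u)
  if (vnorm(E_M - E_L) < 1e-9) stop("epicondyle landmarks coincide", call. = FALSE)
  if (vnorm(S_r - S_u) < 1e-9) stop("styloid landmarks coincide", call. = FALSE)
  structure(list(E_M = E_M, E_L = E_L, S_r = S_r, S_u = S_u,
                 body = c(E_M = "humerus", E_L = "humerus",
                          S_r = "radius_ulna", S_u = "radius_ulna")),
            class = "landmarks")
}

#' Joint-frame axis triad from the mean flexion axis and the head center
#'
#' \eqn{U_Z = n_m}; \eqn{U_X = (\overrightarrow{A_m C_S} \times n_m) /
#' \|\overrightarrow{A_m C_S} \times n_m\|}; \eqn{U_Y = U_Z \times U_X}.
#' The triad is orthonormal and right-handed by construction.
#'
#' @param C_S Center of the best-fit humeral-head sphere, mm.
#' @param A_m Mean helical-axis point, mm.
#' @param n_m Mean flexion-axis unit direction.
#' @return 3 x 3 matrix with columns `U_X`, `U_Y`, `U_Z`.
#' @export
build_frame_axes <- function(C_S, A_m, n_m) {
  C_S <- vec3(C_S); A_m <- vec3(A_m)
  n_m <- unitize(vec3(n_m))
  w <- cross3(C_S - A_m, n_m)
  if (vnorm(w) < 1e-9) {
    stop("degenerate frame: head center lies on the flexion axis", call. = FALSE)
  }
  U_X <- w / vnorm(w)
  U_Z <- n_m
  U_Y <- cross3(U_Z, U_X)
  B <- cbind(U_X = U_X, U_Y = U_Y, U_Z = U_Z)
  rownames(B) <- c("x", "y", "z")
  B
}

#' Joint-frame origin on the flexion axis
#'
#' Intersects the flexion-axis line (through `A_m` along `n_m`) with the
#' plane normal to `n_m` through the epicondyle midpoint
#' `E = (E_M + E_L)/2`:
#' \eqn{O_\beta = A_m + ((E - A_m)\cdot n_m)\, n_m}.
#'
#' @param A_m Mean axis point, mm.
#' @param n_m Unit flexion-axis direction.
#' @param E_M,E_L Epicondyle landmark points, mm.
#' @return 3-vector `O_beta`, mm.
#' @export
locate_origin <- function(A_m, n_m, E_M, E_L) {
  A_m <- vec3(A_m); n_m <- unitize(vec3(n_m))
  E <- (vec3(E_M) + vec3(E_L)) / 2
  A_m + sum((E - A_m) * n_m) * n_m
}

#' Carpal joint center from the radial-trochlea cylinder
#'
#' Intersects the cylinder axis with the plane normal to it through the
#' styloid midpoint `S = (S_r + S_u)/2`; equivalently the orthogonal
#' projection of `S` onto the axis.
#'
#' @param cyl A `fitted_cylinder` (radial trochlea).
#' @param S_r,S_u Styloid landmark points, mm (moving-bone frame).
#' @return A list of class `carpal_centre`: `C_W`, `S`, `source_cylinder`.
#' @export
locate_carpal_centre <- function(cyl, S_r, S_u) {
  stopifnot(inherits(cyl, "fitted_cylinder"))
  S <- (vec3(S_r) + vec3(S_u)) / 2
  d <- unitize(cyl$axis_direction)
  C_W <- cyl$axis_point + sum((S - cyl$axis_point) * d) * d
  structure(list(C_W = C_W, S = S, source_cylinder = cyl),
            class = "carpal_centre")
}

#' Assemble the anatomical joint frame
#'
#' Combines the mean flexion axis, the fitted humeral-head sphere and the
#' epicondyle landmarks into the joint frame: axis triad via
#' [build_frame_axes()], origin via [locate_origin()]. For a left limb the
#' axis direction is flipped first so that flexion is a positive rotation
#' about `U_Z` and `+U_Z` points medially on either side.
#'
#' @param axis A `mean_axis` (from [mean_flexion_axis()]).
#' @param sphere A `fitted_sphere` (humeral head).
#' @param lm A `landmarks` object (uses `E_M`, `E_L`).
#' @param side `"right"` (default) or `"left"`.
#' @return A list of class `anatomical_frame`: `U` (3 x 3, columns U_X,
#'   U_Y, U_Z), `origin` (`O_beta`), `side`, `provenance`.
#' @export
anatomical_frame <- function(axis, sphere, lm, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(axis, "mean_axis"), inherits(sphere, "fitted_sphere"),
            inherits(lm, "landmarks"))
  n_m <- if (side == "left") -axis$n_m else axis$n_m
  U <- build_frame_axes(sphere$center, axis$A_m, n_m)
  O_beta <- locate_origin(axis$A_m, n_m, lm$E_M, lm$E_L)
  structure(list(U = U, origin = O_beta, side = side,
                 provenance = list(axis = axis, sphere = sphere, landmarks = lm)),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("Anatomical joint frame\n")
  cat(sprintf("  O_beta = (%.3f, %.3f, %.3f) mm [%s limb]\n",
              x$origin[1L], x$origin[2L], x$origin[3L], x$side))
  for (k in 1:3) {
    cat(sprintf("  U_%s = (%.5f, %.5f, %.5f)\n", c("X", "Y", "Z")[k],
                x$U[1L, k], x$U[2L, k], x$U[3L, k]))
  }
  invisible(x)
}

#' Export an anatomical frame as JSON
#'
#' Writes the 4 x 4 homogeneous transform of the joint frame (columns of
#' `U` plus origin) and the named auxiliary points.
#'
#' @param frame An `anatomical_frame`.
#' @param path Output path.
#' @param extra_points Optional named list of 3-vectors to include.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path, extra_points = list()) {
  H <- rbind(cbind(frame$U, frame$origin), c(0, 0, 0, 1))
  obj <- list(
    homogeneous_transform = unname(apply(H, 1L, as.numeric, simplify = FALSE)),
    origin = as.numeric(frame$origin),
    U_X = as.numeric(frame$U[, 1L]),
    U_Y = as.numeric(frame$U[, 2L]),
    U_Z = as.numeric(frame$U[, 3L]),
    side = frame$side,
    points = lapply(extra_points, as.numeric)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
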