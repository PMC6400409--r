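# Synthetic bone-surface digitization: labelled point clouds sampled on the
# articular primitives (sphere cap for the humeral head, cylinder patches
# for the trochleae) with Gaussian digitization noise, plus the landmark
# points. Emulates a structured-light surface scan of the two bones in the
# reference configuration.

# n points uniformly on a spherical cap of half-angle `cap_deg` about
# `pole`, radius r, centred at c. Uses the current RNG stream.
sample_sphere_cap <- function(center, radius, pole, cap_deg, n) {
  pole <- unitize(pole)
  u <- stats::runif(n, cos(deg2rad(cap_deg)), 1)  # cos(polar angle)
  az <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - u^2, 0))
  e1 <- orthonormal_to(pole)
  e2 <- cross3(pole, e1)
  dirs <- outer(u, pole) + outer(s * cos(az), e1) + outer(s * sin(az), e2)
  sweep(dirs * radius, 2L, center, "+")
}

# n points on a cylinder patch: axis through p along d, radius r, axial
# extent [-len/2, len/2], azimuth within [-arc/2, arc/2] about e1.
sample_cylinder_patch <- function(axis_point, axis_direction, radius, arc_deg,
                                  length_mm, n) {
  d <- unitize(axis_direction)
  e1 <- orthonormal_to(d)
  e2 <- cross3(d, e1)
  az <- stats::runif(n, -deg2rad(arc_deg) / 2, deg2rad(arc_deg) / 2)
  z <- stats::runif(n, -length_mm / 2, length_mm / 2)
  pts <- outer(z, d) + radius * (outer(cos(az), e1) + outer(sin(az), e2))
  sweep(pts, 2L, axis_point, "+")
}

#' Generate a synthetic digitized bone set
#'
#' Samples labelled point clouds on the three articular primitives of the
#' elbow construction -- humeral head (sphere cap), humeral trochlea
#' (cylinder patch), radial trochlea (cylinder patch) -- each perturbed by
#' isotropic Gaussian digitization noise of SD `truth$surface_noise_sigma`,
#' and attaches the four landmark points. Humeral regions are expressed in
#' the fixed (global) frame; the radial trochlea and styloids in the
#' moving-bone frame at the reference configuration.
#'
#' @param truth A [ground_truth()] (supplies the surface noise SD).
#' @param sphere List `center`, `radius` (mm) for the humeral head; a
#'   `cap_deg` half-angle (default 70) and `pole` direction (default away
#'   from the axis point) may be given.
#' @param trochlea_humeral,trochlea_radial Lists `axis_point`,
#'   `axis_direction`, `radius`, and optionally `arc_deg` (default 140 /
#'   120) and `length` (default 30 / 25 mm).
#' @param lm A [landmarks()] object.
#' @param n_points Points per surface (>= 50).
#' @param seed RNG seed.
#' @return A list of class `synthetic_bone_set`: `surfaces` (named list of
#'   N x 3 matrices), `bodies` (region to bone map), `landmarks`,
#'   `truth_primitives` (the planted parameters), `narrow_patch` flags,
#'   `sigma`.
#' @export
make_bone_geometry <- function(truth, sphere, trochlea_humeral,
                               trochlea_radial, lm, n_points = 2000L,
                               seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(lm, "landmarks"))
  if (n_points < 50L) stop("need at least 50 points per surface", call. = FALSE)
  if (sphere$radius <= 0 || trochlea_humeral$radius <= 0 ||
      trochlea_radial$radius <= 0) {
    stop("primitive radii must be positive", call. = FALSE)
  }
  defaults <- function(x, arc, len) {
    if (is.null(x$arc_deg)) x$arc_deg <- arc
    if (is.null(x$length)) x$length <- len
    x
  }
  trochlea_humeral <- defaults(trochlea_humeral, 140, 30)
  trochlea_radial <- defaults(trochlea_radial, 120, 25)
  if (is.null(sphere$cap_deg)) sphere$cap_deg <- 70
  if (is.null(sphere$pole)) {
    sphere$pole <- unitize(sphere$center - truth$axis_point)
  }
  narrow <- c(humeral_trochlea = trochlea_humeral$arc_deg < 30,
              radial_trochlea = trochlea_radial$arc_deg < 30)
  sigma <- truth$surface_noise_sigma
  surfaces <- withr::with_seed(as.integer(seed), {
    s <- list(
      humeral_head = sample_sphere_cap(sphere$center, sphere$radius,
                                       sphere$pole, sphere$cap_deg, n_points),
      humeral_trochlea = sample_cylinder_patch(trochlea_humeral$axis_point,
                                               trochlea_humeral$axis_direction,
                                               trochlea_humeral$radius,
                                               trochlea_humeral$arc_deg,
                                               trochlea_humeral$length, n_points),
      radial_trochlea = sample_cylinder_patch(trochlea_radial$axis_point,
                                              trochlea_radial$axis_direction,
                                              trochlea_radial$radius,
                                              trochlea_radial$arc_deg,
                                              trochlea_radial$length, n_points)
    )
    if (sigma > 0) {
      s <- lapply(s, function(X) X + matrix(stats::rnorm(length(X), 0, sigma),
                                            nrow(X), 3L))
    }
    s
  })
  structure(list(surfaces = surfaces,
                 bodies = c(humeral_head = "humerus",
                            humeral_trochlea = "humerus",
                            radial_trochlea = "radius_ulna"),
                 landmarks = lm,
                 truth_primitives = list(sphere = sphere,
                                         trochlea_humeral = trochlea_humeral,
                                         trochlea_radial = trochlea_radial),
                 narrow_patch = narrow,
                 sigma = sigma),
            class = "synthetic_bone_set")
}

#' @export
print.synthetic_bone_set <- function(x, ...) {
  cat("Synthetic digitized bone set\n")
  for (nm in names(x$surfaces)) {
    cat(sprintf("  %s (%s): %d points\n", nm, x$bodies[[nm]], nrow(x$surfaces[[nm]])))
  }
  cat(sprintf("  digitization noise: %g mm\n", x$sigma))
  invisible(x)
}

#' Write a point cloud as ascii PLY
#'
#' Minimal ascii PLY with float vertex properties x, y, z.
#'
#' @param points N x 3 matrix, mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path) {
  X <- as.matrix(points)
  stopifnot(ncol(X) == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(X)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(X, digits = 9, trim = TRUE, scientific = FALSE),
                     con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ascii PLY vertex cloud
#'
#' Reads the vertex element (x, y, z properties) of an ascii PLY file.
#'
#' @param path PLY file path.
#' @return N x 3 numeric matrix.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (tolower(trimws(lines[1L])) != "ply") stop("not a PLY file", call. = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header", call. = FALSE)
  vline <- grep("^element vertex", trimws(lines[seq_len(end)]), value = TRUE)
  if (!length(vline)) stop("PLY file has no vertex element", call. = FALSE)
  n <- as.integer(strsplit(vline[1L], "\\s+")[[1L]][3L])
  dat <- utils::read.table(text = lines[(end + 1L):(end + n)])
  as.matrix(dat[, 1:3, drop = FALSE])
}

#' Write landmarks as JSON
#'
#' @param lm A `landmarks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  obj <- list(E_M = as.numeric(lm$E_M), E_L = as.numeric(lm$E_L),
              S_r = as.numeric(lm$S_r), S_u = as.numeric(lm$S_u),
              body = as.list(lm$body))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path JSON path written by [write_landmarks_json()].
#' @return A `landmarks` object.
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("E_M", "E_L", "S_r", "S_u")) {
    if (is.null(obj[[key]])) {
      stop(sprintf("landmark file is missing key '%s'", key), call. = FALSE)
    }
  }
  landmarks(obj$E_M, obj$E_L, obj$S_r, obj$S_u)
}
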