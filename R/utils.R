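# Small geometry helpers shared across the package. All lengths in mm,
# internal angles in radians unless a function name says "deg".

vec3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L || anyNA(x)) stop("expected a finite 3-vector", call. = FALSE)
  x
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two N x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2L] * B[, 3L] - A[, 3L] * B[, 2L],
        A[, 3L] * B[, 1L] - A[, 1L] * B[, 3L],
        A[, 1L] * B[, 2L] - A[, 2L] * B[, 1L])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Any unit vector orthogonal to n (deterministic choice).
orthonormal_to <- function(n) {
  n <- unitize(n)
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitize(cross3(n, ref))
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

stopifnot_rotation <- function(R, tol = 1e-6) {
  if (!is_rotation_matrix(R, tol)) {
    stop("matrix is not a proper rotation (orthonormal, det +1)", call. = FALSE)
  }
  invisible(R)
}

#' Rotation matrix about an arbitrary unit axis
#'
#' Builds the 3x3 proper rotation matrix rotating by `phi` radians about the
#' unit direction `n`, via the Rodrigues rotation formula
#' \eqn{R = \cos\phi\, I + (1-\cos\phi)\, n n^T + \sin\phi\, [n]_\times}.
#'
#' @param n Unit 3-vector, axis direction.
#' @param phi Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(n, phi) {
  n <- unitize(vec3(n))
  K <- matrix(c(0, n[3L], -n[2L], -n[3L], 0, n[1L], n[2L], -n[1L], 0), 3L, 3L)
  cos(phi) * diag(3) + (1 - cos(phi)) * tcrossprod(n) + sin(phi) * K
}

rot_x <- function(a) rotation_about_axis(c(1, 0, 0), a)
rot_y <- function(a) rotation_about_axis(c(0, 1, 0), a)
rot_z <- function(a) rotation_about_axis(c(0, 0, 1), a)

# Distance from points (N x 3) to the line through `p` with unit direction
# `d`, computed from the perpendicular residual to avoid cancellation.
point_line_distance <- function(X, p, d) {
  d <- unitize(d)
  V <- sweep(X, 2L, p)
  perp <- V - outer(as.vector(V %*% d), d)
  sqrt(rowSums(perp * perp))
}
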