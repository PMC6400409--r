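# Orthogonal least-squares fitting of the articular-surface primitives used
# by the anatomical frame: a sphere (humeral head) and cylinders (humeral
# and radial trochleae). Algebraic initialization followed by geometric
# (orthogonal-distance) refinement with a Levenberg-Marquardt solver.

#' Best-fit sphere through a 3-D point cloud
#'
#' Minimizes the geometric objective \eqn{\sum_k (\|p_k - c\| - r)^2}.
#' The center is initialized by the algebraic (linear) sphere fit and
#' refined by Levenberg-Marquardt on the orthogonal distances; the radius is
#' profiled out (optimal radius is the mean center-to-point distance).
#'
#' @param points N x 3 matrix, N >= 4, not coplanar. mm.
#' @return A list of class `fitted_sphere`: `center` (mm), `radius` (mm),
#'   `rms_residual` (mm), `n_points`.
#' @export
fit_sphere <- function(points) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (ncol(X) != 3L || nrow(X) < 4L) stop("need at least 4 points in 3-D", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[3L] <= 1e-9 * max(sv[1L], 1)) {
    stop("degenerate geometry: points are coplanar, sphere fit is singular",
         call. = FALSE)
  }
  # algebraic init: ||p||^2 = 2 c.p + (r^2 - ||c||^2), linear in (c, k)
  A <- cbind(2 * Xc, 1)
  b <- rowSums(Xc * Xc)
  beta <- qr.solve(A, b)
  c0 <- beta[1:3]
  resid_fun <- function(cc) {
    d <- sqrt(rowSums(sweep(Xc, 2L, cc)^2))
    d - mean(d)
  }
  fit <- minpack.lm::nls.lm(par = c0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  cc <- fit$par
  d <- sqrt(rowSums(sweep(Xc, 2L, cc)^2))
  structure(list(center = cc + ctr,
                 radius = mean(d),
                 rms_residual = sqrt(mean((d - mean(d))^2)),
                 n_points = nrow(X)),
            class = "fitted_sphere")
}

#' @export
print.fitted_sphere <- function(x, ...) {
  cat(sprintf("Fitted sphere: center (%.4f, %.4f, %.4f) mm, radius %.4f mm, rms %.4g mm (n = %d)\n",
              x$center[1L], x$center[2L], x$center[3L], x$radius, x$rms_residual,
              x$n_points))
  invisible(x)
}

# Canonical axis sign: make the component of largest magnitude positive;
# on ties prefer +x, then +y, then +z.
canonical_axis_sign <- function(d) {
  k <- which(abs(d) >= max(abs(d)) - 1e-12)[1L]
  if (d[k] < 0) -d else d
}

#' Best-fit cylinder through a 3-D point cloud
#'
#' Minimizes \eqn{\sum_k (\mathrm{dist}(p_k, \mathrm{axis}) - r)^2} over the
#' axis line and radius (radius profiled out). The axis direction is
#' initialized from the principal directions of the point covariance (all
#' three are tried, the best refined fit is kept); the in-plane axis
#' position is initialized by an algebraic circle fit of the projected
#' points. The returned `axis_point` is the projection of the point
#' centroid onto the axis, and the direction sign is canonicalized
#' (largest-magnitude component positive) so fits are deterministic.
#'
#' Points spanning less than 30 degrees of arc around the fitted axis give
#' a `narrow_arc = TRUE` flag; exactly collinear or coplanar points are a
#' degeneracy error.
#'
#' @param points N x 3 matrix, N >= 6. mm.
#' @return A list of class `fitted_cylinder`: `axis_point`,
#'   `axis_direction` (unit), `radius`, `rms_residual`, `n_points`,
#'   `arc_deg`, `narrow_arc`.
#' @export
fit_cylinder <- function(points) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  if (ncol(X) != 3L || nrow(X) < 6L) stop("need at least 6 points in 3-D", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  s <- svd(Xc)
  if (s$d[2L] <= 1e-9 * max(s$d[1L], 1)) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  if (s$d[3L] <= 1e-9 * max(s$d[1L], 1)) {
    stop("degenerate geometry: points are coplanar, cylinder fit is singular",
         call. = FALSE)
  }
  best <- NULL
  for (k in 1:3) {
    cand <- try(refine_cylinder(Xc, s$v[, k]), silent = TRUE)
    if (inherits(cand, "try-error")) next
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (is.null(best)) stop("cylinder fit failed to converge", call. = FALSE)
  d <- canonical_axis_sign(best$direction)
  # canonical point: projection of the centroid (origin of Xc) onto the axis
  p <- best$point - sum(best$point * d) * d
  V <- sweep(Xc, 2L, p)
  along <- as.vector(V %*% d)
  radial <- V - outer(along, d)
  dist <- sqrt(rowSums(radial * radial))
  r <- mean(dist)
  # angular extent around the axis
  u <- orthonormal_to(d); v <- cross3(d, u)
  az <- sort(atan2(radial %*% v, radial %*% u))
  gaps <- diff(c(az, az[1L] + 2 * pi))
  arc <- 2 * pi - max(gaps)
  narrow <- arc < deg2rad(30)
  if (narrow) {
    warning(sprintf("cylinder patch subtends only %.1f degrees; axis poorly identifiable",
                    rad2deg(arc)), call. = FALSE)
  }
  structure(list(axis_point = p + ctr,
                 axis_direction = d,
                 radius = r,
                 rms_residual = sqrt(mean((dist - r)^2)),
                 n_points = nrow(X),
                 arc_deg = rad2deg(arc),
                 narrow_arc = narrow),
            class = "fitted_cylinder")
}

# Levenberg-Marquardt refinement of a cylinder axis from one direction
# candidate. Xc is centred; parameters are the axis direction perturbation
# (2 angles in the tangent basis of d0) and the in-plane axis point (2
# coordinates in the plane through the origin orthogonal to d0).
refine_cylinder <- function(Xc, d0) {
  d0 <- unitize(d0)
  u0 <- orthonormal_to(d0)
  v0 <- cross3(d0, u0)
  # init axis point: algebraic circle fit of the projection onto (u0, v0)
  P2 <- cbind(Xc %*% u0, Xc %*% v0)
  A <- cbind(2 * P2, 1)
  b <- rowSums(P2 * P2)
  beta <- try(qr.solve(A, b), silent = TRUE)
  c2 <- if (inherits(beta, "try-error")) c(0, 0) else beta[1:2]
  par0 <- c(c2[1L], c2[2L], 0, 0)
  resid_fun <- function(par) {
    d <- unitize(d0 + par[3L] * u0 + par[4L] * v0)
    p <- par[1L] * u0 + par[2L] * v0
    V <- sweep(Xc, 2L, p)
    along <- as.vector(V %*% d)
    dist <- sqrt(pmax(rowSums(V * V) - along^2, 0))
    dist - mean(dist)
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  par <- fit$par
  list(direction = unitize(d0 + par[3L] * u0 + par[4L] * v0),
       point = par[1L] * u0 + par[2L] * v0,
       sse = sum(resid_fun(par)^2))
}

#' @export
print.fitted_cylinder <- function(x, ...) {
  cat(sprintf("Fitted cylinder: axis (%.4f, %.4f, %.4f) + t*(%.5f, %.5f, %.5f), radius %.4f mm, rms %.4g mm (n = %d, arc %.0f deg)\n",
              x$axis_point[1L], x$axis_point[2L], x$axis_point[3L],
              x$axis_direction[1L], x$axis_direction[2L], x$axis_direction[3L],
              x$radius, x$rms_residual, x$n_points, x$arc_deg))
  invisible(x)
}
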