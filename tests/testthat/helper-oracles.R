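# Independent oracles used to cross-check the package's implementations.
# They deliberately use different algorithms (quaternion algebra, complex
# matrix logarithm, derivative-free search) than the code paths they test.

# Rotation matrix from a unit quaternion (w, x, y, z) -- the standard
# quaternion-to-matrix map, independent of the package's Rodrigues formula.
oracle_rot_from_quat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# Random proper rotation with angle in a given range (rad).
oracle_random_rotation <- function(phi_range = c(0.01, 3.0)) {
  u <- stats::rnorm(3L)
  u <- u / sqrt(sum(u^2))
  phi <- stats::runif(1L, phi_range[1L], phi_range[2L])
  oracle_rot_from_quat(c(cos(phi / 2), sin(phi / 2) * u))
}

# Rotation vector (phi * axis) via the complex-eigendecomposition matrix
# logarithm: independent of any quaternion or trace-based extraction.
oracle_rotation_vector <- function(R) {
  e <- eigen(R)
  L <- e$vectors %*% diag(log(as.complex(e$values))) %*% solve(e$vectors)
  L <- Re(L)
  c(L[3L, 2L] - L[2L, 3L], L[1L, 3L] - L[3L, 1L], L[2L, 1L] - L[1L, 2L]) / 2
}

# Unit quaternion (w >= 0) from a rotation matrix via the matrix logarithm.
oracle_quat_from_matrix <- function(R) {
  rho <- oracle_rotation_vector(R)
  phi <- sqrt(sum(rho^2))
  if (phi < 1e-300) return(c(1, 0, 0, 0))
  q <- c(cos(phi / 2), sin(phi / 2) * rho / phi)
  if (q[1L] < 0) -q else q
}

# Brute-force geometric sphere fit: multi-start Nelder-Mead over the
# center, radius profiled out.
oracle_fit_sphere <- function(X) {
  obj <- function(cc) {
    d <- sqrt(rowSums(sweep(X, 2L, cc)^2))
    sum((d - mean(d))^2)
  }
  ctr <- colMeans(X)
  span <- max(apply(X, 2L, function(v) diff(range(v))))
  starts <- rbind(ctr,
                  ctr + c(span, 0, 0), ctr - c(span, 0, 0),
                  ctr + c(0, span, 0), ctr - c(0, span, 0),
                  ctr + c(0, 0, span), ctr - c(0, 0, span))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || f$value < best$value) best <- f
  }
  d <- sqrt(rowSums(sweep(X, 2L, best$par)^2))
  list(center = best$par, radius = mean(d))
}

# Brute-force cylinder fit: grid over axis directions (two spherical
# angles), then Nelder-Mead refinement of direction and in-plane position.
oracle_fit_cylinder <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  obj4 <- function(par) {
    th <- par[1L]; ph <- par[2L]
    d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * d) * d; u <- u / sqrt(sum(u^2))
    v <- c(d[2L] * u[3L] - d[3L] * u[2L],
           d[3L] * u[1L] - d[1L] * u[3L],
           d[1L] * u[2L] - d[2L] * u[1L])
    p <- par[3L] * u + par[4L] * v
    V <- sweep(Xc, 2L, p)
    along <- as.vector(V %*% d)
    dist <- sqrt(pmax(rowSums(V * V) - along^2, 0))
    sum((dist - mean(dist))^2)
  }
  grid <- expand.grid(th = seq(0, pi, length.out = 13L),
                      ph = seq(0, pi, length.out = 13L))
  vals <- apply(grid, 1L, function(g) obj4(c(g[1L], g[2L], 0, 0)))
  best <- NULL
  for (i in order(vals)[1:3]) {
    f <- stats::optim(c(grid$th[i], grid$ph[i], 0, 0), obj4,
                      method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-15))
    if (is.null(best) || f$value < best$value) best <- f
  }
  th <- best$par[1L]; ph <- best$par[2L]
  d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  list(direction = d, value = best$value)
}

# Angle (rad) between two lines (sign-insensitive directions).
line_angle <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b))))
}

# Distance of points (N x 3 or 3-vector) from a line (cancellation-free).
dist_to_line <- function(X, p, d) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  d <- d / sqrt(sum(d * d))
  V <- sweep(X, 2L, p)
  perp <- V - outer(as.vector(V %*% d), d)
  sqrt(rowSums(perp * perp))
}

# Small random rigid transform used in equivariance checks.
random_rigid <- function() {
  Q <- oracle_random_rotation(c(0.1, 2.5))
  list(R = Q, t = stats::rnorm(3L, 0, 20))
}
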