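# Samplers for planted primitive surfaces used across tests.

sphere_points <- function(center, radius, n, cap_deg = 180, pole = c(0, 0, 1)) {
  u <- stats::runif(n, cos(cap_deg * pi / 180), 1)
  az <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - u^2, 0))
  e1 <- if (abs(pole[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * pole) * pole; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(pole[2L] * e1[3L] - pole[3L] * e1[2L],
          pole[3L] * e1[1L] - pole[1L] * e1[3L],
          pole[1L] * e1[2L] - pole[2L] * e1[1L])
  dirs <- outer(u, pole) + outer(s * cos(az), e1) + outer(s * sin(az), e2)
  sweep(dirs * radius, 2L, center, "+")
}

cylinder_points <- function(p, d, r, n, arc_deg = 360, len = 30) {
  d <- d / sqrt(sum(d^2))
  e1 <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2L] * e1[3L] - d[3L] * e1[2L],
          d[3L] * e1[1L] - d[1L] * e1[3L],
          d[1L] * e1[2L] - d[2L] * e1[1L])
  az <- stats::runif(n, -arc_deg * pi / 360, arc_deg * pi / 360)
  z <- stats::runif(n, -len / 2, len / 2)
  sweep(outer(z, d) + r * (outer(cos(az), e1) + outer(sin(az), e2)), 2L, p, "+")
}

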