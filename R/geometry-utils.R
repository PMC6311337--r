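# Small vector/polyline helpers shared across the geometric stages.
# Points are rows of n x 3 matrices, millimetres throughout.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors in degrees
vangle <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

as_point_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

# cumulative chord length of an ordered polyline (n x 3)
polyline_arclength <- function(p) {
  p <- as_point_matrix(p)
  if (nrow(p) < 2) return(0)
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# resample an ordered polyline at (roughly) the given chord step
polyline_resample <- function(p, step) {
  p <- as_point_matrix(p)
  s <- polyline_arclength(p)
  total <- s[length(s)]
  if (total <= step) return(p)
  targets <- seq(0, total, by = step)
  if (targets[length(targets)] < total) targets <- c(targets, total)
  out <- matrix(NA_real_, length(targets), 3)
  for (i in seq_along(targets)) {
    out[i, ] <- polyline_point_at(p, s, targets[i])
  }
  out
}

# point at arc length a along polyline with precomputed cumulative lengths s
polyline_point_at <- function(p, s, a) {
  if (a <= 0) return(p[1, ])
  n <- nrow(p)
  if (a >= s[n]) return(p[n, ])
  i <- findInterval(a, s)
  f <- (a - s[i]) / (s[i + 1] - s[i])
  p[i, ] * (1 - f) + p[i + 1, ] * f
}

# nearest point on a polyline to a query point; returns list(point, arc, dist)
polyline_nearest <- function(p, q) {
  p <- as_point_matrix(p)
  n <- nrow(p)
  if (n == 1) {
    return(list(point = p[1, ], arc = 0, dist = vnorm(q - p[1, ])))
  }
  s <- polyline_arclength(p)
  best <- list(point = p[1, ], arc = 0, dist = Inf)
  for (i in seq_len(n - 1)) {
    a <- p[i, ]; b <- p[i + 1, ]
    ab <- b - a
    L2 <- sum(ab * ab)
    t <- if (L2 < 1e-18) 0 else max(0, min(1, sum((q - a) * ab) / L2))
    pt <- a + t * ab
    d <- vnorm(q - pt)
    if (d < best$dist) {
      best <- list(point = pt, arc = s[i] + t * sqrt(L2), dist = d)
    }
  }
  best
}

# rotation matrix for angle deg about unit axis (Rodrigues)
rotation_about <- function(axis, deg) {
  u <- unitv(axis)
  th <- deg2rad(deg)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# orthonormal basis of the plane with unit normal n
plane_basis <- function(n) {
  n <- unitv(n)
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitv(a - sum(a * n) * n)
  e2 <- cross3(n, e1)
  list(e1 = e1, e2 = e2)
}

# component of v inside the plane with unit normal n
project_to_plane <- function(v, n) {
  n <- unitv(n)
  v - sum(v * n) * n
}
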