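# rotation matrices and small geometry helpers shared across tests

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), nrow = 3)
}

rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), nrow = 3)
}

# random rotation matrix via QR of a Gaussian matrix (det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_cloud <- function(cloud, R) {
  m <- as.matrix(as.data.frame(cloud)[, c("x", "y", "z")]) %*% t(R)
  point_cloud(data.frame(x = m[, 1], y = m[, 2], z = m[, 3]),
              grid_shape = grid_shape(cloud))
}

plane_tilt_deg_test <- function(normal) {
  acos(min(1, abs(normal[3]))) * 180 / pi
}

random_unit_normals <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# dense flat elliptical footprint at z = 0
ellipse_cloud <- function(a, b, spacing = 0.5) {
  g <- seq(-a, a, by = spacing)
  x <- rep(g, each = length(g))
  y <- rep(g, times = length(g))
  keep <- (x / a)^2 + (y / b)^2 <= 1
  point_cloud(data.frame(x = x[keep], y = y[keep], z = 0))
}

# width of a 2D point set along each direction, scanned exhaustively
direction_scan_widths <- function(xy, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  dirs <- rbind(cos(th), sin(th))
  proj <- xy %*% dirs
  apply(proj, 2, function(v) diff(range(v)))
}
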