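# Internal vector geometry helpers shared by the builders and analyses.
# All angles in degrees unless a function name says otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

bead_distance <- function(a, b) vnorm(b - a)

# angle a-b-c at vertex b
bead_angle <- function(a, b, c) {
  u <- unitv(a - b)
  w <- unitv(c - b)
  ct <- max(-1, min(1, sum(u * w)))
  acos(ct) * 180 / pi
}

# signed dihedral a-b-c-d about the b->c axis, in (-180, 180]
bead_dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap an angular difference (degrees) into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# rotation matrix about a unit axis (Rodrigues), angle in degrees
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}
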