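# Small 3-vector helpers shared by the structure and synthetic modules.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic vector perpendicular to u: cross with the coordinate axis
# least aligned with u.
perpv <- function(u) {
  ax <- diag(3)[, which.min(abs(u))]
  unitv(crossv(u, ax))
}

# Rotation matrix about unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, theta) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Pairwise distance matrix between two coordinate matrices (n x 3, m x 3).
pairwise_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
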