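# Internal vectorized geometry helpers shared across modules.

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n < 1e-300] <- 1
  m / n
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# angle between rows of two unit-vector matrices, robust near 0 and pi
angular_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  cr <- cross_rows(a, b)
  atan2(row_norms(cr), rowSums(a * b))
}

# Rodrigues rotation matrix for one axis-angle pair
rotmat_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) return(diag(3))
  k <- axis / n
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotate row i of p by rotation vector in row i of rho (Rodrigues, vectorized)
rotate_by_rotvecs <- function(p, rho) {
  theta <- row_norms(rho)
  k <- rho / pmax(theta, 1e-300)
  ct <- cos(theta)
  st <- sin(theta)
  kxp <- cross_rows(k, p)
  kdp <- rowSums(k * p)
  p * ct + kxp * st + k * (kdp * (1 - ct))
}

# orthonormal tangent basis at each unit row of p
tangent_basis <- function(p) {
  t1 <- cbind(-p[, 2], p[, 1], 0)
  flip <- abs(p[, 3]) >= 0.9
  if (any(flip)) t1[flip, ] <- cbind(0, -p[flip, 3], p[flip, 2])
  t1 <- normalize_rows(t1)
  list(t1 = t1, t2 = cross_rows(p, t1))
}

# uniformly random rotation matrix (for pose jitter use rotvec gaussians)
random_rotation_small <- function(sd_rad) {
  rotmat_axis_angle(stats::rnorm(3), stats::rnorm(1, 0, sd_rad))
}

# orientation sign of each spherical face: sign of det[p_i, p_j, p_k]
face_orient_signs <- function(pos, faces) {
  a <- pos[faces[, 1], , drop = FALSE]
  b <- pos[faces[, 2], , drop = FALSE]
  c3 <- pos[faces[, 3], , drop = FALSE]
  sign(rowSums(a * cross_rows(b, c3)))
}

# TRUE when all spherical faces share one orientation sign (no flips)
is_flip_free <- function(pos, faces) {
  s <- face_orient_signs(pos, faces)
  all(s > 0) || all(s < 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# undirected edge keys for a face matrix; returns character keys per halfedge
edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
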