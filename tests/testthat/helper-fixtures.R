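# Shared fixtures, built in code and memoized for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  colored_mesh(v, f)
}

single_triangle <- function() {
  colored_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
               rbind(c(1, 2, 3)))
}

# structured torus grid: V = nu*nv, E = 3*nu*nv, F = 2*nu*nv, chi = 0
torus_mesh <- function(nu = 12, nv = 8, R = 2, r = 0.6) {
  iu <- rep(seq_len(nu) - 1, times = nv)
  iv <- rep(seq_len(nv) - 1, each = nu)
  th <- 2 * pi * iu / nu
  ph <- 2 * pi * iv / nv
  v <- cbind((R + r * cos(ph)) * cos(th), (R + r * cos(ph)) * sin(th),
             r * sin(ph))
  id <- function(u, w) (w %% nv) * nu + (u %% nu) + 1L
  f <- NULL
  for (w in 0:(nv - 1)) for (u in 0:(nu - 1)) {
    f <- rbind(f,
               c(id(u, w), id(u + 1, w), id(u + 1, w + 1)),
               c(id(u, w), id(u + 1, w + 1), id(u, w + 1)))
  }
  colored_mesh(v, f)
}

# triangulated axis-aligned unit cube (12 faces, outward winding)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  f <- rbind(quad(1, 3, 4, 2),   # z = 0, normal -z
             quad(5, 6, 8, 7),   # z = 1, normal +z
             quad(1, 2, 6, 5),   # y = 0
             quad(3, 7, 8, 4),   # y = 1
             quad(1, 5, 7, 3),   # x = 0
             quad(2, 4, 8, 6))   # x = 1
  colored_mesh(v, f)
}

# a prepared (parameterized + featurized) synthetic face subject
prepared_face <- function(seed = 3, jitter = FALSE) {
  cached(paste0("face", seed, jitter), {
    spec <- if (jitter) face_population_spec(seed = seed)
    else face_population_spec(seed = seed, height_jitter_sd = 0,
                              position_jitter_sd = 0,
                              global_scale_jitter_sd = 0,
                              pose_rot_sd = 0, pose_trans_sd = 0)
    f <- make_face(spec, 1)
    sph <- spherical_parameterize(f$mesh)
    list(mesh = f$mesh, sphmap = sph,
         channels = feature_channels(f$mesh), curves = f$curves)
  })
}

# smooth single-bump rotation-vector warp field on the sphere
known_warp_field <- function(p, center, width, amp, axis) {
  d <- acos(pmin(pmax(p %*% center, -1), 1))
  rho <- outer(as.vector(amp * exp(-d^2 / (2 * width^2))), axis / sqrt(sum(axis^2)))
  pn <- morphoface:::rotate_by_rotvecs(p, rho)
  pn / sqrt(rowSums(pn^2))
}

ang_dist <- function(a, b) morphoface:::angular_distance(a, b)

rms <- function(x) sqrt(mean(x^2))

# similarity-aligned RMS between two corresponded vertex matrices
aligned_rms <- function(a, b) {
  tr <- procrustes_pair(a, b)
  sqrt(mean(rowSums((apply_transform(tr, a) - b)^2)))
}
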