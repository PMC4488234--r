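# Spherical parameterization of closed genus-zero meshes: conformal
# relaxation (projected cotangent Laplacian, Gauss-map seeded), Moebius
# centering of the area-weighted centroid, then explicit area-equalizing
# tangential relaxation with flip-guarded steps.

# cotangent weight matrix of a mesh (negative cotangents clamped at zero
# for stability of the projected relaxation)
cotan_weights <- function(mesh) {
  V <- nrow(mesh$vertices)
  ang <- face_corner_angles(mesh$vertices, mesh$faces)
  cots <- pmax(1 / tan(pmax(pmin(ang, pi - 1e-9), 1e-9)), 0)
  opp <- list(c(2, 3), c(3, 1), c(1, 2))
  ii <- jj <- integer(0)
  ww <- numeric(0)
  for (k in 1:3) {
    a <- mesh$faces[, opp[[k]][1]]
    b <- mesh$faces[, opp[[k]][2]]
    ii <- c(ii, a, b)
    jj <- c(jj, b, a)
    ww <- c(ww, cots[, k], cots[, k])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(V, V))
  rs <- Matrix::rowSums(W)
  zero <- rs <= 1e-12
  if (any(zero)) {
    # fall back to uniform weights on starved rows
    a <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
    b <- c(mesh$faces[, 2], mesh$faces[, 3], mesh$faces[, 1])
    U <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1,
                              dims = c(V, V), use.last.ij = TRUE)
    W[zero, ] <- U[zero, ]
  }
  W
}

# one Moebius transform of the unit sphere moving mass toward -a
moebius_shift <- function(p, a) {
  pa <- p + matrix(a, nrow(p), 3, byrow = TRUE)
  n2 <- rowSums(pa * pa)
  (1 - sum(a * a)) * pa / n2 + matrix(a, nrow(p), 3, byrow = TRUE)
}

moebius_center <- function(p, w, tol = 1e-6, max_iter = 200) {
  w <- w / sum(w)
  for (it in seq_len(max_iter)) {
    cen <- colSums(p * w)
    if (sqrt(sum(cen^2)) < tol) break
    p <- normalize_rows(moebius_shift(p, -0.5 * cen))
  }
  p
}

#' Map a closed genus-zero mesh to the unit sphere
#'
#' Three stages: (1) conformal initialization — Gauss-map seeding followed
#' by iterative projected cotangent-Laplacian relaxation on the sphere
#' until the maximum vertex displacement falls below `1e-7`; (2) Moebius
#' normalization so the source-area-weighted centroid of the sphere
#' positions is at the origin (within `1e-6`); (3) area-preserving
#' relaxation — up to `area_relax_iters` tangential gradient steps on
#' \eqn{\sum_f (\mathrm{area\_ratio}_f - 1)^2}, re-projected to the sphere
#' and accepted only when flip-free and decreasing.
#'
#' @param mesh a closed, manifold, genus-zero [colored_mesh()].
#' @param area_relax_iters maximum area-relaxation iterations.
#' @param verbose print stage summaries.
#' @return object of class `spherical_map`: list with `sphere_positions`
#'   (unit rows, same order as mesh vertices), `faces` (shared with the
#'   source), `source` (the input mesh), and `area_trace` (the accepted
#'   area-objective values, non-increasing).
#' @export
spherical_parameterize <- function(mesh, area_relax_iters = 100,
                                   verbose = FALSE) {
  dg <- diagnose(mesh)
  if (!dg$closed || !dg$manifold || is.na(dg$genus) || dg$genus != 0)
    stop("spherical_parameterize requires a closed manifold genus-0 mesh ",
         "(got genus ", ifelse(is.na(dg$genus), "NA", dg$genus), ", ",
         dg$n_boundary_loops, " boundary loops)")
  na <- vertex_normals_areas(mesh)
  W <- cotan_weights(mesh)
  rs <- Matrix::rowSums(W)
  wts <- na$areas / sum(na$areas)

  # stage 1: Gauss-map seed + projected Laplacian relaxation
  delta <- 0.5
  for (attempt in 1:6) {
    p <- na$normals
    p <- normalize_rows(p - matrix(colSums(p * wts), nrow(p), 3, byrow = TRUE))
    for (it in 1:5000) {
      q <- as.matrix(W %*% p) / rs
      pn <- (1 - delta) * p + delta * q
      pn <- pn - matrix(colSums(pn * wts), nrow(pn), 3, byrow = TRUE)
      pn <- normalize_rows(pn)
      disp <- max(abs(pn - p))
      p <- pn
      if (disp < 1e-7) break
    }
    if (is_flip_free(p, mesh$faces)) break
    delta <- delta / 2
    if (attempt == 6)
      stop("spherical_parameterize: conformal stage produced flipped ",
           "triangles even with reduced step")
  }
  if (verbose) message("conformal stage: ", it, " iterations")

  # stage 2: Moebius centering
  p <- moebius_center(p, wts)

  # stage 3: area-equalizing tangential relaxation
  areas <- face_area_vectors(mesh$vertices, mesh$faces)$area
  tfrac <- areas / sum(areas)
  trace <- numeric(0)
  step <- 0.05
  for (it in seq_len(area_relax_iters)) {
    ag <- cpp_area_grad(p, mesh$faces, tfrac, 1e-4)
    if (!length(trace)) trace <- ag$objective
    g <- ag$grad
    gmax <- max(row_norms(g))
    if (gmax < 1e-14) break
    accepted <- FALSE
    s <- step
    for (halv in 1:20) {
      cand <- normalize_rows(p - (s / gmax) * g)  # s = max step, radians
      if (is_flip_free(cand, mesh$faces)) {
        obj <- cpp_area_grad(cand, mesh$faces, tfrac, 1e-4)$objective
        if (obj < trace[length(trace)]) {
          rel <- (trace[length(trace)] - obj) / max(trace[length(trace)], 1e-300)
          p <- cand
          trace <- c(trace, obj)
          step <- min(s * 1.5, 0.2)
          accepted <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!accepted) break
    if (accepted && rel < 1e-6) break
  }
  p <- moebius_center(p, wts)

  structure(list(sphere_positions = p, faces = mesh$faces, source = mesh,
                 area_trace = trace),
            class = "spherical_map")
}

#' Quality audit of a spherical map
#'
#' @param sphmap a `spherical_map`.
#' @return object of class `map_quality`: `n_flipped` (faces whose
#'   spherical orientation disagrees with the majority sign),
#'   `area_ratio` (per-face spherical area fraction over surface area
#'   fraction), and `conformal_distortion` (per-face quasi-conformal
#'   distortion, >= 1).
#' @export
map_quality <- function(sphmap) {
  faces <- sphmap$faces
  s <- face_orient_signs(sphmap$sphere_positions, faces)
  major <- sign(sum(s))
  if (major == 0) major <- 1
  n_flipped <- sum(s != major)
  sph <- cpp_sph_areas(sphmap$sphere_positions, faces)
  sphfrac <- sph / sum(sph)
  surf <- face_area_vectors(sphmap$source$vertices, faces)$area
  surffrac <- surf / sum(surf)
  area_ratio <- sphfrac / surffrac

  # quasi-conformal distortion via the linear map between the flattened
  # source triangle and the flattened chordal spherical triangle
  flat2d <- function(verts) {
    a <- verts[faces[, 1], , drop = FALSE]
    b <- verts[faces[, 2], , drop = FALSE]
    c3 <- verts[faces[, 3], , drop = FALSE]
    e1 <- b - a
    e2 <- c3 - a
    x1 <- row_norms(e1)
    e1n <- e1 / pmax(x1, 1e-300)
    x2 <- rowSums(e2 * e1n)
    y2 <- row_norms(e2 - e1n * x2)
    cbind(x1, x2, y2)
  }
  S <- flat2d(sphmap$source$vertices)
  Q <- flat2d(sphmap$sphere_positions)
  # jacobian J = [[q1/s1, (q2 - q1*s2/s1)/s3], [0 ... ]] via solving
  # [s1 0; s2 s3] -> [q1 0; q2 q3]
  a11 <- Q[, 1] / pmax(S[, 1], 1e-300)
  a21 <- 0
  a12 <- (Q[, 2] - a11 * S[, 2]) / pmax(S[, 3], 1e-300)
  a22 <- Q[, 3] / pmax(S[, 3], 1e-300)
  # singular values of [[a11, a12], [0, a22]]
  t1 <- a11^2 + a12^2 + a22^2
  dt <- abs(a11 * a22)
  disc <- sqrt(pmax(t1^2 - 4 * dt^2, 0))
  s1 <- sqrt(pmax((t1 + disc) / 2, 0))
  s2 <- sqrt(pmax((t1 - disc) / 2, 1e-300))
  structure(list(n_flipped = n_flipped, area_ratio = area_ratio,
                 conformal_distortion = s1 / s2,
                 spherical_area_fractions = sphfrac,
                 surface_area_fractions = surffrac),
            class = "map_quality")
}

#' Locate directions on a spherical map
#'
#' Finds, for each query direction, the spherical triangle containing it
#' and normalized barycentric weights, enabling interpolation of any
#' per-vertex surface attribute.
#'
#' @param sphmap a flip-free `spherical_map` (or any list with
#'   `sphere_positions` and `faces`).
#' @param query numeric matrix of query directions (rows; normalized with
#'   a warning if not unit).
#' @return list with `face` (1-based face index per query) and `bary`
#'   (n x 3 weights, >= 0, rows summing to 1).
#' @export
sphere_lookup <- function(sphmap, query) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  n <- row_norms(query)
  if (any(abs(n - 1) > 1e-9)) {
    warning("sphere_lookup: queries normalized to unit length")
    query <- query / pmax(n, 1e-300)
  }
  cpp_locate(sphmap$sphere_positions, sphmap$faces, query)
}

# interpolate per-vertex attributes (matrix columns) at located points
interp_attr <- function(attr, faces, loc) {
  if (is.null(dim(attr))) attr <- matrix(attr, ncol = 1)
  f <- faces[loc$face, , drop = FALSE]
  w <- loc$bary
  attr[f[, 1], , drop = FALSE] * w[, 1] +
    attr[f[, 2], , drop = FALSE] * w[, 2] +
    attr[f[, 3], , drop = FALSE] * w[, 3]
}

# TRUE where any vertex with strictly positive weight is flagged
interp_flag_any <- function(flag, faces, loc) {
  f <- faces[loc$face, , drop = FALSE]
  (flag[f[, 1]] & loc$bary[, 1] > 0) |
    (flag[f[, 2]] & loc$bary[, 2] > 0) |
    (flag[f[, 3]] & loc$bary[, 3] > 0)
}
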