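#' Construct a colored triangle mesh
#'
#' The universal data structure of the pipeline: a triangle mesh in
#' millimetres with per-vertex RGB color in `[0, 1]` and a per-vertex
#' `filler` flag marking geometry synthesized during boundary closure
#' (filler vertices are excluded from registration and alignment costs).
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param color optional numeric matrix of per-vertex RGB in `[0, 1]`;
#'   defaults to mid-gray `(0.5, 0.5, 0.5)`.
#' @param filler optional logical vector, one entry per vertex; defaults to
#'   all `FALSE`.
#' @return an object of class `colored_mesh`: a list with elements
#'   `vertices`, `faces`, `color`, `filler`.
#' @export
colored_mesh <- function(vertices, faces, color = NULL, filler = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (ncol(faces) != 3) stop("faces must have 3 columns")
    bad <- which(faces < 1L | faces > nrow(vertices))
    if (length(bad))
      stop("face ", ((bad[1] - 1L) %% nrow(faces)) + 1L,
           " references a vertex outside 1..", nrow(vertices))
    dg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(dg)) stop("degenerate face (repeated vertex index) at row ",
                      which(dg)[1])
  }
  if (is.null(color)) {
    color <- matrix(0.5, nrow(vertices), 3)
  } else {
    color <- as.matrix(color)
    storage.mode(color) <- "double"
    if (nrow(color) != nrow(vertices) || ncol(color) != 3)
      stop("color must be an n_vertices x 3 matrix")
    color <- clamp(color, 0, 1)
  }
  if (is.null(filler)) {
    filler <- rep(FALSE, nrow(vertices))
  } else {
    filler <- as.logical(filler)
    if (length(filler) != nrow(vertices))
      stop("filler must have one entry per vertex")
  }
  structure(list(vertices = vertices, faces = faces, color = color,
                 filler = filler),
            class = "colored_mesh")
}

#' @export
print.colored_mesh <- function(x, ...) {
  cat("<colored_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, ", sum(x$filler), " filler\n", sep = "")
  invisible(x)
}

# internal: halfedge table and undirected-edge bookkeeping
mesh_edge_table <- function(faces) {
  he_a <- c(faces[, 1], faces[, 2], faces[, 3])
  he_b <- c(faces[, 2], faces[, 3], faces[, 1])
  he_face <- rep.int(seq_len(nrow(faces)), 3L)
  key <- edge_keys(he_a, he_b)
  ukey <- unique(key)
  eid <- match(key, ukey)
  count <- tabulate(eid, nbins = length(ukey))
  list(he_a = he_a, he_b = he_b, he_face = he_face, eid = eid,
       n_edges = length(ukey), count = count)
}

# internal: tiny union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# Fan decomposition of every vertex star at once. Corners are halfedges
# (corner i sits at vertex he_a[i]); two corners at the same vertex are
# linked when their faces share a manifold (<=2 incident faces) edge
# through that vertex. Components are found by label propagation along
# the corner graph (a union of paths/cycles, so it converges in at most
# max-valence steps). Returns per-corner component labels.
corner_labels <- function(faces, et) {
  F <- nrow(faces)
  nhe <- 3L * F
  succ <- function(i) ifelse(i <= 2L * F, i + F, i - 2L * F)
  pred <- function(i) ifelse(i > F, i - F, i + 2L * F)
  opp <- rep(NA_integer_, nhe)
  interior <- which(et$count == 2L)
  if (length(interior)) {
    ord <- order(et$eid)
    eid_sorted <- et$eid[ord]
    # positions of the two halfedges of each interior edge
    firsts <- match(interior, eid_sorted)
    seconds <- firsts + 1L
    i1 <- ord[firsts]
    i2 <- ord[seconds]
    opp[i1] <- i2
    opp[i2] <- i1
  }
  # direction-aware partners (robust to inconsistent winding): the
  # partner of corner i through its own halfedge's edge is the corner of
  # the opposite face sitting at the same vertex
  out_p <- rep(NA_integer_, nhe)
  ok <- !is.na(opp)
  out_p[ok] <- ifelse(et$he_a[opp[ok]] == et$he_a[ok], opp[ok],
                      succ(opp[ok]))
  in_p <- rep(NA_integer_, nhe)
  e_prev <- pred(seq_len(nhe))
  j <- opp[e_prev]
  ok <- !is.na(j)
  in_p[ok] <- ifelse(et$he_a[j[ok]] == et$he_a[ok], j[ok], succ(j[ok]))
  labels <- seq_len(nhe)
  for (it in 1:200) {
    nl <- labels
    ok <- !is.na(out_p)
    nl[ok] <- pmin(nl[ok], labels[out_p[ok]])
    ok <- !is.na(in_p)
    nl[ok] <- pmin(nl[ok], labels[in_p[ok]])
    if (all(nl == labels)) break
    labels <- nl
  }
  labels
}

#' Topological and combinatorial diagnostics of a mesh
#'
#' Computes vertex/edge/face counts, the Euler characteristic, boundary
#' loops, non-manifold edges and vertices, connected components, and (for
#' closed connected manifolds) the genus. Diagnostics never fail on
#' pathological input; that is their purpose.
#'
#' @param mesh a [colored_mesh()].
#' @return an object of class `mesh_diagnostics`, a list with fields
#'   `n_vertices`, `n_edges`, `n_faces`, `euler_characteristic`,
#'   `n_boundary_loops`, `boundary_loops`, `nonmanifold_edges`,
#'   `nonmanifold_vertices`, `closed`, `manifold`, `n_components`, `genus`
#'   (`NA` unless closed, manifold and connected).
#' @export
diagnose <- function(mesh) {
  V <- nrow(mesh$vertices)
  faces <- mesh$faces
  F <- nrow(faces)
  if (V == 0 || F == 0) stop("diagnose: empty mesh")
  et <- mesh_edge_table(faces)
  E <- et$n_edges
  chi <- V - E + F

  # non-manifold edges: more than two incident faces
  nm_eid <- which(et$count > 2L)
  nm_edges <- if (length(nm_eid)) {
    first <- match(nm_eid, et$eid)
    cbind(pmin(et$he_a[first], et$he_b[first]),
          pmax(et$he_a[first], et$he_b[first]))
  } else matrix(integer(0), 0, 2)

  # boundary halfedges: undirected edge with exactly one incident face
  bnd <- et$count[et$eid] == 1L
  n_boundary_edges <- sum(bnd)

  # boundary loops: traverse reversed boundary halfedges
  boundary_loops <- list()
  if (n_boundary_edges > 0) {
    from <- et$he_b[bnd]   # reversed orientation
    to <- et$he_a[bnd]
    nxt <- rep(NA_integer_, V)
    nxt[from] <- to
    visited <- rep(FALSE, length(from))
    names(visited) <- NULL
    start_of <- from
    used <- rep(FALSE, V)
    for (s in from) {
      if (used[s] || is.na(nxt[s])) next
      loop <- integer(0)
      cur <- s
      repeat {
        if (used[cur]) break
        loop <- c(loop, cur)
        used[cur] <- TRUE
        cur <- nxt[cur]
        if (is.na(cur)) break
        if (cur == s) {
          boundary_loops[[length(boundary_loops) + 1L]] <- loop
          break
        }
      }
    }
  }

  # per-vertex fan test: incident faces must form one component linked by
  # manifold edges at that vertex (corner-graph labeling)
  labels <- corner_labels(faces, et)
  key <- (et$he_a - 1) * (length(labels) + 1) + labels
  ncomp_v <- tabulate(et$he_a[!duplicated(key)], nbins = V)
  nm_vertices <- which(ncomp_v > 1L)

  # connected components over vertices joined by edges
  parent <- uf_new(V)
  first <- match(seq_len(et$n_edges), et$eid)
  ea <- et$he_a[first]
  eb <- et$he_b[first]
  for (i in seq_len(et$n_edges)) {
    ra <- uf_find(parent, ea[i])
    rb <- uf_find(parent, eb[i])
    if (ra != rb) parent[ra] <- rb
  }
  used_v <- unique(as.vector(faces))
  comp <- vapply(used_v, function(i) uf_find(parent, i), 1L)
  n_components <- length(unique(comp))

  closed <- n_boundary_edges == 0L
  manifold <- nrow(nm_edges) == 0L && length(nm_vertices) == 0L
  genus <- if (closed && manifold && n_components == 1L)
    as.integer((2L - chi) / 2L) else NA_integer_

  structure(list(
    n_vertices = V, n_edges = E, n_faces = F,
    euler_characteristic = chi,
    n_boundary_loops = length(boundary_loops),
    boundary_loops = boundary_loops,
    nonmanifold_edges = nm_edges,
    nonmanifold_vertices = nm_vertices,
    closed = closed, manifold = manifold,
    n_components = n_components, genus = genus
  ), class = "mesh_diagnostics")
}

#' @export
print.mesh_diagnostics <- function(x, ...) {
  cat("<mesh_diagnostics> V=", x$n_vertices, " E=", x$n_edges, " F=",
      x$n_faces, " chi=", x$euler_characteristic, " boundaries=",
      x$n_boundary_loops, " nm_edges=", nrow(x$nonmanifold_edges),
      " nm_vertices=", length(x$nonmanifold_vertices),
      " components=", x$n_components,
      " genus=", ifelse(is.na(x$genus), "NA", x$genus), "\n", sep = "")
  invisible(x)
}

# internal: per-face double-area vectors and scalar areas
face_area_vectors <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  n <- cross_rows(b - a, c3 - a)   # length = 2 * area
  list(normal2 = n, area = 0.5 * row_norms(n))
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [colored_mesh()].
#' @export
surface_area <- function(mesh) sum(face_area_vectors(mesh$vertices, mesh$faces)$area)

#' Per-vertex unit normals and barycentric areas
#'
#' Vertex normals are area-vector sums of incident faces, normalized;
#' vertex areas are one third of each incident face's area, so vertex areas
#' sum exactly to the total surface area. Faces of (numerically) zero area
#' are skipped with a warning.
#'
#' @param mesh a [colored_mesh()] with consistent winding.
#' @return list with `normals` (n x 3, unit rows) and `areas` (length n).
#' @export
vertex_normals_areas <- function(mesh) {
  V <- nrow(mesh$vertices)
  fav <- face_area_vectors(mesh$vertices, mesh$faces)
  ok <- fav$area > 1e-12
  if (!all(ok)) warning(sum(!ok), " zero-area face(s) skipped")
  f <- mesh$faces[ok, , drop = FALSE]
  nv <- fav$normal2[ok, , drop = FALSE]
  normals <- matrix(0, V, 3)
  areas <- numeric(V)
  for (k in 1:3) {
    idx <- f[, k]
    for (d in 1:3) {
      s <- rowsum(nv[, d], idx)
      normals[as.integer(rownames(s)), d] <-
        normals[as.integer(rownames(s)), d] + s[, 1]
    }
    s <- rowsum(fav$area[ok], idx)
    areas[as.integer(rownames(s))] <- areas[as.integer(rownames(s))] + s[, 1] / 3
  }
  list(normals = normalize_rows(normals), areas = areas)
}

# internal: corner angles of every face (F x 3 matrix, angle at each vertex)
face_corner_angles <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  angle_at <- function(p, q, r) {          # angle at p between q and r
    u <- q - p
    v <- r - p
    atan2(row_norms(cross_rows(u, v)), rowSums(u * v))
  }
  cbind(angle_at(a, b, c3), angle_at(b, c3, a), angle_at(c3, a, b))
}

#' Discrete mean and Gaussian curvature
#'
#' Mean curvature from the cotangent-Laplacian mean-curvature normal with
#' barycentric (one-third) vertex areas, signed so that a sphere with
#' outward normals has positive mean curvature (H = 1/R). Gaussian
#' curvature is the angle deficit divided by the vertex area (K = 1/R^2 on
#' a sphere); with this discretization the Gauss-Bonnet sum
#' \eqn{\sum_v K_v A_v = 2\pi\chi} holds exactly on closed meshes.
#'
#' @param mesh a manifold [colored_mesh()].
#' @return object of class `curvature_field`: list with per-vertex
#'   `mean_curvature` (1/mm) and `gaussian_curvature` (1/mm^2).
#' @export
curvatures <- function(mesh) {
  dg <- diagnose(mesh)
  if (!dg$manifold)
    stop("curvatures: mesh is non-manifold; run topology correction first")
  V <- nrow(mesh$vertices)
  faces <- mesh$faces
  ang <- face_corner_angles(mesh$vertices, faces)
  cots <- 1 / tan(pmax(pmin(ang, pi - 1e-9), 1e-9))

  # cotan weights: corner k is opposite the edge joining the other two
  opp <- list(c(2, 3), c(3, 1), c(1, 2))
  ii <- jj <- integer(0)
  ww <- numeric(0)
  for (k in 1:3) {
    a <- faces[, opp[[k]][1]]
    b <- faces[, opp[[k]][2]]
    ii <- c(ii, a, b)
    jj <- c(jj, b, a)
    ww <- c(ww, cots[, k], cots[, k])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(V, V))
  na <- vertex_normals_areas(mesh)
  Lp <- as.matrix(Matrix::rowSums(W) * mesh$vertices - W %*% mesh$vertices)
  Hvec <- Lp / (4 * pmax(na$areas, 1e-300))  # approximates H * n
  H <- rowSums(Hvec * na$normals)

  bnd_v <- rep(FALSE, V)
  if (!dg$closed) {
    et <- mesh_edge_table(faces)
    b <- et$count[et$eid] == 1L
    bnd_v[unique(c(et$he_a[b], et$he_b[b]))] <- TRUE
  }
  angsum <- numeric(V)
  for (k in 1:3) {
    s <- rowsum(ang[, k], faces[, k])
    angsum[as.integer(rownames(s))] <- angsum[as.integer(rownames(s))] + s[, 1]
  }
  deficit <- ifelse(bnd_v, pi, 2 * pi) - angsum
  K <- deficit / pmax(na$areas, 1e-300)
  structure(list(mean_curvature = H, gaussian_curvature = K,
                 vertex_areas = na$areas),
            class = "curvature_field")
}
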