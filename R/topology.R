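# Topology correction: make arbitrary scanned meshes closed, manifold and
# genus zero, marking every synthesized vertex as filler.

#' Remove non-manifold elements and islands
#'
#' Iteratively deletes duplicate faces, drops the smallest-area faces at
#' edges with more than two incident faces, keeps only the largest-area
#' fan component at non-manifold vertices, and finally retains only the
#' largest connected component by surface area (island removal). Vertex
#' colors and filler flags are carried through.
#'
#' @param mesh a [colored_mesh()].
#' @param verbose log removed-element counts.
#' @return a manifold [colored_mesh()] (single component, possibly open).
#' @export
remove_nonmanifold <- function(mesh, verbose = FALSE) {
  n_removed <- 0L
  for (round in 1:25) {
    if (nrow(mesh$faces) == 0) stop("no manifold component")
    drop <- integer(0)
    # duplicate faces (same vertex set)
    f <- mesh$faces
    lo <- pmin(f[, 1], f[, 2], f[, 3])
    hi <- pmax(f[, 1], f[, 2], f[, 3])
    key <- paste(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
    drop <- union(drop, which(duplicated(key)))
    et <- mesh_edge_table(mesh$faces)
    areas <- face_area_vectors(mesh$vertices, mesh$faces)$area
    # edges with > 2 incident faces: keep two faces, preferring surface
    # faces over dangling fins (fewer boundary edges) and larger area,
    # and requiring the kept pair to be wound antiparallel so the glued
    # surface stays orientable
    over <- which(et$count > 2L)
    if (length(over)) {
      he_at <- split(seq_along(et$eid), et$eid)
      bnd_per_face <- tabulate(et$he_face[et$count[et$eid] == 1L],
                               nbins = nrow(mesh$faces))
      for (e in over) {
        he <- he_at[[e]]
        fs <- et$he_face[he]
        fwd <- et$he_a[he] < et$he_b[he]
        keep1 <- !duplicated(fs)
        he <- he[keep1]; fs <- fs[keep1]; fwd <- fwd[keep1]
        live <- !(fs %in% drop)
        he <- he[live]; fs <- fs[live]; fwd <- fwd[live]
        if (length(fs) <= 2) next
        ord <- order(bnd_per_face[fs], -areas[fs])
        first <- ord[1]
        second <- ord[ord != first & fwd[ord] != fwd[first]][1]
        if (is.na(second)) second <- ord[2]
        drop <- union(drop, fs[-c(first, second)])
      }
    }
    if (!length(drop)) {
      # non-manifold vertices: keep the largest-area fan component
      labels <- corner_labels(mesh$faces, et)
      key <- (et$he_a - 1) * (length(labels) + 1) + labels
      firsts <- !duplicated(key)
      ncomp_v <- tabulate(et$he_a[firsts], nbins = nrow(mesh$vertices))
      for (v in which(ncomp_v > 1L)) {
        at_v <- et$he_a == v
        grp <- split(et$he_face[at_v], labels[at_v])
        ga <- vapply(grp, function(g) sum(areas[unique(g)]), 0)
        drop <- union(drop, unlist(grp[-which.max(ga)]))
      }
    }
    if (!length(drop)) break
    n_removed <- n_removed + length(drop)
    mesh <- drop_faces(mesh, drop)
  }
  # island removal: largest connected component by area
  et <- mesh_edge_table(mesh$faces)
  V <- nrow(mesh$vertices)
  parent <- uf_new(V)
  first <- match(seq_len(et$n_edges), et$eid)
  ea <- et$he_a[first]
  eb <- et$he_b[first]
  for (i in seq_len(et$n_edges)) {
    ra <- uf_find(parent, ea[i])
    rb <- uf_find(parent, eb[i])
    if (ra != rb) parent[ra] <- rb
  }
  comp_of <- vapply(seq_len(V), function(i) uf_find(parent, i), 1L)
  fcomp <- comp_of[mesh$faces[, 1]]
  areas <- face_area_vectors(mesh$vertices, mesh$faces)$area
  carea <- rowsum(areas, fcomp)
  keep_comp <- as.integer(rownames(carea))[which.max(carea[, 1])]
  drop <- which(fcomp != keep_comp)
  if (length(drop)) {
    n_removed <- n_removed + length(drop)
    mesh <- drop_faces(mesh, drop)
  }
  if (nrow(mesh$faces) == 0) stop("no manifold component")
  if (verbose) message("remove_nonmanifold: removed ", n_removed, " faces")
  mesh
}

#' Sew one boundary loop closed with a centroid fan
#'
#' Adds one vertex at the loop centroid (filler, mean-of-boundary color)
#' and a fan of triangles oriented consistently with the existing winding.
#'
#' @param mesh a [colored_mesh()].
#' @param loop integer vector: a boundary vertex cycle of `mesh` (as
#'   reported by [diagnose()]).
#' @return list with elements `mesh` and `patch` (a `patch_record`: fields
#'   `patch_faces`, `patch_vertices`, `source_loop`, `area_history`).
#' @export
sew_boundary <- function(mesh, loop) {
  if (length(loop) < 3) stop("boundary loop shorter than 3 vertices")
  dirkey <- paste(c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
                  c(mesh$faces[, 2], mesh$faces[, 3], mesh$faces[, 1]),
                  sep = ">")
  centroid <- colMeans(mesh$vertices[loop, , drop = FALSE])
  ccol <- colMeans(mesh$color[loop, , drop = FALSE])
  cidx <- nrow(mesh$vertices) + 1L
  u <- loop
  v <- c(loop[-1], loop[1])
  fwd <- paste(u, v, sep = ">") %in% dirkey
  newf <- cbind(ifelse(fwd, v, u), ifelse(fwd, u, v), cidx)
  mesh2 <- colored_mesh(rbind(mesh$vertices, centroid),
                        rbind(mesh$faces, newf),
                        rbind(mesh$color, ccol),
                        c(mesh$filler, TRUE))
  pf <- nrow(mesh$faces) + seq_len(nrow(newf))
  area <- sum(face_area_vectors(mesh2$vertices,
                                mesh2$faces[pf, , drop = FALSE])$area)
  patch <- structure(list(patch_faces = pf, patch_vertices = cidx,
                          source_loop = loop, area_history = area),
                     class = "patch_record")
  list(mesh = mesh2, patch = patch)
}

#' Relax a sewn patch toward minimal area
#'
#' Solves the discrete-harmonic (uniform-weight Laplace) system placing
#' each interior patch vertex at the average of its neighbors, with the
#' source loop held fixed — the standard linear proxy for patch-area
#' minimization. The relaxed configuration is kept only if the patch area
#' did not increase, so `area_history` is non-increasing.
#'
#' @param mesh a [colored_mesh()] containing the patch.
#' @param patch a `patch_record` from [sew_boundary()].
#' @return list with updated `mesh` and `patch`.
#' @export
relax_patch <- function(mesh, patch) {
  free <- patch$patch_vertices
  if (!length(free)) return(list(mesh = mesh, patch = patch))
  pf <- mesh$faces[patch$patch_faces, , drop = FALSE]
  a <- c(pf[, 1], pf[, 2], pf[, 3])
  b <- c(pf[, 2], pf[, 3], pf[, 1])
  nbr <- unique(rbind(cbind(a, b), cbind(b, a)))
  nbr <- nbr[nbr[, 1] %in% free, , drop = FALSE]
  fidx <- match(nbr[, 1], free)
  is_free_nbr <- nbr[, 2] %in% free
  deg <- tabulate(fidx, nbins = length(free))
  n <- length(free)
  L <- Matrix::sparseMatrix(i = c(seq_len(n), fidx[is_free_nbr]),
                            j = c(seq_len(n), match(nbr[is_free_nbr, 2], free)),
                            x = c(deg, rep(-1, sum(is_free_nbr))),
                            dims = c(n, n))
  rhs <- matrix(0, n, 3)
  fixed_nbr <- nbr[!is_free_nbr, , drop = FALSE]
  if (nrow(fixed_nbr)) {
    for (d in 1:3) {
      s <- rowsum(mesh$vertices[fixed_nbr[, 2], d], match(fixed_nbr[, 1], free))
      rhs[as.integer(rownames(s)), d] <- s[, 1]
    }
  }
  sol <- tryCatch(as.matrix(Matrix::solve(L, rhs)),
                  error = function(e) stop("singular patch system for loop ",
                                           patch$source_loop[1]))
  before <- sum(face_area_vectors(mesh$vertices, pf)$area)
  v2 <- mesh$vertices
  v2[free, ] <- sol
  after <- sum(face_area_vectors(v2, pf)$area)
  if (after <= before + 1e-12) {
    mesh$vertices <- v2
    patch$area_history <- c(patch$area_history, after)
  } else {
    patch$area_history <- c(patch$area_history, before)
  }
  list(mesh = mesh, patch = patch)
}

# conforming refinement of the patch: split every patch edge not on the
# source loop; faces get 1-to-4, 1-to-3 or 1-to-2 according to how many of
# their edges were split (loop edges are shared with original faces and
# must not be split)
subdivide_patch <- function(mesh, patch) {
  pf <- mesh$faces[patch$patch_faces, , drop = FALSE]
  loopkeys <- edge_keys(patch$source_loop,
                        c(patch$source_loop[-1], patch$source_loop[1]))
  ek <- rbind(cbind(pf[, 1], pf[, 2]), cbind(pf[, 2], pf[, 3]),
              cbind(pf[, 3], pf[, 1]))
  keys <- edge_keys(ek[, 1], ek[, 2])
  splittable <- !(keys %in% loopkeys)
  ukeys <- unique(keys[splittable])
  if (!length(ukeys)) return(list(mesh = mesh, patch = patch))
  first <- match(ukeys, keys)
  mids_a <- ek[first, 1]
  mids_b <- ek[first, 2]
  nv0 <- nrow(mesh$vertices)
  midpos <- (mesh$vertices[mids_a, , drop = FALSE] +
               mesh$vertices[mids_b, , drop = FALSE]) / 2
  midcol <- (mesh$color[mids_a, , drop = FALSE] +
               mesh$color[mids_b, , drop = FALSE]) / 2
  mid_id <- nv0 + seq_along(ukeys)
  midmap <- stats::setNames(mid_id, ukeys)

  # per-face midpoint ids on edges 1:(v1,v2), 2:(v2,v3), 3:(v3,v1)
  M <- cbind(unname(midmap[edge_keys(pf[, 1], pf[, 2])]),
             unname(midmap[edge_keys(pf[, 2], pf[, 3])]),
             unname(midmap[edge_keys(pf[, 3], pf[, 1])]))
  k <- rowSums(!is.na(M))
  rot_to <- function(rows, pick_na) {
    # rotate (v,m) so that edge 1 is the NA edge (pick_na) or the split
    # edge (!pick_na); rotation (a,b,c) -> (b,c,a) maps edge slots 1<-2 etc.
    j <- if (pick_na) max.col(is.na(M[rows, , drop = FALSE]), "first")
    else max.col(!is.na(M[rows, , drop = FALSE]), "first")
    ords <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    n <- length(rows)
    idx <- cbind(rep(rows, 3), as.vector(ords[j, ]))
    tri <- matrix(pf[idx], n, 3)
    m <- matrix(M[idx], n, 3)
    list(tri = tri, m = m)
  }
  pieces <- list()
  r3 <- which(k == 3)
  if (length(r3)) {
    tri <- pf[r3, , drop = FALSE]
    m <- M[r3, , drop = FALSE]
    pieces <- c(pieces, list(
      cbind(tri[, 1], m[, 1], m[, 3]), cbind(tri[, 2], m[, 2], m[, 1]),
      cbind(tri[, 3], m[, 3], m[, 2]), cbind(m[, 1], m[, 2], m[, 3])))
  }
  r2 <- which(k == 2)
  if (length(r2)) {
    z <- rot_to(r2, pick_na = TRUE)
    pieces <- c(pieces, list(
      cbind(z$tri[, 1], z$tri[, 2], z$m[, 2]),
      cbind(z$tri[, 1], z$m[, 2], z$m[, 3]),
      cbind(z$m[, 3], z$m[, 2], z$tri[, 3])))
  }
  r1 <- which(k == 1)
  if (length(r1)) {
    z <- rot_to(r1, pick_na = FALSE)
    pieces <- c(pieces, list(
      cbind(z$tri[, 1], z$m[, 1], z$tri[, 3]),
      cbind(z$m[, 1], z$tri[, 2], z$tri[, 3])))
  }
  r0 <- which(k == 0)
  if (length(r0)) pieces <- c(pieces, list(pf[r0, , drop = FALSE]))
  newfaces <- do.call(rbind, pieces)
  keep <- setdiff(seq_len(nrow(mesh$faces)), patch$patch_faces)
  faces2 <- rbind(mesh$faces[keep, , drop = FALSE], newfaces)
  mesh2 <- colored_mesh(rbind(mesh$vertices, midpos),
                        faces2,
                        rbind(mesh$color, midcol),
                        c(mesh$filler, rep(TRUE, length(ukeys))))
  patch$patch_faces <- length(keep) + seq_len(nrow(newfaces))
  patch$patch_vertices <- c(patch$patch_vertices, mid_id)
  list(mesh = mesh2, patch = patch)
}

#' Close every boundary loop with an iteratively refined minimal patch
#'
#' For each boundary loop: sew with a centroid fan, harmonically relax,
#' then repeatedly refine (conforming subdivision of patch faces) and
#' relax until the relative patch-area reduction falls below `rel_tol` or
#' `max_rounds` refinements have run. The output is closed; genus must be
#' zero afterwards (handle removal is out of scope and raises an error).
#'
#' @param mesh a manifold [colored_mesh()] (run [remove_nonmanifold()]
#'   first).
#' @param rel_tol relative area-reduction stopping threshold.
#' @param max_rounds maximum refinement rounds per patch.
#' @return list with `mesh` (closed, genus 0) and `patches` (list of
#'   `patch_record`, one per closed loop, each with non-increasing
#'   `area_history`).
#' @export
close_boundaries <- function(mesh, rel_tol = 1e-3, max_rounds = 6) {
  dg <- diagnose(mesh)
  if (!dg$manifold)
    stop("close_boundaries: mesh is non-manifold; run remove_nonmanifold first")
  if (dg$closed) return(list(mesh = mesh, patches = list()))
  patches <- list()
  for (loop in dg$boundary_loops) {
    sw <- sew_boundary(mesh, loop)
    rl <- relax_patch(sw$mesh, sw$patch)
    mesh <- rl$mesh
    patch <- rl$patch
    for (round in seq_len(max_rounds)) {
      sd2 <- subdivide_patch(mesh, patch)
      rl <- relax_patch(sd2$mesh, sd2$patch)
      mesh <- rl$mesh
      patch <- rl$patch
      h <- patch$area_history
      prev <- h[length(h) - 1]
      if (prev <= 0 || (prev - h[length(h)]) / prev < rel_tol) break
    }
    patches[[length(patches) + 1L]] <- patch
  }
  dg2 <- diagnose(mesh)
  if (dg2$n_boundary_loops != 0)
    stop("close_boundaries: boundaries remain after closure")
  if (!is.na(dg2$genus) && dg2$genus > 0)
    stop("close_boundaries: closed surface has genus ", dg2$genus,
         "; handle removal is out of scope")
  list(mesh = mesh, patches = patches)
}

#' Taubin shrink-compensated smoothing
#'
#' Alternates a positive (`lam`) and a compensating negative smoothing
#' step (Taubin's lambda-mu scheme with pass-band 0.1) using the uniform
#' Laplacian. Connectivity, colors and filler flags are unchanged.
#'
#' @param mesh a manifold [colored_mesh()].
#' @param iterations number of lambda-mu passes (0 = identity).
#' @param lam positive step in (0, 1).
#' @return the smoothed [colored_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 10, lam = 0.5) {
  if (iterations <= 0) return(mesh)
  stopifnot(lam > 0, lam < 1)
  mu <- lam / (0.1 * lam - 1)   # pass-band k_pb = 0.1
  V <- nrow(mesh$vertices)
  a <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  b <- c(mesh$faces[, 2], mesh$faces[, 3], mesh$faces[, 1])
  A <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1,
                            dims = c(V, V), use.last.ij = TRUE)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- mesh$vertices
  for (it in seq_len(iterations)) {
    v <- v + lam * (as.matrix(A %*% v) / deg - v)
    v <- v + mu * (as.matrix(A %*% v) / deg - v)
  }
  mesh$vertices <- v
  mesh
}
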