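# Synthetic 3dMD-like face scans with known ground-truth correspondence.
# Faces are deformed icospheres: a shared template (so cross-subject
# correspondence is vertex identity by construction), radial Gaussian
# feature bumps with per-subject jitter, procedural skin-like color, an
# optional open-neck polar cap, and injectable scan defects (holes,
# non-manifold fins, debris islands).

#' Triangulated icosphere
#'
#' Subdivided icosahedron projected to a sphere; the base template of the
#' synthetic face generator. Subdivision level `L` gives
#' `10 * 4^L + 2` vertices.
#'
#' @param level subdivision level (>= 0).
#' @param radius sphere radius in mm.
#' @return a [colored_mesh()] (mid-gray, outward winding).
#' @export
icosphere <- function(level = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lv in seq_len(level)) {
    nv <- nrow(v)
    ekey <- character(0)
    mid_of <- new.env(hash = TRUE)
    newv <- list()
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      m <- mid_of[[k]]
      if (is.null(m)) {
        newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
        m <- nv + length(newv)
        mid_of[[k]] <- m
      }
      m
    }
    nf <- matrix(0L, 0, 3)
    out <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
      out[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                        c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    v <- normalize_rows(v)
    f <- do.call(rbind, out)
  }
  colored_mesh(v * radius, f)
}

#' Specification of a synthetic face population
#'
#' Defines the study conditions emulated by the generator: cohort size,
#' template resolution, named facial feature bumps (Gaussian radial
#' displacements), per-subject shape/pose/scale/texture jitter,
#' per-vertex scanner noise, and scan-defect injection settings.
#'
#' @param n_subjects cohort size (the reference study used 10).
#' @param base_resolution icosphere subdivision level (>= 3, i.e. >= 642
#'   vertices).
#' @param base_radius head radius in mm.
#' @param features named list of bumps, each
#'   `list(dir = unit 3-vector, width = radians, height = mm)`.
#' @param height_jitter_sd per-feature bump-height jitter SD (mm).
#' @param position_jitter_sd per-feature bump-center jitter SD (radians).
#' @param global_scale_jitter_sd SD of per-subject log-scale.
#' @param pose_rot_sd,pose_trans_sd per-subject rotation (rad) and
#'   translation (mm) jitter SD.
#' @param vertex_noise_sd independent per-vertex radial scanner noise SD
#'   (mm).
#' @param hue_jitter_sd per-subject channel-correlated color shift SD.
#' @param n_holes,hole_width,n_fins,add_island defect-injection settings
#'   for [inject_defects()]: number of punched face-disk holes, their
#'   angular radius (rad), number of non-manifold fin triangles, and
#'   whether to add a disconnected debris island.
#' @param open_neck logical; delete a polar cap (open scan boundary).
#' @param seed master seed; every draw is deterministic in
#'   `(seed, subject_index)`.
#' @return list of class `face_population_spec`.
#' @export
face_population_spec <- function(n_subjects = 10,
                                 base_resolution = 3,
                                 base_radius = 80,
                                 features = default_face_features(),
                                 height_jitter_sd = 1,
                                 position_jitter_sd = 0.02,
                                 global_scale_jitter_sd = 0.03,
                                 pose_rot_sd = 0.1,
                                 pose_trans_sd = 5,
                                 vertex_noise_sd = 0,
                                 hue_jitter_sd = 0.03,
                                 n_holes = 3, hole_width = 0.12,
                                 n_fins = 2, add_island = FALSE,
                                 open_neck = FALSE,
                                 seed = 1) {
  if (base_resolution < 3) stop("base_resolution must be >= 3")
  stopifnot(height_jitter_sd >= 0, position_jitter_sd >= 0,
            global_scale_jitter_sd >= 0, pose_rot_sd >= 0,
            pose_trans_sd >= 0, vertex_noise_sd >= 0, hue_jitter_sd >= 0)
  structure(as.list(environment()), class = "face_population_spec")
}

#' Default facial feature set (nose, eyes, brows, chin, lips, cheeks)
#'
#' Directions are on the unit head sphere with +z the facial front and +y
#' up; heights are radial displacements in mm (negative = indentation).
#' @export
default_face_features <- function() {
  dirs <- function(x, y, z) c(x, y, z) / sqrt(x^2 + y^2 + z^2)
  list(
    nose = list(dir = dirs(0, -0.05, 1), width = 0.22, height = 14),
    eye_left = list(dir = dirs(-0.33, 0.27, 0.9), width = 0.13, height = -3),
    eye_right = list(dir = dirs(0.33, 0.27, 0.9), width = 0.13, height = -3),
    brow_left = list(dir = dirs(-0.3, 0.45, 0.85), width = 0.14, height = 3),
    brow_right = list(dir = dirs(0.3, 0.45, 0.85), width = 0.14, height = 3),
    chin = list(dir = dirs(0, -0.7, 0.72), width = 0.18, height = 7),
    lips = list(dir = dirs(0, -0.42, 0.95), width = 0.12, height = 3),
    cheek_left = list(dir = dirs(-0.5, -0.12, 0.85), width = 0.28, height = 4),
    cheek_right = list(dir = dirs(0.5, -0.12, 0.85), width = 0.28, height = 4)
  )
}

# deterministic per-subject substream seed (kept below 2^31)
subject_seed <- function(seed, subject_index, stream) {
  (abs(seed) %% 65011L) * 33013L + subject_index * 7919L + stream * 104729L
}

# template (zero-jitter) surface from a spec
face_template <- function(spec) {
  base <- icosphere(spec$base_resolution, 1)
  dirs <- base$vertices
  r <- rep(spec$base_radius, nrow(dirs))
  for (ft in spec$features) {
    a <- angular_distance(dirs, matrix(ft$dir, nrow(dirs), 3, byrow = TRUE))
    r <- r + ft$height * exp(-a^2 / (2 * ft$width^2))
  }
  verts <- dirs * r
  col <- face_texture(dirs, spec, hue_shift = c(0, 0, 0))
  m <- colored_mesh(verts, base$faces, col)
  if (spec$open_neck) m <- delete_cap(m, c(0, -0.35, -0.94), 0.5)
  m
}

# procedural skin-like texture: base tone plus feature tints
face_texture <- function(dirs, spec, hue_shift) {
  n <- nrow(dirs)
  col <- matrix(rep(c(0.80, 0.62, 0.52), each = n), n, 3)
  # smooth skin-tone marbling over the whole head (shared anatomy-like
  # pattern, like freckling/hair shading on real scans): gives the
  # texture term signal outside the named features too
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  marble <- 0.06 * sin(4 * x + 2 * y) * cos(3 * z - x) +
    0.05 * sin(6 * y * z + 1) + 0.04 * cos(5 * x * z - 2 * y)
  col <- col + outer(marble, c(0.9, 0.7, 0.5))
  tint_near <- function(col, center, width, tint) {
    a <- angular_distance(dirs, matrix(center, n, 3, byrow = TRUE))
    w <- exp(-a^2 / (2 * width^2))
    col + outer(w, tint)
  }
  ft <- spec$features
  if (!is.null(ft$lips))
    col <- tint_near(col, ft$lips$dir, ft$lips$width, c(0.1, -0.25, -0.2))
  for (nm in c("eye_left", "eye_right"))
    if (!is.null(ft[[nm]]))
      col <- tint_near(col, ft[[nm]]$dir, ft[[nm]]$width * 0.7,
                       c(-0.45, -0.35, -0.25))
  for (nm in c("brow_left", "brow_right"))
    if (!is.null(ft[[nm]]))
      col <- tint_near(col, ft[[nm]]$dir, ft[[nm]]$width * 0.6,
                       c(-0.35, -0.3, -0.25))
  for (nm in c("cheek_left", "cheek_right"))
    if (!is.null(ft[[nm]]))
      col <- tint_near(col, ft[[nm]]$dir, ft[[nm]]$width, c(0.08, 0, 0))
  col <- col + matrix(hue_shift, n, 3, byrow = TRUE)
  clamp(col, 0, 1)
}

# delete faces whose three vertices all lie within `width` rad of dir
delete_cap <- function(mesh, dir, width) {
  a <- angular_distance(mesh$vertices,
                        matrix(dir, nrow(mesh$vertices), 3, byrow = TRUE))
  drop <- rowSums(matrix(a[mesh$faces] < width, nrow(mesh$faces), 3)) == 3
  drop_faces(mesh, which(drop))
}

# remove faces (and orphaned vertices), preserving attributes
drop_faces <- function(mesh, face_idx) {
  keep_f <- setdiff(seq_len(nrow(mesh$faces)), face_idx)
  f <- mesh$faces[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  colored_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               mesh$color[used, , drop = FALSE],
               mesh$filler[used])
}

#' Generate one synthetic face scan
#'
#' Builds the subject by jittering the template's feature heights and
#' centers, applying per-vertex scanner noise, a jittered similarity
#' transform (pose + scale), and a per-subject channel-correlated color
#' shift. All subjects share the template topology, so ground-truth
#' cross-subject correspondence is vertex identity.
#'
#' @param spec a [face_population_spec()].
#' @param subject_index positive integer.
#' @param pose_seed optional separate seed for the pose/noise draws; used
#'   by [make_cohort()] to re-pose the same subjects (a later timepoint).
#' @return list with `mesh` ([colored_mesh()]), `curves` (a `curve_set`),
#'   and `truth` (list: template vertex matrix `template_vertices` and the
#'   subject's own pre-pose vertex matrix `shape_vertices`; correspondence
#'   to the template is by vertex index).
#' @export
make_face <- function(spec, subject_index = 1, pose_seed = NULL) {
  base <- icosphere(spec$base_resolution, 1)
  dirs <- base$vertices
  n <- nrow(dirs)

  set.seed(subject_seed(spec$seed, subject_index, 1L))
  r <- rep(spec$base_radius, n)
  for (ft in spec$features) {
    h <- ft$height + stats::rnorm(1, 0, spec$height_jitter_sd)
    dd <- ft$dir + stats::rnorm(3, 0, spec$position_jitter_sd)
    dd <- dd / sqrt(sum(dd^2))
    a <- angular_distance(dirs, matrix(dd, n, 3, byrow = TRUE))
    r <- r + h * exp(-a^2 / (2 * ft$width^2))
  }
  hue <- stats::rnorm(1, 0, spec$hue_jitter_sd) * c(1, 0.6, 0.3)

  ps <- if (is.null(pose_seed)) spec$seed else pose_seed
  set.seed(subject_seed(ps, subject_index, 2L))
  if (spec$vertex_noise_sd > 0)
    r <- r + stats::rnorm(n, 0, spec$vertex_noise_sd)
  scale <- exp(stats::rnorm(1, 0, spec$global_scale_jitter_sd))
  R <- random_rotation_small(spec$pose_rot_sd)
  trans <- stats::rnorm(3, 0, spec$pose_trans_sd)

  shape <- dirs * r
  verts <- scale * shape %*% t(R) + matrix(trans, n, 3, byrow = TRUE)
  col <- face_texture(dirs, spec, hue)
  mesh <- colored_mesh(verts, base$faces, col)
  curves <- template_curves(spec)
  if (spec$open_neck) {
    keep <- delete_cap_index(mesh, c(0, -0.35, -0.94), 0.5, dirs)
    mesh <- keep$mesh
    curves <- remap_curves(curves, keep$remap)
  }
  list(mesh = mesh,
       curves = curves,
       truth = list(template_vertices = face_template_vertices(spec),
                    shape_vertices = shape))
}

face_template_vertices <- function(spec) {
  base <- icosphere(spec$base_resolution, 1)
  dirs <- base$vertices
  r <- rep(spec$base_radius, nrow(dirs))
  for (ft in spec$features) {
    a <- angular_distance(dirs, matrix(ft$dir, nrow(dirs), 3, byrow = TRUE))
    r <- r + ft$height * exp(-a^2 / (2 * ft$width^2))
  }
  dirs * r
}

delete_cap_index <- function(mesh, dir, width, dirs) {
  a <- angular_distance(dirs, matrix(dir, nrow(dirs), 3, byrow = TRUE))
  drop <- rowSums(matrix(a[mesh$faces] < width, nrow(mesh$faces), 3)) == 3
  keep_f <- which(!drop)
  f <- mesh$faces[keep_f, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- rep(NA_integer_, nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  list(mesh = colored_mesh(mesh$vertices[used, , drop = FALSE],
                           matrix(remap[f], ncol = 3),
                           mesh$color[used, , drop = FALSE],
                           mesh$filler[used]),
       remap = remap)
}

remap_curves <- function(curves, remap) {
  out <- lapply(curves, function(cv) {
    cv2 <- remap[cv]
    cv2 <- cv2[!is.na(cv2)]
    cv2[c(TRUE, diff(cv2) != 0)]
  })
  structure(out, class = "curve_set")
}

# the ten named template curves, as nearest-vertex polylines along
# geodesic paths through feature anchors (identical indices on every
# subject since the template topology is shared)
template_curves <- function(spec) {
  base <- icosphere(spec$base_resolution, 1)
  dirs <- base$vertices
  nearest <- function(d) which.max(dirs %*% d)
  slerp_path <- function(anchors, m = 24) {
    pts <- list()
    for (i in seq_len(length(anchors) - 1)) {
      a <- anchors[[i]] / sqrt(sum(anchors[[i]]^2))
      b <- anchors[[i + 1]] / sqrt(sum(anchors[[i + 1]]^2))
      om <- acos(clamp(sum(a * b), -1, 1))
      ts <- seq(0, 1, length.out = m)
      if (om < 1e-9) seg <- matrix(a, m, 3, byrow = TRUE)
      else seg <- (outer(sin((1 - ts) * om), a) +
                     outer(sin(ts * om), b)) / sin(om)
      pts[[i]] <- seg
    }
    p <- do.call(rbind, pts)
    idx <- apply(p, 1, function(q) nearest(q))
    idx <- idx[c(TRUE, diff(idx) != 0)]
    as.integer(idx)
  }
  ft <- spec$features
  u <- function(...) c(...) / sqrt(sum(c(...)^2))
  ring <- function(center, radius_rad, k = 12) {
    tb <- tangent_basis(matrix(center, 1, 3))
    th <- seq(0, 2 * pi, length.out = k + 1)
    lapply(th, function(t)
      u(cos(radius_rad) * center +
          sin(radius_rad) * (cos(t) * tb$t1[1, ] + sin(t) * tb$t2[1, ])))
  }
  curves <- list(
    midline = slerp_path(list(u(0, 0.6, 0.8), ft$nose$dir, ft$lips$dir,
                              ft$chin$dir)),
    eye_rim_left = slerp_path(ring(ft$eye_left$dir, 0.16)),
    eye_rim_right = slerp_path(ring(ft$eye_right$dir, 0.16)),
    nose_bridge = slerp_path(list(u(-0.15, 0.1, 0.98), ft$nose$dir,
                                  u(0.15, 0.1, 0.98))),
    nostril_line = slerp_path(list(u(-0.12, -0.18, 0.97),
                                   u(0, -0.2, 0.98),
                                   u(0.12, -0.18, 0.97))),
    upper_lip = slerp_path(list(u(-0.15, -0.38, 0.9), ft$lips$dir,
                                u(0.15, -0.38, 0.9))),
    lower_lip = slerp_path(list(u(-0.15, -0.5, 0.85), u(0, -0.52, 0.85),
                                u(0.15, -0.5, 0.85))),
    jaw_left = slerp_path(list(u(-0.75, 0, 0.6), u(-0.45, -0.5, 0.72),
                               ft$chin$dir)),
    jaw_right = slerp_path(list(u(0.75, 0, 0.6), u(0.45, -0.5, 0.72),
                                ft$chin$dir)),
    brow_line = slerp_path(list(ft$brow_left$dir, u(0, 0.48, 0.88),
                                ft$brow_right$dir))
  )
  structure(curves, class = "curve_set")
}

#' Inject scan defects into a closed mesh
#'
#' Punches `n_holes` face-disk holes of angular radius `hole_width`,
#' attaches `n_fins` off-surface fin triangles onto interior edges
#' (creating non-manifold edges), and optionally adds a small disconnected
#' debris island. Deterministic in `spec$seed` and `subject_index`.
#'
#' @param mesh a closed manifold [colored_mesh()].
#' @param spec a [face_population_spec()].
#' @param subject_index used to decorrelate defect draws across subjects.
#' @return a defective [colored_mesh()].
#' @export
inject_defects <- function(mesh, spec, subject_index = 1) {
  set.seed(subject_seed(spec$seed, subject_index, 3L))
  dirs <- normalize_rows(mesh$vertices -
                           matrix(colMeans(mesh$vertices),
                                  nrow(mesh$vertices), 3, byrow = TRUE))
  if (spec$n_holes > 0) {
    fc <- (mesh$vertices[mesh$faces[, 1], ] + mesh$vertices[mesh$faces[, 2], ] +
             mesh$vertices[mesh$faces[, 3], ]) / 3
    fdir <- normalize_rows(fc - matrix(colMeans(mesh$vertices),
                                       nrow(fc), 3, byrow = TRUE))
    drop <- integer(0)
    for (k in seq_len(spec$n_holes)) {
      center <- normalize_rows(matrix(stats::rnorm(3), 1, 3))
      a <- angular_distance(fdir, matrix(center, nrow(fdir), 3, byrow = TRUE))
      sel <- which(a < spec$hole_width)
      if (!length(sel)) sel <- which.min(a)
      if (length(sel) >= nrow(mesh$faces))
        stop("requested hole larger than the mesh")
      drop <- union(drop, sel)
    }
    mesh <- drop_faces(mesh, drop)
  }
  if (spec$n_fins > 0) {
    et <- mesh_edge_table(mesh$faces)
    interior <- which(et$count[et$eid] == 2L)
    pick <- sample(interior, spec$n_fins)
    v <- mesh$vertices
    f <- mesh$faces
    col <- mesh$color
    fil <- mesh$filler
    for (h in pick) {
      a <- et$he_a[h]; b <- et$he_b[h]
      mid <- (v[a, ] + v[b, ]) / 2
      nrm <- mid - colMeans(mesh$vertices)
      nrm <- nrm / sqrt(sum(nrm^2))
      newv <- mid + nrm * sqrt(sum((v[a, ] - v[b, ])^2))
      v <- rbind(v, newv)
      f <- rbind(f, c(a, b, nrow(v)))
      col <- rbind(col, (col[a, ] + col[b, ]) / 2)
      fil <- c(fil, FALSE)
    }
    mesh <- colored_mesh(v, f, col, fil)
  }
  if (isTRUE(spec$add_island)) {
    r0 <- max(row_norms(mesh$vertices)) * 1.5
    tet <- icosphere(0, spec$base_radius * 0.02)
    tv <- tet$vertices + matrix(c(r0, r0, r0), nrow(tet$vertices), 3,
                                byrow = TRUE)
    nv <- nrow(mesh$vertices)
    mesh <- colored_mesh(rbind(mesh$vertices, tv),
                         rbind(mesh$faces, tet$faces + nv),
                         rbind(mesh$color, tet$color),
                         c(mesh$filler, tet$filler))
  }
  mesh
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces `spec$n_subjects` subjects via [make_face()] with consecutive
#' indices, the analytic population mean shape (the jitter-free template),
#' and — when `timepoint_seed` is given — a re-posed variant of the *same*
#' subjects (identical shape draws, new pose/noise draws), emulating a
#' second acquisition of untreated subjects some weeks later.
#'
#' @param spec a [face_population_spec()].
#' @param timepoint_seed optional pose/noise seed for a later timepoint.
#' @return list with `subjects` (list of [make_face()] outputs),
#'   `template` (population mean vertex matrix), `faces` (template faces),
#'   and `curves` (the shared template curve set).
#' @export
make_cohort <- function(spec, timepoint_seed = NULL) {
  if (spec$n_subjects < 2) stop("n_subjects must be >= 2")
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    make_face(spec, i, pose_seed = timepoint_seed))
  list(subjects = subjects,
       template = face_template_vertices(spec),
       faces = icosphere(spec$base_resolution, 1)$faces,
       curves = subjects[[1]]$curves)
}
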