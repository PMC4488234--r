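# Deviation quantification: signed distance-to-average maps with the
# blue-green-red display convention, tensor-based morphometry (log face
# area ratios), and per-vertex permutation statistical maps.

#' Signed distance-to-average map
#'
#' The value at vertex v is `(subject_v - mean_v) . n_v` with `n_v` the
#' average's outward unit vertex normal: signed millimetres, positive =
#' outward. The subject is expected to be Procrustes-aligned to the
#' average already (weights excluding filler).
#'
#' @param subject n x 3 corresponded vertex matrix on the average's
#'   topology.
#' @param average an [average_model()].
#' @param lo,hi display bounds in mm for the attached colorization.
#' @return object of class `distance_map`: `values` (signed mm), `range`,
#'   `colors` (from [colorize()]).
#' @export
signed_distance_map <- function(subject, average, lo = -5, hi = 5) {
  if (nrow(subject) != nrow(average$mean_vertices))
    stop("topology mismatch: subject has ", nrow(subject),
         " vertices, average has ", nrow(average$mean_vertices))
  avg_mesh <- colored_mesh(average$mean_vertices, average$faces)
  n <- vertex_normals_areas(avg_mesh)$normals
  vals <- rowSums((subject - average$mean_vertices) * n)
  structure(list(values = vals, range = c(lo, hi),
                 colors = colorize(vals, lo, hi)),
            class = "distance_map")
}

#' Diverging blue-green-red colorization of signed values
#'
#' Value `<= lo` maps to pure blue `(0,0,1)` (inward deviation), `0` to
#' pure green `(0,1,0)` (no deviation from the norm), `>= hi` to pure red
#' `(1,0,0)` (outward deviation), linear in between and clamped outside.
#'
#' @param values signed values (mm) or a `distance_map`.
#' @param lo,hi display bounds, `lo < 0 < hi`.
#' @return n x 3 RGB matrix in `[0, 1]`.
#' @export
colorize <- function(values, lo = -5, hi = 5) {
  if (inherits(values, "distance_map")) values <- values$values
  if (!(lo < 0 && 0 < hi)) stop("need lo < 0 < hi")
  v <- values
  t_neg <- clamp(v / lo, 0, 1)   # 0 at value 0, 1 at value lo
  t_pos <- clamp(v / hi, 0, 1)
  r <- ifelse(v >= 0, t_pos, 0)
  g <- ifelse(v >= 0, 1 - t_pos, 1 - t_neg)
  b <- ifelse(v >= 0, 0, t_neg)
  cbind(r, g, b)
}

#' Tensor-based morphometry map
#'
#' Per-face `log(area_subject / area_average)` — the surface analogue of
#' the log Jacobian determinant — with an area-weighted per-vertex
#' aggregation. Exactly invariant under rigid motion of either mesh; a
#' uniform scale `s` of the subject shifts every face value by
#' `2 log(s)`. Faces with (numerically) zero average area are flagged
#' undefined and excluded from the vertex aggregation.
#'
#' @param subject n x 3 corresponded vertex matrix.
#' @param average an [average_model()].
#' @return object of class `tbm_map`: `face_values`, `vertex_values`,
#'   `undefined_faces`.
#' @export
tbm_map <- function(subject, average) {
  if (nrow(subject) != nrow(average$mean_vertices))
    stop("topology mismatch")
  faces <- average$faces
  a_sub <- face_area_vectors(subject, faces)$area
  a_avg <- face_area_vectors(average$mean_vertices, faces)$area
  undef <- a_avg < 1e-12 | a_sub < 1e-300
  fv <- rep(NA_real_, nrow(faces))
  fv[!undef] <- log(a_sub[!undef] / a_avg[!undef])
  V <- nrow(subject)
  num <- den <- numeric(V)
  for (k in 1:3) {
    idx <- faces[!undef, k]
    s <- rowsum(fv[!undef] * a_avg[!undef], idx)
    num[as.integer(rownames(s))] <- num[as.integer(rownames(s))] + s[, 1]
    s <- rowsum(a_avg[!undef], idx)
    den[as.integer(rownames(s))] <- den[as.integer(rownames(s))] + s[, 1]
  }
  vv <- ifelse(den > 0, num / pmax(den, 1e-300), NA_real_)
  structure(list(face_values = fv, vertex_values = vv,
                 undefined_faces = which(undef)),
            class = "tbm_map")
}

#' Per-vertex permutation statistical map for two groups
#'
#' The per-vertex statistic is the absolute difference of group mean
#' signed distances to the pooled average; the null is built by randomly
#' relabeling subjects into groups of the original sizes, and
#' `p = (1 + #{null >= observed}) / (n_perm + 1)`, so the smallest
#' attainable p is `1 / (n_perm + 1)`. P-values are reported raw
#' (per-vertex); set `bh_adjust = TRUE` for a Benjamini-Hochberg column.
#'
#' @param groupA,groupB `corresponded_cohort`s (or bare lists of n x 3
#'   matrices) aligned to a common average.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed; same seed, same map.
#' @param bh_adjust also report Benjamini-Hochberg adjusted p-values.
#' @return object of class `p_map`: `p` (per-vertex, in `(0, 1]`),
#'   `observed` (statistic per vertex), `n_permutations`, `seed`,
#'   `statistic`, optionally `p_adjusted`.
#' @export
permutation_pmap <- function(groupA, groupB, n_perm = 999, seed = 0,
                             bh_adjust = FALSE) {
  getv <- function(g) if (inherits(g, "corresponded_cohort")) g$vertices else g
  A <- getv(groupA)
  B <- getv(groupB)
  if (length(A) < 2 || length(B) < 2) stop("each group needs >= 2 subjects")
  if (n_perm < 99) stop("n_perm must be >= 99")
  all_s <- c(A, B)
  nA <- length(A)
  n <- length(all_s)
  pooled <- Reduce(`+`, all_s) / n
  pooled_mesh_faces <- if (inherits(groupA, "corresponded_cohort"))
    groupA$faces else NULL
  nrm <- if (!is.null(pooled_mesh_faces))
    vertex_normals_areas(colored_mesh(pooled, pooled_mesh_faces))$normals
  else normalize_rows(pooled - matrix(colMeans(pooled), nrow(pooled), 3,
                                      byrow = TRUE))
  # signed distances of every subject to the pooled average
  D <- vapply(all_s, function(x) rowSums((x - pooled) * nrm),
              numeric(nrow(pooled)))
  obs <- abs(rowMeans(D[, seq_len(nA), drop = FALSE]) -
               rowMeans(D[, nA + seq_len(n - nA), drop = FALSE]))
  set.seed(seed)
  exceed <- numeric(nrow(D))
  for (b in seq_len(n_perm)) {
    lab <- sample.int(n, nA)
    stat <- abs(rowMeans(D[, lab, drop = FALSE]) -
                  rowMeans(D[, -lab, drop = FALSE]))
    exceed <- exceed + (stat >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  out <- list(p = p, observed = obs, n_permutations = n_perm, seed = seed,
              statistic = "abs difference of group mean signed distances")
  if (bh_adjust) out$p_adjusted <- stats::p.adjust(p, method = "BH")
  structure(out, class = "p_map")
}

#' Compare two average models
#'
#' Procrustes-aligns B's mean to A's mean (weighted by
#' `(1 - filler_fraction_A) * (1 - filler_fraction_B)`), then computes the
#' signed distance map of the aligned B against A, colorized on
#' `(lo, hi)`.
#'
#' @param avgA,avgB [average_model()]s on the same reference topology.
#' @param lo,hi display bounds in mm (average-to-average comparisons
#'   conventionally use -3..3 mm).
#' @return a `distance_map` (see [signed_distance_map()]).
#' @export
compare_averages <- function(avgA, avgB, lo = -3, hi = 3) {
  if (nrow(avgA$mean_vertices) != nrow(avgB$mean_vertices))
    stop("topology mismatch between averages")
  w <- (1 - avgA$filler_fraction) * (1 - avgB$filler_fraction)
  if (sum(w) <= 0) w <- rep(1, length(w))
  tr <- procrustes_pair(avgB$mean_vertices, avgA$mean_vertices, w)
  aligned_b <- apply_transform(tr, avgB$mean_vertices)
  signed_distance_map(aligned_b, avgA, lo, hi)
}

#' Write a distance map as a colored PLY plus CSV sidecar
#'
#' @param map a `distance_map`.
#' @param average the [average_model()] providing geometry/topology.
#' @param path output PLY path (the CSV sidecar gets extension `.csv`).
#' @export
write_distance_map <- function(map, average, path) {
  mesh <- colored_mesh(average$mean_vertices, average$faces, map$colors)
  write_mesh(mesh, path, format = "ply")
  utils::write.csv(data.frame(vertex = seq_along(map$values),
                              value_mm = map$values),
                   sub("\\.ply$", ".csv", path), row.names = FALSE)
  invisible(path)
}
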