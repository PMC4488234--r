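# Dense spherical correspondence: arclength curve matching for a robust
# initial warp, then greedy fluid refinement of a multi-channel mutual
# information (texture) plus curvature-mismatch (geometry) cost, with
# filler regions excluded from every cost term.

#' Registration parameters
#'
#' @param w_texture weight (>= 0) of the negated color mutual-information
#'   term.
#' @param w_geometry weight (>= 0) of the curvature mean-squared-difference
#'   term.
#' @param mi_bins histogram bins per channel (>= 2).
#' @param kernel_sigma spherical Gaussian width (radians) smoothing the
#'   force field into a velocity field.
#' @param step update scale for the composed velocity step.
#' @param max_iters maximum fluid iterations.
#' @param tol relative cost-change stopping threshold.
#' @param seed seed for any stochastic sampling.
#' @return list of class `registration_params`.
#' @export
registration_params <- function(w_texture = 1, w_geometry = 1, mi_bins = 32,
                                kernel_sigma = 0.1, step = 0.5,
                                max_iters = 200, tol = 1e-5, seed = 0) {
  stopifnot(w_texture >= 0, w_geometry >= 0, w_texture + w_geometry > 0,
            mi_bins >= 2)
  structure(as.list(environment()), class = "registration_params")
}

#' Per-vertex feature channels of a subject
#'
#' Five channels: R, G, B color (texture) and robust-z-normalized mean and
#' Gaussian curvature (geometry; zero median, unit MAD on the non-filler
#' mask). The valid mask is the non-filler set.
#'
#' @param mesh a manifold [colored_mesh()].
#' @param curv optional precomputed [curvatures()] result.
#' @return list of class `feature_channels` with `channels` (n x 5 matrix,
#'   columns `R,G,B,H,K`), `is_geometry` (logical per column), and `valid`.
#' @export
feature_channels <- function(mesh, curv = NULL) {
  if (is.null(curv)) curv <- curvatures(mesh)
  valid <- !mesh$filler
  robust_z <- function(x) {
    med <- stats::median(x[valid])
    md <- stats::mad(x[valid])
    if (md < 1e-12) md <- stats::sd(x[valid]) + 1e-12
    # winsorize at +-6 MAD: curvature tails (bump apices) would otherwise
    # dominate the mean-squared mismatch; median and MAD are unaffected
    clamp((x - med) / md, -6, 6)
  }
  ch <- cbind(R = mesh$color[, 1], G = mesh$color[, 2], B = mesh$color[, 3],
              H = robust_z(curv$mean_curvature),
              K = robust_z(curv$gaussian_curvature))
  structure(list(channels = ch,
                 is_geometry = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                 valid = valid),
            class = "feature_channels")
}

# bundle of everything the registrar needs about one subject
registration_subject <- function(mesh, sphmap, channels = NULL,
                                 curves = NULL) {
  if (is.null(channels)) channels <- feature_channels(mesh)
  list(mesh = mesh, sphmap = sphmap, channels = channels, curves = curves)
}

#' Arclength correspondence between matching named curves
#'
#' Each curve is resampled at `n_samples` points equally spaced by
#' normalized arclength measured on the 3D surface polyline (endpoints
#' included); the i-th sample on the moving subject corresponds to the
#' i-th on the fixed. Samples are carried to the sphere through each
#' subject's spherical map.
#'
#' @param curves_moving,curves_fixed `curve_set`s with identical names.
#' @param sph_moving,sph_fixed the two subjects' `spherical_map`s.
#' @param n_samples samples per curve.
#' @return list with unit-row matrices `moving` and `fixed` (one row per
#'   sample pair).
#' @export
curve_correspondence <- function(curves_moving, curves_fixed,
                                 sph_moving, sph_fixed, n_samples = 15) {
  miss <- setdiff(names(curves_moving), names(curves_fixed))
  if (length(miss)) stop("curve '", miss[1], "' missing on fixed subject")
  miss <- setdiff(names(curves_fixed), names(curves_moving))
  if (length(miss)) stop("curve '", miss[1], "' missing on moving subject")
  sample_curve <- function(idx, mesh, sphmap) {
    pts <- mesh$vertices[idx, , drop = FALSE]
    seg <- row_norms(diff(pts))
    L <- sum(seg)
    if (L <= 0) stop("zero-length curve")
    cum <- c(0, cumsum(seg))
    targ <- seq(0, L, length.out = n_samples)
    sp <- sphmap$sphere_positions[idx, , drop = FALSE]
    out <- matrix(0, n_samples, 3)
    for (i in seq_len(n_samples)) {
      k <- findInterval(targ[i], cum, rightmost.closed = TRUE)
      k <- min(max(k, 1L), length(seg))
      t <- (targ[i] - cum[k]) / seg[k]
      out[i, ] <- (1 - t) * sp[k, ] + t * sp[k + 1, ]
    }
    normalize_rows(out)
  }
  mv <- fx <- list()
  for (nm in names(curves_moving)) {
    mv[[nm]] <- sample_curve(curves_moving[[nm]], sph_moving$source, sph_moving)
    fx[[nm]] <- sample_curve(curves_fixed[[nm]], sph_fixed$source, sph_fixed)
  }
  list(moving = do.call(rbind, mv), fixed = do.call(rbind, fx))
}

#' Initial warp from curve correspondences
#'
#' Each pair contributes the rotation taking its moving sphere point to
#' its fixed partner (axis = cross product, angle = arc distance); the
#' dense field blends pair rotation vectors with normalized spherical
#' Gaussian weights and re-projects to the sphere. The blended field is
#' applied at the largest flip-free global amplitude (step-halving, at
#' most 20 halvings).
#'
#' @param pairs output of [curve_correspondence()] (or any list with unit
#'   row-matrices `moving`, `fixed`).
#' @param domain the moving subject's `spherical_map`.
#' @param kernel_sigma spherical Gaussian blending width (radians).
#' @return object of class `spherical_warp`: list with `domain` and
#'   `warped_positions` (unit rows, flip-free).
#' @export
initial_warp <- function(pairs, domain, kernel_sigma = 0.3) {
  m <- pairs$moving
  f <- pairs$fixed
  if (nrow(m) < 3) stop("need at least 3 correspondence pairs")
  # global prealignment: optimal rotation taking the moving pair
  # directions onto the fixed ones (orthogonal Procrustes), so the
  # blended field only carries local residuals
  sv <- svd(t(f) %*% m)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  Rg <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  m <- m %*% t(Rg)
  axis <- cross_rows(m, f)
  ang <- angular_distance(m, f)
  an <- row_norms(axis)
  ok <- an > 1e-12
  rv <- matrix(0, nrow(m), 3)
  rv[ok, ] <- axis[ok, , drop = FALSE] / an[ok] * ang[ok]
  p <- domain$sphere_positions %*% t(Rg)
  d <- angular_distance_matrix(p, m)
  w <- exp(-d^2 / (2 * kernel_sigma^2))
  w <- w / pmax(rowSums(w), 1e-300)
  rho <- w %*% rv
  for (halv in 0:20) {
    amp <- 2^(-halv)
    warped <- normalize_rows(rotate_by_rotvecs(p, amp * rho))
    if (is_flip_free(warped, domain$faces))
      return(structure(list(domain = domain, warped_positions = warped),
                       class = "spherical_warp"))
  }
  stop("initial_warp: flips persist even at 2^-20 amplitude")
}

#' Identity warp on a spherical map
#' @param domain a `spherical_map`.
#' @export
identity_warp <- function(domain) {
  structure(list(domain = domain,
                 warped_positions = domain$sphere_positions),
            class = "spherical_warp")
}

# dense angular distance matrix between unit row sets (n x m)
angular_distance_matrix <- function(a, b) {
  cp <- clamp(a %*% t(b), -1, 1)
  acos(cp)
}

#' Histogram mutual information between two sample vectors
#'
#' Joint histogram with `bins` x `bins` equal-width bins spanning each
#' variable's observed range; MI in bits with the `0 log 0 = 0`
#' convention. A constant channel yields `MI = 0` with attribute
#' `degenerate = TRUE`.
#'
#' @param a,b equal-length numeric samples (length >= `bins`).
#' @param bins histogram bins per variable.
#' @return non-negative MI in bits.
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (length(a) != length(b)) stop("samples must have equal length")
  if (length(a) < bins) stop("need at least `bins` samples")
  ba <- bin_index(a, bins)
  bb <- bin_index(b, bins)
  if (is.null(ba) || is.null(bb)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  joint <- tabulate(ba + bins * (bb - 1L), nbins = bins * bins)
  mi_from_joint(joint, bins, length(a))
}

bin_index <- function(x, bins) {
  r <- range(x)
  if (r[2] - r[1] < 1e-300) return(NULL)
  idx <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(as.integer(idx), bins)
}

mi_from_joint <- function(joint, bins, n) {
  J <- matrix(joint, bins, bins)
  pa <- rowSums(J)
  pb <- colSums(J)
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  (sum(xlx(J)) - sum(xlx(pa)) - sum(xlx(pb)) + xlx(n)) / n
}

#' Registration cost of a warp
#'
#' Samples the fixed subject's channels at the warped positions of the
#' moving subject's vertices and returns
#' `- w_texture * sum_RGB MI + w_geometry * mean squared curvature
#' difference`, computed only over pairs where neither side involves
#' filler geometry (a sampled point is a filler pair whenever any
#' positively-weighted contributing fixed vertex is filler, so filler
#' colors can never influence the cost).
#'
#' @param warp a `spherical_warp` from moving onto the fixed sphere.
#' @param moving,fixed registration subjects (lists with `sphmap` and
#'   `channels`; see [feature_channels()]).
#' @param params a [registration_params()].
#' @return scalar cost with attribute `breakdown` (list with `texture_mi`
#'   per channel, `geometry_msd`, `n_valid`).
#' @export
registration_cost <- function(warp, moving, fixed, params) {
  st <- cost_state(warp$warped_positions, moving, fixed, params)
  if (st$n_valid < params$mi_bins)
    stop("fewer valid samples (", st$n_valid, ") than mi_bins")
  cost_from_state(st, params)
}

# sample fixed channels at warped positions and assemble cost ingredients
cost_state <- function(warped, moving, fixed, params) {
  loc <- cpp_locate(fixed$sphmap$sphere_positions, fixed$sphmap$faces, warped)
  sampled <- interp_attr(fixed$channels$channels, fixed$sphmap$faces, loc)
  sfiller <- interp_flag_any(!fixed$channels$valid, fixed$sphmap$faces, loc)
  valid <- moving$channels$valid & !sfiller
  list(loc = loc, sampled = sampled, valid = valid, n_valid = sum(valid),
       mov = moving$channels$channels, is_geom = moving$channels$is_geometry)
}

cost_from_state <- function(st, params) {
  v <- st$valid
  tex_idx <- which(!st$is_geom)
  geo_idx <- which(st$is_geom)
  mi <- vapply(tex_idx, function(k)
    as.numeric(mutual_information(st$mov[v, k], st$sampled[v, k],
                                  params$mi_bins)), 0)
  msd <- vapply(geo_idx, function(k)
    mean((st$mov[v, k] - st$sampled[v, k])^2), 0)
  cost <- -params$w_texture * sum(mi) + params$w_geometry * mean(msd)
  attr(cost, "breakdown") <- list(texture_mi = mi, geometry_msd = mean(msd),
                                  n_valid = st$n_valid)
  cost
}

# delta of n*log-entropy helper: f(x) = x log2 x
xlx2 <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Fluid spherical registration
#'
#' Greedy fluid iteration: the per-vertex force is the negative numerical
#' gradient of the registration cost with respect to that vertex's
#' tangential displacement (central differences, `h = 1e-3` rad, with
#' O(1) incremental histogram updates); the velocity is the spherical
#' Gaussian smoothing (width `kernel_sigma`) of the force field; the warp
#' is composed with `exp(step * velocity)` re-projected to the sphere. A
#' step is accepted only if flip-free and cost-decreasing, else halved
#' (up to 10 times, then the iteration stops). The accepted cost trace is
#' strictly decreasing.
#'
#' @param moving,fixed registration subjects (see
#'   [registration_subject()]).
#' @param init a flip-free `spherical_warp` (e.g. [initial_warp()] or
#'   [identity_warp()]).
#' @param params a [registration_params()].
#' @return list with `warp` (the refined `spherical_warp`) and `trace`
#'   (accepted costs, strictly decreasing).
#' @export
fluid_register <- function(moving, fixed, init, params = registration_params()) {
  if (!is_flip_free(init$warped_positions, init$domain$faces))
    stop("fluid_register: initial warp has flipped triangles")
  W <- init$warped_positions
  faces <- init$domain$faces
  h <- 1e-3
  # smoothing matrix over the moving domain (fixed through the iteration)
  D <- angular_distance_matrix(init$domain$sphere_positions,
                               init$domain$sphere_positions)
  S <- exp(-D^2 / (2 * params$kernel_sigma^2))
  S <- S / rowSums(S)

  st <- cost_state(W, moving, fixed, params)
  if (st$n_valid < params$mi_bins)
    stop("fewer valid samples (", st$n_valid, ") than mi_bins")
  cost <- cost_from_state(st, params)
  trace <- as.numeric(cost)
  step <- params$step * params$kernel_sigma  # initial amplitude, radians
  for (iter in seq_len(params$max_iters)) {
    force <- fluid_force(W, st, moving, fixed, params, h)
    vel <- as.matrix(S %*% force)
    # project tangentially at the warped positions
    vel <- vel - W * rowSums(vel * W)
    vmax <- max(row_norms(vel))
    if (vmax < 1e-12) break
    vel <- vel / vmax                       # unit maximum displacement
    accepted <- FALSE
    s <- step
    for (halv in 0:10) {
      cand <- normalize_rows(W + s * vel)
      if (is_flip_free(cand, faces)) {
        st2 <- cost_state(cand, moving, fixed, params)
        c2 <- cost_from_state(st2, params)
        if (as.numeric(c2) < trace[length(trace)]) {
          W <- cand
          st <- st2
          rel <- (trace[length(trace)] - as.numeric(c2)) /
            max(abs(trace[length(trace)]), 1e-300)
          trace <- c(trace, as.numeric(c2))
          step <- min(s * 1.5, 2 * params$kernel_sigma)
          accepted <- TRUE
          break
        }
      }
      s <- s / 2
    }
    if (!accepted) break
    if (rel < params$tol) break
  }
  list(warp = structure(list(domain = init$domain, warped_positions = W),
                        class = "spherical_warp"),
       trace = trace)
}

# negative cost gradient per vertex (tangential, 3-vector rows) using
# incremental MI/MSD deltas: moving one vertex changes exactly one sample
fluid_force <- function(W, st, moving, fixed, params, h) {
  V <- nrow(W)
  v <- st$valid
  vid <- which(v)
  nv <- length(vid)
  tb <- tangent_basis(W[vid, , drop = FALSE])
  probes <- rbind(normalize_rows(W[vid, ] + h * tb$t1),
                  normalize_rows(W[vid, ] - h * tb$t1),
                  normalize_rows(W[vid, ] + h * tb$t2),
                  normalize_rows(W[vid, ] - h * tb$t2))
  loc <- cpp_locate(fixed$sphmap$sphere_positions, fixed$sphmap$faces, probes)
  snew <- interp_attr(fixed$channels$channels, fixed$sphmap$faces, loc)

  tex_idx <- which(!st$is_geom)
  geo_idx <- which(st$is_geom)
  bins <- params$mi_bins
  n <- st$n_valid
  delta <- numeric(4 * nv)

  for (k in tex_idx) {
    a <- st$mov[v, k]
    b <- st$sampled[v, k]
    ra <- bin_index(a, bins)
    rb_all <- bin_index_with_range(c(b, snew[, k]), bins, range(b))
    if (is.null(ra) || is.null(rb_all)) next
    rb <- rb_all[seq_len(nv)]
    rb_new <- matrix(rb_all[-seq_len(nv)], nv, 4)
    J <- tabulate(ra + bins * (rb - 1L), nbins = bins * bins)
    Mb <- tabulate(rb, nbins = bins)
    # delta MI (bits) for moving sample i from bin c1 -> c2 (same row r)
    for (p in 1:4) {
      c1 <- rb
      c2 <- rb_new[, p]
      same <- c1 == c2
      jc1 <- J[ra + bins * (c1 - 1L)]
      jc2 <- J[ra + bins * (c2 - 1L)]
      dJ <- xlx2(jc1 - 1) - xlx2(jc1) + xlx2(jc2 + 1) - xlx2(jc2)
      dM <- xlx2(Mb[c1] - 1) - xlx2(Mb[c1]) + xlx2(Mb[c2] + 1) - xlx2(Mb[c2])
      dmi <- ifelse(same, 0, (dJ - dM) / n)
      # cost uses -w_texture * MI
      delta[(p - 1) * nv + seq_len(nv)] <-
        delta[(p - 1) * nv + seq_len(nv)] - params$w_texture * dmi
    }
  }
  ngeo <- length(geo_idx)
  for (k in geo_idx) {
    a <- st$mov[v, k]
    b <- st$sampled[v, k]
    for (p in 1:4) {
      bn <- snew[(p - 1) * nv + seq_len(nv), k]
      dmsd <- ((a - bn)^2 - (a - b)^2) / n / ngeo
      delta[(p - 1) * nv + seq_len(nv)] <-
        delta[(p - 1) * nv + seq_len(nv)] + params$w_geometry * dmsd
    }
  }
  g1 <- (delta[seq_len(nv)] - delta[nv + seq_len(nv)]) / (2 * h)
  g2 <- (delta[2 * nv + seq_len(nv)] - delta[3 * nv + seq_len(nv)]) / (2 * h)
  force <- matrix(0, V, 3)
  force[vid, ] <- -(g1 * tb$t1 + g2 * tb$t2)
  force
}

bin_index_with_range <- function(x, bins, r) {
  if (r[2] - r[1] < 1e-300) return(NULL)
  idx <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(pmax(as.integer(idx), 1L), bins)
}

#' Evaluate a warp at arbitrary domain directions
#'
#' Interpolates the warped positions barycentrically over the domain
#' triangulation and re-normalizes.
#'
#' @param warp a `spherical_warp`.
#' @param query unit direction matrix on the warp's domain sphere.
#' @export
warp_evaluate <- function(warp, query) {
  loc <- cpp_locate(warp$domain$sphere_positions, warp$domain$faces, query)
  normalize_rows(interp_attr(warp$warped_positions, warp$domain$faces, loc))
}

#' Invert a warp at target-sphere directions
#'
#' Looks the directions up in the warped triangulation and interpolates
#' the domain positions: `warp_invert(warp, warp_evaluate(warp, p))`
#' recovers `p` for flip-free warps.
#'
#' @param warp a `spherical_warp`.
#' @param query unit direction matrix on the fixed (target) sphere.
#' @export
warp_invert <- function(warp, query) {
  if (!is_flip_free(warp$warped_positions, warp$domain$faces))
    stop("warp_invert: warp has flipped triangles")
  loc <- cpp_locate(warp$warped_positions, warp$domain$faces, query)
  normalize_rows(interp_attr(warp$domain$sphere_positions,
                             warp$domain$faces, loc))
}

#' Resample subjects onto a common reference topology
#'
#' For each reference vertex direction, inverts each subject's warp (by
#' lookup in its warped triangulation) and interpolates that subject's
#' surface position, color and filler flag (filler is `TRUE` whenever any
#' positively-weighted contributing vertex is filler). The result is a
#' corresponded cohort: one vertex matrix per subject on identical
#' topology, point-to-point correspondence by row index.
#'
#' @param subjects list of registration subjects (each with `mesh`,
#'   `sphmap`).
#' @param reference list with `sphere_positions` and `faces` (typically
#'   the fixed subject's `spherical_map`).
#' @param warps list of flip-free `spherical_warp`s, one per subject, all
#'   into the reference sphere.
#' @return object of class `corresponded_cohort`: list with `vertices`
#'   (list of n_ref x 3 matrices), `colors` (list), `filler` (n_ref x
#'   n_subjects logical matrix), `faces` (reference topology).
#' @export
resample_to_reference <- function(subjects, reference, warps) {
  stopifnot(length(subjects) == length(warps))
  refdir <- reference$sphere_positions
  verts <- cols <- vector("list", length(subjects))
  fil <- matrix(FALSE, nrow(refdir), length(subjects))
  for (i in seq_along(subjects)) {
    w <- warps[[i]]
    if (!is_flip_free(w$warped_positions, w$domain$faces))
      stop("resample_to_reference: warp ", i, " has flipped triangles")
    loc <- cpp_locate(w$warped_positions, w$domain$faces, refdir)
    verts[[i]] <- interp_attr(subjects[[i]]$mesh$vertices, w$domain$faces, loc)
    cols[[i]] <- interp_attr(subjects[[i]]$mesh$color, w$domain$faces, loc)
    fil[, i] <- interp_flag_any(subjects[[i]]$mesh$filler, w$domain$faces, loc)
  }
  structure(list(vertices = verts, colors = cols, filler = fil,
                 faces = reference$faces,
                 reference_positions = refdir),
            class = "corresponded_cohort")
}
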