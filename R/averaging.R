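# Seven-parameter (similarity) Procrustes alignment and cohort averaging,
# with filler geometry excluded through per-vertex weights.

#' Weighted similarity (7-parameter) Procrustes fit
#'
#' Closed-form weighted Procrustes: weighted centroids, SVD of the
#' weighted cross-covariance with determinant correction so a reflection
#' is never returned, scale from the trace ratio. Minimizes
#' \eqn{\sum_i w_i \| s R x_i + t - y_i \|^2} over 3 translations, 3
#' rotations and 1 uniform scale.
#'
#' @param moving,fixed n x 3 vertex matrices in correspondence.
#' @param weights per-vertex weights in `[0, 1]` (use 0 on filler rows);
#'   default all 1.
#' @return object of class `similarity_transform`: list with `scale`
#'   (positive scalar), `rotation` (proper orthogonal 3 x 3) and
#'   `translation` (length-3, mm).
#' @export
procrustes_pair <- function(moving, fixed, weights = NULL) {
  stopifnot(nrow(moving) == nrow(fixed))
  if (is.null(weights)) weights <- rep(1, nrow(moving))
  if (sum(weights) <= 0) stop("sum of weights must be positive")
  w <- weights / sum(weights)
  cx <- colSums(moving * w)
  cy <- colSums(fixed * w)
  X <- moving - matrix(cx, nrow(moving), 3, byrow = TRUE)
  Y <- fixed - matrix(cy, nrow(fixed), 3, byrow = TRUE)
  M <- t(Y * w) %*% X            # weighted cross-covariance
  sv <- svd(M)
  if (sv$d[1] <= 0 || sv$d[2] < 1e-12 * sv$d[1])
    stop("rank-deficient configuration (collinear support)")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) stop("rank-deficient configuration (collinear support)")
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)
  varx <- sum(w * rowSums(X^2))
  if (varx < 1e-300) stop("rank-deficient configuration (degenerate moving)")
  s <- sum(sv$d * c(1, 1, d)) / varx
  if (s <= 0) stop("non-positive Procrustes scale")
  t_vec <- cy - s * as.vector(R %*% cx)
  structure(list(scale = s, rotation = R, translation = t_vec),
            class = "similarity_transform")
}

#' Apply a similarity transform to a vertex matrix
#' @param transform a `similarity_transform`.
#' @param x n x 3 matrix.
#' @export
apply_transform <- function(transform, x) {
  transform$scale * x %*% t(transform$rotation) +
    matrix(transform$translation, nrow(x), 3, byrow = TRUE)
}

#' Generalized (group-wise) Procrustes alignment of a corresponded cohort
#'
#' Alternates aligning every subject to the current consensus mean
#' (weights `1 - filler`) and recomputing the mean, until the relative
#' mean change falls below `tol`. Sizes are standardized by rescaling the
#' consensus each round: to the cohort's mean centroid size by default
#' (relative size removed, millimetre scale retained) or to unit centroid
#' size with `mean_size = "unit"`. Deterministic in subject order.
#'
#' @param cohort a `corresponded_cohort` (see [resample_to_reference()]),
#'   or a bare list of n x 3 matrices.
#' @param tol relative consensus-change stopping threshold.
#' @param max_iters maximum alternation rounds.
#' @param mean_size `"cohort"` or `"unit"` consensus size standardization.
#' @return list with `aligned` (a `corresponded_cohort` of aligned vertex
#'   matrices), `transforms` (per-subject `similarity_transform`s),
#'   `mean_vertices`, and `objective_trace` (non-increasing weighted
#'   residual).
#' @export
generalized_procrustes <- function(cohort, tol = 1e-9, max_iters = 100,
                                   mean_size = c("cohort", "unit")) {
  mean_size <- match.arg(mean_size)
  if (!inherits(cohort, "corresponded_cohort")) {
    cohort <- structure(list(vertices = cohort,
                             colors = NULL,
                             filler = matrix(FALSE, nrow(cohort[[1]]),
                                             length(cohort)),
                             faces = NULL),
                        class = "corresponded_cohort")
  }
  n <- length(cohort$vertices)
  if (n < 2) stop("generalized_procrustes needs at least 2 subjects")
  Xs <- cohort$vertices
  wts <- lapply(seq_len(n), function(i) as.numeric(!cohort$filler[, i]))
  csize <- function(x) {
    c0 <- colMeans(x)
    sqrt(sum((x - matrix(c0, nrow(x), 3, byrow = TRUE))^2))
  }
  target_size <- if (mean_size == "cohort")
    mean(vapply(Xs, csize, 0)) else 1
  mean_v <- Reduce(`+`, Xs) / n
  objective <- numeric(0)
  transforms <- vector("list", n)
  for (iter in seq_len(max_iters)) {
    for (i in seq_len(n)) {
      tr <- procrustes_pair(cohort$vertices[[i]], mean_v, wts[[i]])
      transforms[[i]] <- tr
      Xs[[i]] <- apply_transform(tr, cohort$vertices[[i]])
    }
    new_mean <- Reduce(`+`, Xs) / n
    c0 <- colMeans(new_mean)
    new_mean <- (new_mean - matrix(c0, nrow(new_mean), 3, byrow = TRUE)) *
      (target_size / csize(new_mean)) +
      matrix(c0, nrow(new_mean), 3, byrow = TRUE)
    obj <- mean(vapply(seq_len(n), function(i)
      sum(wts[[i]] * rowSums((Xs[[i]] - new_mean)^2)) / sum(wts[[i]]), 0))
    objective <- c(objective, obj)
    chg <- sqrt(mean((new_mean - mean_v)^2)) / max(csize(new_mean), 1e-300)
    mean_v <- new_mean
    if (chg < tol) break
  }
  aligned <- cohort
  aligned$vertices <- Xs
  list(aligned = aligned, transforms = transforms, mean_vertices = mean_v,
       objective_trace = objective)
}

#' Average model of an aligned cohort
#'
#' Per-vertex arithmetic mean shape, scalar positional variance (mean
#' squared distance of the subjects' vertices to the mean, mm^2), mean
#' color over non-filler contributions, and the per-vertex fraction of
#' subjects contributing filler.
#'
#' @param aligned a `corresponded_cohort` of aligned subjects (e.g.
#'   `generalized_procrustes(...)$aligned`).
#' @return object of class `average_model`: `mean_vertices`,
#'   `per_vertex_variance`, `mean_color`, `filler_fraction`, `n_subjects`,
#'   `faces`.
#' @export
average_model <- function(aligned) {
  Xs <- aligned$vertices
  n <- length(Xs)
  V <- nrow(Xs[[1]])
  mean_v <- Reduce(`+`, Xs) / n
  var_v <- Reduce(`+`, lapply(Xs, function(x)
    rowSums((x - mean_v)^2))) / n
  fil <- aligned$filler
  if (is.null(fil)) fil <- matrix(FALSE, V, n)
  mean_col <- NULL
  if (!is.null(aligned$colors)) {
    num <- matrix(0, V, 3)
    den <- numeric(V)
    for (i in seq_len(n)) {
      keep <- !fil[, i]
      num[keep, ] <- num[keep, ] + aligned$colors[[i]][keep, , drop = FALSE]
      den[keep] <- den[keep] + 1
    }
    all_fil <- den == 0
    den[all_fil] <- 1
    mean_col <- num / den
    if (any(all_fil))
      mean_col[all_fil, ] <- Reduce(`+`, aligned$colors)[all_fil, ] / n
  }
  structure(list(mean_vertices = mean_v,
                 per_vertex_variance = var_v,
                 mean_color = mean_col,
                 filler_fraction = rowMeans(fil),
                 n_subjects = n,
                 faces = aligned$faces),
            class = "average_model")
}

#' @export
print.average_model <- function(x, ...) {
  cat("<average_model> ", nrow(x$mean_vertices), " vertices, ",
      x$n_subjects, " subjects, mean per-vertex SD ",
      signif(mean(sqrt(x$per_vertex_variance)), 3), " mm\n", sep = "")
  invisible(x)
}
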