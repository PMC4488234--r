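# End-to-end orchestration: cohort averaging, individual-to-average
# superimposition and average-to-average comparison, with a config
# object, per-stage artifacts, and full determinism under a fixed seed.

#' Build a run configuration
#'
#' Either pass a YAML file path or override defaults directly. Unknown
#' fields are rejected.
#'
#' @param path optional YAML file with fields named as the arguments.
#' @param rel_tol,max_rounds boundary-closure tolerances.
#' @param smooth_iterations,smooth_lambda Taubin smoothing after closure
#'   (0 iterations disables).
#' @param area_relax_iters spherical-map area relaxation iterations.
#' @param registration a [registration_params()] list.
#' @param curve_samples samples per curve for the initial warp.
#' @param init_kernel_sigma blending width (rad) of the curve-based
#'   initial warp.
#' @param gpa_tol,gpa_max_iters generalized Procrustes controls.
#' @param mean_size `"cohort"` or `"unit"` size standardization.
#' @param range_individual,range_compare display ranges (mm).
#' @param reference_rounds 1 = register everyone to the first subject;
#'   2 = one further round registering to the evolving average's closest
#'   subject-space representation.
#' @param seed master seed recorded in the manifest.
#' @param output_dir optional directory for artifacts (`NULL` = none).
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL,
                       rel_tol = 1e-3, max_rounds = 6,
                       smooth_iterations = 0, smooth_lambda = 0.5,
                       area_relax_iters = 60,
                       registration = registration_params(),
                       curve_samples = 15,
                       init_kernel_sigma = 0.3,
                       gpa_tol = 1e-9, gpa_max_iters = 100,
                       mean_size = "cohort",
                       range_individual = c(-5, 5),
                       range_compare = c(-3, 3),
                       reference_rounds = 1,
                       seed = 0,
                       output_dir = NULL) {
  cfg <- as.list(environment())
  cfg$path <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    unknown <- setdiff(names(y), c(names(cfg), "registration"))
    if (length(unknown)) stop("unknown config field: ", unknown[1])
    for (nm in setdiff(names(y), "registration")) cfg[[nm]] <- y[[nm]]
    if (!is.null(y$registration))
      cfg$registration <- do.call(registration_params, y$registration)
  }
  structure(cfg, class = "run_config")
}

# correct + parameterize + featurize one subject
prepare_subject <- function(mesh, curves, config) {
  mesh <- remove_nonmanifold(mesh)
  cb <- close_boundaries(mesh, config$rel_tol, config$max_rounds)
  mesh <- cb$mesh
  if (config$smooth_iterations > 0)
    mesh <- smooth_mesh(mesh, config$smooth_iterations, config$smooth_lambda)
  sphmap <- spherical_parameterize(mesh, config$area_relax_iters)
  registration_subject(mesh, sphmap, curves = curves)
}

register_pair <- function(moving, fixed, config) {
  init <- if (!is.null(moving$curves) && !is.null(fixed$curves)) {
    pairs <- curve_correspondence(moving$curves, fixed$curves,
                                  moving$sphmap, fixed$sphmap,
                                  config$curve_samples)
    initial_warp(pairs, moving$sphmap, config$init_kernel_sigma)
  } else identity_warp(moving$sphmap)
  fluid_register(moving, fixed, init, config$registration)
}

#' Run the cohort-averaging pipeline
#'
#' For every subject: topology correction, spherical mapping, curve-based
#' initialization and fluid registration to the reference (the first
#' subject); then resampling onto the reference topology, generalized
#' Procrustes alignment, and averaging. Rerunning with the same config
#' and inputs reproduces the average bit-identically.
#'
#' @param subjects list of subjects, each a list with `mesh` (a
#'   [colored_mesh()] or a file path) and `curves` (a `curve_set` or JSON
#'   path); [make_cohort()] output's `subjects` field works directly.
#' @param config a [run_config()].
#' @return list with `average` ([average_model()]), `cohort` (aligned
#'   `corresponded_cohort`), `gpa`, `subjects` (prepared subjects),
#'   `warps`, `traces`, `manifest`.
#' @export
run_average <- function(subjects, config = run_config()) {
  if (length(subjects) < 2) stop("run_average needs >= 2 subjects")
  set.seed(config$seed)
  prepared <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    mesh <- if (is.character(s$mesh)) read_mesh(s$mesh) else s$mesh
    curves <- if (is.character(s$curves)) read_curves(s$curves) else s$curves
    prepared[[i]] <- tryCatch(prepare_subject(mesh, curves, config),
                              error = function(e)
                                stop("stage 'prepare' failed for subject ", i,
                                     ": ", conditionMessage(e)))
  }
  reference <- prepared[[1]]
  warps <- vector("list", length(prepared))
  traces <- vector("list", length(prepared))
  for (i in seq_along(prepared)) {
    if (i == 1) {
      warps[[i]] <- identity_warp(reference$sphmap)
      traces[[i]] <- numeric(0)
      next
    }
    fr <- tryCatch(register_pair(prepared[[i]], reference, config),
                   error = function(e)
                     stop("stage 'register' failed for subject ", i, ": ",
                          conditionMessage(e)))
    warps[[i]] <- fr$warp
    traces[[i]] <- fr$trace
  }
  cohort <- resample_to_reference(prepared, reference$sphmap, warps)
  gpa <- generalized_procrustes(cohort, config$gpa_tol, config$gpa_max_iters,
                                config$mean_size)
  avg <- average_model(gpa$aligned)
  cfg_plain <- rapply(unclass(config[setdiff(names(config), "output_dir")]),
                      identity, how = "replace")
  cfg_plain$registration <- unclass(cfg_plain$registration)
  manifest <- list(n_subjects = length(subjects), seed = config$seed,
                   config = cfg_plain)
  out <- list(average = avg, cohort = gpa$aligned, gpa = gpa,
              subjects = prepared, warps = warps, traces = traces,
              manifest = manifest)
  if (!is.null(config$output_dir)) write_run_artifacts(out, config)
  out
}

write_run_artifacts <- function(run, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  avg <- run$average
  write_mesh(colored_mesh(avg$mean_vertices, avg$faces, avg$mean_color),
             file.path(config$output_dir, "average.ply"))
  utils::write.csv(data.frame(vertex = seq_len(nrow(avg$mean_vertices)),
                              variance_mm2 = avg$per_vertex_variance,
                              filler_fraction = avg$filler_fraction),
                   file.path(config$output_dir, "average_variance.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Superimpose one subject on an average model
#'
#' Accepts either a corresponded vertex matrix (already on the average's
#' topology) or a raw subject (mesh + curves), which is then corrected,
#' mapped, registered to the supplied reference and resampled. The
#' subject is Procrustes-aligned to the average (filler excluded) before
#' the signed distance map is computed at the configured individual
#' display range (-5..5 mm by default).
#'
#' @param subject n x 3 corresponded matrix, or list with `mesh` and
#'   `curves`.
#' @param average an [average_model()].
#' @param reference the run's reference subject (from
#'   `run_average()$subjects[[1]]`); required for raw subjects.
#' @param config a [run_config()].
#' @return a `distance_map` with attribute `aligned_subject`.
#' @export
run_superimpose <- function(subject, average, reference = NULL,
                            config = run_config()) {
  if (is.list(subject) && !is.null(subject$mesh)) {
    if (is.null(reference))
      stop("raw subjects need the run's reference subject")
    prep <- prepare_subject(
      if (is.character(subject$mesh)) read_mesh(subject$mesh) else subject$mesh,
      if (is.character(subject$curves)) read_curves(subject$curves)
      else subject$curves,
      config)
    fr <- register_pair(prep, reference, config)
    cohort <- resample_to_reference(list(prep), reference$sphmap,
                                    list(fr$warp))
    subject_m <- cohort$vertices[[1]]
    w <- as.numeric(!cohort$filler[, 1]) * (1 - average$filler_fraction)
  } else {
    subject_m <- as.matrix(subject)
    w <- 1 - average$filler_fraction
  }
  if (sum(w) <= 0) w <- rep(1, length(w))
  tr <- procrustes_pair(subject_m, average$mean_vertices, w)
  aligned <- apply_transform(tr, subject_m)
  dm <- signed_distance_map(aligned, average,
                            config$range_individual[1],
                            config$range_individual[2])
  attr(dm, "aligned_subject") <- aligned
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_map(dm, average,
                       file.path(config$output_dir, "superimposition.ply"))
  }
  dm
}

#' Compare two cohort averages
#'
#' [compare_averages()] at the configured average-to-average display
#' range (-3..3 mm by default), with optional artifact output.
#'
#' @param avgA,avgB [average_model()]s on one reference topology.
#' @param config a [run_config()].
#' @return a `distance_map`.
#' @export
run_compare <- function(avgA, avgB, config = run_config()) {
  dm <- compare_averages(avgA, avgB, config$range_compare[1],
                         config$range_compare[2])
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_distance_map(dm, avgA,
                       file.path(config$output_dir, "comparison.ply"))
  }
  dm
}
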