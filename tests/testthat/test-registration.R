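test_that("curve resampling is equally spaced by arclength", {
  # polyline along a great-circle arc with unequal vertex spacing; the
  # expected sample points are computed independently with approx()
  th <- c(0, 0.05, 0.3, 0.35, 0.6, 1.0)
  pts <- cbind(cos(th), sin(th), 0)
  mesh <- colored_mesh(pts, matrix(integer(0), 0, 3))
  sph <- list(sphere_positions = pts, faces = NULL, source = mesh)
  curves <- structure(list(arc = 1:6), class = "curve_set")
  cc <- curve_correspondence(curves, curves, sph, sph, n_samples = 5)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  targ <- seq(0, sum(seg), length.out = 5)
  expected <- vapply(1:3, function(d)
    approx(cum, pts[, d], xout = targ)$y, numeric(5))
  expected <- expected / sqrt(rowSums(expected^2))
  expect_equal(cc$moving, expected, tolerance = 1e-12)
  # identity subjects: zero spherical distance between pair points
  expect_equal(cc$moving, cc$fixed, tolerance = 0)
})

test_that("curve correspondence is invariant to polyline vertex density", {
  sub <- prepared_face(3)
  cv <- sub$curves$midline
  # densified copy: insert chord midpoints as extra (unreferenced)
  # vertices, leaving arclength geometry identical
  mesh2 <- sub$mesh
  sph2 <- sub$sphmap
  n0 <- nrow(mesh2$vertices)
  mids <- (mesh2$vertices[cv[-1], ] + mesh2$vertices[cv[-length(cv)], ]) / 2
  midsph <- (sph2$sphere_positions[cv[-1], ] +
               sph2$sphere_positions[cv[-length(cv)], ]) / 2
  mesh2$vertices <- rbind(mesh2$vertices, mids)
  mesh2$color <- rbind(mesh2$color, matrix(0.5, nrow(mids), 3))
  mesh2$filler <- c(mesh2$filler, rep(FALSE, nrow(mids)))
  sph2$sphere_positions <- rbind(sph2$sphere_positions, midsph)
  sph2$source <- mesh2
  dense <- integer(0)
  for (i in seq_along(cv[-1]))
    dense <- c(dense, cv[i], n0 + i)
  dense <- c(dense, cv[length(cv)])
  c1 <- structure(list(midline = cv), class = "curve_set")
  c2 <- structure(list(midline = dense), class = "curve_set")
  cc <- curve_correspondence(c2, c1, sph2, sub$sphmap, n_samples = 9)
  expect_equal(cc$moving, cc$fixed, tolerance = 1e-3)

  expect_error(curve_correspondence(
    structure(list(other = cv), class = "curve_set"), c1,
    sph2, sub$sphmap), "missing")
})

test_that("initial_warp recovers a global rotation and honors constraints", {
  sub <- prepared_face(3)
  p <- sub$sphmap$sphere_positions
  R <- morphoface:::rotmat_axis_angle(c(0.3, 1, 0.2), 0.25)
  set.seed(2)
  idx <- sample(nrow(p), 40)
  pairs <- list(moving = p[idx, ], fixed = p[idx, ] %*% t(R))
  w <- initial_warp(pairs, sub$sphmap, kernel_sigma = 0.3)
  expect_lt(max(ang_dist(w$warped_positions, p %*% t(R))), 1e-3)

  # zero displacement: identity warp
  w0 <- initial_warp(list(moving = p[idx, ], fixed = p[idx, ]),
                     sub$sphmap, 0.3)
  expect_equal(w0$warped_positions, p, tolerance = 1e-12)

  # a constraint point lands on its partner for small sigma
  idx3 <- idx[1:3]
  tgt <- morphoface:::normalize_rows(p[idx3, ] +
    0.05 * matrix(c(1, -1, 0.5, 0, 0.3, -0.2, 0.1, 0, 0.4), 3, 3))
  w3 <- initial_warp(list(moving = p[idx3, ], fixed = tgt),
                     sub$sphmap, kernel_sigma = 0.01)
  expect_lt(max(ang_dist(w3$warped_positions[idx3, , drop = FALSE], tgt)),
            1e-2)

  expect_error(initial_warp(list(moving = p[1:2, ], fixed = p[1:2, ]),
                            sub$sphmap), "at least 3")
})

test_that("mutual information matches its analytic anchors", {
  set.seed(42)
  a <- runif(10000)
  expect_equal(mutual_information(a, a, 32), log2(32), tolerance = 0.05)
  b <- runif(10000)
  expect_lt(mutual_information(a, b, 16), 0.05)
  expect_identical(mutual_information(a, b, 16), mutual_information(b, a, 16))
  expect_equal(as.numeric(mutual_information(a, 1 - a, 32)),
               as.numeric(mutual_information(a, a, 32)), tolerance = 1e-9)
  mi <- mutual_information(a, rep(1, length(a)), 16)
  expect_equal(as.numeric(mi), 0)
  expect_true(attr(mi, "degenerate"))
  expect_error(mutual_information(a[1:10], b[1:10], 32), "bins")
})

test_that("registration cost decomposes correctly at self-match", {
  sub <- prepared_face(3)
  par <- registration_params()
  cost <- registration_cost(identity_warp(sub$sphmap), sub, sub, par)
  br <- attr(cost, "breakdown")
  expect_equal(br$geometry_msd, 0, tolerance = 1e-20)
  # texture term at self-match: MI(x, x) = H(x) per channel
  entr <- vapply(1:3, function(k) {
    x <- sub$channels$channels[sub$channels$valid, k]
    cnt <- tabulate(morphoface:::bin_index(x, par$mi_bins), par$mi_bins)
    p <- cnt[cnt > 0] / sum(cnt)
    -sum(p * log2(p))
  }, 0)
  expect_equal(br$texture_mi, entr, tolerance = 1e-9)
  expect_equal(as.numeric(cost), -par$w_texture * sum(entr), tolerance = 1e-9)

  # w_texture = 0 reduces to the curvature MSD, recomputed independently
  par0 <- registration_params(w_texture = 0, w_geometry = 2)
  W <- known_warp_field(sub$sphmap$sphere_positions, c(0, 0, 1), 0.7, 0.1,
                        c(0, 1, 0))
  warp <- structure(list(domain = sub$sphmap, warped_positions = W),
                    class = "spherical_warp")
  cost0 <- registration_cost(warp, sub, sub, par0)
  loc <- sphere_lookup(sub$sphmap, W)
  samp <- morphoface:::interp_attr(sub$channels$channels, sub$sphmap$faces, loc)
  v <- sub$channels$valid &
    !morphoface:::interp_flag_any(!sub$channels$valid, sub$sphmap$faces, loc)
  msd <- mean(c(mean((sub$channels$channels[v, 4] - samp[v, 4])^2),
                mean((sub$channels$channels[v, 5] - samp[v, 5])^2)))
  expect_equal(as.numeric(cost0), 2 * msd, tolerance = 1e-12)
})

test_that("cost prefers alignment on a textured sphere", {
  sph <- icosphere(3, 1)
  dirs <- sph$vertices
  patch <- exp(-ang_dist(dirs, matrix(rep(c(1, 0, 0), each = nrow(dirs)),
                                      ncol = 3))^2 / (2 * 0.3^2))
  sph$color <- cbind(0.2 + 0.7 * patch, 0.4, 0.6 - 0.4 * patch)
  sm <- spherical_parameterize(sph)
  subj <- list(mesh = sph, sphmap = sm, channels = feature_channels(sph))
  par <- registration_params()
  c_id <- registration_cost(identity_warp(sm), subj, subj, par)
  R <- morphoface:::rotmat_axis_angle(c(0, 0, 1), 0.2)
  rot <- structure(list(domain = sm,
                        warped_positions = sm$sphere_positions %*% t(R)),
                   class = "spherical_warp")
  c_rot <- registration_cost(rot, subj, subj, par)
  expect_lt(as.numeric(c_id), as.numeric(c_rot))
})

test_that("filler geometry can never influence the cost", {
  sub <- prepared_face(3)
  fixed <- sub
  set.seed(8)
  fil <- sample(nrow(fixed$mesh$vertices), 60)
  fixed$mesh$filler[fil] <- TRUE
  fixed$channels <- feature_channels(fixed$mesh)
  par <- registration_params()
  W <- known_warp_field(sub$sphmap$sphere_positions, c(0, 1, 0), 0.8, 0.05,
                        c(1, 0, 0))
  warp <- structure(list(domain = sub$sphmap, warped_positions = W),
                    class = "spherical_warp")
  c1 <- registration_cost(warp, sub, fixed, par)
  fixed2 <- fixed
  fixed2$mesh$color[fil, ] <- matrix(runif(180), ncol = 3)
  fixed2$channels$channels[fil, 1:3] <- fixed2$mesh$color[fil, ]
  c2 <- registration_cost(warp, sub, fixed2, par)
  expect_identical(as.numeric(c1), as.numeric(c2))
  # moving-side filler likewise
  mov2 <- sub
  mov2$mesh$filler[1:40] <- TRUE
  mov2$channels <- feature_channels(mov2$mesh)
  c3 <- registration_cost(warp, mov2, fixed, par)
  mov3 <- mov2
  mov3$channels$channels[1:40, 1:3] <- 0.123
  c4 <- registration_cost(warp, mov3, fixed, par)
  expect_identical(as.numeric(c3), as.numeric(c4))
})

test_that("fluid registration is stationary at self-match and recovers a known warp", {
  sub <- prepared_face(3)
  par <- registration_params(max_iters = 10)
  fr <- fluid_register(sub, sub, identity_warp(sub$sphmap), par)
  expect_lte(length(fr$trace), 2)
  expect_equal(fr$warp$warped_positions, sub$sphmap$sphere_positions,
               tolerance = 1e-12)

  # single-bump 0.15 rad warp, identity init
  p <- sub$sphmap$sphere_positions
  Wtrue <- known_warp_field(p, c(0, 0.2, 0.98), 1.0, 0.15, c(1, 0, 0))
  fixed <- sub
  fixed$sphmap <- structure(list(sphere_positions = Wtrue,
                                 faces = sub$sphmap$faces,
                                 source = sub$mesh),
                            class = "spherical_map")
  fr <- fluid_register(sub, fixed, identity_warp(sub$sphmap),
                       registration_params(kernel_sigma = 0.3,
                                           max_iters = 80, tol = 1e-6))
  err <- ang_dist(fr$warp$warped_positions, Wtrue)
  expect_lt(mean(err), 0.03)
  expect_true(all(diff(fr$trace) < 0))        # strictly decreasing

  expect_error(fluid_register(sub, sub, structure(
    list(domain = sub$sphmap,
         warped_positions = p[c(2, 1, seq(3, nrow(p))), ]),
    class = "spherical_warp"), par), "flipped")
})

test_that("warps invert consistently and resampling preserves identity", {
  sub <- prepared_face(3)
  p <- sub$sphmap$sphere_positions
  W <- known_warp_field(p, c(0.5, 0, 0.8), 0.6, 0.12, c(0, 1, 1))
  warp <- structure(list(domain = sub$sphmap, warped_positions = W),
                    class = "spherical_warp")
  expect_equal(warp_evaluate(warp, p), W, tolerance = 1e-9)
  back <- warp_invert(warp, W)
  expect_lt(max(ang_dist(back, p)), 1e-6)

  # identity resampling reproduces the subject exactly
  coh <- resample_to_reference(list(sub), sub$sphmap,
                               list(identity_warp(sub$sphmap)))
  expect_equal(coh$vertices[[1]], sub$mesh$vertices, tolerance = 1e-9)
  # duplicated subject: identical rows
  coh2 <- resample_to_reference(list(sub, sub), sub$sphmap,
                                list(identity_warp(sub$sphmap),
                                     identity_warp(sub$sphmap)))
  expect_identical(coh2$vertices[[1]], coh2$vertices[[2]])

  # a subject pair with known ground-truth correspondence (the generator
  # re-poses one shape, so reference vertex i corresponds to subject
  # vertex i by construction): corresponded positions match the truth
  spec <- face_population_spec(n_subjects = 2, seed = 56,
                               height_jitter_sd = 0, position_jitter_sd = 0,
                               global_scale_jitter_sd = 0,
                               pose_rot_sd = 0.1, pose_trans_sd = 5)
  coh <- make_cohort(spec)
  cfg <- run_config(seed = 1,
                    registration = registration_params(kernel_sigma = 0.2,
                                                       max_iters = 40))
  s1 <- morphoface:::prepare_subject(coh$subjects[[1]]$mesh,
                                     coh$subjects[[1]]$curves, cfg)
  s2 <- morphoface:::prepare_subject(coh$subjects[[2]]$mesh,
                                     coh$subjects[[2]]$curves, cfg)
  fr2 <- morphoface:::register_pair(s2, s1, cfg)
  coh3 <- resample_to_reference(list(s2), s1$sphmap, list(fr2$warp))
  err_mm <- morphoface:::row_norms(coh3$vertices[[1]] - s2$mesh$vertices)
  expect_lt(mean(err_mm), 0.5)
})
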