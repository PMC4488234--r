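test_that("remove_nonmanifold drops fins, islands and duplicates", {
  # three triangles on one shared edge: smallest-area one is dropped
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, -2, 0), c(0, 0, 0.1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  m <- remove_nonmanifold(colored_mesh(v, f))
  d <- diagnose(m)
  expect_equal(d$n_faces, 2)
  expect_equal(nrow(d$nonmanifold_edges), 0)
  # the small face (apex z = 0.1) is gone
  expect_false(any(abs(m$vertices[, 3] - 0.1) < 1e-12))

  # two disjoint spheres: only the larger survives
  a <- icosphere(2, 2)
  b <- icosphere(2, 1)
  b$vertices <- b$vertices + 10
  both <- colored_mesh(rbind(a$vertices, b$vertices),
                       rbind(a$faces, b$faces + nrow(a$vertices)))
  m <- remove_nonmanifold(both)
  expect_equal(nrow(m$vertices), nrow(a$vertices))
  expect_true(all(morphoface:::row_norms(m$vertices) < 3))

  # already-manifold input returned unchanged
  m2 <- remove_nonmanifold(a)
  expect_identical(m2$vertices, a$vertices)
  expect_identical(m2$faces, a$faces)
})

test_that("sew_boundary closes a loop with a consistent filler fan", {
  tri <- single_triangle()
  sw <- sew_boundary(tri, diagnose(tri)$boundary_loops[[1]])
  d <- diagnose(sw$mesh)
  expect_equal(d$n_boundary_loops, 0)
  expect_equal(nrow(sw$mesh$vertices), 4)
  expect_equal(nrow(sw$mesh$faces), 4)
  expect_identical(sw$mesh$filler, c(FALSE, FALSE, FALSE, TRUE))
  expect_true(d$manifold)

  spec <- face_population_spec(seed = 2, n_holes = 1, hole_width = 0.18,
                               n_fins = 0)
  hole <- inject_defects(make_face(spec, 1)$mesh, spec, 1)
  nloops <- diagnose(hole)$n_boundary_loops
  sw <- sew_boundary(hole, diagnose(hole)$boundary_loops[[1]])
  expect_equal(diagnose(sw$mesh)$n_boundary_loops, nloops - 1)

  expect_error(sew_boundary(tri, c(1, 2)), "shorter than 3")
})

test_that("relax_patch is harmonic: planar boundary pulls the patch flat", {
  # planar hexagonal annulus with a hexagon hole; sew it, push the new
  # centroid off-plane, relax: harmonic interpolation of a planar
  # boundary is planar
  th <- 2 * pi * (0:5) / 6
  inner <- cbind(cos(th), sin(th), 0)
  outer_v <- cbind(2 * cos(th), 2 * sin(th), 0)
  v <- rbind(inner, outer_v)
  f <- NULL
  for (i in 0:5) {
    j <- (i + 1) %% 6
    f <- rbind(f, c(i + 7, j + 7, i + 1), c(j + 7, j + 1, i + 1))
  }
  ann <- colored_mesh(v, f)
  loops <- diagnose(ann)$boundary_loops
  inner_loop <- loops[[which(vapply(loops, function(l)
    all(l <= 6), TRUE))]]
  sw <- sew_boundary(ann, inner_loop)
  sw$mesh$vertices[sw$patch$patch_vertices, 3] <- 0.7   # perturb off-plane
  rl <- relax_patch(sw$mesh, sw$patch)
  expect_lt(abs(rl$mesh$vertices[sw$patch$patch_vertices, 3]), 1e-8)

  # non-planar boundary: relaxed area <= sewn area (both measured on the
  # meshes with mesh-core area computations)
  spec <- face_population_spec(seed = 4, n_holes = 1, hole_width = 0.2,
                               n_fins = 0)
  hole <- inject_defects(make_face(spec, 1)$mesh, spec, 1)
  sw <- sew_boundary(hole, diagnose(hole)$boundary_loops[[1]])
  sewn_area <- sum(morphoface:::face_area_vectors(
    sw$mesh$vertices, sw$mesh$faces[sw$patch$patch_faces, , drop = FALSE])$area)
  rl <- relax_patch(sw$mesh, sw$patch)
  relaxed_area <- sum(morphoface:::face_area_vectors(
    rl$mesh$vertices, rl$mesh$faces[rl$patch$patch_faces, , drop = FALSE])$area)
  expect_lte(relaxed_area, sewn_area)
  expect_equal(sewn_area, sw$patch$area_history[1])
})

test_that("close_boundaries yields a closed genus-0 surface with filler marked", {
  spec <- face_population_spec(seed = 6, n_holes = 3, n_fins = 0)
  mesh <- inject_defects(make_face(spec, 1)$mesh, spec, 1)
  n0 <- nrow(mesh$vertices)
  cb <- close_boundaries(mesh, max_rounds = 3)
  d <- diagnose(cb$mesh)
  expect_equal(d$euler_characteristic, 2)
  expect_equal(d$n_boundary_loops, 0)
  expect_equal(d$genus, 0L)
  expect_equal(length(cb$patches), 3)
  for (p in cb$patches) {
    expect_true(all(diff(p$area_history[-1]) <= 1e-9))   # non-increasing
    expect_true(all(cb$mesh$filler[p$patch_vertices]))
  }
  # filler accounting: exactly the synthesized vertices are flagged
  expect_false(any(cb$mesh$filler[seq_len(n0)]))
  expect_equal(sum(cb$mesh$filler), nrow(cb$mesh$vertices) - n0)

  # closed input: unchanged, no patches
  sph <- icosphere(2, 1)
  cb2 <- close_boundaries(sph)
  expect_identical(cb2$mesh$faces, sph$faces)
  expect_length(cb2$patches, 0)

  # idempotence of the full correction
  again <- close_boundaries(remove_nonmanifold(cb$mesh), max_rounds = 3)
  expect_identical(again$mesh$vertices, cb$mesh$vertices)
  expect_length(again$patches, 0)
})

test_that("full correction pipeline repairs random defect fixtures", {
  for (s in 1:8) {
    spec <- face_population_spec(seed = 100 + s, n_holes = 1 + s %% 3,
                                 n_fins = s %% 3, add_island = s %% 2 == 0)
    mesh <- inject_defects(make_face(spec, 1)$mesh, spec, 1)
    fixed <- close_boundaries(remove_nonmanifold(mesh), max_rounds = 2)
    d <- diagnose(fixed$mesh)
    expect_equal(d$euler_characteristic, 2)
    expect_equal(d$n_boundary_loops, 0)
    expect_equal(nrow(d$nonmanifold_edges), 0)
    expect_length(d$nonmanifold_vertices, 0)
  }
})

test_that("Taubin smoothing reduces noise without shrinking or rewiring", {
  set.seed(9)
  sph <- icosphere(3, 10)
  dirs <- morphoface:::normalize_rows(sph$vertices)
  noisy <- sph
  noisy$vertices <- dirs * (10 + rnorm(nrow(dirs), 0, 0.1))
  sm <- smooth_mesh(noisy, iterations = 10, lam = 0.5)
  expect_identical(sm$faces, noisy$faces)
  expect_identical(sm$filler, noisy$filler)
  sd_pre <- sd(morphoface:::row_norms(noisy$vertices))
  sd_post <- sd(morphoface:::row_norms(sm$vertices))
  expect_lt(sd_post, sd_pre)
  # shrink compensation keeps the mean radius close
  expect_lt(abs(mean(morphoface:::row_norms(sm$vertices)) - 10), 0.2)

  expect_identical(smooth_mesh(noisy, 0), noisy)
})
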