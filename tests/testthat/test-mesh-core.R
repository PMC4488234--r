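test_that("mesh I/O roundtrips vertices, faces and colors in all formats", {
  set.seed(10)
  m <- icosphere(2, 2)
  m$color <- matrix(runif(nrow(m$vertices) * 3), ncol = 3)

  ply_bin <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, ply_bin)
  r <- read_mesh(ply_bin)
  expect_identical(r$vertices, m$vertices)     # double-precision PLY
  expect_identical(r$faces, m$faces)
  expect_lt(max(abs(r$color - m$color)), 1 / 255)
  expect_false(any(r$filler))

  ply_asc <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, ply_asc, binary = FALSE)
  r <- read_mesh(ply_asc)
  expect_equal(r$vertices, m$vertices, tolerance = 0)
  expect_identical(r$faces, m$faces)

  obj <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, obj)
  r <- read_mesh(obj)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-15)
  expect_identical(r$faces, m$faces)
  expect_lt(max(abs(r$color - m$color)), 1e-5)
})

test_that("colorless OBJ defaults to mid-gray and bad inputs error", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  r <- read_mesh(p)
  expect_true(all(r$color == 0.5))

  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 999"), p)
  expect_error(read_mesh(p), "missing vertex")

  expect_error(read_mesh(file.path(tempdir(), "does-not-exist.ply")),
               "cannot read")
  expect_error(suppressWarnings(
    write_mesh(tetrahedron(), "/proc/definitely/not/writable.ply")),
    "cannot write")
  expect_error(colored_mesh(diag(3), rbind(c(1, 2, 9))), "face 1")
})

test_that("diagnose reports counts, boundaries and genus correctly", {
  d <- diagnose(tetrahedron())
  expect_equal(d$n_vertices, 4)
  expect_equal(d$n_edges, 6)
  expect_equal(d$n_faces, 4)
  expect_equal(d$euler_characteristic, 2)
  expect_equal(d$n_boundary_loops, 0)
  expect_equal(d$genus, 0L)
  expect_true(d$closed && d$manifold)

  d <- diagnose(single_triangle())
  expect_equal(d$euler_characteristic, 1)
  expect_equal(d$n_boundary_loops, 1)
  expect_equal(sort(d$boundary_loops[[1]]), 1:3)
  expect_true(is.na(d$genus))

  # torus grid: chi = V - E + F = 0, genus 1 (derived from the construction)
  tor <- torus_mesh(12, 8)
  d <- diagnose(tor)
  expect_equal(d$n_vertices, 96)
  expect_equal(d$n_edges, 288)
  expect_equal(d$n_faces, 192)
  expect_equal(d$euler_characteristic, 0)
  expect_equal(d$genus, 1L)

  # three triangles sharing one edge: that edge is non-manifold
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  d <- diagnose(colored_mesh(v, f))
  expect_equal(nrow(d$nonmanifold_edges), 1)
  expect_equal(sort(d$nonmanifold_edges[1, ]), c(1, 2))
  expect_false(d$manifold)

  # purity: repeated calls identical
  expect_identical(diagnose(tor), diagnose(tor))
})

test_that("curvatures match the analytic sphere and satisfy Gauss-Bonnet", {
  # the 12 seed vertices of the icosphere keep valence 5; pointwise
  # accuracy there is bounded but does not converge for this scheme, so
  # they are asserted with a looser band than the regular vertices
  s1 <- cached("sph4", icosphere(4, 1))
  cv <- curvatures(s1)
  reg <- -(1:12)
  expect_lt(max(abs(cv$mean_curvature[reg] - 1)), 0.05)
  expect_lt(max(abs(cv$gaussian_curvature[reg] - 1)), 0.05)
  expect_lt(max(abs(cv$mean_curvature - 1)), 0.16)
  expect_lt(max(abs(cv$gaussian_curvature - 1)), 0.16)

  s2 <- icosphere(3, 2)
  cv2 <- curvatures(s2)
  expect_lt(max(abs(cv2$mean_curvature[reg] - 0.5)), 0.05 * 0.5)
  expect_lt(max(abs(cv2$gaussian_curvature[reg] - 0.25)), 0.05 * 0.25)

  # discrete Gauss-Bonnet is exact for the angle-deficit scheme
  for (m in list(s2, tetrahedron(), torus_mesh())) {
    cv <- curvatures(m)
    chi <- diagnose(m)$euler_characteristic
    gb <- sum(cv$gaussian_curvature * cv$vertex_areas)
    expect_equal(gb, 2 * pi * chi, tolerance = 1e-6)
  }

  expect_error(curvatures(colored_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))), "non-manifold")
})

test_that("mean-curvature error on the sphere shrinks with refinement", {
  errs <- vapply(2:4, function(lv) {
    cv <- curvatures(if (lv == 4) cached("sph4", icosphere(4, 1))
                     else icosphere(lv, 1))
    c(max(abs(cv$mean_curvature[-(1:12)] - 1)),
      mean(abs(cv$mean_curvature - 1)))
  }, numeric(2))
  expect_true(all(diff(errs[1, ]) < 0))   # regular-vertex max error
  expect_true(all(diff(errs[2, ]) < 0))   # mean error over all vertices
})

test_that("vertex normals and barycentric areas are consistent", {
  cube <- cube_mesh()
  na <- vertex_normals_areas(cube)
  expect_equal(sum(na$areas), 6, tolerance = 1e-12)
  expect_equal(sum(na$areas), surface_area(cube), tolerance = 0)

  sph <- icosphere(3, 1)
  na <- vertex_normals_areas(sph)
  expect_true(all(rowSums(na$normals * sph$vertices) > 0))  # outward
  expect_equal(unname(morphoface:::row_norms(na$normals)),
               rep(1, nrow(sph$vertices)), tolerance = 1e-12)

  # a degenerate face is skipped with a warning, result stays finite
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.5, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4))   # second face has zero area
  expect_warning(na <- vertex_normals_areas(colored_mesh(v, f)),
                 "zero-area")
  expect_true(all(is.finite(na$normals[1:3, ])) && all(is.finite(na$areas)))
})
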