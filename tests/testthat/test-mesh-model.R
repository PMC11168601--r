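test_that("validate_mesh accepts valid meshes and prunes unreferenced vertices", {
  tri <- single_triangle()
  out <- validate_mesh(tri)
  expect_equal(out$vertices, tri$vertices)
  expect_equal(attr(out, "n_vertices_removed"), 0L)

  padded <- triangle_mesh(rbind(tri$vertices, c(9, 9, 9)), tri$faces)
  pruned <- validate_mesh(padded, prune = TRUE)
  expect_equal(n_vertices(pruned), 3)
  expect_equal(attr(pruned, "n_vertices_removed"), 1L)
  expect_equal(pruned$faces, tri$faces)
})

test_that("validate_mesh reports the offending face or vertex", {
  bad_face <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                            rbind(c(1, 2, 6)))
  expect_error(validate_mesh(bad_face), "face 1")
  dup <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 2)))
  expect_error(validate_mesh(dup), "same vertex twice")
  naughty <- triangle_mesh(rbind(c(0, 0, 0), c(NA, 0, 0), c(0, 1, 0)),
                           rbind(c(1, 2, 3)))
  expect_error(validate_mesh(naughty), "vertex 2")
})

test_that("merge_meshes concatenates with offset indices and no welding", {
  a <- cube_mesh()                       # 8 vertices, 12 faces
  b <- single_triangle()                 # 3 vertices, 1 face
  m <- merge_meshes(list(a, b))
  expect_equal(n_vertices(m), 11)
  expect_equal(n_faces(m), 13)
  expect_equal(m$faces[13, ], b$faces[1, ] + 8L)

  expect_equal(merge_meshes(list(a))$vertices, a$vertices)
  expect_error(merge_meshes(list()), "non-empty")
})

test_that("merging phantom bone components preserves per-part vertex counts", {
  parts <- phantom_hard_components(small_phantom_spec())
  merged <- merge_meshes(parts, name = "hard_tissue")
  expect_equal(n_vertices(merged), sum(vapply(parts, n_vertices, integer(1))))
  expect_equal(n_faces(merged), sum(vapply(parts, n_faces, integer(1))))
  # merge then validate never changes the face count
  expect_equal(n_faces(validate_mesh(merged, prune = TRUE)), n_faces(merged))
})

test_that("vertex normals: cube corners, sphere radial oracle, isolated vertex", {
  nrm <- vertex_normals(cube_mesh())
  # every corner normal points into its own octant
  expect_true(all(sign(nrm) == sign(cube_mesh()$vertices - 0.5)))
  # corners whose incident triangles are symmetric across all three faces
  # realise the exact (+-1,+-1,+-1)/sqrt(3) direction
  expect_equal(nrm[1, ], -c(1, 1, 1) / sqrt(3), tolerance = 1e-12)
  expect_equal(nrm[8, ], c(1, 1, 1) / sqrt(3), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, 8), tolerance = 1e-12)

  sph <- sphere_mesh(radius = 1, na = 128, nphi = 64)
  nrm_s <- vertex_normals(sph)
  radial <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  expect_lt(max(abs(nrm_s - radial)), 0.01)

  iso <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(5, 5, 5)),
                       rbind(c(1, 2, 3)))
  nrm_i <- vertex_normals(iso)
  expect_equal(nrm_i[4, ], c(0, 0, 0))
  expect_equal(attr(nrm_i, "unreferenced"), 4L)
})

test_that("rigid transforms apply exactly and preserve rigidity", {
  m <- sphere_mesh(radius = 20, na = 24, nphi = 12)
  expect_equal(apply_transform(m, rigid_transform())$vertices, m$vertices)

  t_shift <- rigid_transform(translation = c(5, -3, 2))
  shifted <- apply_transform(m, t_shift)
  expect_equal(colMeans(shifted$vertices) - colMeans(m$vertices),
               c(x = 5, y = -3, z = 2))

  ang <- 30 * pi / 180
  rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  t_rot <- rigid_transform(rz, c(1, 2, 3))
  back <- apply_transform(apply_transform(m, t_rot), invert_transform(t_rot))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)

  # rigidity: pairwise distances and face areas preserved
  moved <- apply_transform(m, t_rot)
  i <- c(1, 10, 50, 100); j <- c(5, 200, 150, 250)
  d0 <- sqrt(rowSums((m$vertices[i, ] - m$vertices[j, ])^2))
  d1 <- sqrt(rowSums((moved$vertices[i, ] - moved$vertices[j, ])^2))
  expect_lt(max(abs(d0 - d1) / d0), 1e-9)
  expect_lt(max(abs(face_areas(moved) - face_areas(m)) /
                pmax(face_areas(m), 1e-12)), 1e-9)
})

test_that("rigid_transform rejects reflections and non-orthonormal matrices", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(diag(c(2, 1, 1))), "orthonormal")
})

test_that("extreme_point matches an exhaustive scan and breaks ties by index", {
  cube <- cube_mesh()
  p <- extreme_point(cube, c(0, 0, -1))
  expect_equal(attr(p, "index"), 1L)  # four z=0 corners tie; lowest index wins
  expect_equal(unname(p["z"]), 0)

  meshes <- list(cube, sphere_mesh(5, 16, 8),
                 generate_phantom_limb(small_phantom_spec())$hard)
  dirs <- rbind(c(0, 0, -1), c(1, 1, 1) / sqrt(3), c(-1, 0.2, 0.5))
  for (m in meshes) {
    for (k in seq_len(nrow(dirs))) {
      got <- extreme_point(m, dirs[k, ])
      proj <- as.vector(m$vertices %*% dirs[k, ])
      expect_equal(attr(got, "index"), which.max(proj))
    }
  }

  one <- triangle_mesh(rbind(c(3, 4, 5)), NULL)
  expect_equal(as.numeric(extreme_point(one, c(1, 0, 0))), c(3, 4, 5))
  expect_error(extreme_point(triangle_mesh(matrix(numeric(0), ncol = 3), NULL),
                             c(1, 0, 0)), "no vertices")
})

test_that("anatomical_trim_plane sits offset_mm proximal of the distal pole", {
  ph <- generate_phantom_limb(small_phantom_spec())
  # distal pole of the bone is its lowest vertex
  pl <- anatomical_trim_plane(ph$hard, c(0, 0, -1), offset_mm = 50)
  zmin <- min(ph$hard$vertices[, 3])
  expect_equal(pl$point[3], zmin + 50)
  expect_equal(pl$normal, c(0, 0, -1))
  # kept side is distal
  expect_gt(plane_signed_distance(rbind(c(0, 0, zmin)), pl), 0)

  expect_error(anatomical_trim_plane(ph$hard, c(0, 0, -1), offset_mm = 0),
               "positive")
  expect_error(anatomical_trim_plane(ph$hard, c(0, 0, 0), 50), "degenerate")
})

test_that("trim_by_plane halves a cylinder wall to within 0.5% of analytic area", {
  cyl <- cylinder_shell(radius = 10, height = 100, na = 64, nz = 40)
  pl <- plane(point = c(0, 0, 50), normal = c(0, 0, -1))  # keep z <= 50
  cut <- trim_by_plane(cyl, pl)
  a_full <- sum(face_areas(cyl))
  a_half <- sum(face_areas(cut))
  expect_lt(abs(a_half / a_full - 0.5), 0.005)
  expect_lt(max(plane_signed_distance(cut$vertices, pl) * -1), 1e-9)
})

test_that("trim_by_plane splits crossing triangles and leaves clean cases alone", {
  tri <- single_triangle()  # vertices at x = 0, 0, 1
  pl <- plane(point = c(0.5, 0, 0), normal = c(-1, 0, 0))  # keep x <= 0.5
  cut <- trim_by_plane(tri, pl)
  expect_equal(n_faces(cut), 2)  # retained quad as two triangles
  expect_true(all(plane_signed_distance(cut$vertices, pl) >= -1e-9))
  expect_true(any(abs(cut$vertices[, 1] - 0.5) < 1e-9))  # cut lies on plane

  below <- plane(point = c(0, 0, -5), normal = c(0, 0, 1))
  expect_equal(trim_by_plane(tri, below)$vertices, tri$vertices)

  away <- plane(point = c(0, 0, 5), normal = c(0, 0, 1))
  expect_warning(empty <- trim_by_plane(tri, away), "entirely")
  expect_equal(n_faces(empty), 0)
})

test_that("trim_by_plane is idempotent and respects the half-space bound", {
  ph <- generate_phantom_limb(small_phantom_spec())
  pl <- plane(point = c(0, 0, 60), normal = c(0, 0, -1))
  once <- trim_by_plane(ph$skin, pl)
  twice <- trim_by_plane(once, pl)
  expect_equal(n_vertices(twice), n_vertices(once))
  expect_lt(max(abs(twice$vertices - once$vertices)), 1e-9)
  expect_true(all(plane_signed_distance(once$vertices, pl) >= -1e-9))
})

test_that("landmark_pairs enforces count and non-collinearity", {
  p <- matrix(rnorm(9), 3, 3)
  expect_s3_class(landmark_pairs(p, p), "landmark_pairs")
  expect_error(landmark_pairs(p[1:2, ], p[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_pairs(line, line), "collinear")
})
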