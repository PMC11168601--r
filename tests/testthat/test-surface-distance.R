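test_that("nearest distances: identity, 3-4-5 case, and directedness", {
  cube <- cube_mesh()
  f <- nearest_vertex_distances(cube, cube)
  expect_true(all(f$distance == 0))
  expect_equal(f$nearest_index, 1:8)

  src <- triangle_mesh(rbind(c(0, 0, 0)), NULL)
  tgt <- triangle_mesh(rbind(c(3, 4, 0), c(6, 8, 0)), NULL)
  f2 <- nearest_vertex_distances(src, tgt)
  expect_equal(f2$distance, 5)
  expect_equal(f2$nearest_index, 1L)

  # directed measure: d(A->B) != d(B->A) in general
  a <- triangle_mesh(rbind(c(0, 0, 0)), NULL)
  b <- triangle_mesh(rbind(c(1, 0, 0), c(100, 0, 0)), NULL)
  expect_equal(nearest_vertex_distances(a, b)$distance, 1)
  expect_equal(nearest_vertex_distances(b, a)$distance, c(1, 100))

  empty <- triangle_mesh(matrix(numeric(0), ncol = 3), NULL)
  expect_error(nearest_vertex_distances(empty, cube), "at least one vertex")
})

test_that("accelerated distances are bit-identical to the brute-force oracle", {
  fixtures <- list(
    list(cube_mesh(), sphere_mesh(2, 16, 8)),
    list(random_cloud(150, 1), random_cloud(180, 2)),
    list(random_cloud(200, 3), random_cloud(50, 4)),
    list(generate_phantom_limb(small_phantom_spec())$hard,
         generate_phantom_limb(small_phantom_spec())$skin)
  )
  for (fx in fixtures) {
    fast <- nearest_vertex_distances(fx[[1]], fx[[2]])
    slow <- nearest_vertex_distances_bruteforce(fx[[1]], fx[[2]])
    expect_identical(fast$distance, slow$distance)
    expect_identical(fast$nearest_index, slow$nearest_index)
  }
})

test_that("ties in the nearest target go to the lowest index in both paths", {
  # duplicate coincident targets (unwelded merge): indices must prefer first
  tgt <- triangle_mesh(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)), NULL)
  src <- triangle_mesh(rbind(c(0, 0, 0), c(2, 0, 0)), NULL)
  fast <- nearest_vertex_distances(src, tgt)
  slow <- nearest_vertex_distances_bruteforce(src, tgt)
  expect_equal(fast$nearest_index, c(1L, 1L))
  expect_identical(fast$nearest_index, slow$nearest_index)
})

test_that("phantom annulus distances match the analytic clearance", {
  ph <- generate_phantom_limb(phantom_spec(angular_resolution = 48,
                                           axial_resolution = 32))
  f <- nearest_vertex_distances(ph$hard, ph$skin)
  edge <- ph$truth$skin_edge_length
  # mid-shaft bone vertices: clearance has the closed form r_skin(z) - r_bone
  zr <- ph$truth$shaft_range
  mid <- which(ph$hard$vertices[, 3] > zr[1] + 5 &
               ph$hard$vertices[, 3] < zr[2] - 5)
  expected <- ph$truth$clearance(ph$hard$vertices[mid, 3])
  expect_lt(max(abs(f$distance[mid] - expected)), edge)
})

test_that("refining the target never increases a nearest distance", {
  src <- generate_phantom_limb(small_phantom_spec())$hard
  tgt <- sphere_mesh(radius = 80, na = 24, nphi = 12)
  d0 <- nearest_vertex_distances(src, tgt)$distance
  d1 <- nearest_vertex_distances(src, subdivide_mesh(tgt))$distance
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("distance field is invariant under a common rigid motion", {
  ph <- generate_phantom_limb(small_phantom_spec())
  t <- apply_rigid_perturbation(ph$hard, 40, 30, seed = 11)$transform
  f0 <- nearest_vertex_distances(ph$hard, ph$skin)
  f1 <- nearest_vertex_distances(apply_transform(ph$hard, t),
                                 apply_transform(ph$skin, t))
  expect_lt(max(abs(f0$distance - f1$distance)), 1e-9)
})

test_that("histogram honours the uniform example and the right-closed edge rule", {
  f <- structure(tibble::tibble(vertex = 1:4, distance = c(1, 2, 3, 4),
                                nearest_index = 1L),
                 class = c("distance_field", class(tibble::tibble())))
  h <- distance_histogram(f, n_bins = 4, range = c(0, 4))
  expect_equal(h$percent, c(25, 25, 25, 25))
  expect_equal(attr(h, "bin_edges"), 0:4)

  # range minimum joins the first bin; maximum the last
  f0 <- structure(tibble::tibble(vertex = 1:2, distance = c(0, 4),
                                 nearest_index = 1L),
                  class = c("distance_field", class(tibble::tibble())))
  h0 <- distance_histogram(f0, n_bins = 4, range = c(0, 4))
  expect_equal(h0$percent, c(50, 0, 0, 50))
})

test_that("histogram percents always sum to 100 and bins are uniform", {
  ph <- generate_phantom_limb(small_phantom_spec())
  f <- nearest_vertex_distances(ph$hard, ph$skin)
  for (rng in list(NULL, c(0, 100), c(20, 30))) {
    h <- distance_histogram(f, range = rng)
    expect_equal(sum(h$percent), 100, tolerance = 1e-9)
    w <- diff(attr(h, "bin_edges"))
    expect_lt(max(w) - min(w), 1e-9)
  }
})

test_that("shared-range overlay matches a direct recount per bin", {
  ph <- generate_phantom_limb(small_phantom_spec())
  on <- apply_socket_deformation(ph$skin, deformation_spec("hands_on"))
  off <- apply_socket_deformation(ph$skin, deformation_spec("hands_off"))
  fon <- nearest_vertex_distances(ph$hard, on$deformed)
  foff <- nearest_vertex_distances(ph$hard, off$deformed)
  rng <- c(0, max(fon$distance, foff$distance))
  hon <- distance_histogram(fon, range = rng)
  hoff <- distance_histogram(foff, range = rng)
  edges <- attr(hon, "bin_edges")
  recount <- function(d, lo, hi, first) sum(if (first) d >= lo & d <= hi else d > lo & d <= hi)
  for (b in c(1, 25, 50, 100)) {
    expect_equal(hon$count[b],
                 recount(fon$distance, edges[b], edges[b + 1], b == 1))
    expect_equal(hoff$count[b],
                 recount(foff$distance, edges[b], edges[b + 1], b == 1))
  }
})

test_that("degenerate all-equal distances demand an explicit range", {
  f <- structure(tibble::tibble(vertex = 1:3, distance = c(2, 2, 2),
                                nearest_index = 1L),
                 class = c("distance_field", class(tibble::tibble())))
  expect_error(distance_histogram(f), "explicit range")
  h <- distance_histogram(f, n_bins = 4, range = c(0, 4))
  expect_equal(h$percent, c(0, 100, 0, 0))
})

test_that("distance_summary reports modal bin, extrema and shallow percent", {
  f <- structure(tibble::tibble(vertex = 1:4, distance = c(1, 2, 3, 4),
                                nearest_index = 1L),
                 class = c("distance_field", class(tibble::tibble())))
  h <- distance_histogram(f, n_bins = 4, range = c(0, 4))
  s <- distance_summary(f, h)
  expect_equal(s$modal_percent, 25)  # tie -> lowest bin
  expect_equal(s$modal_bin_lower_mm, 0)
  expect_equal(s$max_mm, 4)
  expect_equal(s$shallow_threshold_mm, 3)  # first three of four bins
  expect_equal(s$shallow_percent, 50)      # strictly below 3: {1, 2}

  ph <- generate_phantom_limb(small_phantom_spec())
  fp <- nearest_vertex_distances(ph$hard, ph$skin)
  hp <- distance_histogram(fp)
  sp <- distance_summary(fp, hp, shallow_threshold_mm = 27)
  expect_equal(sp$shallow_percent, 100 * mean(fp$distance < 27))
})

test_that("point-to-triangle distances are exact in all closest-point regimes", {
  tri <- single_triangle()
  cases <- list(
    list(p = c(0.2, 0.2, 3), d = 3),                 # face interior
    list(p = c(-1, -1, 0), d = sqrt(2)),             # vertex region (origin)
    list(p = c(0.5, -2, 0), d = 2),                  # edge ab region
    list(p = c(1, 1, 0), d = sqrt(2) / 2)            # hypotenuse edge region
  )
  for (cs in cases) {
    src <- triangle_mesh(rbind(cs$p), NULL)
    f <- nearest_triangle_distances(src, tri)
    expect_equal(f$distance, cs$d, tolerance = 1e-12)
  }

  ph <- generate_phantom_limb(small_phantom_spec())
  fv <- nearest_vertex_distances(ph$hard, ph$skin)
  ft <- nearest_triangle_distances(ph$hard, ph$skin)
  expect_true(all(ft$distance <= fv$distance + 1e-9))
})
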