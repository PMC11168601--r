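make_rot <- function(axis, deg) {
  limbmorph:::rotation_about_axis(axis, deg * pi / 180)
}

test_that("landmark fit recovers exact rigid motions to 1e-9", {
  set.seed(42)
  x <- matrix(rnorm(30, sd = 40), 10, 3)

  ident <- landmark_rigid_fit(landmark_pairs(x, x))
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
  expect_lt(attr(ident, "rms"), 1e-9)

  rz <- make_rot(c(0, 0, 1), 30)
  truth <- rigid_transform(rz, c(5, -3, 2))
  fit <- landmark_rigid_fit(landmark_pairs(x, transform_points(x, truth)))
  expect_lt(max(abs(fit$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(fit$translation - truth$translation)), 1e-9)
  expect_lt(attr(fit, "rms"), 1e-9)
})

test_that("landmark fit is equivariant under pre-rotation of all inputs", {
  set.seed(1)
  x <- matrix(rnorm(30, sd = 30), 10, 3)
  truth <- rigid_transform(make_rot(c(1, 2, 3), 25), c(2, 0, -4))
  y <- transform_points(x, truth)
  q <- rigid_transform(make_rot(c(0, 1, 0), 40), c(-1, 7, 2))
  # rotate the source frame: solution must compose accordingly
  fit_q <- landmark_rigid_fit(landmark_pairs(transform_points(x, q), y))
  composed <- compose_transforms(fit_q, q)
  expect_lt(max(abs(composed$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(composed$translation - truth$translation)), 1e-9)
})

test_that("landmark fit never returns a reflection and flags collinear input", {
  # targets mirrored: best proper rotation must still have det +1
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  y <- x %*% diag(c(-1, 1, 1))
  fit <- landmark_rigid_fit(landmark_pairs(x, y))
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  line <- cbind(seq(0, 9), 0, 0) + matrix(rnorm(30, sd = 1e-12), 10, 3)
  expect_error(landmark_rigid_fit(landmark_pairs(line, line)),
               "collinear")
})

test_that("noisy landmarks give RMS near sigma and small rotation errors", {
  set.seed(3)
  x <- matrix(rnorm(30, sd = 50), 10, 3)
  truth <- rigid_transform(make_rot(c(1, 0, 1), 15), c(3, 3, 3))
  sigma <- 0.5
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    y <- transform_points(x, truth) + matrix(rnorm(30, sd = sigma), 10, 3)
    fit <- landmark_rigid_fit(landmark_pairs(x, y))
    rel <- crossprod(fit$rotation, truth$rotation)
    c(rms = attr(fit, "rms"),
      rot = rotation_angle_deg(rigid_transform(rel)))
  }, numeric(2))
  # per-coordinate noise sigma gives 3-D residual RMS around sqrt(3) * sigma
  expect_true(all(errs["rms", ] > 0 & errs["rms", ] < 1.5 * sqrt(3) * sigma))
  expect_gt(mean(errs["rms", ]), 0.3 * sqrt(3) * sigma)
  expect_lt(median(errs["rot", ]), 2)
})

test_that("ICP is a fixed point on aligned inputs and recovers perturbations", {
  ph <- generate_phantom_limb(small_phantom_spec())
  tib <- ph$hard

  same <- icp_refine(tib, tib, params = icp_params(max_iterations = 5))
  expect_true(attr(same, "converged"))
  expect_lte(nrow(icp_trace(same)), 2)
  expect_lt(attr(same, "rms"), 1e-9)

  pert <- apply_rigid_perturbation(tib, 5, 3, seed = 9)
  # register the perturbed copy back onto the original, no landmark init
  rec <- icp_refine(pert$mesh, tib)
  moved <- apply_transform(pert$mesh, rec)
  rms_vert <- sqrt(mean(rowSums((moved$vertices - tib$vertices)^2)))
  expect_lt(rms_vert, 0.1)
})

test_that("ICP traces are non-increasing and compose correctly", {
  ph <- generate_phantom_limb(small_phantom_spec())
  for (seed in c(5, 21)) {
    pert <- apply_rigid_perturbation(ph$hard, 8, 5, seed = seed)
    t <- icp_refine(pert$mesh, ph$hard)
    tr <- icp_trace(t)
    expect_true(all(diff(tr$rms_mm) <= 1e-12))
    # applying the returned transform reproduces the last-iteration RMS
    moved <- transform_points(pert$mesh$vertices, t)
    nn <- nearest_vertex_distances(
      triangle_mesh(moved, pert$mesh$faces), ph$hard)
    expect_equal(sqrt(mean(nn$distance^2)), tr$rms_mm[nrow(tr)],
                 tolerance = 1e-6)
  }
})

test_that("ICP respects the correspondence cutoff failure mode", {
  a <- triangle_mesh(matrix(rnorm(30), 10, 3), NULL)
  b <- triangle_mesh(matrix(rnorm(30) + 500, 10, 3), NULL)
  expect_error(
    icp_refine(a, b, params = icp_params(max_pair_distance = 1)),
    "correspondences")
})

test_that("hausdorff report satisfies its contract on hand-computable input", {
  seg <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), NULL)
  pt <- triangle_mesh(rbind(c(0, 0, 0)), NULL)
  h <- hausdorff_report(seg, pt)
  expect_equal(h$directed_max_ab, 1)
  expect_equal(h$directed_max_ba, 0)
  expect_equal(h$absolute_bidirectional, 1)
  expect_equal(h$average_bidirectional, 1 / 3)  # pooled mean of {1, 0, 0}

  cube <- cube_mesh()
  zero <- hausdorff_report(cube, cube)
  expect_equal(zero$absolute_bidirectional, 0)
  expect_equal(zero$average_bidirectional, 0)
})

test_that("hausdorff absolute is swap-symmetric; directed components swap", {
  a <- random_cloud(80, 31)
  b <- random_cloud(60, 32)
  h1 <- hausdorff_report(a, b)
  h2 <- hausdorff_report(b, a)
  expect_equal(h1$absolute_bidirectional, h2$absolute_bidirectional)
  expect_equal(h1$average_bidirectional, h2$average_bidirectional)
  expect_equal(h1$directed_max_ab, h2$directed_max_ba)
  expect_equal(h1$absolute_bidirectional,
               max(h1$directed_max_ab, h1$directed_max_ba))
  expect_lte(h1$average_bidirectional, h1$absolute_bidirectional)
})

test_that("registration strictly improves Hausdorff metrics on perturbed tibias", {
  ph <- generate_phantom_limb(small_phantom_spec())
  pert <- apply_rigid_perturbation(ph$hard, 6, 4, seed = 13)
  before <- hausdorff_report(pert$mesh, ph$hard)
  lm <- phantom_landmarks(ph$hard, n = 10,
                          transform = pert$transform, sigma_mm = 0.2, seed = 2)
  # note: landmarks map original -> perturbed; we register perturbed -> original
  init <- invert_transform(landmark_rigid_fit(lm))
  reg <- icp_refine(pert$mesh, ph$hard, init = init)
  after <- hausdorff_report(apply_transform(pert$mesh, reg), ph$hard)
  expect_lt(after$absolute_bidirectional, before$absolute_bidirectional)
  expect_lt(after$average_bidirectional, before$average_bidirectional)
})
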