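# Small geometric fixtures built in code, independent of the package's own
# generators where they serve as oracles.

single_triangle <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3)), name = "tri")
}

# axis-aligned unit cube, 8 shared vertices, 12 outward-wound faces
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, outward -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, outward +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, outward -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, outward +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, outward -x
    c(2, 4, 6), c(4, 8, 6)    # x = 1, outward +x
  )
  triangle_mesh(v, f, name = "cube")
}

# open lateral wall of a cylinder (no caps), outward-oriented
cylinder_shell <- function(radius = 10, height = 100, na = 48, nz = 20,
                           name = "cylinder") {
  theta <- 2 * pi * (seq_len(na) - 1) / na
  zs <- height * (seq_len(nz + 1) - 1) / nz
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(radius * cos(theta), radius * sin(theta), z)))
  idx <- function(i, j) (i - 1) * na + ((j - 1) %% na) + 1
  jj <- seq_len(na)
  f <- do.call(rbind, lapply(seq_len(nz), function(i) {
    rbind(cbind(idx(i, jj), idx(i, jj + 1), idx(i + 1, jj + 1)),
          cbind(idx(i, jj), idx(i + 1, jj + 1), idx(i + 1, jj)))
  }))
  triangle_mesh(v, f, name = name)
}

# UV sphere centred at the origin (poles on z), outward-oriented
sphere_mesh <- function(radius = 1, na = 48, nphi = 24, name = "sphere") {
  phi <- pi * seq_len(nphi - 1) / nphi
  theta <- 2 * pi * (seq_len(na) - 1) / na
  rings <- do.call(rbind, lapply(phi, function(p)
    cbind(radius * sin(p) * cos(theta), radius * sin(p) * sin(theta),
          radius * cos(p))))
  v <- rbind(c(0, 0, radius), rings, c(0, 0, -radius))
  idx <- function(i, j) 1 + (i - 1) * na + ((j - 1) %% na) + 1
  jj <- seq_len(na)
  top <- cbind(1, idx(1, jj), idx(1, jj + 1))
  mid <- do.call(rbind, lapply(seq_len(nphi - 2), function(i) {
    rbind(cbind(idx(i, jj), idx(i + 1, jj), idx(i + 1, jj + 1)),
          cbind(idx(i, jj), idx(i + 1, jj + 1), idx(i, jj + 1)))
  }))
  bottom_id <- nrow(v)
  bot <- cbind(bottom_id, idx(nphi - 1, jj + 1), idx(nphi - 1, jj))
  triangle_mesh(v, rbind(top, mid, bot), name = name)
}

# random point cloud as a faceless mesh (nearest-neighbour fixtures)
random_cloud <- function(n, seed, scale = 100) {
  set.seed(seed)
  triangle_mesh(matrix(runif(3 * n, -scale, scale), ncol = 3), NULL,
                name = paste0("cloud", seed))
}

# 1-to-4 subdivision keeping all original vertices (refinement fixtures);
# midpoints are appended unwelded, which is fine for vertex-set queries
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  mab <- (a + b) / 2
  mbc <- (b + cc) / 2
  mca <- (cc + a) / 2
  n0 <- nrow(v)
  m <- nrow(f)
  iab <- n0 + seq_len(m)
  ibc <- n0 + m + seq_len(m)
  ica <- n0 + 2 * m + seq_len(m)
  newf <- rbind(
    cbind(f[, 1], iab, ica),
    cbind(iab, f[, 2], ibc),
    cbind(ica, ibc, f[, 3]),
    cbind(iab, ibc, ica)
  )
  triangle_mesh(rbind(v, mab, mbc, mca), newf,
                name = paste0(mesh$name, "_sub"))
}

small_phantom_spec <- function(na = 16, nax = 10) {
  phantom_spec(angular_resolution = na, axial_resolution = nax)
}

expect_valid_mesh <- function(mesh) {
  expect_s3_class(mesh, "triangle_mesh")
  expect_silent(validate_mesh(mesh))
}
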