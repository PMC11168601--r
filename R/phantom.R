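#' Phantom limb specification
#'
#' Parametric stand-in for a transtibial residual limb: an axisymmetric,
#' tapered soft-tissue envelope (skin) with a hemispherical distal cap,
#' around a capsule-shaped bone. The geometry is simple on purpose — the
#' bone-to-skin clearance has a closed form, so every downstream measurement
#' can be checked against analytic ground truth.
#'
#' The bone capsule runs from a distal hemispherical cap (centre fixed at
#' z = 25 mm, so the bone tip clears the skin's distal cap) up to a proximal
#' tip 10 mm below the proximal face of the envelope, leaving a soft-tissue
#' pad above the bone as at a real proximal cut-off.
#'
#' @param limb_length Length of the tapered shaft region in mm (default 160).
#' @param bone_radius Bone capsule radius in mm (default 15).
#' @param skin_radius_proximal,skin_radius_distal Envelope radii at the
#'   proximal face and at the distal end of the shaft (defaults 50 and 40);
#'   must satisfy `bone_radius < skin_radius_distal <= skin_radius_proximal`.
#' @param angular_resolution Vertices per ring (default 64, minimum 8).
#' @param axial_resolution Axial stations along the shaft (default 48,
#'   minimum 8); cap ring counts scale with it.
#' @param seed Integer recorded for provenance (generation itself is
#'   deterministic).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(limb_length = 160, bone_radius = 15,
                         skin_radius_proximal = 50, skin_radius_distal = 40,
                         angular_resolution = 64, axial_resolution = 48,
                         seed = 1L) {
  if (!(bone_radius < skin_radius_distal &&
        skin_radius_distal <= skin_radius_proximal)) {
    stop("need bone_radius < skin_radius_distal <= skin_radius_proximal",
         call. = FALSE)
  }
  if (angular_resolution < 8 || axial_resolution < 8) {
    stop("resolutions must be at least 8", call. = FALSE)
  }
  structure(list(
    limb_length = limb_length,
    bone_radius = bone_radius,
    skin_radius_proximal = skin_radius_proximal,
    skin_radius_distal = skin_radius_distal,
    angular_resolution = as.integer(angular_resolution),
    axial_resolution = as.integer(axial_resolution),
    bone_distal_center = 25,
    bone_proximal_gap = 10,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Surface of revolution about z. rings_r/rings_z: profile ordered by
# ascending z (all r > 0); bottom_point/top_point: optional on-axis points
# closing the surface with triangle fans. Winding is outward.
revolve_mesh <- function(rings_r, rings_z, na, bottom_point = NULL,
                         top_point = NULL, name = "revolve") {
  k <- length(rings_r)
  theta <- 2 * pi * (seq_len(na) - 1) / na
  v <- matrix(0, k * na, 3)
  for (i in seq_len(k)) {
    rows <- (i - 1) * na + seq_len(na)
    v[rows, 1] <- rings_r[i] * cos(theta)
    v[rows, 2] <- rings_r[i] * sin(theta)
    v[rows, 3] <- rings_z[i]
  }
  nb <- 0L
  if (!is.null(bottom_point)) {
    v <- rbind(bottom_point, v)
    nb <- 1L
  }
  top_id <- NULL
  if (!is.null(top_point)) {
    v <- rbind(v, top_point)
    top_id <- nrow(v)
  }
  ring_id <- function(i, j) nb + (i - 1L) * na + ((j - 1L) %% na) + 1L

  faces <- list()
  jj <- seq_len(na)
  if (nb == 1L) {  # bottom fan, outward facing -z
    faces[[length(faces) + 1L]] <-
      cbind(1L, ring_id(1L, jj + 1L), ring_id(1L, jj))
  }
  for (i in seq_len(k - 1)) {  # side quads
    lo <- ring_id(i, jj); lo2 <- ring_id(i, jj + 1L)
    up <- ring_id(i + 1L, jj); up2 <- ring_id(i + 1L, jj + 1L)
    faces[[length(faces) + 1L]] <- cbind(lo, lo2, up2)
    faces[[length(faces) + 1L]] <- cbind(lo, up2, up)
  }
  if (!is.null(top_id)) {  # top fan, outward facing +z
    faces[[length(faces) + 1L]] <-
      cbind(top_id, ring_id(k, jj), ring_id(k, jj + 1L))
  }
  triangle_mesh(v, do.call(rbind, faces), name = name)
}

# capsule about z: hemispherical caps at both ends
capsule_mesh <- function(radius, z_lo, z_hi, na, n_shaft, n_cap,
                         center_xy = c(0, 0), name = "capsule") {
  phi <- (pi / 2) * seq_len(n_cap) / n_cap           # bottom cap (incl equator)
  r_bot <- radius * sin(phi)
  z_bot <- z_lo - radius * cos(phi)
  zs <- z_lo + (z_hi - z_lo) * seq_len(n_shaft) / n_shaft
  phi_t <- (pi / 2) * (1 - seq_len(n_cap - 1) / n_cap)  # top cap (excl pole)
  r_top <- radius * sin(phi_t)
  z_top <- z_hi + radius * cos(phi_t)
  m <- revolve_mesh(c(r_bot, rep(radius, n_shaft), r_top),
                    c(z_bot, zs, z_top), na,
                    bottom_point = c(0, 0, z_lo - radius),
                    top_point = c(0, 0, z_hi + radius),
                    name = name)
  if (any(center_xy != 0)) {
    m$vertices[, 1] <- m$vertices[, 1] + center_xy[1]
    m$vertices[, 2] <- m$vertices[, 2] + center_xy[2]
  }
  m
}

#' Generate the phantom limb surfaces and their analytic truth
#'
#' Builds the watertight, outward-oriented skin envelope and bone capsule
#' described by a [phantom_spec()], together with a record of the closed-form
#' geometry: the skin radius profile and the radial bone-to-skin clearance as
#' a function of axial position (valid over the shaft overlap region where
#' both surfaces are cylindrical/conical). Generation is deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `hard` ([triangle_mesh()], the bone capsule),
#'   `skin` ([triangle_mesh()], carrying the bone profile as an attribute so
#'   [apply_socket_deformation()] can enforce clearance), and `truth` (list:
#'   `skin_radius(z)`, `clearance(z)`, `shaft_range`, `params`,
#'   `skin_edge_length`).
#' @export
generate_phantom_limb <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$limb_length
  rb <- spec$bone_radius
  rp <- spec$skin_radius_proximal
  rd <- spec$skin_radius_distal
  na <- spec$angular_resolution
  nax <- spec$axial_resolution

  # skin: distal hemisphere + tapered shaft + flat proximal disc
  n_cap_s <- max(4L, round(nax * (pi / 2 * rd) / L))
  phi <- (pi / 2) * seq_len(n_cap_s) / n_cap_s
  cap_r <- rd * sin(phi)
  cap_z <- -rd * cos(phi)
  zs <- L * seq_len(nax) / nax
  shaft_r <- rd + (rp - rd) * zs / L
  skin <- revolve_mesh(c(cap_r, shaft_r), c(cap_z, zs), na,
                       bottom_point = c(0, 0, -rd),
                       top_point = c(0, 0, L),
                       name = "skin")

  # bone capsule
  z0 <- spec$bone_distal_center
  z1 <- L - spec$bone_proximal_gap - rb
  n_shaft_b <- max(4L, round(nax * (z1 - z0) / L))
  n_cap_b <- max(4L, round(nax * (pi / 2 * rb) / L))
  hard <- capsule_mesh(rb, z0, z1, na, n_shaft_b, n_cap_b,
                       name = "hard_tissue")

  skin_radius <- function(z) {
    ifelse(z >= 0, rd + (rp - rd) * pmin(z, L) / L,
           sqrt(pmax(rd^2 - pmin(z, 0)^2, 0)))
  }
  clearance <- function(z) skin_radius(z) - rb
  bone_profile <- list(radius = rb, z0 = z0, z1 = z1)
  attr(skin, "phantom_bone") <- bone_profile
  truth <- list(
    skin_radius = skin_radius,
    clearance = clearance,
    shaft_range = c(z0, z1),
    params = spec,
    bone_profile = bone_profile,
    skin_edge_length = median_edge_length(skin)
  )
  list(hard = hard, skin = skin, truth = truth)
}

#' Multi-part hard-tissue phantom components
#'
#' A variant with several internal structures — a main (tibia-like) capsule,
#' a thin offset (fibula-like) capsule and a small (patella-like) sphere —
#' for exercising surface compilation ([merge_meshes()]) the way separately
#' segmented bones are compiled into one hard-tissue model. No closed-form
#' clearance is claimed for this variant.
#'
#' @param spec A [phantom_spec()].
#' @return Named list of [triangle_mesh()] objects: `tibia`, `fibula`,
#'   `patella`.
#' @export
phantom_hard_components <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$limb_length
  na <- spec$angular_resolution
  nax <- spec$axial_resolution
  tibia <- capsule_mesh(spec$bone_radius, spec$bone_distal_center,
                        L - spec$bone_proximal_gap - spec$bone_radius,
                        na, max(4L, nax %/% 2), 4L, name = "tibia")
  fibula <- capsule_mesh(5, spec$bone_distal_center + 20, L - 30,
                         max(8L, na %/% 2), max(4L, nax %/% 2), 4L,
                         center_xy = c(spec$skin_radius_distal - 15, 0),
                         name = "fibula")
  patella <- capsule_mesh(8, L - 25, L - 24, max(8L, na %/% 2), 2L, 6L,
                          center_xy = c(18, 0), name = "patella")
  list(tibia = tibia, fibula = fibula, patella = patella)
}

#' Socket deformation specification
#'
#' Describes how an interface condition deforms the skin envelope: a uniform
#' radial compression plus a set of Gaussian radial indentation patches, each
#' located at an axial position (mm) and angular position (rad) with an
#' inward amplitude (mm, negative = outward relief) and an isotropic standard
#' deviation (mm, measured along the surface: axially and as arc length).
#'
#' Presets mirror the two casting philosophies:
#' * `hands_off` — pressure-cast: near-uniform radial compression
#'   (`uniform_radial = 2` mm), no patches.
#' * `hands_on` — PTB-style rectification: a global volume reduction
#'   (`uniform_radial = 3` mm) plus the classic localised features — a
#'   patellar-tendon bar and popliteal depression, medial and lateral
#'   supracondylar depressions (all in the proximal half, where the soft
#'   tissue is deepest), and a narrow distal tibial-end relief (negative
#'   amplitude). Indentation amplitudes sit in the 4-6 mm band.
#'
#' @param mode `"hands_on"`, `"hands_off"` or `"custom"`.
#' @param uniform_radial Uniform inward compression in mm (overrides the
#'   preset when supplied).
#' @param patches Data frame with columns `label`, `z_mm`, `theta_rad`,
#'   `amplitude_mm`, `sd_mm` (overrides the preset when supplied).
#' @param seed Integer recorded for provenance.
#' @return Object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("hands_on", "hands_off", "custom"),
                             uniform_radial = NULL, patches = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  preset <- switch(mode,
    hands_off = list(uniform = 2, patches = empty_patches()),
    hands_on = list(
      uniform = 3,
      patches = tibble::tibble(
        label = c("patellar_bar", "popliteal", "supracondylar_medial",
                  "supracondylar_lateral", "distal_relief"),
        z_mm = c(115, 115, 125, 125, 5),
        theta_rad = c(0, pi, pi / 2, -pi / 2, 0),
        amplitude_mm = c(6, 6, 6, 6, -2),
        sd_mm = c(30, 30, 25, 25, 10)
      )
    ),
    custom = list(uniform = 0, patches = empty_patches())
  )
  if (is.null(uniform_radial)) uniform_radial <- preset$uniform
  if (is.null(patches)) patches <- preset$patches
  patches <- tibble::as_tibble(patches)
  need <- c("z_mm", "theta_rad", "amplitude_mm", "sd_mm")
  if (nrow(patches) > 0 && !all(need %in% names(patches))) {
    stop("patches need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(patches)) {
    patches$label <- paste0("patch_", seq_len(nrow(patches)))
  }
  structure(list(mode = mode, uniform_radial = uniform_radial,
                 patches = patches, seed = as.integer(seed)),
            class = "deformation_spec")
}

empty_patches <- function() {
  tibble::tibble(label = character(0), z_mm = numeric(0),
                 theta_rad = numeric(0), amplitude_mm = numeric(0),
                 sd_mm = numeric(0))
}

# inward radial displacement (mm) of the deformation field at cylindrical
# coordinates (r, theta, z); tapers to zero within axis_taper of the axis so
# vertices near the distal pole cannot cross the axis
deformation_displacement <- function(r, theta, z, d, axis_taper = 8) {
  u <- rep(d$uniform_radial, length(r))
  if (nrow(d$patches) > 0) {
    for (k in seq_len(nrow(d$patches))) {
      p <- d$patches[k, ]
      dtheta <- atan2(sin(theta - p$theta_rad), cos(theta - p$theta_rad))
      arc <- r * dtheta
      dz <- z - p$z_mm
      u <- u + p$amplitude_mm * exp(-(dz^2 + arc^2) / (2 * p$sd_mm^2))
    }
  }
  u * pmin(1, r / axis_taper)
}

#' Apply a socket deformation to the phantom skin
#'
#' Moves each skin vertex radially inward (in cylindrical coordinates about
#' the limb axis) by the uniform compression plus the sum of Gaussian patch
#' contributions at its (axial, angular) position. The displacement tapers
#' linearly to zero within 8 mm of the axis so the distal pole region stays
#' geometrically valid. The exact per-vertex displacement actually applied is
#' returned as ground truth.
#'
#' When the skin carries the phantom's bone profile (as produced by
#' [generate_phantom_limb()]), the deformed surface is checked against it:
#' any vertex pushed inside the bone raises an error naming the patch that
#' contributed most at that vertex.
#'
#' @param skin Skin [triangle_mesh()] from [generate_phantom_limb()].
#' @param d A [deformation_spec()].
#' @return List with `deformed` (the displaced mesh, name suffixed with the
#'   mode) and `displacement` (numeric vector, mm, inward positive — the
#'   applied ground-truth field).
#' @export
apply_socket_deformation <- function(skin, d) {
  stopifnot(inherits(skin, "triangle_mesh"), inherits(d, "deformation_spec"))
  v <- skin$vertices
  r <- sqrt(v[, 1]^2 + v[, 2]^2)
  theta <- atan2(v[, 2], v[, 1])
  z <- v[, 3]
  u <- deformation_displacement(r, theta, z, d)
  new_r <- r - u

  bone <- attr(skin, "phantom_bone")
  if (!is.null(bone)) {
    prof <- bone_radial_profile(z, bone)
    bad <- which(new_r <= prof + 0.5)
    if (length(bad) > 0) {
      i <- bad[1]
      culprit <- "uniform_radial"
      if (nrow(d$patches) > 0) {
        contrib <- vapply(seq_len(nrow(d$patches)), function(k) {
          p <- d$patches[k, ]
          dtheta <- atan2(sin(theta[i] - p$theta_rad),
                          cos(theta[i] - p$theta_rad))
          p$amplitude_mm *
            exp(-((z[i] - p$z_mm)^2 + (r[i] * dtheta)^2) / (2 * p$sd_mm^2))
        }, numeric(1))
        if (max(contrib) > d$uniform_radial) {
          culprit <- d$patches$label[which.max(contrib)]
        }
      }
      stop(sprintf(
        "deformation drives skin into bone at vertex %d (z = %.1f mm); largest contribution: %s",
        i, z[i], culprit), call. = FALSE)
    }
  }
  scale <- ifelse(r > 1e-12, new_r / r, 1)
  out <- skin
  out$vertices[, 1] <- v[, 1] * scale
  out$vertices[, 2] <- v[, 2] * scale
  out$name <- paste0(skin$name, "_", d$mode)
  list(deformed = out, displacement = u)
}

# bone surface radial extent at height z (-Inf where no bone)
bone_radial_profile <- function(z, bone) {
  out <- rep(-Inf, length(z))
  shaft <- z >= bone$z0 & z <= bone$z1
  out[shaft] <- bone$radius
  lo <- z < bone$z0 & z >= bone$z0 - bone$radius
  out[lo] <- sqrt(pmax(bone$radius^2 - (bone$z0 - z[lo])^2, 0))
  hi <- z > bone$z1 & z <= bone$z1 + bone$radius
  out[hi] <- sqrt(pmax(bone$radius^2 - (z[hi] - bone$z1)^2, 0))
  out
}

#' Apply a seeded random rigid perturbation
#'
#' Registration test fixture: rotates the mesh by a random angle up to
#' `max_angle_deg` about a random axis and translates it by a random vector
#' of length up to `max_translation_mm`, all drawn from a local RNG stream
#' seeded with `seed`. The exact transform is returned so registration can
#' be scored against it. Zero bounds give the identity.
#'
#' @param mesh A [triangle_mesh()].
#' @param max_angle_deg,max_translation_mm Non-negative bounds.
#' @param seed Integer seed.
#' @return List with `mesh` (perturbed) and `transform` (the applied
#'   [rigid_transform()]).
#' @export
apply_rigid_perturbation <- function(mesh, max_angle_deg, max_translation_mm,
                                     seed = 1L) {
  stopifnot(max_angle_deg >= 0, max_translation_mm >= 0)
  t <- with_local_seed(seed, {
    ang <- if (max_angle_deg > 0) runif(1, 0, max_angle_deg) * pi / 180 else 0
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    tr <- if (max_translation_mm > 0) {
      dir <- stats::rnorm(3)
      dir / sqrt(sum(dir^2)) * runif(1, 0, max_translation_mm)
    } else {
      c(0, 0, 0)
    }
    rigid_transform(rotation_about_axis(axis, ang), tr)
  })
  list(mesh = apply_transform(mesh, t), transform = t)
}

# Rodrigues rotation matrix
rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * k + (1 - cos(angle_rad)) * (k %*% k)
}

#' Generate landmark pairs on a phantom bone
#'
#' Picks `n` well-spread vertices by farthest-point (maxmin) sampling seeded
#' at the most distal vertex — emulating the protocol of selecting points at
#' recognisable features and at the bone extremities — and pairs them with
#' the same vertices under `transform`, optionally jittered with Gaussian
#' noise to mimic manual selection error.
#'
#' @param mesh Reference bone [triangle_mesh()].
#' @param n Number of pairs (>= 3; default 10, the study protocol).
#' @param transform [rigid_transform()] mapping reference onto the second
#'   model (e.g. from [apply_rigid_perturbation()]).
#' @param sigma_mm Standard deviation of target-point jitter in mm
#'   (default 0).
#' @param seed Integer seed for the jitter.
#' @return A [landmark_pairs()]; attribute `indices` gives the sampled
#'   vertex indices.
#' @export
phantom_landmarks <- function(mesh, n = 10, transform = rigid_transform(),
                              sigma_mm = 0, seed = 1L) {
  nv <- n_vertices(mesh)
  if (n > nv) stop("n exceeds vertex count", call. = FALSE)
  if (n < 3) stop("at least 3 landmarks are required", call. = FALSE)
  v <- mesh$vertices
  start <- attr(extreme_point(mesh, c(0, 0, -1)), "index")
  sel <- integer(n)
  sel[1] <- start
  d2min <- (v[, 1] - v[start, 1])^2 + (v[, 2] - v[start, 2])^2 +
    (v[, 3] - v[start, 3])^2
  for (k in seq_len(n - 1)) {
    nxt <- which.max(d2min)
    sel[k + 1] <- nxt
    d2 <- (v[, 1] - v[nxt, 1])^2 + (v[, 2] - v[nxt, 2])^2 +
      (v[, 3] - v[nxt, 3])^2
    d2min <- pmin(d2min, d2)
  }
  src <- v[sel, , drop = FALSE]
  dst <- transform_points(src, transform)
  if (sigma_mm > 0) {
    dst <- dst + with_local_seed(seed,
                                 matrix(stats::rnorm(3 * n, 0, sigma_mm), n, 3))
  }
  out <- landmark_pairs(src, dst)
  attr(out, "indices") <- sel
  out
}

#' Signed volume enclosed by a mesh
#'
#' Positive for a watertight, outward-oriented surface (divergence theorem);
#' used to check phantom orientation.
#' @param mesh A [triangle_mesh()].
#' @return Volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}
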