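#' Construct a triangle mesh
#'
#' The universal geometric currency of the package: a shared-vertex
#' triangulated surface in millimetres, in the scanner (global) frame.
#' Faces are vertex-index triples; counter-clockwise winding seen from
#' outside the surface means outward orientation.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z in mm), one row per
#'   vertex. A data frame with columns x, y, z is also accepted.
#' @param faces Integer matrix with 3 columns of 1-based vertex indices, one
#'   row per triangle.
#' @param name Free-text label (e.g. `"skin_hands_on"`, `"hard_tissue"`).
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices` (n x 3 numeric matrix), `faces` (m x 3 integer matrix) and
#'   `name`.
#' @seealso [validate_mesh()], [read_stl()], [merge_meshes()]
#' @export
triangle_mesh <- function(vertices, faces, name = "mesh") {
  if (is.data.frame(vertices)) {
    vertices <- as.matrix(vertices[, c("x", "y", "z")])
  }
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  if (is.null(faces) || length(faces) == 0) {
    faces <- matrix(integer(0), ncol = 3)
  }
  faces <- matrix(as.integer(faces), ncol = 3)
  structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1]),
    class = "triangle_mesh"
  )
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0) {
    rng <- apply(x$vertices, 2, range)
    cat(sprintf("  bounds [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A [triangle_mesh()].
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' Validate (and optionally prune) a triangle mesh
#'
#' Checks the structural invariants every downstream operation relies on:
#' face indices in range, no degenerate face referencing a vertex twice,
#' finite coordinates. With `prune = TRUE`, vertices referenced by no face
#' are removed and face indices remapped.
#'
#' @param mesh A [triangle_mesh()].
#' @param prune Remove unreferenced vertices? Default `FALSE`.
#' @return The validated mesh. Attribute `n_vertices_removed` reports how
#'   many vertices pruning removed (0 when `prune = FALSE`).
#' @export
validate_mesh <- function(mesh, prune = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  bad_coord <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(bad_coord) > 0) {
    stop(sprintf("non-finite coordinate at vertex %d", bad_coord[1, 1]),
         call. = FALSE)
  }
  if (nrow(f) > 0) {
    out_of_range <- f < 1L | f > nrow(v)
    if (any(out_of_range)) {
      bad_face <- which(apply(out_of_range, 1, any))[1]
      stop(sprintf("face %d references vertex index out of range (indices: %s)",
                   bad_face, paste(f[bad_face, ], collapse = ", ")),
           call. = FALSE)
    }
    dup <- f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]
    if (any(dup)) {
      stop(sprintf("face %d references the same vertex twice", which(dup)[1]),
           call. = FALSE)
    }
  }
  removed <- 0L
  if (prune) {
    used <- sort(unique(as.vector(f)))
    removed <- nrow(v) - length(used)
    if (removed > 0) {
      remap <- integer(nrow(v))
      remap[used] <- seq_along(used)
      mesh$vertices <- v[used, , drop = FALSE]
      mesh$faces <- matrix(remap[f], ncol = 3)
    }
  }
  attr(mesh, "n_vertices_removed") <- removed
  mesh
}

#' Merge meshes by concatenation
#'
#' Compiles several surfaces (for example the separately segmented bones plus
#' the meniscus/patellar-tendon assembly) into one surface model, exactly as
#' segmentation outputs are compiled into a single STL: vertex and face lists
#' are concatenated with face indices offset. No boolean union and no vertex
#' welding is performed; coincident vertices at segmentation boundaries are
#' tolerated because nearest-neighbour distance is insensitive to duplication.
#'
#' @param meshes A list of [triangle_mesh()] objects (non-empty).
#' @param name Label for the merged mesh.
#' @return A single `triangle_mesh` whose vertex count is the sum of the
#'   inputs' vertex counts.
#' @export
merge_meshes <- function(meshes, name = "merged") {
  if (inherits(meshes, "triangle_mesh")) meshes <- list(meshes)
  if (!is.list(meshes) || length(meshes) == 0) {
    stop("merge_meshes() needs a non-empty list of meshes", call. = FALSE)
  }
  offsets <- cumsum(c(0L, vapply(meshes, n_vertices, integer(1))))
  v <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  f <- do.call(rbind, Map(function(m, off) m$faces + off,
                          meshes, offsets[seq_along(meshes)]))
  triangle_mesh(v, f, name = name)
}

# Unnormalised face normals: cross products, magnitude = 2 * triangle area.
face_cross_products <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
}

#' Per-vertex outward unit normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#' Assumes consistently outward (counter-clockwise) face winding. Vertices
#' incident to no face get a zero vector and are flagged.
#'
#' @param mesh A valid [triangle_mesh()].
#' @return An n x 3 matrix of unit normals. Attribute `unreferenced` holds the
#'   indices of vertices with no incident face (their rows are zero).
#' @export
vertex_normals <- function(mesh) {
  n <- n_vertices(mesh)
  acc <- matrix(0, n, 3)
  if (n_faces(mesh) > 0) {
    fx <- face_cross_products(mesh)  # magnitude = 2 * area: area weighting
    idx <- as.vector(mesh$faces)     # 3m incident-vertex indices
    w <- rbind(fx, fx, fx)           # matching face weights
    present <- sort(unique(idx))
    for (j in 1:3) {
      sums <- rowsum(w[, j], idx, reorder = TRUE)
      acc[present, j] <- sums[, 1]
    }
  }
  len <- sqrt(rowSums(acc^2))
  unref <- which(len == 0)
  len[len == 0] <- 1
  normals <- acc / len
  attr(normals, "unreferenced") <- unref
  normals
}

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation Length-3 translation vector (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal (tolerance 1e-9)", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix must have determinant +1 (no reflection/scaling)",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat(sprintf("<rigid_transform: rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a rigid transform, in degrees
#' @param t A [rigid_transform()].
#' @return Rotation angle in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(t) {
  c_ang <- (sum(diag(t$rotation)) - 1) / 2
  acos(max(-1, min(1, c_ang))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is "apply `a`, then `b`".
#' @param b,a [rigid_transform()] objects.
#' @return The composite `rigid_transform`.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.vector(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(t) {
  rt <- t(t$rotation)
  rigid_transform(rt, -as.vector(rt %*% t$translation))
}

#' Apply a rigid transform to points
#' @param points n x 3 matrix of points.
#' @param t A [rigid_transform()].
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(points, t) {
  points %*% t(t$rotation) + matrix(t$translation, nrow(points), 3, byrow = TRUE)
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex is mapped `v -> R v + translation`; faces are unchanged, so
#' all pairwise distances and triangle areas are preserved (rigidity).
#'
#' @param mesh A [triangle_mesh()].
#' @param t A [rigid_transform()].
#' @return The transformed mesh.
#' @export
apply_transform <- function(mesh, t) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(t, "rigid_transform"))
  mesh$vertices <- transform_points(mesh$vertices, t)
  colnames(mesh$vertices) <- c("x", "y", "z")
  mesh
}

#' Extreme vertex of a mesh along a direction
#'
#' Returns the vertex with the largest projection onto `direction` — e.g. the
#' most distal point of a bone surface when `direction` is the distal axis.
#' Ties are broken by lowest vertex index for determinism.
#'
#' @param mesh A [triangle_mesh()] with at least one vertex.
#' @param direction Length-3 direction vector (need not be unit length).
#' @return The 3-D point (named numeric, mm); attribute `index` gives its
#'   vertex index.
#' @export
extreme_point <- function(mesh, direction) {
  if (n_vertices(mesh) == 0) stop("mesh has no vertices", call. = FALSE)
  direction <- as.numeric(direction)
  if (length(direction) != 3 || sqrt(sum(direction^2)) < 1e-12) {
    stop("direction must be a nonzero 3-vector", call. = FALSE)
  }
  proj <- as.vector(mesh$vertices %*% direction)
  i <- which.max(proj)  # first maximum = lowest index
  p <- mesh$vertices[i, ]
  attr(p, "index") <- i
  p
}

#' Construct a plane
#'
#' @param point A 3-D point on the plane (mm).
#' @param normal Direction of the kept half-space; normalised to unit length.
#' @return Object of class `plane` with unit `normal`.
#' @export
plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3, length(normal) == 3)
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be nonzero", call. = FALSE)
  structure(list(point = point, normal = normal / len), class = "plane")
}

#' Signed distance from points to a plane
#' @param points n x 3 matrix.
#' @param pl A [plane()].
#' @return Numeric vector; positive on the kept (normal) side.
#' @export
plane_signed_distance <- function(points, pl) {
  as.vector((points - matrix(pl$point, nrow(points), 3, byrow = TRUE)) %*% pl$normal)
}

#' Anatomical trim plane a fixed offset proximal to the most distal point
#'
#' Builds the plane used to cut both the hard-tissue and skin surfaces at the
#' same anatomical level: it passes `offset_mm` proximally (against the distal
#' direction) of the most distal vertex of `reference_mesh`, and its normal is
#' the distal direction, so the kept half-space is the distal portion of the
#' limb. The same plane object is reused for every surface of a scan so all
#' surfaces are cut at exactly the same level in the global frame.
#'
#' @param reference_mesh Mesh whose most distal vertex anchors the plane
#'   (typically the hard-tissue surface).
#' @param distal_direction Unit 3-vector pointing distally. MRI axial stacks
#'   conventionally order slices along z, so the default is `c(0, 0, -1)`.
#' @param offset_mm Proximal offset of the plane from the distal point, in mm
#'   (default 50). Must be positive.
#' @return A [plane()].
#' @export
anatomical_trim_plane <- function(reference_mesh,
                                  distal_direction = c(0, 0, -1),
                                  offset_mm = 50) {
  if (!is.numeric(offset_mm) || length(offset_mm) != 1 || offset_mm <= 0) {
    stop("offset_mm must be a positive length in mm", call. = FALSE)
  }
  d <- as.numeric(distal_direction)
  len <- sqrt(sum(d^2))
  if (length(d) != 3 || len < 1e-12) {
    stop("distal_direction is degenerate", call. = FALSE)
  }
  d <- d / len
  distal_pt <- as.numeric(extreme_point(reference_mesh, d))
  plane(point = distal_pt - offset_mm * d, normal = d)
}

#' Trim a mesh by a plane
#'
#' Keeps all geometry on the plane's normal side. Triangles crossing the plane
#' are split at their exact edge-plane intersections, so the cut boundary lies
#' on the plane and no output vertex lies beyond the plane by more than
#' 1e-9 mm. The cut is left open (no cap): capping would add fictitious
#' surface that does not exist on a segmented skin or bone model.
#'
#' @param mesh A valid [triangle_mesh()].
#' @param pl A [plane()]; its normal points toward the kept half-space.
#' @return The trimmed mesh (pruned of unreferenced vertices). If the whole
#'   mesh lies on the discarded side an empty mesh is returned with a warning.
#' @export
trim_by_plane <- function(mesh, pl) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(pl, "plane"))
  eps <- 1e-9
  s <- plane_signed_distance(mesh$vertices, pl)
  side <- ifelse(s > eps, 1L, ifelse(s < -eps, -1L, 0L))  # on-plane counts kept

  fs <- matrix(side[mesh$faces], ncol = 3)
  keep_all <- rowSums(fs >= 0L) == 3L
  drop_all <- rowSums(fs <= 0L) == 3L & !keep_all
  crossing <- which(!keep_all & !drop_all)

  v <- mesh$vertices
  new_faces <- mesh$faces[keep_all, , drop = FALSE]
  extra_faces <- list()

  if (length(crossing) > 0) {
    # cache of intersection vertices keyed by (lo, hi) vertex pair,
    # so split triangles sharing an edge share the cut vertex
    cut_cache <- new.env(parent = emptyenv())
    next_id <- nrow(v)
    extra_v <- list()
    edge_cut <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- get0(key, envir = cut_cache)
      if (!is.null(hit)) return(hit)
      t <- s[i] / (s[i] - s[j])
      p <- v[i, ] + t * (v[j, ] - v[i, ])
      next_id <<- next_id + 1L
      extra_v[[length(extra_v) + 1L]] <<- p
      assign(key, next_id, envir = cut_cache)
      next_id
    }
    for (fi in crossing) {
      f <- mesh$faces[fi, ]
      # Sutherland-Hodgman clip of the triangle against the kept half-space
      poly <- integer(0)
      for (k in 1:3) {
        a <- f[k]; b <- f[if (k == 3) 1 else k + 1]
        if (side[a] >= 0L) poly <- c(poly, a)
        if ((side[a] > 0L && side[b] < 0L) || (side[a] < 0L && side[b] > 0L)) {
          poly <- c(poly, edge_cut(a, b))
        }
      }
      if (length(poly) >= 3) {
        for (k in 2:(length(poly) - 1)) {  # fan triangulation
          extra_faces[[length(extra_faces) + 1L]] <-
            c(poly[1], poly[k], poly[k + 1])
        }
      }
    }
    if (length(extra_v) > 0) v <- rbind(v, do.call(rbind, extra_v))
  }

  if (length(extra_faces) > 0) {
    new_faces <- rbind(new_faces, do.call(rbind, extra_faces))
  }
  out <- triangle_mesh(v, new_faces, name = mesh$name)
  out <- validate_mesh(out, prune = TRUE)
  if (n_faces(out) == 0) {
    warning("mesh lies entirely on the discarded side of the trim plane",
            call. = FALSE)
  }
  out
}

#' Construct landmark pairs
#'
#' Index-paired 3-D points on two models of the same bone, used to initialise
#' rigid registration (the protocol uses 10 manually selected pairs at
#' recognisable anatomical features and bone extremities).
#'
#' @param source_points,target_points n x 3 matrices (mm), row i of one paired
#'   with row i of the other; n >= 3 and source points not all collinear.
#' @return Object of class `landmark_pairs`.
#' @export
landmark_pairs <- function(source_points, target_points) {
  source_points <- matrix(as.numeric(source_points), ncol = 3)
  target_points <- matrix(as.numeric(target_points), ncol = 3)
  if (nrow(source_points) != nrow(target_points)) {
    stop("source and target landmark counts differ", call. = FALSE)
  }
  if (nrow(source_points) < 3) {
    stop("at least 3 landmark pairs are required", call. = FALSE)
  }
  if (landmarks_collinear(source_points)) {
    stop("source landmarks are collinear: rigid fit is degenerate",
         call. = FALSE)
  }
  structure(list(source_points = source_points, target_points = target_points),
            class = "landmark_pairs")
}

landmarks_collinear <- function(p, tol = 1e-9) {
  pc <- sweep(p, 2, colMeans(p))
  sv <- svd(pc, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' @export
print.landmark_pairs <- function(x, ...) {
  cat(sprintf("<landmark_pairs: %d paired points>\n", nrow(x$source_points)))
  invisible(x)
}

#' Triangle areas of a mesh
#' @param mesh A [triangle_mesh()].
#' @return Numeric vector of areas (mm^2), one per face.
#' @export
face_areas <- function(mesh) {
  if (n_faces(mesh) == 0) return(numeric(0))
  0.5 * sqrt(rowSums(face_cross_products(mesh)^2))
}

#' Median edge length of a mesh
#'
#' Used as the natural discretisation scale: analytic comparisons on phantom
#' meshes are expected to hold "within one edge length".
#' @param mesh A [triangle_mesh()].
#' @return Median edge length in mm.
#' @export
median_edge_length <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(NA_real_)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  v <- mesh$vertices
  stats::median(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                              v[e[, 2], , drop = FALSE])^2)))
}

#' Indices of boundary vertices (vertices on open edges)
#'
#' An edge is a boundary edge when it belongs to exactly one face; its
#' endpoints are boundary vertices. Watertight meshes have none.
#' @param mesh A [triangle_mesh()].
#' @return Integer vector of vertex indices (possibly empty).
#' @export
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(integer(0))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  open_keys <- names(tab)[tab == 1L]
  if (length(open_keys) == 0) return(integer(0))
  open_e <- e[key %in% open_keys, , drop = FALSE]
  sort(unique(as.vector(open_e)))
}
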