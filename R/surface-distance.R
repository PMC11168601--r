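new_distance_field <- function(distance, nearest_index, source_name,
                               target_name) {
  out <- tibble::tibble(
    vertex = seq_along(distance),
    distance = as.numeric(distance),
    nearest_index = as.integer(nearest_index)
  )
  class(out) <- c("distance_field", class(out))
  attr(out, "source_name") <- source_name
  attr(out, "target_name") <- target_name
  out
}

#' Nearest-vertex distances from one surface to another
#'
#' The core of analysis method 1: for each vertex of `source` (typically the
#' compiled internal hard-tissue surface) the nearest vertex of `target`
#' (typically the skin surface) is found and the Euclidean distance computed.
#' The measure is directed — `d(A -> B)` is generally not `d(B -> A)`.
#' Queries run through a KD-tree; ties in the nearest target vertex are
#' broken by lowest target index, so results are identical (not merely close)
#' to the exhaustive oracle [nearest_vertex_distances_bruteforce()].
#'
#' @param source,target [triangle_mesh()] objects with at least one vertex
#'   each.
#' @return A `distance_field`: a tibble with one row per source vertex and
#'   columns `vertex`, `distance` (mm, >= 0) and `nearest_index` (index into
#'   the target's vertices). Attributes `source_name`/`target_name` record
#'   the inputs.
#' @export
nearest_vertex_distances <- function(source, target) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  if (n_vertices(source) == 0 || n_vertices(target) == 0) {
    stop("both meshes must have at least one vertex", call. = FALSE)
  }
  res <- cpp_nearest_points(source$vertices, target$vertices)
  new_distance_field(res$distance, res$index, source$name, target$name)
}

#' Brute-force nearest-vertex distances (test oracle)
#'
#' Exhaustive O(N x M) pairwise scan, definitionally correct, with the same
#' lowest-index tie-breaking as the accelerated path. Intended as the
#' independent oracle for small meshes.
#'
#' @inheritParams nearest_vertex_distances
#' @return A `distance_field` (see [nearest_vertex_distances()]).
#' @export
nearest_vertex_distances_bruteforce <- function(source, target) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  ns <- n_vertices(source)
  if (ns == 0 || n_vertices(target) == 0) {
    stop("both meshes must have at least one vertex", call. = FALSE)
  }
  tv <- target$vertices
  idx <- integer(ns)
  d <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- source$vertices[i, ]
    d2 <- (tv[, 1] - s[1])^2 + (tv[, 2] - s[2])^2 + (tv[, 3] - s[3])^2
    j <- which.min(d2)  # first minimum = lowest target index
    idx[i] <- j
    d[i] <- sqrt(d2[j])
  }
  new_distance_field(d, idx, source$name, target$name)
}

#' Histogram of a nearest-distance field
#'
#' Splits the distances into `n_bins` equal-width intervals and normalises
#' counts to percent of source vertices, correcting for differing vertex
#' counts between conditions so two interface conditions can be overlaid on
#' one graph. The default range is `[0, max(distance)]` per condition; pass a
#' shared `range` to put two conditions on identical bins.
#'
#' Bins are right-closed: a value exactly on an interior edge belongs to the
#' bin closing at that edge, and the range minimum joins the first bin, so
#' the maximum always lands in the last bin. When an explicit `range`
#' excludes some distances they are counted in the nearest end bin, so
#' percents always sum to 100.
#'
#' @param field A `distance_field` from [nearest_vertex_distances()].
#' @param n_bins Number of intervals (default 100).
#' @param range Optional `c(lo, hi)` in mm with `lo < hi`.
#' @return A `distance_histogram`: tibble with columns `bin`, `bin_lower_mm`,
#'   `bin_upper_mm`, `count`, `percent`; attributes `bin_edges` (length
#'   `n_bins + 1`) and `n_source_vertices`.
#' @export
distance_histogram <- function(field, n_bins = 100, range = NULL) {
  stopifnot(inherits(field, "distance_field"))
  d <- field$distance
  if (length(d) == 0) stop("distance field is empty", call. = FALSE)
  if (is.null(range)) {
    if (length(unique(d)) == 1L) {
      stop("all distances are identical; supply an explicit range = c(lo, hi)",
           call. = FALSE)
    }
    range <- c(0, max(d))
  } else {
    range <- as.numeric(range)
    if (length(range) != 2 || !(range[1] < range[2])) {
      stop("range must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(d, edges, left.open = TRUE)  # right-closed bins
  idx[idx < 1L] <- 1L                     # range minimum / below -> first bin
  idx[idx > n_bins] <- n_bins             # above range -> last bin
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    bin_lower_mm = edges[-length(edges)],
    bin_upper_mm = edges[-1],
    count = counts,
    percent = 100 * counts / length(d)
  )
  class(out) <- c("distance_histogram", class(out))
  attr(out, "bin_edges") <- edges
  attr(out, "n_source_vertices") <- length(d)
  attr(out, "source_name") <- attr(field, "source_name")
  attr(out, "target_name") <- attr(field, "target_name")
  out
}

#' Summary statistics of a distance field and its histogram
#'
#' Reports the headline quantities of method 1: minimum and maximum nearest
#' distance, the modal bin (the most common soft-tissue depth) and the
#' percentage of source vertices at shallow tissue depth. The shallow
#' threshold defaults to the upper edge of the histogram's first three bins —
#' at shallow depths little absolute deformation suffices to induce high
#' tissue strain, which is why this tail is reported separately.
#'
#' @param field A `distance_field`.
#' @param hist The matching `distance_histogram`.
#' @param shallow_threshold_mm Depth threshold in mm; default
#'   `bin_edges[4]` (first three bins).
#' @return One-row tibble: `min_mm`, `max_mm`, `modal_bin_lower_mm`,
#'   `modal_bin_upper_mm`, `modal_percent`, `shallow_threshold_mm`,
#'   `shallow_percent`, `n_source_vertices`.
#' @export
distance_summary <- function(field, hist, shallow_threshold_mm = NULL) {
  stopifnot(inherits(field, "distance_field"),
            inherits(hist, "distance_histogram"))
  if (attr(hist, "n_source_vertices") != nrow(field)) {
    stop("field and histogram describe different vertex counts", call. = FALSE)
  }
  edges <- attr(hist, "bin_edges")
  if (is.null(shallow_threshold_mm)) shallow_threshold_mm <- edges[4]
  m <- which.max(hist$percent)  # ties -> lowest bin
  tibble::tibble(
    min_mm = min(field$distance),
    max_mm = max(field$distance),
    modal_bin_lower_mm = hist$bin_lower_mm[m],
    modal_bin_upper_mm = hist$bin_upper_mm[m],
    modal_percent = hist$percent[m],
    shallow_threshold_mm = shallow_threshold_mm,
    shallow_percent = 100 * mean(field$distance < shallow_threshold_mm),
    n_source_vertices = nrow(field)
  )
}

#' Nearest point-on-triangle distances (facet mode)
#'
#' Optional companion to the vertex-to-vertex measure: distance from each
#' source vertex to the closest point anywhere on the target's triangles,
#' never larger than the vertex-to-vertex distance. Reported alongside the
#' primary measure so the discrepancy between the two conventions can be
#' quantified. O(N x M) over faces; intended for moderate meshes.
#'
#' @inheritParams nearest_vertex_distances
#' @return A `distance_field` whose `nearest_index` column indexes target
#'   faces rather than vertices.
#' @export
nearest_triangle_distances <- function(source, target) {
  stopifnot(inherits(source, "triangle_mesh"), inherits(target, "triangle_mesh"))
  if (n_vertices(source) == 0 || n_faces(target) == 0) {
    stop("source needs vertices and target needs faces", call. = FALSE)
  }
  tv <- target$vertices
  tf <- target$faces
  a <- tv[tf[, 1], , drop = FALSE]
  b <- tv[tf[, 2], , drop = FALSE]
  cc <- tv[tf[, 3], , drop = FALSE]
  ns <- n_vertices(source)
  d <- numeric(ns)
  idx <- integer(ns)
  for (i in seq_len(ns)) {
    d2 <- point_triangle_dist2(source$vertices[i, ], a, b, cc)
    j <- which.min(d2)
    idx[i] <- j
    d[i] <- sqrt(d2[j])
  }
  new_distance_field(d, idx, source$name, paste0(target$name, ":faces"))
}

# squared distance from point p to each triangle (a,b,c); vectorised over
# triangles (Ericson's real-time collision detection region test)
point_triangle_dist2 <- function(p, a, b, c) {
  ab <- b - a
  ac <- c - a
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)
  ap <- pm - a
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- pm - c
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  # interior barycentric solution
  vv <- vb / denom
  ww <- vc / denom
  cl <- a + vv * ab + ww * ac

  # vertex regions
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  # edge regions
  v_ab <- d1 / (d1 - d3)
  reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  w_ac <- d2 / (d2 - d6)
  reg_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  w_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  reg_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0

  cl[reg_bc, ] <- b[reg_bc, , drop = FALSE] +
    w_bc[reg_bc] * (c - b)[reg_bc, , drop = FALSE]
  cl[reg_ac, ] <- a[reg_ac, , drop = FALSE] +
    w_ac[reg_ac] * ac[reg_ac, , drop = FALSE]
  cl[reg_ab, ] <- a[reg_ab, , drop = FALSE] +
    v_ab[reg_ab] * ab[reg_ab, , drop = FALSE]
  cl[reg_c, ] <- c[reg_c, , drop = FALSE]
  cl[reg_b, ] <- b[reg_b, , drop = FALSE]
  cl[reg_a, ] <- a[reg_a, , drop = FALSE]
  rowSums((pm - cl)^2)
}

#' Export a distance field as a heat-map scalar mesh
#'
#' @param field A `distance_field` computed from `source`.
#' @param source The source mesh the field was computed on.
#' @return A [scalar_mesh()] carrying the distances, ready for
#'   [write_scalar_mesh()].
#' @export
distance_heatmap <- function(field, source) {
  stopifnot(inherits(field, "distance_field"))
  if (nrow(field) != n_vertices(source)) {
    stop("field does not match source mesh vertex count", call. = FALSE)
  }
  scalar_mesh(source, field$distance, scalar_name = "nearest_distance")
}
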