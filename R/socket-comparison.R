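#' Signed skin-to-skin difference field
#'
#' For each vertex `v` of the reference skin, with outward unit normal
#' `n(v)` and nearest vertex `w` on the other condition's skin (both skins
#' already registered into a common frame), computes the normal-projected
#' signed offset `(w - v) . n(v)` together with the unsigned nearest
#' distance `|w - v|`. Negative offsets mean the other skin lies inward of
#' the reference — i.e. the other interface is more compressive at `v`;
#' positive means more relaxed. "More compressive" is a directional claim,
#' which is why the sign is carried explicitly; the unsigned distance is
#' retained alongside.
#'
#' Vertices within one median edge length of an open (trim) boundary are
#' flagged: nearest-neighbour matches across an open boundary are
#' unreliable, so flagged vertices are excluded from summary statistics but
#' kept in heat maps.
#'
#' @param reference Skin mesh the field lives on; must have consistently
#'   outward-oriented faces (an error is raised if more than 1% of vertices
#'   have zero normals).
#' @param other The other condition's skin mesh, same frame.
#' @return A `signed_comparison_field`: tibble with columns `vertex`,
#'   `signed_offset` (mm), `unsigned_distance` (mm), `nearest_index`,
#'   `boundary` (logical flag). Attributes `reference_name`, `other_name`.
#' @export
signed_skin_difference <- function(reference, other) {
  stopifnot(inherits(reference, "triangle_mesh"),
            inherits(other, "triangle_mesh"))
  if (n_vertices(reference) == 0 || n_vertices(other) == 0) {
    stop("both skins must have vertices", call. = FALSE)
  }
  nrm <- vertex_normals(reference)
  n_zero <- length(attr(nrm, "unreferenced"))
  if (n_zero > 0.01 * n_vertices(reference)) {
    stop(sprintf(
      "reference mesh is not usably oriented: %d of %d vertices have no normal",
      n_zero, n_vertices(reference)), call. = FALSE)
  }
  nn <- cpp_nearest_points(reference$vertices, other$vertices)
  delta <- other$vertices[nn$index, , drop = FALSE] - reference$vertices
  signed <- rowSums(delta * nrm)

  bset <- boundary_vertices(reference)
  boundary <- rep(FALSE, n_vertices(reference))
  if (length(bset) > 0) {
    edge <- median_edge_length(reference)
    near_b <- cpp_nearest_points(reference$vertices,
                                 reference$vertices[bset, , drop = FALSE])
    boundary <- near_b$distance <= edge
  }
  out <- tibble::tibble(
    vertex = seq_len(n_vertices(reference)),
    signed_offset = signed,
    unsigned_distance = nn$distance,
    nearest_index = nn$index,
    boundary = boundary
  )
  class(out) <- c("signed_comparison_field", class(out))
  attr(out, "reference_name") <- reference$name
  attr(out, "other_name") <- other$name
  out
}

#' Bidirectional signed skin comparison
#'
#' Runs [signed_skin_difference()] with each skin as the reference in turn,
#' mirroring the protocol of repeating the comparison with the other
#' interface as the reference and the heat map inverted: the field on
#' `skin_b` has its sign flipped, so on *both* maps negative consistently
#' means "`skin_b`'s interface is more compressive".
#'
#' @param skin_a,skin_b Registered skin meshes (common frame).
#' @return Object of class `skin_comparison`: list with elements `on_a` and
#'   `on_b` (both `signed_comparison_field`s, sign convention as above) and
#'   the two meshes.
#' @export
bidirectional_comparison <- function(skin_a, skin_b) {
  on_a <- signed_skin_difference(skin_a, skin_b)
  on_b <- signed_skin_difference(skin_b, skin_a)
  on_b$signed_offset <- -on_b$signed_offset  # invert: negative = b compressive
  attr(on_b, "sign_inverted") <- TRUE
  structure(list(on_a = on_a, on_b = on_b, skin_a = skin_a, skin_b = skin_b),
            class = "skin_comparison")
}

#' @export
print.skin_comparison <- function(x, ...) {
  ok <- !x$on_a$boundary
  cat(sprintf(
    "<skin_comparison '%s' vs '%s': mean signed offset on A %.3f mm (non-boundary)>\n",
    x$skin_a$name, x$skin_b$name, mean(x$on_a$signed_offset[ok])))
  invisible(x)
}

#' Heat-map scalar meshes of a skin comparison
#'
#' @param cmp A `skin_comparison` from [bidirectional_comparison()].
#' @return List of two [scalar_mesh()] objects (`on_a`, `on_b`) carrying the
#'   signed offsets, ready for [write_scalar_mesh()].
#' @export
comparison_heatmaps <- function(cmp) {
  stopifnot(inherits(cmp, "skin_comparison"))
  list(
    on_a = scalar_mesh(cmp$skin_a, cmp$on_a$signed_offset,
                       scalar_name = "signed_offset"),
    on_b = scalar_mesh(cmp$skin_b, cmp$on_b$signed_offset,
                       scalar_name = "signed_offset")
  )
}

#' Overlay two skins as one labelled scene
#'
#' Concatenates both surfaces into a single scalar mesh whose per-vertex
#' scalar labels the condition (0 for `skin_a`, 1 for `skin_b`), so the two
#' surface topologies can be inspected together in any PLY viewer.
#'
#' @param skin_a,skin_b Registered skin meshes.
#' @return A [scalar_mesh()] scene.
#' @export
overlay_surfaces <- function(skin_a, skin_b) {
  merged <- merge_meshes(list(skin_a, skin_b),
                         name = paste0(skin_a$name, "+", skin_b$name))
  labels <- c(rep(0, n_vertices(skin_a)), rep(1, n_vertices(skin_b)))
  scalar_mesh(merged, labels, scalar_name = "condition")
}

#' Summary of a signed comparison field
#'
#' Boundary-flagged vertices are excluded (their correspondences cross the
#' open trim boundary).
#'
#' @param field A `signed_comparison_field`.
#' @return One-row tibble: `mean_signed_mm`, `min_signed_mm`,
#'   `max_signed_mm`, `percent_compressive` (share of non-boundary vertices
#'   with negative offset), `n_used`, `n_boundary_excluded`.
#' @export
comparison_summary <- function(field) {
  stopifnot(inherits(field, "signed_comparison_field"))
  ok <- !field$boundary
  s <- field$signed_offset[ok]
  tibble::tibble(
    mean_signed_mm = mean(s),
    min_signed_mm = min(s),
    max_signed_mm = max(s),
    percent_compressive = 100 * mean(s < 0),
    n_used = sum(ok),
    n_boundary_excluded = sum(!ok)
  )
}
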