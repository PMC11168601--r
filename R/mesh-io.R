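#' Read an STL surface model
#'
#' Reads both binary and ASCII STL, auto-detected from the file contents.
#' STL stores a facet soup (every triangle carries its own three vertex
#' coordinates); coincident facet corners are welded within `weld_tol` mm to
#' recover a shared-vertex mesh. Facet normals stored in the file are ignored
#' — orientation is carried by the winding order of each facet.
#'
#' Welding snaps coordinates to a `weld_tol` grid before grouping, so the
#' welded vertex set does not depend on facet order in the file. The default
#' tolerance (1e-6 mm) is far below the voxel scale of any segmentation, so
#' anatomy is unaffected.
#'
#' @param path Path to an `.stl` file.
#' @param name Label for the mesh; defaults to the file name.
#' @param weld_tol Welding tolerance in mm.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path, name = NULL, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- readBin(path, what = "raw", n = file.size(path))

  tri <- NULL
  if (length(raw) >= 84) {
    n_declared <- readBin(raw[81:84], what = "integer", size = 4,
                          endian = "little")
    if (n_declared >= 0 && length(raw) == 84 + 50 * n_declared) {
      tri <- parse_stl_binary(raw, n_declared)
    } else if (!stl_looks_ascii(raw)) {
      stop(sprintf(
        "truncated or corrupt binary STL: %d facets declared but file holds %d bytes",
        n_declared, length(raw)), call. = FALSE)
    }
  }
  if (is.null(tri)) {
    tri <- parse_stl_ascii(raw, path)
  }
  weld_facets(tri, name = name, weld_tol = weld_tol)
}

stl_looks_ascii <- function(raw) {
  head_txt <- rawToChar(raw[seq_len(min(length(raw), 4000L))])
  Encoding(head_txt) <- "latin1"
  grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
}

parse_stl_binary <- function(raw, n_tri) {
  if (n_tri == 0) return(matrix(numeric(0), ncol = 3))
  # each 50-byte facet: 12 little-endian float32 (normal + 3 vertices) + 2 pad
  base <- 84 + 50 * (seq_len(n_tri) - 1)
  idx <- as.vector(outer(1:48, base, `+`))
  vals <- readBin(raw[idx], what = "numeric", size = 4, n = 12 * n_tri,
                  endian = "little")
  m <- matrix(vals, ncol = 12, byrow = TRUE)
  verts <- m[, 4:12, drop = FALSE]  # drop the stored normal
  matrix(t(verts), ncol = 3, byrow = TRUE)
}

parse_stl_ascii <- function(raw, path) {
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  lines <- strsplit(txt, "\r?\n")[[1]]
  if (!any(grepl("^\\s*solid", lines)) || !any(grepl("facet", lines))) {
    stop("not a recognisable STL file (no 'solid'/'facet' tokens): ", path,
         call. = FALSE)
  }
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0) {
    stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path,
         call. = FALSE)
  }
  nums <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(sub("^\\s*vertex\\s+", "", vlines)), "\\s+"))))
  if (anyNA(nums) || length(nums) != 3 * length(vlines)) {
    stop("malformed ASCII STL: non-numeric vertex coordinates in ", path,
         call. = FALSE)
  }
  matrix(nums, ncol = 3, byrow = TRUE)
}

# facet-soup (3T x 3) -> shared-vertex mesh, grid-snap welding
weld_facets <- function(soup, name, weld_tol) {
  n_tri <- nrow(soup) / 3
  if (n_tri == 0) return(triangle_mesh(matrix(numeric(0), ncol = 3), NULL, name))
  snapped <- round(soup / weld_tol) * weld_tol
  key <- paste(snapped[, 1], snapped[, 2], snapped[, 3])
  first <- !duplicated(key)
  ids <- match(key, key[first])
  verts <- snapped[first, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  # drop facets degenerate after welding (two corners in one weld cell)
  ok <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  validate_mesh(triangle_mesh(verts, faces[ok, , drop = FALSE], name),
                prune = TRUE)
}

#' Write a mesh as STL
#'
#' Binary STL is the default: compact and lossless up to single precision —
#' coordinates are quantised to IEEE float32, i.e. about 7 significant
#' digits, which is sub-nanometre at limb scale. The ASCII dialect is offered
#' for readability and text-only pipelines.
#'
#' @param mesh A valid [triangle_mesh()].
#' @param path Output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  mesh <- validate_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  n_tri <- nrow(f)
  normals <- if (n_tri > 0) {
    fx <- face_cross_products(mesh)
    len <- sqrt(rowSums(fx^2))
    len[len == 0] <- 1
    fx / len
  } else {
    matrix(numeric(0), ncol = 3)
  }
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "limbmorph binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(n_tri), con, size = 4, endian = "little")
    if (n_tri > 0) {
      tri_block <- cbind(normals,
                         v[f[, 1], , drop = FALSE],
                         v[f[, 2], , drop = FALSE],
                         v[f[, 3], , drop = FALSE])
      floats <- as.vector(t(tri_block))
      pad <- as.raw(c(0, 0))
      for (i in seq_len(n_tri)) {
        writeBin(floats[(12 * (i - 1) + 1):(12 * i)], con, size = 4,
                 endian = "little")
        writeBin(pad, con)
      }
    }
  } else {
    lines <- c(sprintf("solid %s", mesh$name))
    if (n_tri > 0) {
      for (i in seq_len(n_tri)) {
        lines <- c(lines,
          sprintf("  facet normal %.9g %.9g %.9g",
                  normals[i, 1], normals[i, 2], normals[i, 3]),
          "    outer loop",
          sprintf("      vertex %.9g %.9g %.9g",
                  v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
          "    endloop",
          "  endfacet")
      }
    }
    lines <- c(lines, sprintf("endsolid %s", mesh$name))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Attach a per-vertex scalar to a mesh
#'
#' The carrier for heat-map data: a mesh plus one scalar value (mm or signed
#' mm) per vertex, e.g. nearest distances or signed skin offsets.
#'
#' @param mesh A valid [triangle_mesh()].
#' @param scalars Numeric vector, one value per vertex.
#' @param scalar_name Label for the scalar channel (becomes the PLY property
#'   name), e.g. `"nearest_distance"` or `"signed_offset"`.
#' @param missing_ok Allow NA scalars (written as NaN)? Default `FALSE`.
#' @return Object of class `scalar_mesh`.
#' @export
scalar_mesh <- function(mesh, scalars, scalar_name = "scalar",
                        missing_ok = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  scalars <- as.numeric(scalars)
  if (length(scalars) != n_vertices(mesh)) {
    stop(sprintf("scalar count (%d) does not match vertex count (%d)",
                 length(scalars), n_vertices(mesh)), call. = FALSE)
  }
  if (!missing_ok && any(!is.finite(scalars))) {
    stop("non-finite scalar values present; set missing_ok = TRUE to allow",
         call. = FALSE)
  }
  structure(list(mesh = mesh, scalars = scalars,
                 scalar_name = as.character(scalar_name)[1]),
            class = "scalar_mesh")
}

#' @export
print.scalar_mesh <- function(x, ...) {
  cat(sprintf("<scalar_mesh '%s' on '%s': %d vertices, range [%.3f, %.3f]>\n",
              x$scalar_name, x$mesh$name, n_vertices(x$mesh),
              suppressWarnings(min(x$scalars, na.rm = TRUE)),
              suppressWarnings(max(x$scalars, na.rm = TRUE))))
  invisible(x)
}

#' Write a scalar mesh as ASCII PLY
#'
#' PLY is used for heat-map export because STL cannot carry per-vertex
#' scalars; the scalar is written as a float vertex property named by
#' `scalar_name`, which standard mesh viewers map to a colour ramp.
#'
#' @param sm A [scalar_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalar_mesh <- function(sm, path) {
  stopifnot(inherits(sm, "scalar_mesh"))
  v <- sm$mesh$vertices
  f <- sm$mesh$faces
  prop <- gsub("[^A-Za-z0-9_]", "_", sm$scalar_name)
  header <- c(
    "ply",
    "format ascii 1.0",
    "comment limbmorph heat-map export (mm)",
    sprintf("element vertex %d", nrow(v)),
    "property float x",
    "property float y",
    "property float z",
    sprintf("property float %s", prop),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vlines <- sprintf("%.9g %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3], sm$scalars)
  flines <- if (nrow(f) > 0) {
    sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  } else {
    character(0)
  }
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read an ASCII PLY written by [write_scalar_mesh()]
#'
#' Minimal reader for round-tripping the package's own heat-map exports
#' (x, y, z plus one scalar vertex property, triangular faces).
#'
#' @param path Path to an ASCII `.ply` file.
#' @return A [scalar_mesh()].
#' @export
read_ply_scalar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  endh <- match("end_header", lines)
  header <- lines[1:endh]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header,
                                                   value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header,
                                                 value = TRUE)[1]))
  vprops <- sub("^property float ", "",
                grep("^property float ", header, value = TRUE))
  scalar_name <- setdiff(vprops, c("x", "y", "z"))[1]
  body <- lines[(endh + 1):length(lines)]
  vdat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                 ncol = length(vprops), byrow = TRUE)
  colnames(vdat) <- vprops
  faces <- NULL
  if (nf > 0) {
    fdat <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE),
                   ncol = 4, byrow = TRUE)
    faces <- fdat[, 2:4, drop = FALSE] + 1L
  }
  mesh <- triangle_mesh(vdat[, c("x", "y", "z"), drop = FALSE], faces,
                        name = sub("\\.[^.]*$", "", basename(path)))
  scalar_mesh(mesh, vdat[, scalar_name], scalar_name = scalar_name,
              missing_ok = TRUE)
}

#' Read landmark pairs from CSV
#'
#' Expects a header row and columns `src_x, src_y, src_z, dst_x, dst_y, dst_z`
#' (mm); row order is preserved. Landmarks as a file rather than interactive
#' clicks keep the registration protocol reproducible.
#'
#' @param path Path to the landmark CSV.
#' @return A [landmark_pairs()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("src_x", "src_y", "src_z", "dst_x", "dst_y", "dst_z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 3) {
    stop(sprintf("landmark CSV has %d rows; at least 3 pairs are required",
                 nrow(df)), call. = FALSE)
  }
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
    }
    df[[col]] <- vals
  }
  landmark_pairs(as.matrix(df[, need[1:3]]), as.matrix(df[, need[4:6]]))
}

#' Write landmark pairs to CSV
#' @param pairs A [landmark_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(pairs, path) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  df <- data.frame(pairs$source_points, pairs$target_points)
  names(df) <- c("src_x", "src_y", "src_z", "dst_x", "dst_y", "dst_z")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write one or two distance histograms to CSV
#'
#' With two histograms (the two interface conditions overlaid on shared bins,
#' the combined-graph presentation), both percent columns are written against
#' the common bin edges; bins must agree.
#'
#' @param hist_a A `distance_histogram` (see [distance_histogram()]).
#' @param path Output path.
#' @param hist_b Optional second `distance_histogram` on identical bins.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist_a, path, hist_b = NULL) {
  stopifnot(inherits(hist_a, "distance_histogram"))
  edges <- attr(hist_a, "bin_edges")
  df <- data.frame(bin_lower_mm = edges[-length(edges)],
                   bin_upper_mm = edges[-1],
                   percent_condition_A = hist_a$percent)
  if (!is.null(hist_b)) {
    stopifnot(inherits(hist_b, "distance_histogram"))
    if (max(abs(attr(hist_b, "bin_edges") - edges)) > 1e-9) {
      stop("histograms have different bin edges; rebuild with a shared range",
           call. = FALSE)
    }
    df$percent_condition_B <- hist_b$percent
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run report as JSON
#'
#' Serialises summary metrics together with provenance (inputs, parameters,
#' seed, package version) so a run can be audited and reproduced.
#'
#' @param results A named list (nested lists/tibbles allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path) {
  results$provenance <- c(results$provenance,
                          list(tool = "limbmorph",
                               version = as.character(utils::packageVersion("limbmorph"))))
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialise a rigid transform to JSON (4x4 homogeneous, row-major)
#' @param t A [rigid_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  h <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(matrix_4x4_row_major = as.vector(t(h))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rigid transform written by [write_transform_json()]
#' @param path Path to the transform JSON.
#' @return A [rigid_transform()].
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  h <- matrix(obj$matrix_4x4_row_major, 4, 4, byrow = TRUE)
  rigid_transform(h[1:3, 1:3], h[1:3, 4])
}
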