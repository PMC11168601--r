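#' ICP parameters
#'
#' @param max_iterations Maximum ICP iterations (default 100).
#' @param convergence_tol Stop when the RMS correspondence error changes by
#'   less than this between iterations, in mm (default 1e-6).
#' @param max_pair_distance Optional correspondence-rejection cutoff in mm;
#'   pairs farther apart are dropped from the fit (default: none). Note the
#'   monotone-RMS guarantee only holds without a cutoff.
#' @param subsample Maximum number of source vertices used (default 5000);
#'   drawn once per call so the iteration trace stays monotone.
#' @param seed Integer seed for the subsample draw.
#' @return Object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100, convergence_tol = 1e-6,
                       max_pair_distance = NULL, subsample = 5000,
                       seed = 1L) {
  stopifnot(max_iterations >= 1, convergence_tol > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 max_pair_distance = max_pair_distance,
                 subsample = as.integer(subsample),
                 seed = as.integer(seed)),
            class = "icp_params")
}

#' Least-squares rigid fit from landmark pairs
#'
#' Orthogonal-Procrustes (Kabsch) solution: the rotation plus translation —
#' no scale, no reflection — minimising the sum of squared residuals between
#' the transformed source landmarks and their paired targets. Reflections
#' are excluded by a determinant correction on the SVD solution, since
#' anatomy must never be mirrored by registration.
#'
#' @param pairs A [landmark_pairs()] (n >= 3, source not collinear).
#' @return A [rigid_transform()] with attributes `residuals` (per-pair mm)
#'   and `rms` (mm).
#' @export
landmark_rigid_fit <- function(pairs) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  x <- pairs$source_points
  y <- pairs$target_points
  if (landmarks_collinear(x)) {
    stop("source landmarks are collinear: rigid fit is degenerate",
         call. = FALSE)
  }
  xc <- colMeans(x)
  yc <- colMeans(y)
  h <- crossprod(sweep(x, 2, xc), sweep(y, 2, yc))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- yc - as.vector(rot %*% xc)
  t <- rigid_transform(rot, tr)
  resid <- sqrt(rowSums((transform_points(x, t) - y)^2))
  attr(t, "residuals") <- resid
  attr(t, "rms") <- sqrt(mean(resid^2))
  t
}

#' Iterative-closest-point refinement of a rigid alignment
#'
#' Point-to-point ICP on mesh vertices, the fine-registration step after the
#' landmark fit: starting from `init`, alternate (a) nearest-vertex
#' correspondences from the currently transformed source to the target and
#' (b) the rigid fit minimising their squared distances, until the RMS
#' change drops below `convergence_tol` or `max_iterations` is reached.
#'
#' The trace records, per iteration, the post-update RMS under that
#' iteration's correspondences — the quantity with the classical monotone
#' non-increase guarantee. Subsampling (if any) is drawn once, seeded, so
#' runs are deterministic and the guarantee survives.
#'
#' @param source,target Non-empty [triangle_mesh()] objects; `source` is
#'   moved onto `target`.
#' @param init Initial [rigid_transform()] (e.g. from
#'   [landmark_rigid_fit()]); default identity.
#' @param params An [icp_params()].
#' @return The refined [rigid_transform()] (composing the refinement with
#'   `init`), with attributes `trace` (tibble: `iteration`, `rms_mm`,
#'   `n_pairs`) and `converged` (logical).
#' @export
icp_refine <- function(source, target, init = rigid_transform(),
                       params = icp_params()) {
  stopifnot(inherits(source, "triangle_mesh"),
            inherits(target, "triangle_mesh"),
            inherits(init, "rigid_transform"),
            inherits(params, "icp_params"))
  if (n_vertices(source) == 0 || n_vertices(target) == 0) {
    stop("both meshes must have vertices", call. = FALSE)
  }
  src_pts <- source$vertices
  if (!is.null(params$subsample) && nrow(src_pts) > params$subsample) {
    keep <- with_local_seed(params$seed,
                            sample.int(nrow(src_pts), params$subsample))
    src_pts <- src_pts[sort(keep), , drop = FALSE]
  }
  tgt_pts <- target$vertices
  current <- init
  trace <- list()
  rms_prev <- Inf
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    moved <- transform_points(src_pts, current)
    nn <- cpp_nearest_points(moved, tgt_pts)
    sel <- seq_along(nn$distance)
    if (!is.null(params$max_pair_distance)) {
      sel <- which(nn$distance <= params$max_pair_distance)
      if (length(sel) < 3) {
        stop(sprintf(
          "ICP failed: only %d correspondences under max_pair_distance = %g mm",
          length(sel), params$max_pair_distance), call. = FALSE)
      }
    }
    # rigid fit on this iteration's correspondences (guard collinear subsets)
    fit <- landmark_rigid_fit(landmark_pairs(
      moved[sel, , drop = FALSE],
      tgt_pts[nn$index[sel], , drop = FALSE]))
    current <- compose_transforms(fit, current)
    moved2 <- transform_points(src_pts[sel, , drop = FALSE], current)
    rms <- sqrt(mean(rowSums((moved2 - tgt_pts[nn$index[sel], , drop = FALSE])^2)))
    trace[[it]] <- c(iteration = it, rms_mm = rms, n_pairs = length(sel))
    if (is.finite(rms_prev) && abs(rms_prev - rms) < params$convergence_tol) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
  }
  tr <- tibble::as_tibble(do.call(rbind, trace))
  attr(current, "trace") <- tr
  attr(current, "converged") <- converged
  attr(current, "rms") <- tr$rms_mm[nrow(tr)]
  current
}

#' Hausdorff-distance similarity report between two surfaces
#'
#' Registration quality metric: nearest-vertex distances are computed in both
#' directions; the absolute bidirectional Hausdorff distance is the larger of
#' the two directed maxima, and the average bidirectional Hausdorff distance
#' is the mean of all nearest distances pooled over both directions (the
#' usual symmetric mesh-comparison convention).
#'
#' @param a,b Non-empty [triangle_mesh()] objects.
#' @return Object of class `hausdorff_report`: list with
#'   `directed_max_ab`, `directed_max_ba`, `absolute_bidirectional`,
#'   `average_bidirectional` (all mm), `n_a`, `n_b`.
#' @export
hausdorff_report <- function(a, b) {
  dab <- nearest_vertex_distances(a, b)$distance
  dba <- nearest_vertex_distances(b, a)$distance
  structure(list(
    directed_max_ab = max(dab),
    directed_max_ba = max(dba),
    absolute_bidirectional = max(max(dab), max(dba)),
    average_bidirectional = mean(c(dab, dba)),
    n_a = length(dab),
    n_b = length(dba)
  ), class = "hausdorff_report")
}

#' @export
print.hausdorff_report <- function(x, ...) {
  cat(sprintf(
    "<hausdorff_report: absolute %.4f mm, average %.4f mm (n = %d / %d)>\n",
    x$absolute_bidirectional, x$average_bidirectional, x$n_a, x$n_b))
  invisible(x)
}

# run expr under a temporary RNG state; global .Random.seed untouched
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
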