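#' Run configuration for the analysis pipeline
#'
#' Collects the parameters shared by the pipeline commands. Defaults mirror
#' the study protocol: a 50 mm proximal trim offset, 100 histogram
#' intervals, 10 landmarks, distal direction along -z.
#'
#' @param output_dir Directory for all data products (created if needed).
#' @param distal_direction Unit 3-vector pointing distally.
#' @param trim_offset_mm Proximal trim-plane offset in mm (default 50); set
#'   `NULL` to skip trimming (e.g. for phantoms that are entirely within the
#'   socket region).
#' @param n_bins Histogram intervals (default 100).
#' @param range_mode `"per_condition"` (each histogram spans `[0, max]` of
#'   its own condition) or `"shared"` (both conditions on one common range
#'   for overlay).
#' @param icp An [icp_params()].
#' @param seed Integer seed recorded in provenance and used for any seeded
#'   step.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir = ".",
                       distal_direction = c(0, 0, -1),
                       trim_offset_mm = 50,
                       n_bins = 100,
                       range_mode = c("per_condition", "shared"),
                       icp = icp_params(),
                       seed = 1L) {
  range_mode <- match.arg(range_mode)
  if (!is.null(trim_offset_mm) && trim_offset_mm <= 0) {
    stop("trim_offset_mm must be positive (or NULL to disable trimming)",
         call. = FALSE)
  }
  structure(list(output_dir = output_dir,
                 distal_direction = as.numeric(distal_direction),
                 trim_offset_mm = trim_offset_mm,
                 n_bins = as.integer(n_bins),
                 range_mode = range_mode,
                 icp = icp,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `output_dir`, `distal_direction`, `trim_offset_mm`,
#' `n_bins`, `range_mode`, `seed`, and an `icp` block with [icp_params()]
#' fields. Missing keys take the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_classed("limbmorph_missing_file", paste("config not found:", path))
  }
  y <- yaml::read_yaml(path)
  icp <- do.call(icp_params, y$icp %||% list())
  args <- y[setdiff(names(y), "icp")]
  args$icp <- icp
  do.call(run_config, args)
}

stop_classed <- function(class, message) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = message, call = NULL)))
}

require_file <- function(path, what) {
  if (!file.exists(path)) {
    stop_classed("limbmorph_missing_file",
                 sprintf("%s not found: %s", what, path))
  }
  path
}

provenance_list <- function(config, inputs) {
  list(inputs = inputs,
       parameters = list(
         distal_direction = config$distal_direction,
         trim_offset_mm = config$trim_offset_mm,
         n_bins = config$n_bins,
         range_mode = config$range_mode,
         seed = config$seed))
}

#' Generate phantom fixture files
#'
#' Writes the deterministic phantom fixture set: hard-tissue and undeformed
#' skin STLs plus the hands-on and hands-off deformed skins, per-vertex
#' displacement truth CSVs, the analytic clearance table, and a spec/
#' provenance JSON. The same seed always reproduces byte-identical files.
#'
#' @param config A [run_config()].
#' @param spec A [phantom_spec()].
#' @return (Invisibly) list of the objects written (`hard`, `skin`,
#'   `skin_hands_on`, `skin_hands_off`, `truth`, `paths`).
#' @export
cmd_phantom <- function(config = run_config(), spec = phantom_spec(seed = config$seed)) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ph <- tryCatch(generate_phantom_limb(spec),
                 error = function(e) stop_classed("limbmorph_bad_spec",
                                                  conditionMessage(e)))
  on <- apply_socket_deformation(ph$skin, deformation_spec("hands_on",
                                                           seed = config$seed))
  off <- apply_socket_deformation(ph$skin, deformation_spec("hands_off",
                                                            seed = config$seed))
  paths <- list(
    hard = file.path(out, "hard_tissue.stl"),
    skin = file.path(out, "skin.stl"),
    skin_hands_on = file.path(out, "skin_hands_on.stl"),
    skin_hands_off = file.path(out, "skin_hands_off.stl")
  )
  write_stl(ph$hard, paths$hard)
  write_stl(ph$skin, paths$skin)
  write_stl(on$deformed, paths$skin_hands_on)
  write_stl(off$deformed, paths$skin_hands_off)
  utils::write.csv(
    data.frame(vertex = seq_along(on$displacement),
               displacement_hands_on_mm = on$displacement,
               displacement_hands_off_mm = off$displacement),
    file.path(out, "displacement_truth.csv"), row.names = FALSE)
  zs <- seq(0, spec$limb_length, length.out = 81)
  utils::write.csv(
    data.frame(z_mm = zs, clearance_mm = ph$truth$clearance(zs)),
    file.path(out, "clearance_truth.csv"), row.names = FALSE)
  write_report_json(
    list(spec = unclass(spec),
         provenance = provenance_list(config, inputs = list())),
    file.path(out, "phantom_spec.json"))
  message("phantom fixtures written to ", out)
  invisible(list(hard = ph$hard, skin = ph$skin,
                 skin_hands_on = on$deformed, skin_hands_off = off$deformed,
                 truth = ph$truth, paths = paths))
}

#' Method 1: bone-to-skin nearest-distance analysis
#'
#' For each condition: optionally trims hard-tissue and skin surfaces with
#' one shared anatomical plane (anchored on that condition's hard-tissue
#' surface), computes the nearest-vertex distance field from hard tissue to
#' skin, its 100-interval normalised histogram and summary, and a
#' distance heat-map PLY. With two conditions a combined overlay CSV is also
#' written; in `"shared"` range mode both histograms use one common range.
#'
#' @param config A [run_config()].
#' @param hard_paths,skin_paths Named character vectors (one entry per
#'   condition, same names) of STL paths.
#' @return (Invisibly) per-condition list of `field`, `histogram`, `summary`,
#'   plus `combined_csv` when two conditions are given.
#' @export
cmd_distance <- function(config, hard_paths, skin_paths) {
  stopifnot(length(hard_paths) == length(skin_paths), length(hard_paths) >= 1)
  if (is.null(names(hard_paths))) names(hard_paths) <- paste0("condition_", seq_along(hard_paths))
  if (is.null(names(skin_paths))) names(skin_paths) <- names(hard_paths)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  conditions <- names(hard_paths)
  fields <- list()
  for (cond in conditions) {
    hard <- read_stl(require_file(hard_paths[[cond]], "hard-tissue STL"))
    skin <- read_stl(require_file(skin_paths[[cond]], "skin STL"))
    if (!is.null(config$trim_offset_mm)) {
      pl <- anatomical_trim_plane(hard, config$distal_direction,
                                  config$trim_offset_mm)
      hard <- trim_by_plane(hard, pl)
      skin <- trim_by_plane(skin, pl)
      if (n_vertices(hard) == 0 || n_vertices(skin) == 0) {
        stop_classed("limbmorph_empty_trim",
                     sprintf("condition '%s': surface empty after trimming", cond))
      }
    }
    fields[[cond]] <- list(hard = hard, skin = skin,
                           field = nearest_vertex_distances(hard, skin))
  }

  shared_range <- NULL
  if (config$range_mode == "shared") {
    shared_range <- c(0, max(vapply(fields, function(x) max(x$field$distance),
                                    numeric(1))))
  }
  results <- list()
  for (cond in conditions) {
    f <- fields[[cond]]$field
    h <- distance_histogram(f, n_bins = config$n_bins, range = shared_range)
    s <- distance_summary(f, h)
    write_histogram_csv(h, file.path(out, paste0("histogram_", cond, ".csv")))
    write_scalar_mesh(distance_heatmap(f, fields[[cond]]$hard),
                      file.path(out, paste0("distance_heatmap_", cond, ".ply")))
    results[[cond]] <- list(field = f, histogram = h, summary = s)
  }
  if (length(conditions) == 2 && config$range_mode == "shared") {
    combined <- file.path(out, "histogram_combined.csv")
    write_histogram_csv(results[[1]]$histogram, combined,
                        hist_b = results[[2]]$histogram)
    results$combined_csv <- combined
  }
  write_report_json(
    list(summaries = lapply(results[conditions],
                            function(x) as.list(x$summary)),
         provenance = provenance_list(config,
                                      inputs = list(hard = as.list(hard_paths),
                                                    skin = as.list(skin_paths)))),
    file.path(out, "distance_summary.json"))
  invisible(results)
}

#' Method 2 alignment: landmark fit + ICP on the tibia surfaces
#'
#' Fits the landmark-based rigid transform, refines it with ICP on the bone
#' surfaces, and reports registration quality as Hausdorff distances before
#' and after. The transform is saved for [cmd_compare()].
#'
#' @param config A [run_config()].
#' @param tibia_moving_path,tibia_fixed_path STL paths; the moving tibia is
#'   registered onto the fixed one.
#' @param landmarks_path Landmark CSV (`src_*` on the moving model, `dst_*`
#'   on the fixed one).
#' @return (Invisibly) list with `transform`, `hausdorff_before`,
#'   `hausdorff_after`, `landmark_fit`, and the transform JSON path.
#' @export
cmd_register <- function(config, tibia_moving_path, tibia_fixed_path,
                         landmarks_path) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  moving <- read_stl(require_file(tibia_moving_path, "moving tibia STL"))
  fixed <- read_stl(require_file(tibia_fixed_path, "fixed tibia STL"))
  pairs <- tryCatch(read_landmarks(require_file(landmarks_path, "landmark CSV")),
                    error = function(e) {
                      if (inherits(e, "limbmorph_missing_file")) stop(e)
                      stop_classed("limbmorph_degenerate_landmarks",
                                   conditionMessage(e))
                    })
  init <- tryCatch(landmark_rigid_fit(pairs),
                   error = function(e) stop_classed(
                     "limbmorph_degenerate_landmarks", conditionMessage(e)))
  refined <- icp_refine(moving, fixed, init = init, params = config$icp)
  before <- hausdorff_report(moving, fixed)
  after <- hausdorff_report(apply_transform(moving, refined), fixed)
  tpath <- file.path(out, "registration_transform.json")
  write_transform_json(refined, tpath)
  write_report_json(
    list(landmark_fit_rms_mm = attr(init, "rms"),
         icp_rms_mm = attr(refined, "rms"),
         icp_converged = attr(refined, "converged"),
         hausdorff_before = unclass(before),
         hausdorff_after = unclass(after),
         provenance = provenance_list(config,
                                      inputs = list(moving = tibia_moving_path,
                                                    fixed = tibia_fixed_path,
                                                    landmarks = landmarks_path))),
    file.path(out, "registration_report.json"))
  invisible(list(transform = refined, hausdorff_before = before,
                 hausdorff_after = after, landmark_fit = init,
                 transform_path = tpath))
}

#' Method 2 output: signed skin-to-skin comparison
#'
#' Applies the registration transform to the moving condition's skin, runs
#' the bidirectional signed comparison and the overlay scene, and writes two
#' signed heat-map PLYs, the overlay PLY and a summary JSON (boundary-flagged
#' vertices excluded from summary statistics).
#'
#' @param config A [run_config()].
#' @param skin_moving_path,skin_fixed_path STL paths of the two conditions'
#'   skins (the moving skin rides the moving tibia of [cmd_register()]).
#' @param transform A [rigid_transform()], a path to a transform JSON from
#'   [cmd_register()], or `NULL` to look it up in `output_dir`.
#' @return (Invisibly) the `skin_comparison` plus summaries.
#' @export
cmd_compare <- function(config, skin_moving_path, skin_fixed_path,
                        transform = NULL) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (is.null(transform)) {
    transform <- file.path(out, "registration_transform.json")
  }
  if (is.character(transform)) {
    if (!file.exists(transform)) {
      stop_classed("limbmorph_unregistered",
                   paste("no registration transform at", transform,
                         "- run cmd_register() first"))
    }
    transform <- read_transform_json(transform)
  }
  stopifnot(inherits(transform, "rigid_transform"))
  moving <- read_stl(require_file(skin_moving_path, "moving skin STL"))
  fixed <- read_stl(require_file(skin_fixed_path, "fixed skin STL"))
  moving <- apply_transform(moving, transform)

  cmp <- bidirectional_comparison(moving, fixed)
  maps <- comparison_heatmaps(cmp)
  write_scalar_mesh(maps$on_a, file.path(out, "signed_offset_on_moving.ply"))
  write_scalar_mesh(maps$on_b, file.path(out, "signed_offset_on_fixed.ply"))
  write_scalar_mesh(overlay_surfaces(moving, fixed),
                    file.path(out, "skin_overlay.ply"))
  sum_a <- comparison_summary(cmp$on_a)
  sum_b <- comparison_summary(cmp$on_b)
  write_report_json(
    list(summary_on_moving = as.list(sum_a),
         summary_on_fixed = as.list(sum_b),
         provenance = provenance_list(config,
                                      inputs = list(moving = skin_moving_path,
                                                    fixed = skin_fixed_path))),
    file.path(out, "comparison_summary.json"))
  invisible(list(comparison = cmp, summary_on_moving = sum_a,
                 summary_on_fixed = sum_b))
}
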