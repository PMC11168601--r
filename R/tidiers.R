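#' @export
tidy.distance_field <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "distance_field")
  out
}

#' @export
glance.distance_field <- function(x, ...) {
  tibble::tibble(
    n_source_vertices = nrow(x),
    min_mm = min(x$distance),
    max_mm = max(x$distance),
    mean_mm = mean(x$distance),
    median_mm = stats::median(x$distance),
    source = attr(x, "source_name"),
    target = attr(x, "target_name")
  )
}

#' @export
tidy.distance_histogram <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "distance_histogram")
  out
}

#' @export
glance.distance_histogram <- function(x, ...) {
  m <- which.max(x$percent)
  tibble::tibble(
    n_bins = nrow(x),
    n_source_vertices = attr(x, "n_source_vertices"),
    modal_bin_lower_mm = x$bin_lower_mm[m],
    modal_bin_upper_mm = x$bin_upper_mm[m],
    modal_percent = x$percent[m],
    bin_width_mm = x$bin_upper_mm[1] - x$bin_lower_mm[1]
  )
}

#' @export
tidy.rigid_transform <- function(x, ...) {
  tibble::tibble(
    term = c("rotation_angle_deg", "translation_x_mm", "translation_y_mm",
             "translation_z_mm"),
    estimate = c(rotation_angle_deg(x), x$translation)
  )
}

#' @export
glance.rigid_transform <- function(x, ...) {
  tibble::tibble(
    rotation_angle_deg = rotation_angle_deg(x),
    translation_norm_mm = sqrt(sum(x$translation^2)),
    rms_mm = attr(x, "rms") %||% NA_real_,
    converged = attr(x, "converged") %||% NA
  )
}

#' ICP iteration trace of a refined transform
#' @param t A transform returned by [icp_refine()].
#' @return Tibble with `iteration`, `rms_mm`, `n_pairs`.
#' @export
icp_trace <- function(t) {
  tr <- attr(t, "trace")
  if (is.null(tr)) stop("transform carries no ICP trace", call. = FALSE)
  tr
}

#' @export
tidy.hausdorff_report <- function(x, ...) {
  tibble::tibble(
    metric = c("directed_max_ab", "directed_max_ba",
               "absolute_bidirectional", "average_bidirectional"),
    value_mm = c(x$directed_max_ab, x$directed_max_ba,
                 x$absolute_bidirectional, x$average_bidirectional)
  )
}

#' @export
glance.hausdorff_report <- function(x, ...) {
  tibble::tibble(
    absolute_bidirectional_mm = x$absolute_bidirectional,
    average_bidirectional_mm = x$average_bidirectional,
    directed_max_ab_mm = x$directed_max_ab,
    directed_max_ba_mm = x$directed_max_ba,
    n_a = x$n_a,
    n_b = x$n_b
  )
}

#' @export
tidy.signed_comparison_field <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "signed_comparison_field")
  out
}

#' @export
glance.signed_comparison_field <- function(x, ...) {
  comparison_summary(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
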