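#' Plot a distance histogram
#'
#' Percent of source vertices per nearest-distance interval — the method-1
#' presentation of soft-tissue depth distribution.
#'
#' @param object A `distance_histogram`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lower_mm + .data$bin_upper_mm) / 2,
    y = .data$percent)) +
    ggplot2::geom_col(width = df$bin_upper_mm[1] - df$bin_lower_mm[1],
                      fill = "grey30") +
    ggplot2::labs(x = "nearest bone-to-skin distance [mm]",
                  y = "% of source vertices") +
    ggplot2::theme_minimal()
}

#' Overlay two distance histograms (two interface conditions)
#'
#' The combined-graph presentation of method 1: both conditions'
#' vertex-count-normalised histograms on shared bins.
#'
#' @param hist_a,hist_b `distance_histogram`s built on identical bin edges
#'   (use a shared `range` in [distance_histogram()]).
#' @param labels Character vector of length 2 naming the conditions.
#' @return A ggplot.
#' @export
plot_histogram_overlay <- function(hist_a, hist_b,
                                   labels = c("hands-on", "hands-off")) {
  if (max(abs(attr(hist_a, "bin_edges") - attr(hist_b, "bin_edges"))) > 1e-9) {
    stop("histograms must share bin edges", call. = FALSE)
  }
  df <- dplyr::bind_rows(
    dplyr::mutate(tidy(hist_a), condition = labels[1]),
    dplyr::mutate(tidy(hist_b), condition = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_lower_mm + .data$bin_upper_mm) / 2,
    y = .data$percent, colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "nearest bone-to-skin distance [mm]",
                  y = "% of source vertices", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of signed skin-to-skin offsets
#'
#' Negative offsets (the other interface more compressive) are shown in
#' blue-red convention: compressive red, relaxed blue, matching heat-map
#' reading of comparison maps.
#'
#' @param object A `signed_comparison_field`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.signed_comparison_field <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !.data$boundary)
  df$region <- ifelse(df$signed_offset < 0, "more compressive", "more relaxed")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signed_offset,
                                   fill = .data$region)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::scale_fill_manual(values = c("more compressive" = "#b2182b",
                                          "more relaxed" = "#2166ac")) +
    ggplot2::labs(x = "signed skin offset [mm] (negative = other interface more compressive)",
                  y = "vertices", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ICP convergence trace
#' @param t A transform returned by [icp_refine()].
#' @return A ggplot of RMS against iteration.
#' @export
plot_icp_trace <- function(t) {
  df <- icp_trace(t)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$rms_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ICP iteration", y = "RMS correspondence error [mm]") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
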