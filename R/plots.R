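# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of subject x parcel decoding performance
#'
#' @param object a `decoding_result` tibble.
#' @param target which target to plot.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.decoding_result <- function(object, target = "rt", ...) {
  d <- object |> filter(.data$target == !!target, !.data$missing)
  ggplot(d, aes(x = .data$roi_id, y = .data$subject_id,
                fill = .data$r_aggregated)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, name = "r") +
    labs(x = "ROI", y = "subject",
         title = sprintf("Decoding performance (%s)", target)) +
    theme_minimal()
}

#' Sufficiency curve: performance and variability vs training fraction
#'
#' Mirrors the two-axis summary of the trial-number sufficiency test: mean
#' decoding performance (black) and across-repeat variability (red) as a
#' function of the training fraction, with the two optima marked.
#'
#' @param object a `sufficiency_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.sufficiency_curve <- function(object, ...) {
  opt <- optimal_fractions(object)
  scale <- max(object$mean_perf, na.rm = TRUE) /
    max(object$sd_perf, na.rm = TRUE)
  ggplot(object, aes(x = .data$fraction)) +
    geom_line(aes(y = .data$mean_perf)) +
    geom_point(aes(y = .data$mean_perf)) +
    geom_line(aes(y = .data$sd_perf * scale), colour = "firebrick") +
    geom_point(aes(y = .data$sd_perf * scale), colour = "firebrick") +
    geom_vline(xintercept = opt$min_variance_fraction,
               linetype = "dashed", colour = "darkgreen") +
    geom_vline(xintercept = opt$max_gap_fraction,
               linetype = "dashed", colour = "orange") +
    scale_y_continuous(
      name = "mean decoding performance (r)",
      sec.axis = sec_axis(~ . / scale, name = "across-repeat SD")) +
    labs(x = "training fraction",
         title = sprintf("Trial-number sufficiency (%s)",
                         attr(object, "target") %||% "")) +
    theme_minimal()
}

#' Coverage percentages across correction levels
#'
#' @param object a `coverage_summary`.
#' @param ... unused.
#' @return A ggplot of the percentage of parcels decodable in at least one
#'   subject, per target and correction level.
#' @export
autoplot.coverage_summary <- function(object, ...) {
  ggplot(object$rois_any_subject,
         aes(x = .data$level, y = .data$pct, fill = .data$target)) +
    geom_col(position = "dodge") +
    labs(x = "correction level", y = "% of ROIs with >= 1 significant subject") +
    theme_minimal()
}

#' Divergence percentages by network
#'
#' @param x a `divergence_result` with a network breakdown.
#' @param level correction level to show.
#' @return A ggplot of the percentage of each network's parcels flagged as
#'   carrying opposite-sign relationships.
#' @export
plot_divergence_networks <- function(x, level = "by_subjects") {
  stopifnot(!is.null(x$by_network))
  d <- x$by_network |> filter(.data$level == !!level)
  ggplot(d, aes(x = .data$network, y = .data$pct_divergent,
                fill = .data$target)) +
    geom_col(position = "dodge") +
    labs(x = "network", y = "% of network's ROIs divergent",
         title = sprintf("Opposite-sign ROIs by network (%s)", level)) +
    theme_minimal()
}
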