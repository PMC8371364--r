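# ggplot2 helpers for the result types. Tables are the contract; these are
# thin convenience layers.

#' Plot one or more per-frame metric series
#'
#' @param series A metric tibble from [rmsd_series()], [rgyr_series()],
#'   [line_angle_series()], [dfg_atp_distance_series()] or
#'   [sasa_region_series()], or several row-bound together (the `metric`
#'   column becomes the colour).
#' @return A ggplot.
#' @export
plot_metric_series <- function(series) {
  xvar <- if (all(is.na(series$time_ns))) "frame" else "time_ns"
  ggplot2::ggplot(series, ggplot2::aes(
    x = .data[[xvar]], y = .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "frame") "Frame" else "Time (ns)",
                  y = unique(series$units)[1]) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue RMSF profile
#'
#' @param profile A tibble from [rmsf_profile()]; several profiles may be
#'   row-bound with an extra `group` column for comparison.
#' @return A ggplot.
#' @export
plot_rmsf_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$res_seq,
                                             y = .data$value))
  if ("group" %in% names(profile)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "Residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}

#' Plot a bond presence timeline
#'
#' @param timeline A tibble from [bond_timeline()] (several bonds may be
#'   row-bound).
#' @return A ggplot with one row per bond.
#' @export
plot_bond_timeline <- function(timeline) {
  ggplot2::ggplot(timeline, ggplot2::aes(
    x = .data$frame, y = .data$bond, fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey20",
                                          `FALSE` = "grey90")) +
    ggplot2::labs(x = "Frame", y = NULL, fill = "Present") +
    ggplot2::theme_minimal()
}

#' Autoplot a group comparison
#'
#' Group means with standard-deviation error bars per metric, significant
#' contrasts starred.
#'
#' @param object An `md_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.md_comparison <- function(object, ...) {
  tab <- tidy(object)
  long <- dplyr::bind_rows(
    tibble(metric = tab$metric, group = object$labels[1],
           mean = tab$mean_a, sd = tab$sd_a),
    tibble(metric = tab$metric, group = object$labels[2],
           mean = tab$mean_b, sd = tab$sd_b))
  lab <- tibble(metric = tab$metric,
                star = ifelse(tab$significant, "*", ""))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(data = lab, inherit.aes = FALSE, x = 1.5,
                       y = Inf, vjust = 1.5,
                       ggplot2::aes(label = .data$star), size = 6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
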