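# Optional ggplot2 displays; the package's tables are the primary output.

#' Plot group abundance trajectories with LOESS ribbons
#'
#' @param rel_table A `rel_abundance`.
#' @param metadata Matching sample metadata.
#' @param taxon Taxon id to plot.
#' @param span LOESS span.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(rel_table, metadata, taxon, span = 0.75) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_trajectories requires the ggplot2 package")
  }
  md <- metadata[match(colnames(rel_table$fractions),
                       metadata$sample_id), ]
  traj <- loess_trajectory(md$age_days,
                           rel_table$fractions[taxon, ],
                           md$group, span = span)
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$age_days, y = .data$fit,
                                     colour = .data$group,
                                     fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit - .data$se,
                                      ymax = .data$fit + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (days)", y = "relative abundance",
                  title = taxon) +
    ggplot2::theme_minimal()
}

#' Plot the sliding-window p-value track for one taxon
#'
#' @param scan A [scan_windows()] result.
#' @param taxon Taxon id present in the scan.
#' @return A ggplot object with windows flagged at 0.05 and 0.01.
#' @export
plot_window_track <- function(scan, taxon) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_window_track requires the ggplot2 package")
  }
  m <- merge(scan$tests[scan$tests$taxon == taxon, ], scan$windows,
             by = "window_index")
  m$flag <- ifelse(m$sig01, "p < 0.01",
                   ifelse(m$sig05, "p < 0.05", "ns"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$median_age,
                                  y = -log10(.data$boot_p),
                                  colour = .data$flag)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window median age (days)",
                  y = "-log10 bootstrap-averaged p", title = taxon) +
    ggplot2::theme_minimal()
}
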