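# ggplot2 autoplot methods for the result objects.

#' Screen scatter with wild-type thresholds
#'
#' Strain summaries in the (volume ratio, intensity ratio) plane,
#' coloured by call, with dashed lines at the high and low thresholds.
#'
#' @param object a `screen_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  thr <- object$thresholds
  ggplot2::ggplot(object$hits,
                  ggplot2::aes(x = .data$median_volume_ratio,
                               y = .data$median_intensity_ratio,
                               colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(thr$volume[["high"]],
                                       thr$volume[["low"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = c(thr$intensity[["high"]],
                                       thr$intensity[["low"]]),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(data = object$wt_medians,
                        ggplot2::aes(x = .data$volume_ratio,
                                     y = .data$intensity_ratio),
                        inherit.aes = FALSE, shape = 21, fill = "white",
                        size = 2.5) +
    ggplot2::scale_colour_manual(values = c(high = "#D55E00",
                                            low = "#0072B2",
                                            normal = "grey60")) +
    ggplot2::labs(x = "median rDNA volume ratio",
                  y = "median rDNA intensity ratio",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' SGA fold-change heatmap
#'
#' Queries by candidate genes, filled by log2 Torin1/DMSO fold change;
#' unmeasured pairs are grey.
#'
#' @param object an `sga_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sga_result <- function(object, ...) {
  calls <- object$calls
  qlev <- c(object$resistant_queries, object$control_queries)
  calls$query_strain <- factor(calls$query_strain, levels = qlev)
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$query_strain,
                               y = .data$candidate_gene,
                               fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#0072B2", mid = "white",
                                  high = "#D55E00", midpoint = object$cutoff,
                                  na.value = "grey70") +
    ggplot2::labs(x = "query strain", y = "candidate gene",
                  fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Average FRAP recovery curve
#'
#' Mean normalized recovery with a +/- 1 SD ribbon.
#'
#' @param object a `frap_summary` from [average_recovery()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.frap_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(colour = "#009E73") +
    ggplot2::labs(x = "time (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of a scene channel
#'
#' Convenience display of a stack channel as a z maximum projection.
#'
#' @param stack an [image_stack()].
#' @param role channel role to project.
#' @return a ggplot object.
#' @export
plot_projection <- function(stack, role = "nuclear_gfp") {
  vol <- get_channel(stack, role)
  proj <- apply(vol, c(2, 3), max)
  df <- tidyr::expand_grid(y = seq_len(nrow(proj)), x = seq_len(ncol(proj)))
  df$intensity <- as.vector(proj)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = role) +
    ggplot2::theme_void()
}
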