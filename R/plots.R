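# ggplot2 figure builders for the main result types.

#' Plot an ECG strip with detected fiducials
#'
#' @param record ECG record (`time_ms`, `mv`).
#' @param fiducials Optional [delineate()] output to overlay.
#' @param window_ms Optional `c(from, to)` time window to display.
#' @return A ggplot object.
#' @export
plot_ecg <- function(record, fiducials = NULL, window_ms = NULL) {
  if (!is.null(window_ms)) {
    record <- dplyr::filter(record, .data$time_ms >= window_ms[1],
                            .data$time_ms <= window_ms[2])
  }
  p <- ggplot2::ggplot(record, ggplot2::aes(.data$time_ms, .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "mV")
  if (!is.null(fiducials)) {
    fid <- dplyr::filter(fiducials, .data$accepted)
    if (!is.null(window_ms)) {
      fid <- dplyr::filter(fid, .data$r_ms >= window_ms[1],
                           .data$r_ms <= window_ms[2])
    }
    long <- tidyr::pivot_longer(
      dplyr::select(fid, "beat", "p_on_ms", "q_on_ms", "r_ms", "s_end_ms",
                    "t_peak_ms", "t90_ms"),
      -"beat", names_to = "landmark", values_to = "time_ms"
    )
    p <- p + ggplot2::geom_vline(
      data = long,
      ggplot2::aes(xintercept = .data$time_ms, colour = .data$landmark),
      alpha = 0.6, linetype = "dashed"
    )
  }
  p
}

#' @export
autoplot.ecg_analysis <- function(object, window_ms = NULL, ...) {
  plot_ecg(object$filtered, object$fiducials, window_ms)
}

#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- object |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(time = c(0, .data$time), surv = c(1, .data$surv))
  ggplot2::ggplot(steps,
                  ggplot2::aes(.data$time, .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival S(t)")
}

#' Plot telomere-intensity distributions per group
#'
#' @param data Data frame with per-nucleus intensities.
#' @param intensity,group Column names.
#' @return A ggplot object (overlaid densities).
#' @export
plot_telomere_distributions <- function(data, intensity = "mean_cy3_auf",
                                        group = "group") {
  ggplot2::ggplot(data, ggplot2::aes(.data[[intensity]],
                                     fill = .data[[group]])) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(x = "per-nucleus mean Cy3 (auf)", y = "density")
}

#' @export
autoplot.heatmap_matrix <- function(object, ...) {
  z <- object$z[object$row_order, object$col_order, drop = FALSE]
  df <- tibble(
    gene_id = factor(rep(rownames(z), ncol(z)), levels = rev(rownames(z))),
    sample_id = factor(rep(colnames(z), each = nrow(z)), levels = colnames(z)),
    z = as.vector(z)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_id, .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}

#' Volcano plot of differential-expression results
#'
#' @param results [fold_changes()] output.
#' @param fc_min,p_max Thresholds to display.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, fc_min = 2, p_max = 0.05) {
  results <- dplyr::mutate(
    results,
    pass = (.data$fc >= fc_min | .data$fc <= 1 / fc_min) & .data$p <= p_max
  )
  ggplot2::ggplot(results, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                        colour = .data$pass)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
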