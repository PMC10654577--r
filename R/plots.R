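#' Spatial map of spot classifications
#'
#' @param spot_metrics Labelled spot tibble from [classify_spots()].
#' @param spot_table Spot tibble providing coordinates.
#' @param graph Optional `spot_graph`; when given, its edges are drawn
#'   underneath the spots.
#' @return A ggplot object.
#' @export
plot_spot_map <- function(spot_metrics, spot_table, graph = NULL) {
  df <- left_join(spot_metrics, spot_table[, c("barcode", "x", "y")], by = "barcode")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(graph)) {
    seg <- graph$edges |>
      left_join(graph$nodes, by = c(from = "barcode")) |>
      rename(x0 = "x", y0 = "y") |>
      left_join(graph$nodes, by = c(to = "barcode"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y),
      colour = "grey85", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(
      colour = .data$label,
      size = .data$total_tcr_umis
    )) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      colour = "niche", size = "TCR UMIs",
      title = "Spot classification"
    ) +
    ggplot2::theme_minimal()
}

#' Clone abundance versus spatial extension
#'
#' Scatter of per-clone total UMIs against the number of occupied spots,
#' coloured by clonality index when clone statistics are supplied.
#'
#' @param clones A `tcr_clones` object.
#' @param clone_stats Optional output of [clonality_index()].
#' @return A ggplot object.
#' @export
plot_clone_abundance <- function(clones, clone_stats = NULL) {
  df <- as_tibble(clones)
  if (!is.null(clone_stats)) {
    df <- left_join(df, clone_stats[, c("clone_id", "clonality_index")],
      by = "clone_id"
    )
    aes <- ggplot2::aes(
      x = .data$total_umis, y = .data$n_spots,
      colour = .data$clonality_index
    )
  } else {
    aes <- ggplot2::aes(x = .data$total_umis, y = .data$n_spots)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "clone UMIs", y = "spots occupied",
      colour = "clonality\nindex",
      title = "Clonal abundance vs spatial extension"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Density plot of per-read error rates before/after correction
#'
#' @param object An `error_report` (typically post-correction).
#' @param pre Optional second `error_report` measured before correction.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_report <- function(object, pre = NULL, ...) {
  df <- mutate(object$per_read, set = "corrected")
  if (!is.null(pre)) {
    df <- bind_rows(df, mutate(pre$per_read, set = "uncorrected"))
  }
  df <- filter(df, !is.na(.data$error_rate))
  ggplot2::ggplot(df, ggplot2::aes(
    x = 100 * .data$error_rate,
    fill = .data$set
  )) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      x = "per-read error rate (%)", y = "density", fill = NULL,
      title = "Error rate vs constant-region references"
    ) +
    ggplot2::theme_minimal()
}
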