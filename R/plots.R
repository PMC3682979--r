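#' Plot cluster center profiles
#'
#' One panel per cluster showing the center's Z-scale temporal profile.
#'
#' @param object A [fuzzy_cmeans()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuzzy_clustering <- function(object, ...) {
  d <- as_tibble(object$centers, rownames = "cluster") %>%
    tidyr::pivot_longer(-"cluster", names_to = "time", values_to = "center") %>%
    mutate(time = as_time_axis(.data$time))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$center, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time", y = "Z-scale expression",
                  title = sprintf("Cluster centers (c = %d, m = %.3g)",
                                  object$c, object$m))
}

as_time_axis <- function(labels) {
  h <- suppressWarnings(as.numeric(labels))
  if (anyNA(h)) factor(labels, levels = unique(labels)) else h
}

#' Plot TF utilization trajectories
#'
#' Per-family fraction of TFs called present over time, with the overall
#' fraction as a dashed reference; optionally marks the onset of
#' gastrulation.
#'
#' @param object A [family_representation()] result.
#' @param gastrulation Optional time label or numeric hour where
#'   gastrulation starts (drawn as a grey vertical line).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.utilization_profile <- function(object, gastrulation = NULL, ...) {
  d <- mutate(as_tibble(object), time = as_time_axis(.data$time))
  overall <- mutate(attr(object, "overall"), time = as_time_axis(.data$time))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$fraction,
                                       colour = .data$family, group = .data$family)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = overall,
                       ggplot2::aes(x = .data$time, y = .data$fraction, group = 1),
                       inherit.aes = FALSE, linetype = "dashed") +
    ggplot2::labs(x = "time", y = "fraction expressed",
                  title = sprintf("TF utilization (%s)", attr(object, "species")))
  if (!is.null(gastrulation)) {
    g <- if (is.numeric(gastrulation)) gastrulation
         else as_time_axis(gastrulation)
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(g), colour = "grey50")
  }
  p
}

#' Heatmap of the cross-species stage-distance matrix
#'
#' @param object A [stage_distance_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object (darker = more similar).
#' @export
autoplot.stage_distance <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(time_a = factor(.data$time_a, levels = rownames(object$matrix)),
           time_b = factor(.data$time_b, levels = colnames(object$matrix)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_b, y = .data$time_a,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = object$species_b, y = object$species_a,
                  fill = "distance",
                  title = "TF transcriptome distance between stages")
}

#' Plot a minimum-distance profile
#'
#' @param object A [min_distance_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.min_distance_profile <- function(object, ...) {
  d <- mutate(as_tibble(object), time = as_time_axis(.data$time))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$min_distance, group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("time (%s)", attr(object, "species")),
                  y = "minimum distance to other species")
}

#' Histogram of a permutation null with the observed value marked
#'
#' @param object A `perm_null` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "null sets",
                  title = sprintf("Z = %.2f, empirical p = %.4g",
                                  object$z_score, object$empirical_p))
}

#' Dendrogram of the combined cluster centers
#'
#' @param x A [pair_clusters()] result.
#' @param ... Passed to [plot()].
#' @export
plot.cluster_pairing <- function(x, ...) {
  plot(stats::as.dendrogram(x$tree),
       main = "Hierarchical clustering of cluster centers", ...)
  invisible(x)
}
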