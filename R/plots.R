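#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster plot of a spike record
#'
#' @param object a `spike_record`.
#' @param frac fraction of neurons to show (random thinning by neuron id).
#' @param areas optional subset of areas.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spike_record <- function(object, frac = 0.025, areas = NULL, ...) {
  idx <- neuron_index(object)
  sp <- dplyr::left_join(object$spikes, idx, by = "neuron_id")
  if (!is.null(areas)) sp <- sp[sp$area %in% areas, ]
  keep <- unique(sp$neuron_id)
  keep <- keep[(seq_along(keep) %% ceiling(1 / frac)) == 0]
  sp <- sp[sp$neuron_id %in% keep, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$time_ms, y = .data$neuron_id,
                                   colour = .data$ei)) +
    ggplot2::geom_point(shape = ".", alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(E = "#2166ac", I = "#b2182b")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$area), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a functional-connectivity matrix
#'
#' @param object a `functional_connectivity` matrix.
#' @param ... unused.
#' @export
autoplot.functional_connectivity <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "fc"))
  names(df)[1:2] <- c("area_1", "area_2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area_1, y = .data$area_2,
                                   fill = .data$fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Distance-decay scatter of a validation report
#'
#' Log synapse count per area pair against inter-areal distance with the
#' fitted exponential decay.
#'
#' @param object a `validation_report`.
#' @param ... unused.
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- object$decay_data
  lam <- object$distance_decay$lambda_mm
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_mm,
                                        y = log(.data$n_synapses))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "distance (mm)", y = "ln synapses per area pair") +
    ggplot2::theme_minimal()
  if (is.finite(lam)) {
    b <- mean(log(df$n_synapses) + df$distance_mm / lam)
    p <- p + ggplot2::geom_abline(intercept = b, slope = -1 / lam,
                                  colour = "black")
  }
  p
}

#' Arrival times of a perturbation across areas
#'
#' @param object a `propagation_trace`.
#' @param ... unused.
#' @export
autoplot.propagation_trace <- function(object, ...) {
  df <- object$per_area |>
    dplyr::arrange(.data$first_diff_ms) |>
    dplyr::mutate(area = factor(.data$area, levels = .data$area))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$first_diff_ms, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "first spike-count difference (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Delay-matrix heatmap of a temporal-hierarchy estimate
#'
#' Areas ordered from most leading to most lagging; undecided pairs blank.
#'
#' @param object a `hierarchy_estimate`.
#' @param ... unused.
#' @export
autoplot.hierarchy_estimate <- function(object, ...) {
  m <- object$delay_ms[object$ordering, object$ordering]
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "delay_ms"))
  names(df)[1:2] <- c("source", "target")
  df$source <- factor(df$source, levels = object$ordering)
  df$target <- factor(df$target, levels = rev(object$ordering))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data$delay_ms)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "delay (ms)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
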