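#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(statistic = "log10_count_mean", class = NA_character_,
                   value = x$lognormal_fit$meanlog10),
    tibble::tibble(statistic = "log10_count_sd", class = NA_character_,
                   value = x$lognormal_fit$sdlog10),
    tibble::tibble(statistic = "decay_lambda_mm", class = NA_character_,
                   value = x$distance_decay$lambda_mm),
    tibble::tibble(statistic = "mean_outdegree",
                   class = as.character(x$outdegree_stats$class),
                   value = x$outdegree_stats$mean_outdegree),
    tibble::tibble(statistic = "mean_outdegree_surface_corrected",
                   class = as.character(x$outdegree_stats$class),
                   value = x$outdegree_stats$mean_outdegree_corrected),
    tibble::tibble(statistic = "mean_target_areas",
                   class = as.character(x$target_area_stats$class),
                   value = x$target_area_stats$mean_target_areas),
    tibble::tibble(statistic = "max_shortest_path", class = NA_character_,
                   value = as.numeric(x$path_stats$max_unweighted)),
    tibble::tibble(statistic = "max_dijkstra_delay_ms",
                   class = NA_character_,
                   value = x$path_stats$max_delay_ms)
  )
}

#' @export
glance.validation_report <- function(x, ...) {
  od <- function(cls) {
    v <- x$outdegree_stats$mean_outdegree[x$outdegree_stats$class == cls]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    lambda_mm = x$distance_decay$lambda_mm,
    log10_count_mean = x$lognormal_fit$meanlog10,
    log10_count_sd = x$lognormal_fit$sdlog10,
    ff_outdegree = od("FF"),
    fb_outdegree = od("FB"),
    max_path = as.numeric(x$path_stats$max_unweighted),
    max_dijkstra_ms = x$path_stats$max_delay_ms
  )
}

#' @export
tidy.spike_record <- function(x, transient_ms = 0, ...) {
  spike_statistics(x, transient_ms = transient_ms, ...) |>
    dplyr::group_by(.data$area, .data$layer, .data$ei) |>
    dplyr::summarise(
      n_neurons = dplyr::n(),
      rate = mean(.data$rate),
      cv_isi = mean(.data$cv_isi, na.rm = TRUE),
      lvr = mean(.data$lvr, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @export
glance.spike_record <- function(x, ...) {
  n <- sum(x$populations$size)
  tibble::tibble(
    n_neurons = n,
    n_spikes = nrow(x$spikes),
    duration_ms = x$duration_ms,
    mean_rate = nrow(x$spikes) / n / (x$duration_ms / 1000)
  )
}

#' @export
tidy.hierarchy_estimate <- function(x, ...) {
  tibble::tibble(area = x$ordering, rank = seq_along(x$ordering))
}

#' @export
glance.hierarchy_estimate <- function(x, ...) {
  tibble::tibble(
    n_areas = length(x$ordering),
    n_undecided = x$n_undecided,
    alpha_ms_per_rank = x$alpha_ms_per_rank,
    sse = x$sse
  )
}

#' @export
tidy.propagation_trace <- function(x, ...) {
  x$per_area
}

#' @export
glance.propagation_trace <- function(x, ...) {
  tibble::tibble(
    mean_ms = x$mean_ms, sd_ms = x$sd_ms,
    n_unreached = x$n_unreached,
    no_propagation = x$no_propagation
  )
}
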