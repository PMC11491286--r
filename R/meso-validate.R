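#' Population-level projection table of a connectome
#'
#' Aggregates the long synapse table to one row per (source population,
#' target population) pair with population ids, areas, synapse count, and the
#' mean transmission delay (local excitatory/inhibitory delay within an area;
#' fiber length over conduction velocity between areas).
#'
#' @param conn a [assemble_connectome()] result.
#' @param delays a [delay_params()] list.
#' @return A tibble with columns `src_pop_id`, `tgt_pop_id`, `source_area`,
#'   `target_area`, `source_ei`, `n_synapses`, `d_mean_ms`.
#' @export
connectome_projections <- function(conn, delays = delay_params()) {
  grid <- conn$grid
  key <- stats::setNames(grid$pop_id,
                         paste(grid$area, grid$layer, grid$ei))
  syn <- conn$synapses
  src_id <- unname(key[paste(syn$source_area, syn$source_layer,
                             syn$source_ei)])
  tgt_id <- unname(key[paste(syn$target_area, syn$target_layer,
                             syn$target_ei)])
  fib <- conn$bundle$fiber_length_mm
  inter <- syn$source_area != syn$target_area
  d_mean <- ifelse(
    inter,
    fib[cbind(syn$source_area, syn$target_area)] / delays$v_t,
    ifelse(syn$source_ei == "E", delays$d_e, delays$d_i)
  )
  tibble::tibble(
    src_pop_id = src_id, tgt_pop_id = tgt_id,
    source_area = syn$source_area, target_area = syn$target_area,
    source_ei = syn$source_ei,
    n_synapses = syn$n_synapses, d_mean_ms = d_mean
  ) |>
    dplyr::group_by(.data$src_pop_id, .data$tgt_pop_id) |>
    dplyr::summarise(
      source_area = dplyr::first(.data$source_area),
      target_area = dplyr::first(.data$target_area),
      source_ei = dplyr::first(.data$source_ei),
      n_synapses = sum(.data$n_synapses),
      d_mean_ms = dplyr::first(.data$d_mean_ms),
      .groups = "drop"
    )
}

#' Structural validation statistics of a connectome
#'
#' Computes the statistics used to compare the assembled mesoconnectome
#' against regularities of tracing data that were not built in:
#'
#' * a log-normal fit (mean and SD of `log10` counts) over the nonzero
#'   population-pair synapse counts;
#' * the exponential distance decay of area-pair synapse counts (ordinary
#'   least squares of `log` count on fiber length; decay constant =
#'   `-1/slope`);
#' * mean outdegrees of inter-areal projections per direction class
#'   (feedforward / lateral / feedback by predicted SLN, boundary values
#'   counting as lateral), plus the variant corrected by the source/target
#'   surface ratio (applied per projection, then averaged);
#' * the mean number of target areas per source population and direction
#'   class, counting only projections with outdegree above
#'   `outdegree_filter` (filter applied before classification);
#' * shortest-path statistics of the directed population graph: unweighted
#'   path lengths and mean-delay-weighted Dijkstra path lengths.
#'
#' @param conn a [assemble_connectome()] result.
#' @param delays [delay_params()] for the mean-delay edge weights.
#' @param outdegree_filter outdegree threshold of the target-area statistic.
#' @return A list of class `validation_report`.
#' @export
validate_connectome <- function(conn, delays = delay_params(),
                                outdegree_filter = 100) {
  proj <- connectome_projections(conn, delays)
  if (sum(proj$n_synapses > 0) < 3L) {
    stop("fewer than 3 nonzero population pairs: nothing to fit")
  }
  grid <- conn$grid

  lognormal_fit <- tibble::tibble(
    meanlog10 = mean(log10(proj$n_synapses[proj$n_synapses > 0])),
    sdlog10 = stats::sd(log10(proj$n_synapses[proj$n_synapses > 0])),
    n_pairs = sum(proj$n_synapses > 0)
  )

  area_pairs <- proj |>
    dplyr::filter(.data$source_area != .data$target_area) |>
    dplyr::group_by(.data$source_area, .data$target_area) |>
    dplyr::summarise(n_synapses = sum(.data$n_synapses), .groups = "drop")
  fib <- conn$bundle$fiber_length_mm
  decay <- if (nrow(area_pairs) >= 3L) {
    m <- matrix(0, nrow(fib), ncol(fib), dimnames = dimnames(fib))
    m[cbind(area_pairs$source_area, area_pairs$target_area)] <-
      area_pairs$n_synapses
    fit_distance_decay(m, fib) |>
      dplyr::select(lambda_mm = "lambda_mm", r_squared = "r_squared",
                    n_pairs = "n_pairs")
  } else {
    tibble::tibble(lambda_mm = NA_real_, r_squared = NA_real_, n_pairs = 0L)
  }

  # outdegree and target-area statistics over inter-areal projections --------
  surf <- conn$bundle$areas |>
    dplyr::distinct(.data$area, .data$surface_mm2)
  surf_v <- stats::setNames(surf$surface_mm2, surf$area)
  size_v <- stats::setNames(grid$size, grid$pop_id)
  area_of_pop <- stats::setNames(grid$area, grid$pop_id)

  inter <- proj |>
    dplyr::filter(.data$source_area != .data$target_area,
                  .data$n_synapses > 0) |>
    dplyr::group_by(.data$src_pop_id, .data$target_area) |>
    dplyr::summarise(n_synapses = sum(.data$n_synapses), .groups = "drop") |>
    dplyr::mutate(
      source_area = unname(area_of_pop[as.character(.data$src_pop_id)]),
      outdegree = .data$n_synapses /
        unname(size_v[as.character(.data$src_pop_id)]),
      outdegree_corrected = .data$outdegree *
        unname(surf_v[.data$source_area] / surf_v[.data$target_area]),
      sln = conn$sln[cbind(.data$source_area, .data$target_area)],
      class = sln_class(.data$sln, conn$bundle$constants)
    )

  outdegree_stats <- inter |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      mean_outdegree = mean(.data$outdegree),
      mean_outdegree_corrected = mean(.data$outdegree_corrected),
      n_projections = dplyr::n(),
      .groups = "drop"
    )

  target_area_stats <- inter |>
    dplyr::filter(.data$outdegree > outdegree_filter) |>
    dplyr::group_by(.data$src_pop_id, class = .data$class) |>
    dplyr::summarise(n_target_areas = dplyr::n_distinct(.data$target_area),
                     .groups = "drop") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(mean_target_areas = mean(.data$n_target_areas),
                     n_source_populations = dplyr::n(), .groups = "drop")

  path_stats <- population_path_stats(proj, grid)

  decay_data <- area_pairs |>
    dplyr::mutate(distance_mm =
                    fib[cbind(.data$source_area, .data$target_area)]) |>
    dplyr::filter(.data$n_synapses > 0)

  structure(
    list(lognormal_fit = lognormal_fit, distance_decay = decay,
         outdegree_stats = outdegree_stats,
         target_area_stats = target_area_stats,
         path_stats = path_stats, decay_data = decay_data),
    class = "validation_report"
  )
}

#' Classify projections by SLN
#'
#' Feedforward above the upper threshold, feedback below the lower one,
#' lateral in between (boundary values inclusive to lateral).
#' @param sln SLN values.
#' @param constants [model_constants()].
#' @return Factor with levels `FF`, `LAT`, `FB`.
#' @export
sln_class <- function(sln, constants = model_constants()) {
  factor(
    ifelse(sln > constants$sln_ff_threshold, "FF",
           ifelse(sln < constants$sln_fb_threshold, "FB", "LAT")),
    levels = c("FF", "LAT", "FB")
  )
}

# Shortest-path statistics of the directed population graph (present
# populations only); edges carry the mean transmission delay.
population_path_stats <- function(proj, grid) {
  present <- grid$pop_id[grid$present]
  edges <- proj[proj$n_synapses > 0 &
                  proj$src_pop_id %in% present &
                  proj$tgt_pop_id %in% present, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$src_pop_id),
               to = as.character(edges$tgt_pop_id)),
    vertices = data.frame(name = as.character(present))
  )
  du <- igraph::distances(g, mode = "out", weights = NA)
  dw <- igraph::distances(g, mode = "out",
                          weights = edges$d_mean_ms)
  offdiag <- row(du) != col(du)
  finite_u <- du[offdiag & is.finite(du)]
  finite_w <- dw[offdiag & is.finite(dw)]
  list(
    max_unweighted = if (length(finite_u)) max(finite_u) else NA_real_,
    unweighted_hist = tibble::as_tibble(table(path_length = finite_u)),
    max_delay_ms = if (length(finite_w)) max(finite_w) else NA_real_,
    mean_delay_ms = if (length(finite_w)) mean(finite_w) else NA_real_,
    n_pairs = sum(offdiag),
    n_unreachable = sum(offdiag & !is.finite(du))
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  log10 synapse counts: %.2f +- %.2f over %d pairs\n",
              x$lognormal_fit$meanlog10, x$lognormal_fit$sdlog10,
              x$lognormal_fit$n_pairs))
  cat(sprintf("  distance decay: lambda = %.1f mm (R^2 = %.2f)\n",
              x$distance_decay$lambda_mm, x$distance_decay$r_squared))
  od <- x$outdegree_stats
  for (i in seq_len(nrow(od))) {
    cat(sprintf("  mean outdegree %s: %.0f (surface-corrected %.0f)\n",
                od$class[i], od$mean_outdegree[i],
                od$mean_outdegree_corrected[i]))
  }
  cat(sprintf("  max shortest path: %s steps; max Dijkstra delay: %.1f ms\n",
              format(x$path_stats$max_unweighted),
              x$path_stats$max_delay_ms))
  invisible(x)
}
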