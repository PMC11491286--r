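#' Track the propagation of a single-spike perturbation
#'
#' Compares the two spike records of a paired run: spike counts per
#' population are binned at the simulation resolution and subtracted; the
#' first bin with a nonzero difference marks the arrival of the
#' perturbation's effect in that population. Per area, the arrival time is
#' the earliest arrival over its populations.
#'
#' @param pair a `paired_spike_records` object (or a list with elements
#'   `unperturbed` and `perturbed`).
#' @param bin_ms difference bin, ms (defaults to the simulation step).
#' @return A list of class `propagation_trace`: `per_population` (tibble
#'   `pop_index`, `area`, `layer`, `ei`, `first_diff_ms`), `per_area` (tibble
#'   `area`, `first_diff_ms`), `mean_ms`, `sd_ms`, `n_unreached`,
#'   `no_propagation` (TRUE when the records are identical).
#' @export
perturbation_propagation <- function(pair, bin_ms = NULL) {
  u <- pair$unperturbed
  p <- pair$perturbed
  if (is.null(bin_ms)) bin_ms <- u$dt
  stopifnot(u$duration_ms == p$duration_ms)
  pops <- u$populations
  idx <- neuron_index(u)
  pop_of <- idx$pop_index
  nbins <- ceiling(u$duration_ms / bin_ms)

  bin_of <- function(rec) {
    b <- pmin(pmax(ceiling(rec$spikes$time_ms / bin_ms), 1L), nbins)
    cbind(pop_of[rec$spikes$neuron_id], b)
  }
  first_diff <- rep(NA_real_, nrow(pops))
  cu <- bin_of(u)
  cp <- bin_of(p)
  # sparse difference: tabulate per (population, bin) and subtract
  key_u <- paste(cu[, 1], cu[, 2])
  key_v <- paste(cp[, 1], cp[, 2])
  tu <- table(key_u)
  tv <- table(key_v)
  keys <- union(names(tu), names(tv))
  du <- as.numeric(tu[keys])
  dv <- as.numeric(tv[keys])
  du[is.na(du)] <- 0
  dv[is.na(dv)] <- 0
  diffkeys <- keys[du != dv]
  if (length(diffkeys)) {
    parts <- do.call(rbind, strsplit(diffkeys, " "))
    popi <- as.integer(parts[, 1])
    bini <- as.integer(parts[, 2])
    agg <- tapply(bini, popi, min)
    first_diff[as.integer(names(agg))] <- as.numeric(agg) * bin_ms
  }

  per_population <- tibble::tibble(
    pop_index = pops$pop_index, area = pops$area, layer = pops$layer,
    ei = pops$ei, first_diff_ms = first_diff
  )
  per_area <- per_population |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(
      first_diff_ms = if (all(is.na(.data$first_diff_ms))) NA_real_
        else min(.data$first_diff_ms, na.rm = TRUE),
      .groups = "drop"
    )
  reached <- per_area$first_diff_ms[is.finite(per_area$first_diff_ms)]
  structure(
    list(
      per_population = per_population,
      per_area = per_area,
      mean_ms = if (length(reached)) mean(reached) else NA_real_,
      sd_ms = if (length(reached) > 1) stats::sd(reached) else NA_real_,
      n_unreached = sum(is.na(per_area$first_diff_ms)),
      no_propagation = length(diffkeys) == 0,
      bin_ms = bin_ms
    ),
    class = "propagation_trace"
  )
}

#' @export
print.propagation_trace <- function(x, ...) {
  if (x$no_propagation) {
    cat("<propagation_trace> no propagation: records are identical\n")
  } else {
    cat(sprintf(
      "<propagation_trace> first difference %.1f +- %.1f ms across areas (%d unreached)\n",
      x$mean_ms, x$sd_ms, x$n_unreached
    ))
  }
  invisible(x)
}

#' Causal lower bound on perturbation arrival times
#'
#' Dijkstra shortest paths on the population graph of a realized network with
#' each projection weighted by its *minimum realized* delay (see
#' [projection_min_delays()]). No effect of a perturbation of a neuron in the
#' source population can appear in another population earlier than this bound
#' after the perturbation time.
#'
#' @param net a [lif_network()].
#' @param source_pop index (row of `net$populations`) of the perturbed
#'   population.
#' @return A tibble `pop_index`, `area`, `bound_ms` (Inf if unreachable).
#' @export
propagation_delay_bounds <- function(net, source_pop) {
  proj <- projection_min_delays(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = proj$src, to = proj$tgt, weight = proj$d_min_ms),
    vertices = data.frame(name = seq_len(nrow(net$populations)))
  )
  d <- igraph::distances(g, v = as.character(source_pop), mode = "out")[1, ]
  tibble::tibble(
    pop_index = seq_len(nrow(net$populations)),
    area = net$populations$area,
    bound_ms = as.numeric(d[as.character(seq_len(nrow(net$populations)))])
  )
}
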