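#' Population sizes of the simulated columns
#'
#' Computes the neuron count of every (area, layer, E/I) population from the
#' layer-resolved volume density, layer thickness and column surface:
#' `N = round(rho * h * A_column)`, split into excitatory and inhibitory
#' neurons by the layer's excitatory fraction (`N_E = round(N * f_E)`,
#' `N_I = N - N_E`). Populations with zero neurons (absent layers of
#' agranular areas) are retained and flagged.
#'
#' @param bundle an [anatomy_bundle()].
#' @return A tibble of class `population_grid` with columns `pop_id`, `area`,
#'   `area_id`, `layer`, `ei`, `population` (e.g. `"4E"`), `size`, `present`,
#'   ordered by area (bundle order) and population (2/3E, 2/3I, ..., 6I).
#' @export
#' @examples
#' grid <- compute_population_sizes(synth_anatomy(1, n_areas = 3))
#' sum(grid$size)
compute_population_sizes <- function(bundle) {
  a_col <- bundle$constants$column_area
  nm <- bundle_area_names(bundle)
  rows <- bundle$areas |>
    dplyr::filter(.data$layer != "1") |>
    dplyr::mutate(
      n_layer = round(.data$density_per_mm3 * .data$thickness_mm * a_col),
      n_e = round(.data$n_layer * .data$exc_fraction),
      n_i = .data$n_layer - .data$n_e
    )
  grid <- rows |>
    dplyr::select("area", "layer", "n_e", "n_i") |>
    tidyr::pivot_longer(c("n_e", "n_i"), names_to = "ei", values_to = "size") |>
    dplyr::mutate(ei = ifelse(.data$ei == "n_e", "E", "I"),
                  population = paste0(.data$layer, .data$ei),
                  area_id = match(.data$area, nm)) |>
    dplyr::arrange(.data$area_id, match(.data$population, .pops8)) |>
    dplyr::mutate(pop_id = dplyr::row_number(),
                  present = .data$size > 0) |>
    dplyr::select("pop_id", "area", "area_id", "layer", "ei",
                  "population", "size", "present")
  class(grid) <- c("population_grid", class(grid))
  grid
}

#' Total synapse budget of an area
#'
#' The number of synapses in the modeled column of an area follows from the
#' (approximately cortex-wide constant) synapse volume density and the column
#' volume: `N = round(rho_synapse * A_column * sum(h_layer))`, including the
#' layer-1 thickness when present.
#'
#' @param bundle an [anatomy_bundle()].
#' @param area area name.
#' @return Number of synapses (double, counts can exceed 2^31).
#' @export
compute_area_synapse_budget <- function(bundle, area) {
  if (!area %in% bundle$areas$area) stop("unknown area: ", area)
  round(bundle$constants$rho_synapse * bundle$constants$column_area *
          area_height(bundle, area))
}

#' Fraction of synapses from long-range (white-matter) projections
#'
#' The relative number of neurons sending axons into the white matter scales
#' as a power law of the total gray-matter neuron count. Calibrated with a
#' macaque tracing estimate (fraction `calib_fraction` at `calib_neurons`
#' neurons) and evaluated at the human count, this gives the fraction of
#' nonlocal synapses under the assumption that the neuron fraction equals the
#' synapse fraction:
#' `f = calib_fraction * (calib_neurons / human_neurons)^scaling_exponent`.
#'
#' @param constants a [model_constants()] list.
#' @return Fraction in (0, 1).
#' @export
#' @examples
#' round(nonlocal_fraction(model_constants()), 2) # 0.14
nonlocal_fraction <- function(constants = model_constants()) {
  f <- constants$calib_fraction *
    (constants$calib_neurons / constants$human_neurons)^constants$scaling_exponent
  stopifnot(f > 0, f <= 1)
  f
}
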