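#' Aggregate cytoarchitectonic sub-areas onto a target parcel
#'
#' Collapses layer-resolved thickness/density measurements from one or more
#' cytoarchitectonic sub-areas (e.g. the von Economo-Koskinas areas mapped to
#' one Desikan-Killiany parcel) onto the model's layer scheme. Within each
#' sub-area, rows sharing a model layer (finer sub-layers) are first combined:
#' thicknesses are summed and densities averaged weighted by the sub-layer
#' thickness. Across sub-areas, the layer thickness is the unweighted mean and
#' the density the thickness-weighted mean.
#'
#' @param sub_areas tibble with columns `sub_area`, `layer`, `thickness_mm`,
#'   `density_per_mm3`. `layer` names the model layer each measured (sub-)layer
#'   belongs to; several rows per (sub_area, layer) are allowed.
#' @return A tibble with columns `layer`, `thickness_mm`, `density_per_mm3`,
#'   one row per layer present in the input.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   sub_area = c("a", "b"), layer = "4",
#'   thickness_mm = c(1, 1), density_per_mm3 = c(10, 30)
#' )
#' aggregate_vek_to_dk(x) # density 20
aggregate_vek_to_dk <- function(sub_areas) {
  need <- c("sub_area", "layer", "thickness_mm", "density_per_mm3")
  if (!all(need %in% names(sub_areas))) {
    stop("sub_areas needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(sub_areas) == 0L) stop("sub_areas is empty")
  if (any(sub_areas$thickness_mm < 0) || any(sub_areas$density_per_mm3 < 0)) {
    stop("thicknesses and densities must be nonnegative")
  }
  zero_thick <- sub_areas$thickness_mm == 0 & sub_areas$density_per_mm3 > 0
  if (any(zero_thick)) {
    stop("zero thickness with nonzero density in sub-area ",
         sub_areas$sub_area[which(zero_thick)[1]])
  }

  per_sub <- sub_areas |>
    dplyr::group_by(.data$sub_area, .data$layer) |>
    dplyr::summarise(
      density_per_mm3 = ifelse(
        sum(.data$thickness_mm) > 0,
        sum(.data$thickness_mm * .data$density_per_mm3) /
          sum(.data$thickness_mm),
        0
      ),
      thickness_mm = sum(.data$thickness_mm),
      .groups = "drop"
    )

  per_sub |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      density_per_mm3 = ifelse(
        sum(.data$thickness_mm) > 0,
        sum(.data$thickness_mm * .data$density_per_mm3) /
          sum(.data$thickness_mm),
        0
      ),
      thickness_mm = mean(.data$thickness_mm),
      .groups = "drop"
    ) |>
    dplyr::select("layer", "thickness_mm", "density_per_mm3")
}
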