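#' Construct an anatomy bundle
#'
#' Bundles every anatomical input the connectome builder consumes: per-area
#' layer thicknesses, neuron volume densities, excitatory fractions and
#' surface areas; the inter-areal streamline-count (NoS) and fiber-length
#' matrices; the local-circuit blueprint; the dendritic-length profile; the
#' SLN fit parameters; and the model constants. All invariants are checked.
#'
#' @param areas tibble with columns `area`, `layer` (among `"1"`, `"2/3"`,
#'   `"4"`, `"5"`, `"6"`; layer 1 rows are optional and carry no neurons),
#'   `thickness_mm`, `density_per_mm3`, `exc_fraction`, `surface_mm2`.
#' @param nos numeric area-by-area matrix of streamline counts, rows = source
#'   area, columns = target area; the diagonal is ignored by all consumers.
#' @param fiber_length_mm symmetric area-by-area matrix of inter-areal fiber
#'   lengths in mm (median vertex-pair distance).
#' @param blueprint a [blueprint_pd()]-shaped local blueprint.
#' @param dendrites 5x4 dendritic-length matrix, rows = synapse layers
#'   1, 2/3, 4, 5, 6, columns = soma layers 2/3, 4, 5, 6.
#' @param sln_fit list with probit fit parameters `a0`, `a1` (see
#'   [sln_fit_params()]).
#' @param constants a [model_constants()] list.
#'
#' @return A list of class `anatomy_bundle`.
#' @export
anatomy_bundle <- function(areas, nos, fiber_length_mm,
                           blueprint = blueprint_pd(),
                           dendrites = dendritic_profile_synthetic(),
                           sln_fit = sln_fit_params(),
                           constants = model_constants()) {
  bundle <- structure(
    list(
      areas = tibble::as_tibble(areas),
      nos = nos,
      fiber_length_mm = fiber_length_mm,
      blueprint = blueprint,
      dendrites = dendrites,
      sln_fit = sln_fit,
      constants = constants
    ),
    class = "anatomy_bundle"
  )
  validate_anatomy_bundle(bundle)
}

#' SLN probit-fit parameters
#'
#' Parameters of the probit model relating the fraction of supragranular
#' labeled neurons (SLN) of a projection to the log-ratio of target and
#' source area neuron densities. Defaults are the macaque beta-binomial fit
#' values used for predictive connectomics in human.
#'
#' @param a0,a1 intercept and slope on the probit scale.
#' @return A list of class `sln_fit_params`.
#' @export
sln_fit_params <- function(a0 = -0.152, a1 = -1.534) {
  if (!is.finite(a0) || !is.finite(a1)) stop("SLN fit parameters must be finite")
  structure(list(a0 = a0, a1 = a1), class = "sln_fit_params")
}

#' @export
print.anatomy_bundle <- function(x, ...) {
  n <- length(bundle_area_names(x))
  cat("<anatomy_bundle>", n, "areas,",
      nrow(x$areas), "(area, layer) rows\n")
  invisible(x)
}

bundle_area_names <- function(bundle) {
  unique(bundle$areas$area)
}

validate_anatomy_bundle <- function(bundle) {
  areas <- bundle$areas
  need <- c("area", "layer", "thickness_mm", "density_per_mm3",
            "exc_fraction", "surface_mm2")
  missing_cols <- setdiff(need, names(areas))
  if (length(missing_cols)) {
    stop("areas table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_layer <- setdiff(unique(areas$layer), .syn_layers)
  if (length(bad_layer)) {
    stop("unknown layer label(s) in areas table: ",
         paste(bad_layer, collapse = ", "))
  }
  nm <- bundle_area_names(bundle)
  if (length(nm) < 2L) stop("an anatomy bundle needs at least 2 areas")
  # every area needs the four neuron-bearing layers
  for (a in nm) {
    lay <- areas$layer[areas$area == a]
    if (!all(.layers %in% lay)) {
      stop("area ", a, " is missing layer row(s): ",
           paste(setdiff(.layers, lay), collapse = ", "))
    }
    if (anyDuplicated(lay)) stop("area ", a, " has duplicated layer rows")
    s <- unique(areas$surface_mm2[areas$area == a])
    if (length(s) != 1L || !is.finite(s) || s <= 0) {
      stop("area ", a, ": surface_mm2 must be a single positive value")
    }
  }
  bad <- areas[!is.finite(areas$thickness_mm) | areas$thickness_mm < 0, ]
  if (nrow(bad)) {
    stop("negative or non-finite thickness for area ", bad$area[1],
         " layer ", bad$layer[1])
  }
  bad <- areas[!is.finite(areas$density_per_mm3) | areas$density_per_mm3 < 0, ]
  if (nrow(bad)) {
    stop("negative or non-finite density for area ", bad$area[1],
         " layer ", bad$layer[1])
  }
  neuron_rows <- areas$layer != "1"
  ef <- areas$exc_fraction[neuron_rows]
  if (any(!is.na(ef) & (ef < 0 | ef > 1))) {
    i <- which(neuron_rows)[which(!is.na(ef) & (ef < 0 | ef > 1))[1]]
    stop("exc_fraction outside [0, 1] for area ", areas$area[i],
         " layer ", areas$layer[i])
  }

  for (mnm in c("nos", "fiber_length_mm")) {
    m <- bundle[[mnm]]
    if (!is.matrix(m) || nrow(m) != length(nm) || ncol(m) != length(nm)) {
      stop(mnm, " matrix must be ", length(nm), "x", length(nm),
           " to match the area list (got ",
           paste(dim(m), collapse = "x"), ")")
    }
    if (is.null(dimnames(m)) ||
        !identical(rownames(m), nm) || !identical(colnames(m), nm)) {
      stop(mnm, " matrix dimnames must match the area list (unknown or ",
           "reordered area names)")
    }
  }
  if (any(bundle$nos[!diag(length(nm)) == 1] < 0, na.rm = TRUE)) {
    stop("nos matrix has negative entries")
  }
  fl <- bundle$fiber_length_mm
  off <- fl[row(fl) != col(fl)]
  if (any(!is.finite(off) | off <= 0)) {
    stop("fiber_length_mm must be positive off the diagonal")
  }
  if (max(abs(fl - t(fl))) > 1e-8 * max(abs(fl))) {
    stop("fiber_length_mm must be symmetric")
  }

  bp <- bundle$blueprint
  if (!all(dim(bp$q) == c(8L, 8L)) || any(bp$q < 0)) {
    stop("blueprint q must be a nonnegative 8x8 matrix")
  }
  if (length(bp$k_ext) != 8L || any(bp$k_ext < 0)) {
    stop("blueprint k_ext must be 8 nonnegative values")
  }
  d <- bundle$dendrites
  if (!is.matrix(d) || !all(dim(d) == c(5L, 4L)) || any(d < 0)) {
    stop("dendrites must be a nonnegative 5x4 matrix (synapse x soma layer)")
  }
  validate_model_constants(bundle$constants)
  bundle
}

# Fill missing excitatory fractions with the per-layer defaults; layer-1 rows
# carry no neurons and get NA.
fill_exc_fraction <- function(areas) {
  idx <- is.na(areas$exc_fraction) & areas$layer != "1"
  areas$exc_fraction[idx] <- .exc_fraction_default[areas$layer[idx]]
  areas$exc_fraction[areas$layer == "1"] <- NA_real_
  areas
}

#' Total column height of an area (mm)
#'
#' Sum of all layer thicknesses (including layer 1 when present).
#' @keywords internal
area_height <- function(bundle, area) {
  sum(bundle$areas$thickness_mm[bundle$areas$area == area])
}

#' Area-level neuron volume density (neurons/mm^3)
#'
#' Total neurons divided by the column volume: thickness-weighted mean of
#' the per-layer densities over the full column height (layer 1 contributes
#' thickness but no neurons).
#' @keywords internal
area_density <- function(bundle, area) {
  rows <- bundle$areas[bundle$areas$area == area, ]
  sum(rows$thickness_mm * rows$density_per_mm3) / sum(rows$thickness_mm)
}
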