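# Layer and population conventions used throughout the package.
# Neurons live in layers 2/3, 4, 5, 6; synapses may additionally sit in layer 1
# (which holds no somata in the model).

#' @keywords internal
.layers <- c("2/3", "4", "5", "6")

#' @keywords internal
.syn_layers <- c("1", "2/3", "4", "5", "6")

#' @keywords internal
.pops8 <- c("2/3E", "2/3I", "4E", "4I", "5E", "5I", "6E", "6I")

# Default fractions of excitatory neurons per layer (human temporal lobe EM
# reconstruction): 65% in L2/3, 79% in L4, 78% in L5, 86% in L6.
.exc_fraction_default <- c("2/3" = 0.65, "4" = 0.79, "5" = 0.78, "6" = 0.86)

#' Model constants for the connectome builder
#'
#' Returns the global constants used by the mesoconnectome construction:
#' the cortical synapse volume density, the lateral connectivity decay
#' constant, the column surface area, the calibration of the white-matter
#' scaling rule (fraction of neurons sending axons into the white matter,
#' calibrated at a macaque reference point and evaluated at the human
#' gray-matter neuron count), the SLN thresholds separating feedforward,
#' lateral, and feedback projections, and the fixed excitatory target
#' fraction of feedback projections.
#'
#' @param ... named overrides for any constant, e.g. `rho_synapse = 3e8`.
#'
#' @return A named list of class `model_constants` with elements
#'   `rho_synapse` (synapses/mm^3), `lambda_conn` (mm), `column_area` (mm^2),
#'   `calib_fraction`, `calib_neurons`, `human_neurons`, `scaling_exponent`,
#'   `sln_ff_threshold`, `sln_fb_threshold`, `fb_exc_target_fraction`, and
#'   `ei_target_exc_share` (cortex-wide excitatory share of long-range
#'   postsynaptic targets per synapse layer; a configurable placeholder for a
#'   laminar aggregate that is not published in tabular form).
#' @export
#' @examples
#' const <- model_constants()
#' nonlocal_fraction(const)
model_constants <- function(...) {
  const <- list(
    rho_synapse = 6.6e8,        # synapses / mm^3
    lambda_conn = 0.160,        # mm, lateral connection-probability decay
    column_area = 1.0,          # mm^2 simulated column surface
    calib_fraction = 0.21,      # nonlocal neuron fraction at the calibration point
    calib_neurons = 1.4e9,      # gray-matter neurons at the calibration point
    human_neurons = 16e9,       # gray-matter neurons in human cortex
    scaling_exponent = 0.16,    # exponent of the white-matter scaling rule
    sln_ff_threshold = 0.65,    # SLN > 0.65: feedforward
    sln_fb_threshold = 0.35,    # SLN < 0.35: feedback
    fb_exc_target_fraction = 0.93,
    ei_target_exc_share = stats::setNames(rep(0.85, 5), .syn_layers)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad)) {
      stop("unknown model constant(s): ", paste(bad, collapse = ", "))
    }
    const[names(over)] <- over
  }
  validate_model_constants(const)
  structure(const, class = "model_constants")
}

validate_model_constants <- function(const) {
  scalars <- c(
    "rho_synapse", "lambda_conn", "column_area", "calib_fraction",
    "calib_neurons", "human_neurons", "scaling_exponent",
    "sln_ff_threshold", "sln_fb_threshold", "fb_exc_target_fraction"
  )
  for (nm in scalars) {
    v <- const[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("model constant '", nm, "' must be a positive finite scalar")
    }
  }
  if (const$sln_fb_threshold >= const$sln_ff_threshold) {
    stop("SLN thresholds must satisfy fb_threshold < ff_threshold")
  }
  e <- const$ei_target_exc_share
  if (!is.numeric(e) || length(e) != 5L || any(e < 0 | e > 1)) {
    stop("ei_target_exc_share must be 5 probabilities (synapse layers 1, 2/3, 4, 5, 6)")
  }
  invisible(const)
}

#' The 34 Desikan-Killiany areas of one hemisphere
#'
#' Area names and acronyms of the Desikan-Killiany cortical parcellation, in
#' the fixed order used by every matrix and table in this package.
#'
#' @return A tibble with columns `area` and `acronym` (34 rows).
#' @export
#' @examples
#' dk_areas()
dk_areas <- function() {
  tibble::tibble(
    area = c(
      "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
      "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
      "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
      "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
      "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
      "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
      "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
      "superiorfrontal", "superiorparietal", "superiortemporal",
      "supramarginal", "frontalpole", "temporalpole", "transversetemporal",
      "insula"
    ),
    acronym = c(
      "BSTS", "CAC", "CMF", "CUN", "ENT", "FUS", "INFP", "IT", "ISTC", "LOCC",
      "LORB", "LIN", "MORB", "MT", "PARH", "PARC", "POPE", "PORB", "PTRI",
      "PCAL", "PSTS", "PC", "PREC", "PCUN", "RAC", "RMF", "SF", "SP", "ST",
      "SMAR", "FP", "TP", "TT", "INS"
    )
  )
}

#' Local-circuit blueprint (layered microcircuit reference)
#'
#' The within-column connectivity blueprint: mean numbers of synapses per
#' neuron pair between the eight local populations, derived from the published
#' connection probabilities of the layered cortical microcircuit model of
#' Potjans & Diesmann (2014), together with its reference external indegrees.
#' Under the fixed-total-number connectivity rule, a connection probability
#' `p` corresponds to `q = -log(1 - p)` mean synapses per (ordered) neuron
#' pair.
#'
#' Only relative values of `q` and `k_ext` matter downstream: the builder
#' rescales them so that each area's anatomically determined synapse budget is
#' met. The doubling of 4E to 2/3E synaptic *weights* is part of the blueprint
#' but is metadata here (`doubling`), applied at network realization, not
#' baked into `q`.
#'
#' @return A list of class `local_blueprint` with `q` (8x8 matrix, rows =
#'   source population, columns = target population, order 2/3E, 2/3I, 4E, 4I,
#'   5E, 5I, 6E, 6I), `k_ext` (length-8 reference external indegrees per
#'   target population), and `doubling` (the weight-doubled projection).
#' @export
blueprint_pd <- function() {
  # Connection probabilities, rows = target population, columns = source
  # population, order 2/3E 2/3I 4E 4I 5E 5I 6E 6I.
  p <- matrix(c(
    0.1009, 0.1689, 0.0437, 0.0818, 0.0323, 0.0000, 0.0076, 0.0000,
    0.1346, 0.1371, 0.0316, 0.0515, 0.0755, 0.0000, 0.0042, 0.0000,
    0.0077, 0.0059, 0.0497, 0.1350, 0.0067, 0.0003, 0.0453, 0.0000,
    0.0691, 0.0029, 0.0794, 0.1597, 0.0033, 0.0000, 0.1057, 0.0000,
    0.1004, 0.0622, 0.0505, 0.0057, 0.0831, 0.3726, 0.0204, 0.0000,
    0.0548, 0.0269, 0.0257, 0.0022, 0.0600, 0.3158, 0.0086, 0.0000,
    0.0156, 0.0066, 0.0211, 0.0166, 0.0572, 0.0197, 0.0396, 0.2252,
    0.0364, 0.0010, 0.0034, 0.0005, 0.0277, 0.0080, 0.0658, 0.1443
  ), nrow = 8, byrow = TRUE, dimnames = list(.pops8, .pops8))
  q <- t(-log(1 - p)) # rows = source, cols = target
  structure(
    list(
      q = q,
      k_ext = stats::setNames(
        c(1600, 1500, 2100, 1900, 2000, 1900, 2900, 2100), .pops8
      ),
      doubling = c(source = "4E", target = "2/3E")
    ),
    class = "local_blueprint"
  )
}

#' Synthetic layer-resolved dendritic-length profile
#'
#' A synthetic stand-in for the dendritic-length matrix estimated from
#' morphological reconstructions of human pyramidal cells: entry
#' `[A, B]` is the total dendritic length in (synapse) layer A belonging to
#' excitatory neurons with soma in layer B, in arbitrary consistent units.
#' The shape follows pyramidal-cell anatomy: most dendrite in the soma layer,
#' an apical tuft contribution in layer 1, and apical trunk passing through
#' intervening layers. Use real reconstruction-derived values via
#' `dendrites.csv` when available.
#'
#' @return A 5x4 matrix, rows = synapse layers 1, 2/3, 4, 5, 6; columns =
#'   soma layers 2/3, 4, 5, 6.
#' @export
dendritic_profile_synthetic <- function() {
  m <- matrix(c(
    # soma:  2/3    4     5     6
    0.35, 0.15, 0.25, 0.05,  # dendrite in layer 1 (apical tufts)
    1.00, 0.25, 0.30, 0.10,  # layer 2/3
    0.05, 1.00, 0.25, 0.15,  # layer 4
    0.00, 0.05, 1.00, 0.30,  # layer 5
    0.00, 0.00, 0.10, 1.00   # layer 6
  ), nrow = 5, byrow = TRUE, dimnames = list(.syn_layers, .layers))
  m
}
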