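#' Predict the laminar origin (SLN) of a projection
#'
#' The fraction of supragranular labeled neurons (SLN) of a projection is
#' predicted from the cytoarchitecture via a probit model of the log-ratio of
#' the target and source area-level neuron densities:
#' `SLN = Phi(a0 + a1 * log(rho_target / rho_source))` with the standard
#' normal CDF `Phi` and the macaque fit parameters as default. Since
#' `a1 < 0`, projections from denser (typically earlier) areas to less dense
#' areas have high SLN (feedforward) and vice versa.
#'
#' @param rho_target,rho_source area-level neuron densities (neurons/mm^3).
#' @param fit [sln_fit_params()].
#' @return SLN value(s) in (0, 1).
#' @export
#' @examples
#' predict_sln(5e4, 5e4) # pnorm(-0.152) = 0.4396
predict_sln <- function(rho_target, rho_source, fit = sln_fit_params()) {
  if (any(rho_target <= 0) || any(rho_source <= 0)) {
    stop("neuron densities must be positive")
  }
  stats::pnorm(fit$a0 + fit$a1 * log(rho_target / rho_source))
}

#' Laminar origin of a projection's synapses
#'
#' Splits a projection's synapses over the source populations: the SLN
#' fraction originates from layer 2/3 excitatory neurons; the remainder is
#' split between the two infragranular excitatory populations (5E, 6E)
#' proportionally to their sizes. Layer 4 forms no long-range projections and
#' inhibitory neurons never project between areas. If a nominal origin is
#' absent in the source area, its share goes to the remaining eligible
#' populations.
#'
#' @param sln SLN value in `[0, 1]`.
#' @param source_sizes named population sizes of the source area (at least
#'   `"2/3E"`, `"5E"`, `"6E"`).
#' @param n_syn synapse count of the projection.
#' @return Named vector (`"2/3E"`, `"5E"`, `"6E"`) summing to `n_syn` exactly.
#' @export
#' @examples
#' laminar_source_counts(0.6, c("2/3E" = 100, "5E" = 300, "6E" = 100), 1000)
laminar_source_counts <- function(sln, source_sizes, n_syn) {
  n23 <- source_sizes[["2/3E"]]
  n5 <- source_sizes[["5E"]]
  n6 <- source_sizes[["6E"]]
  if (n23 + n5 + n6 == 0 && n_syn > 0) {
    stop("source area has no excitatory neurons in layers 2/3, 5, or 6")
  }
  w_supra <- if (n23 > 0) sln else 0
  infra_total <- n5 + n6
  w_infra <- if (infra_total > 0) (1 - sln) else 0
  # re-normalize when one compartment is absent
  if (w_supra + w_infra == 0) {
    w <- c(0, 0, 0)
  } else {
    w <- c(w_supra, w_infra * n5 / max(infra_total, 1),
           w_infra * n6 / max(infra_total, 1)) / (w_supra + w_infra)
  }
  stats::setNames(largest_remainder(w, n_syn), c("2/3E", "5E", "6E"))
}

#' Laminar target pattern of a projection
#'
#' Distributes a projection's synapses over the target layers according to
#' its SLN class. Feedforward projections (SLN above the upper threshold)
#' target layer 4 only (layer 2/3 in agranular target areas); feedback
#' projections (SLN below the lower threshold) target layers 1, 2/3, 5, 6;
#' lateral projections target all layers 1, 2/3, 4, 5, 6. Within a
#' multi-layer pattern, weights are proportional to the layer thicknesses
#' relative to all layers of the pattern.
#'
#' @param sln SLN value in `[0, 1]`.
#' @param thickness_mm named layer thicknesses of the target area (layers
#'   among `"1"`, `"2/3"`, `"4"`, `"5"`, `"6"`; missing layers count as 0).
#' @param agranular is the target area agranular (no layer-4 population)?
#' @param constants [model_constants()] (SLN thresholds).
#' @return Named weights over synapse layers `"1"`, `"2/3"`, `"4"`, `"5"`,
#'   `"6"`, summing to 1.
#' @export
laminar_target_distribution <- function(sln, thickness_mm, agranular = FALSE,
                                        constants = model_constants()) {
  th <- stats::setNames(rep(0, 5), .syn_layers)
  th[names(thickness_mm)] <- thickness_mm
  w <- stats::setNames(rep(0, 5), .syn_layers)
  if (sln > constants$sln_ff_threshold) {
    w[if (agranular) "2/3" else "4"] <- 1
    return(w)
  }
  pattern <- if (sln < constants$sln_fb_threshold) {
    c("1", "2/3", "5", "6")
  } else {
    .syn_layers
  }
  tot <- sum(th[pattern])
  if (tot <= 0) {
    stop("target pattern layers have zero total thickness")
  }
  w[pattern] <- th[pattern] / tot
  w
}

#' Postsynaptic population weights of a long-range projection
#'
#' Turns a laminar synapse-location distribution into weights over the target
#' populations. Per synapse layer, a configurable share of synapses contacts
#' excitatory neurons; the excitatory share is routed to soma layers through
#' the dendritic-length profile (probability of the soma being in layer B
#' given a synapse in layer A is the dendritic length `l[A, B]` relative to
#' the row total) and the synapse location is marginalized. Inhibitory
#' targets sit in the synapse's own layer; the layer-1 inhibitory share
#' (layer 1 holds no somata) is reassigned proportionally to the other
#' layers' inhibitory shares. For feedback projections (SLN below the lower
#' threshold) the total excitatory share is fixed at
#' `constants$fb_exc_target_fraction`. Weights of populations absent from the
#' target area are redistributed within their E/I class.
#'
#' @param layer_weights named weights over synapse layers (from
#'   [laminar_target_distribution()]).
#' @param dendrites 5x4 dendritic-length matrix (synapse layer x soma layer).
#' @param sln SLN of the projection.
#' @param target_sizes named sizes of the 8 target populations.
#' @param constants [model_constants()] (`ei_target_exc_share`,
#'   `fb_exc_target_fraction`, SLN thresholds).
#' @return Named weights over the 8 target populations, summing to 1.
#' @export
resolve_postsynaptic_targets <- function(layer_weights, dendrites, sln,
                                         target_sizes,
                                         constants = model_constants()) {
  lw <- stats::setNames(rep(0, 5), .syn_layers)
  lw[names(layer_weights)] <- layer_weights
  exc_share <- constants$ei_target_exc_share
  target_sizes <- target_sizes[.pops8]

  e_w <- stats::setNames(rep(0, 4), .layers) # soma layers, excitatory
  i_w <- stats::setNames(rep(0, 4), .layers) # synapse layers, inhibitory
  i_l1 <- 0
  for (a in .syn_layers) {
    if (lw[[a]] == 0) next
    e_share <- exc_share[[a]]
    row <- dendrites[a, ]
    rs <- sum(row)
    has_inh <- a != "1" && target_sizes[[paste0(a, "I")]] > 0
    if (rs <= 0) {
      if (!has_inh) {
        stop("synapse layer ", a, " has an all-zero dendrite row and no ",
             "inhibitory population to absorb its synapses")
      }
      # no dendrites reach this layer: everything contacts local inhibition
      i_w[[a]] <- i_w[[a]] + lw[[a]]
      next
    }
    e_w <- e_w + lw[[a]] * e_share * row / rs
    if (a == "1") {
      i_l1 <- i_l1 + lw[[a]] * (1 - e_share)
    } else {
      i_w[[a]] <- i_w[[a]] + lw[[a]] * (1 - e_share)
    }
  }
  if (i_l1 > 0) {
    if (sum(i_w) > 0) {
      i_w <- i_w * (1 + i_l1 / sum(i_w))
    } else {
      # no inhibitory share anywhere else: layer-1 synapses all go to
      # excitatory somata via the dendrite profile
      row <- dendrites["1", ]
      e_w <- e_w + i_l1 * row / sum(row)
    }
  }

  if (sln < constants$sln_fb_threshold && sum(e_w) > 0 && sum(i_w) > 0) {
    f <- constants$fb_exc_target_fraction
    e_w <- e_w / sum(e_w) * f
    i_w <- i_w / sum(i_w) * (1 - f)
  }

  w <- stats::setNames(rep(0, 8), .pops8)
  w[paste0(.layers, "E")] <- e_w
  w[paste0(.layers, "I")] <- i_w

  # drop absent populations, renormalizing within the E/I class to preserve
  # the class shares where possible
  absent <- target_sizes == 0
  for (cls in c("E", "I")) {
    sel <- endsWith(.pops8, cls)
    tot <- sum(w[sel])
    w[sel & absent] <- 0
    kept <- sum(w[sel])
    if (tot > 0 && kept > 0) w[sel] <- w[sel] / kept * tot
  }
  if (sum(w) == 0) {
    stop("no existing target population can receive this projection")
  }
  w / sum(w)
}
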