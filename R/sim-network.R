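#' Low-level LIF network constructor
#'
#' Wraps already-parameterized population and projection tables into the
#' network container the engine consumes. Most users should call
#' [realize_network()] on an assembled connectome; this constructor exists
#' for bespoke networks (single neurons, minimal circuits, method tests).
#'
#' @param populations tibble with columns `area`, `layer`, `ei`, `size`
#'   (> 0), and optionally `k_ext` (external indegree, default 0),
#'   `ext_weight_scale` (default 1), `i_const_pA` (constant input current,
#'   default 0).
#' @param projections tibble with columns `src`, `tgt` (row indices into
#'   `populations`), `n_synapses`, `w_mean_pA`, `w_sd_pA`, `d_mean_ms`,
#'   `d_rel_sd`. May be empty.
#' @param neuron [neuron_params()].
#' @param delays [delay_params()] (supplies `dt` and the delay cap).
#' @param net_seed integer seed of the network realization.
#' @return A list of class `lif_network`.
#' @export
lif_network <- function(populations, projections = NULL,
                        neuron = neuron_params(), delays = delay_params(),
                        net_seed = 1) {
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("area", "layer", "ei", "size") %in% names(populations)))
  if (any(populations$size < 1)) stop("population sizes must be >= 1")
  if (!"k_ext" %in% names(populations)) populations$k_ext <- 0
  if (!"ext_weight_scale" %in% names(populations)) {
    populations$ext_weight_scale <- 1
  }
  if (!"i_const_pA" %in% names(populations)) populations$i_const_pA <- 0
  if (is.null(projections) || nrow(projections) == 0) {
    projections <- tibble::tibble(
      src = integer(), tgt = integer(), n_synapses = numeric(),
      w_mean_pA = numeric(), w_sd_pA = numeric(), d_mean_ms = numeric(),
      d_rel_sd = numeric()
    )
  }
  projections <- tibble::as_tibble(projections)
  if (nrow(projections)) {
    stopifnot(
      all(projections$src >= 1), all(projections$src <= nrow(populations)),
      all(projections$tgt >= 1), all(projections$tgt <= nrow(populations)),
      all(projections$n_synapses >= 0), all(projections$d_mean_ms > 0)
    )
    projections <- projections[projections$n_synapses > 0, ]
  }
  populations$first_id <- cumsum(dplyr::lag(populations$size, default = 0)) + 1
  populations$last_id <- populations$first_id + populations$size - 1
  structure(
    list(populations = populations, projections = projections,
         neuron = neuron, delays = delays, net_seed = net_seed),
    class = "lif_network"
  )
}

#' @export
print.lif_network <- function(x, ...) {
  cat("<lif_network>", sum(x$populations$size), "neurons in",
      nrow(x$populations), "populations,",
      format(sum(x$projections$n_synapses), big.mark = ","), "synapses\n")
  invisible(x)
}

#' Realize a connectome as an explicit LIF network
#'
#' Instantiates a (possibly down-scaled) network from the synapse counts of an
#' assembled connectome. Neuron and synapse counts are both multiplied by
#' `scale` (rounded), which preserves the indegree per neuron. For every
#' projection, exactly the specified number of synapses is drawn with source
#' and target neurons sampled uniformly with replacement (autapses and
#' multapses allowed). Weights are truncated-normal PSPs converted to currents
#' with the target population's capacitance, with all multipliers applied:
#' `-g` for inhibitory sources, the 4E-to-2/3E doubling within an area, `chi`
#' for inter-areal synapses, and additionally `chi_I` onto inhibitory targets.
#' Local delays use the excitatory/inhibitory means; inter-areal delays use
#' fiber length over conduction velocity.
#'
#' @param conn a [assemble_connectome()] result.
#' @param scale fraction in (0, 1] applied to neuron and synapse counts.
#' @param net_seed integer seed of the realization.
#' @param synapse [synapse_model_params()].
#' @param delays [delay_params()].
#' @param neuron [neuron_params()].
#' @param fluctuation_scaling multiply recurrent weights by `1/sqrt(scale)`
#'   to preserve input fluctuations under down-scaling. Off by default: the
#'   reference parameterization uses full-density weights at every scale.
#' @return A `lif_network`. Populations that scale to zero neurons are
#'   dropped with a warning naming the synapses lost with them.
#' @export
realize_network <- function(conn, scale = 1, net_seed = 1,
                            synapse = synapse_model_params(),
                            delays = delay_params(),
                            neuron = neuron_params(),
                            fluctuation_scaling = FALSE) {
  stopifnot(inherits(conn, "connectome"), scale > 0, scale <= 1)
  grid <- conn$grid
  grid$size_scaled <- round(grid$size * scale)
  gone <- grid$size > 0 & grid$size_scaled == 0
  if (any(gone)) {
    warning(sum(gone), " population(s) scaled to zero neurons and were ",
            "dropped (e.g. ", grid$area[which(gone)[1]], " ",
            grid$population[which(gone)[1]], "); their projections are lost")
  }
  keep <- grid[grid$size_scaled > 0, ]

  proj <- connectome_projections(conn, delays)
  proj$n_scaled <- round(proj$n_synapses * scale)
  sizes <- stats::setNames(grid$size_scaled, grid$pop_id)
  proj <- proj[proj$n_scaled > 0 &
                 sizes[as.character(proj$src_pop_id)] > 0 &
                 sizes[as.character(proj$tgt_pop_id)] > 0, ]

  info <- grid |>
    dplyr::select("pop_id", "area", "layer", "ei", "population")
  key <- stats::setNames(seq_len(nrow(keep)), keep$pop_id)

  src_info <- info[match(proj$src_pop_id, info$pop_id), ]
  tgt_info <- info[match(proj$tgt_pop_id, info$pop_id), ]
  inter <- src_info$area != tgt_info$area
  psp <- synapse$psp_mean *
    ifelse(src_info$ei == "I", -synapse$g, 1) *
    ifelse(!inter & src_info$population == "4E" &
             tgt_info$population == "2/3E", synapse$l4e_to_l23e_factor, 1) *
    ifelse(inter, synapse$chi, 1) *
    ifelse(inter & tgt_info$ei == "I", synapse$chi_I, 1)
  cm_tgt <- ifelse(tgt_info$ei == "E", neuron$C_m[["E"]], neuron$C_m[["I"]])
  w_mean <- psp_to_psc(psp, cm_tgt, neuron$tau_m, neuron$tau_s)
  if (isTRUE(fluctuation_scaling)) w_mean <- w_mean / sqrt(scale)

  projections <- tibble::tibble(
    src = unname(key[as.character(proj$src_pop_id)]),
    tgt = unname(key[as.character(proj$tgt_pop_id)]),
    n_synapses = proj$n_scaled,
    w_mean_pA = w_mean,
    w_sd_pA = synapse$psp_rel_sd * abs(w_mean),
    d_mean_ms = proj$d_mean_ms,
    d_rel_sd = delays$rel_sd
  )

  ext <- conn$external_drive |>
    dplyr::mutate(population = paste0(.data$layer, .data$ei))
  ext_key <- stats::setNames(round(ext$n_synapses_ext * scale),
                             paste(ext$area, ext$population))
  k_ext <- unname(ext_key[paste(keep$area, keep$population)]) /
    keep$size_scaled
  k_ext[is.na(k_ext)] <- 0

  populations <- tibble::tibble(
    area = keep$area, layer = keep$layer, ei = keep$ei,
    size = keep$size_scaled,
    k_ext = k_ext,
    ext_weight_scale = ifelse(
      keep$population == "5E", synapse$ext_scale_5E,
      ifelse(keep$population == "6E", synapse$ext_scale_6E, 1)
    ),
    i_const_pA = 0,
    pop_id = keep$pop_id
  )
  net <- lif_network(populations, projections, neuron = neuron,
                     delays = delays, net_seed = net_seed)
  net$scale <- scale
  net
}

# engine argument marshalling shared by simulate/materialize
engine_args <- function(net) {
  pops <- net$populations
  nr <- net$neuron
  cm <- ifelse(pops$ei == "E", nr$C_m[["E"]], nr$C_m[["I"]])
  pop_par <- cbind(
    Cm = cm, tau_m = nr$tau_m, V_th = nr$V_th, E_L = nr$E_L,
    V_reset = nr$V_reset, tau_r = nr$tau_r, tau_s = nr$tau_s,
    i_const = pops$i_const_pA
  )
  cv_par <- cbind(
    v = unname(nr$cv$V_th[pops$ei]),
    c = unname(nr$cv$C_m[pops$ei]),
    t = unname(nr$cv$tau_m[pops$ei])
  )
  areas <- unique(pops$area)
  list(
    pop_size = as.integer(pops$size),
    pop_par = pop_par,
    cv_par = cv_par,
    distributed = any(cv_par > 0),
    pop_area0 = match(pops$area, areas) - 1L,
    areas = areas,
    proj_src0 = as.integer(net$projections$src - 1L),
    proj_tgt0 = as.integer(net$projections$tgt - 1L),
    proj_k = as.numeric(net$projections$n_synapses),
    w_mean = net$projections$w_mean_pA,
    w_sd = net$projections$w_sd_pA,
    d_mean = net$projections$d_mean_ms,
    d_rel_sd = net$projections$d_rel_sd
  )
}

#' Materialize the explicit synapse list of a network
#'
#' Regenerates the full (source, target, weight, delay) synapse table of a
#' realized network — the same draws the engine uses during simulation.
#' Intended for small networks and structural tests; refuses networks beyond
#' 5e7 synapses.
#'
#' @param net a [lif_network()].
#' @return A tibble with `source`, `target` (1-based neuron ids),
#'   `projection` (row of `net$projections`), `weight_pA`, `delay_ms`.
#' @export
get_synapses <- function(net) {
  a <- engine_args(net)
  m <- cpp_materialize_network(
    a$pop_size, a$proj_src0, a$proj_tgt0, a$proj_k,
    a$w_mean, a$w_sd, a$d_mean, a$d_rel_sd,
    net$delays$dt, net$delays$cap_ms, as.numeric(net$net_seed)
  )
  tibble::tibble(
    source = m$source + 1L, target = m$target + 1L,
    projection = m$projection + 1L,
    weight_pA = m$weight,
    delay_ms = m$delay_steps * net$delays$dt
  )
}

#' Minimum realized delay per projection
#'
#' The smallest transmission delay actually realized in each projection of
#' the network — the exact edge weights for causal lower bounds on
#' perturbation propagation.
#'
#' @param net a [lif_network()].
#' @return `net$projections` with an extra column `d_min_ms`.
#' @export
projection_min_delays <- function(net) {
  a <- engine_args(net)
  d <- cpp_projection_min_delays(a$proj_k, a$d_mean, a$d_rel_sd,
                                 net$delays$dt, net$delays$cap_ms,
                                 as.numeric(net$net_seed))
  dplyr::mutate(net$projections, d_min_ms = d)
}
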