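#' Simulate a LIF network
#'
#' Integrates the network with the exact propagator of the linear
#' (membrane potential, synaptic current) system on the fixed time grid.
#' Threshold crossings emit spikes; the membrane potential is clamped at the
#' reset potential for the refractory period while synaptic currents keep
#' integrating. Every neuron receives independent Poisson drive through its
#' external indegree. Initial membrane potentials are drawn uniformly between
#' reset and threshold from each neuron's private stream. Identical
#' `(net, seed)` give bit-identical spike records.
#'
#' @param net a [lif_network()].
#' @param duration_ms simulated time, a multiple of the step `net$delays$dt`.
#' @param drive [external_drive_params()].
#' @param seed integer seed of the simulation (initial states and drive).
#' @param probes record the per-area summed absolute synaptic current, one
#'   sample per ms (the functional-connectivity proxy source)?
#' @param perturbation optional `list(neuron_id =, time_ms =)`: raise that
#'   neuron's membrane potential above threshold at that time so it emits one
#'   extra spike.
#' @param record_vm optional neuron id whose membrane potential is recorded
#'   every step.
#' @return A list of class `spike_record`: `spikes` (tibble `neuron_id`,
#'   `time_ms`, sorted by time), `populations` (population index with neuron
#'   id ranges), `duration_ms`, `dt`, `probes` (tibble `time_ms` + one column
#'   per area, or NULL), `vm` (tibble `time_ms`, `v_mV`, or NULL), `seed`.
#' @export
simulate_network <- function(net, duration_ms,
                             drive = external_drive_params(), seed = 1,
                             probes = TRUE, perturbation = NULL,
                             record_vm = NULL) {
  stopifnot(inherits(net, "lif_network"), duration_ms > 0)
  dt <- net$delays$dt
  if (abs(duration_ms / dt - round(duration_ms / dt)) > 1e-9) {
    stop("duration_ms must be a multiple of dt = ", dt, " ms")
  }
  a <- engine_args(net)
  pops <- net$populations
  nr <- net$neuron

  # external Poisson intensity per neuron and step
  nu <- rep(0, nrow(pops))
  pos <- pops$k_ext > 0
  nu[pos] <- external_poisson_rate(drive, nr, pops$k_ext[pos])
  lam <- pops$k_ext * nu * dt / 1000
  cm <- ifelse(pops$ei == "E", nr$C_m[["E"]], nr$C_m[["I"]])
  wext_mean <- psp_to_psc(drive$w_ext * pops$ext_weight_scale, cm,
                          nr$tau_m, nr$tau_s)
  wext_sd <- drive$rel_sd * wext_mean

  n_neurons <- sum(pops$size)
  pn <- -1; pt <- -1
  if (!is.null(perturbation)) {
    pn <- perturbation$neuron_id
    pt <- perturbation$time_ms
    if (is.null(pn) || is.null(pt) || pn < 1 || pn > n_neurons) {
      stop("perturbation needs a valid neuron_id (1..", n_neurons,
           ") and time_ms")
    }
    if (pt <= 0 || pt > duration_ms) {
      stop("perturbation time must lie within the simulated interval")
    }
    pn <- pn - 1
  }
  vmn <- if (is.null(record_vm)) -1 else record_vm - 1
  if (vmn >= n_neurons) stop("record_vm: unknown neuron id")

  res <- cpp_simulate(
    a$pop_size, a$pop_par, a$pop_area0,
    a$proj_src0, a$proj_tgt0, a$proj_k,
    a$w_mean, a$w_sd, a$d_mean, a$d_rel_sd,
    lam, wext_mean, wext_sd,
    duration_ms, dt, net$delays$cap_ms,
    as.numeric(net$net_seed), as.numeric(seed),
    pn, pt, isTRUE(probes), length(a$areas), vmn,
    a$cv_par, a$distributed
  )
  spikes <- tibble::tibble(
    neuron_id = res$spike_neuron + 1L,
    time_ms = res$spike_step * dt
  )
  ord <- order(spikes$time_ms, spikes$neuron_id)
  spikes <- spikes[ord, ]

  probe_tbl <- NULL
  if (isTRUE(probes)) {
    probe_tbl <- tibble::as_tibble(as.data.frame(res$probes))
    names(probe_tbl) <- a$areas
    probe_tbl <- dplyr::bind_cols(
      tibble::tibble(time_ms = seq_len(nrow(probe_tbl))), probe_tbl
    )
  }
  vm_tbl <- NULL
  if (vmn >= 0) {
    vm_tbl <- tibble::tibble(
      time_ms = seq_along(res$vm) * dt,
      v_mV = res$vm
    )
  }
  structure(
    list(
      spikes = spikes,
      populations = pops |>
        dplyr::mutate(pop_index = dplyr::row_number()) |>
        dplyr::select(dplyr::any_of(c(
          "pop_index", "pop_id", "area", "layer", "ei", "size",
          "first_id", "last_id"
        ))),
      duration_ms = duration_ms, dt = dt,
      probes = probe_tbl, vm = vm_tbl, seed = seed,
      perturbation = perturbation
    ),
    class = "spike_record"
  )
}

#' @export
print.spike_record <- function(x, ...) {
  n <- sum(x$populations$size)
  cat(sprintf(
    "<spike_record> %d spikes from %d neurons over %g ms (%.2f spikes/s)\n",
    nrow(x$spikes), n, x$duration_ms,
    nrow(x$spikes) / n / (x$duration_ms / 1000)
  ))
  invisible(x)
}

#' Exactly paired perturbation runs
#'
#' Runs the same network twice with identical seeds, once without and once
#' with a single-neuron perturbation. Because every neuron owns a private
#' random stream (keyed by the simulation seed and the neuron id) that is
#' consumed independently of network activity, the two runs use exactly the
#' same random numbers; any difference between the spike records is caused by
#' the perturbation alone.
#'
#' @inheritParams simulate_network
#' @param perturbation `list(neuron_id =, time_ms =)`, or `NULL` for a
#'   control pair (the two records are then identical).
#' @return A list of class `paired_spike_records` with elements `unperturbed`
#'   and `perturbed`.
#' @export
paired_perturbation_simulate <- function(net, duration_ms,
                                         drive = external_drive_params(),
                                         seed = 1, perturbation = NULL,
                                         probes = FALSE) {
  unperturbed <- simulate_network(net, duration_ms, drive, seed,
                                  probes = probes)
  perturbed <- simulate_network(net, duration_ms, drive, seed,
                                probes = probes,
                                perturbation = perturbation)
  structure(list(unperturbed = unperturbed, perturbed = perturbed),
            class = "paired_spike_records")
}

#' Population index of a spike record as one row per neuron
#'
#' @param record a `spike_record`.
#' @return A tibble with `neuron_id`, `pop_index`, `area`, `layer`, `ei`.
#' @export
neuron_index <- function(record) {
  pops <- record$populations
  tibble::tibble(
    neuron_id = seq_len(sum(pops$size)),
    pop_index = rep(pops$pop_index, pops$size),
    area = rep(pops$area, pops$size),
    layer = rep(pops$layer, pops$size),
    ei = rep(pops$ei, pops$size)
  )
}
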