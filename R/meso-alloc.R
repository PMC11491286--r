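#' Largest-remainder integer apportionment
#'
#' Distributes an integer `total` over cells proportionally to nonnegative
#' `weights`, rounding with the largest-remainder rule so that the result sums
#' to `total` exactly. Ties in the remainders are broken by cell index.
#'
#' @param weights nonnegative numeric vector (not all zero when `total > 0`).
#' @param total nonnegative integer-valued scalar.
#' @return Numeric vector of integer values, `sum(out) == total`.
#' @export
largest_remainder <- function(weights, total) {
  if (total < 0) stop("total must be nonnegative")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (total == 0) return(rep(0, length(weights)))
  s <- sum(weights)
  if (s == 0) stop("all-zero weights with a positive total")
  ideal <- weights / s * total
  out <- floor(ideal)
  rem <- total - sum(out)
  if (rem > 0) {
    frac <- ideal - out
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  out
}

#' Split an area's synapse budget into internal, external, and nonlocal parts
#'
#' The nonlocal (white-matter) share is `round(f * N_total)`; the remaining
#' local synapses are split between presynaptic neurons inside the column
#' (internal) and in the rest of the area (external) proportionally to the
#' column connection-density integrals, with largest-remainder rounding so
#' that `N_internal + N_external == N_local` exactly.
#'
#' @param n_total total synapse budget of the area.
#' @param nonlocal_fraction fraction of synapses from long-range projections.
#' @param rho_internal,rho_external the [column_density_integrals()] values.
#' @return A list with `n_total`, `n_local`, `n_nonlocal`, `n_internal`,
#'   `n_external`.
#' @export
split_synapse_budget <- function(n_total, nonlocal_fraction,
                                 rho_internal, rho_external) {
  stopifnot(n_total >= 0, nonlocal_fraction >= 0, nonlocal_fraction <= 1,
            rho_internal >= 0, rho_external >= 0)
  n_nonlocal <- round(nonlocal_fraction * n_total)
  n_local <- n_total - n_nonlocal
  ie <- largest_remainder(c(rho_internal, rho_external), n_local)
  list(
    n_total = n_total, n_local = n_local, n_nonlocal = n_nonlocal,
    n_internal = ie[1], n_external = ie[2]
  )
}

#' Distribute an area's internal synapses over population pairs
#'
#' Allocates the within-column synapses over the 8x8 (source, target)
#' population pairs keeping the relative mean number of synapses per neuron
#' pair of the local blueprint: the weight of pair (B -> A) is
#' `N_B * q[B, A] * N_A`. Populations with zero neurons send and receive
#' nothing (agranular layer 4 is handled automatically).
#'
#' @param blueprint a [blueprint_pd()] local blueprint.
#' @param sizes named vector of the 8 population sizes (`"2/3E"` ... `"6I"`).
#' @param n_internal internal synapse budget of the area.
#' @return An 8x8 matrix (rows = source, columns = target) of synapse counts
#'   summing to `n_internal` exactly.
#' @export
distribute_internal <- function(blueprint, sizes, n_internal) {
  sizes <- sizes[.pops8]
  w <- outer(sizes, sizes) * blueprint$q # [source, target]
  if (sum(w) == 0 && n_internal > 0) {
    stop("no connectable population pair: blueprint weights are all zero ",
         "for these population sizes")
  }
  if (n_internal == 0) return(matrix(0, 8, 8, dimnames = dimnames(w)))
  matrix(largest_remainder(as.vector(w), n_internal), 8, 8,
         dimnames = list(.pops8, .pops8))
}

#' Distribute an area's external-drive synapses over target populations
#'
#' Synapses whose presynaptic neuron lies outside the simulated column are
#' distributed over the target populations proportionally to the reference
#' external indegree times the population size; only the relative indegrees
#' of the blueprint matter.
#'
#' @inheritParams distribute_internal
#' @param n_external external synapse budget of the area.
#' @return Named vector of synapse counts per target population, summing to
#'   `n_external` exactly.
#' @export
distribute_external_drive <- function(blueprint, sizes, n_external) {
  sizes <- sizes[.pops8]
  w <- blueprint$k_ext[.pops8] * sizes
  if (sum(w) == 0 && n_external > 0) {
    stop("external-drive weights are all zero for these population sizes")
  }
  if (n_external == 0) return(stats::setNames(rep(0, 8), .pops8))
  stats::setNames(largest_remainder(w, n_external), .pops8)
}

#' Allocate a target area's long-range synapses over source areas
#'
#' Long-range synapses of a target area are distributed over the other areas
#' proportionally to the relative streamline counts of the tractography data;
#' self-connections are excluded.
#'
#' @param nos streamline-count matrix (rows = source, columns = target).
#' @param target_area target area name.
#' @param n_nonlocal the target area's nonlocal synapse budget.
#' @return Named vector of synapse counts per source area (target excluded),
#'   summing to `n_nonlocal` exactly.
#' @export
allocate_longrange_sources <- function(nos, target_area, n_nonlocal) {
  if (!target_area %in% colnames(nos)) stop("unknown area: ", target_area)
  w <- nos[, target_area]
  w <- w[names(w) != target_area]
  if (n_nonlocal > 0 && sum(w) == 0) {
    stop("area ", target_area, " is isolated: no incoming streamlines to ",
         "carry its nonlocal synapses")
  }
  if (n_nonlocal == 0) return(w * 0)
  stats::setNames(largest_remainder(w, n_nonlocal), names(w))
}
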