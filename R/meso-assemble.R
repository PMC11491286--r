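#' Assemble the mesoconnectome
#'
#' Runs the full construction pipeline: population sizes from cytoarchitecture;
#' per-area synapse budgets from the synapse volume density; the local /
#' long-range split from the white-matter scaling rule; the internal /
#' external split from the column connection-density integrals; local
#' population-pair allocation from the blueprint; long-range source-area
#' allocation from streamline counts; laminar origins from the predicted SLN;
#' laminar target patterns and postsynaptic-population resolution through the
#' dendritic profile. Every allocation stage conserves its parent budget
#' exactly (largest-remainder rounding).
#'
#' @param bundle an [anatomy_bundle()].
#' @param quad_rel_tol convergence tolerance of the column integrals.
#' @return A list of class `connectome` with elements
#'   * `grid`: the [compute_population_sizes()] population grid,
#'   * `synapses`: long tibble (`target_area`, `target_layer`, `target_ei`,
#'     `source_area`, `source_layer`, `source_ei`, `n_synapses`), nonzero
#'     rows only, covering both within-area and inter-areal synapses,
#'   * `external_drive`: tibble (`area`, `layer`, `ei`, `n_synapses_ext`),
#'   * `bookkeeping`: per-area budgets (`n_total`, `n_local`, `n_nonlocal`,
#'     `n_internal`, `n_external`),
#'   * `sln`: source-by-target area matrix of predicted SLN values,
#'   * `bundle`: the input bundle (for delays, surfaces, and constants).
#' @export
#' @examples
#' conn <- assemble_connectome(synth_anatomy(1, n_areas = 3))
#' conn$bookkeeping
assemble_connectome <- function(bundle, quad_rel_tol = 1e-3) {
  stopifnot(inherits(bundle, "anatomy_bundle"))
  const <- bundle$constants
  nm <- bundle_area_names(bundle)
  grid <- compute_population_sizes(bundle)
  f_nonlocal <- nonlocal_fraction(const)

  sizes_of <- function(area) {
    g <- grid[grid$area == area, ]
    stats::setNames(g$size, g$population)[.pops8]
  }
  thickness_of <- function(area) {
    rows <- bundle$areas[bundle$areas$area == area, ]
    stats::setNames(rows$thickness_mm, rows$layer)
  }

  # per-area budgets and local allocation ------------------------------------
  bookkeeping <- vector("list", length(nm))
  local_syn <- vector("list", length(nm))
  ext_drive <- vector("list", length(nm))
  for (i in seq_along(nm)) {
    a <- nm[i]
    n_total <- compute_area_synapse_budget(bundle, a)
    rho <- column_density_integrals(
      h = area_height(bundle, a),
      area_surface = unique(bundle$areas$surface_mm2[bundle$areas$area == a]),
      lambda_conn = const$lambda_conn,
      column_area = const$column_area,
      rel_tol = quad_rel_tol
    )
    split <- split_synapse_budget(n_total, f_nonlocal,
                                  rho$rho_internal, rho$rho_external)
    sizes <- sizes_of(a)
    internal <- distribute_internal(bundle$blueprint, sizes, split$n_internal)
    external <- distribute_external_drive(bundle$blueprint, sizes,
                                          split$n_external)
    bookkeeping[[i]] <- tibble::tibble(
      area = a, n_total = split$n_total, n_local = split$n_local,
      n_nonlocal = split$n_nonlocal, n_internal = split$n_internal,
      n_external = split$n_external
    )
    idx <- which(internal > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      local_syn[[i]] <- tibble::tibble(
        target_area = a,
        target_pop = .pops8[idx[, 2]],
        source_area = a,
        source_pop = .pops8[idx[, 1]],
        n_synapses = internal[idx]
      )
    }
    ext_drive[[i]] <- tibble::tibble(
      area = a,
      population = .pops8,
      n_synapses_ext = unname(external)
    )
  }
  bookkeeping <- dplyr::bind_rows(bookkeeping)

  # predicted SLN matrix (source x target) -----------------------------------
  dens <- vapply(nm, function(a) area_density(bundle, a), 0)
  sln <- outer(seq_along(nm), seq_along(nm), function(ysrc, xtgt) {
    predict_sln(dens[xtgt], dens[ysrc], bundle$sln_fit)
  })
  dimnames(sln) <- list(nm, nm)

  # long-range projections ----------------------------------------------------
  lr <- list()
  k <- 0L
  for (x in nm) {
    n_nonlocal <- bookkeeping$n_nonlocal[bookkeeping$area == x]
    if (n_nonlocal == 0) next
    alloc <- allocate_longrange_sources(bundle$nos, x, n_nonlocal)
    tgt_sizes <- sizes_of(x)
    agranular <- tgt_sizes[["4E"]] + tgt_sizes[["4I"]] == 0
    th <- thickness_of(x)
    for (y in names(alloc)[alloc > 0]) {
      s <- sln[y, x]
      src_sizes <- sizes_of(y)
      src_counts <- laminar_source_counts(s, src_sizes, alloc[[y]])
      lay_w <- laminar_target_distribution(s, th, agranular, const)
      tgt_w <- resolve_postsynaptic_targets(lay_w, bundle$dendrites, s,
                                            tgt_sizes, const)
      cells <- largest_remainder(as.vector(outer(src_counts, tgt_w)),
                                 alloc[[y]])
      cells <- matrix(cells, nrow = 3,
                      dimnames = list(names(src_counts), names(tgt_w)))
      idx <- which(cells > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        k <- k + 1L
        lr[[k]] <- tibble::tibble(
          target_area = x,
          target_pop = colnames(cells)[idx[, 2]],
          source_area = y,
          source_pop = rownames(cells)[idx[, 1]],
          n_synapses = cells[idx]
        )
      }
    }
  }

  synapses <- dplyr::bind_rows(dplyr::bind_rows(local_syn),
                               dplyr::bind_rows(lr)) |>
    dplyr::mutate(
      target_layer = sub("[EI]$", "", .data$target_pop),
      target_ei = sub("^.*(E|I)$", "\\1", .data$target_pop),
      source_layer = sub("[EI]$", "", .data$source_pop),
      source_ei = sub("^.*(E|I)$", "\\1", .data$source_pop)
    ) |>
    dplyr::select("target_area", "target_layer", "target_ei",
                  "source_area", "source_layer", "source_ei", "n_synapses")

  ext <- dplyr::bind_rows(ext_drive) |>
    dplyr::mutate(
      layer = sub("[EI]$", "", .data$population),
      ei = sub("^.*(E|I)$", "\\1", .data$population)
    ) |>
    dplyr::select("area", "layer", "ei", "n_synapses_ext")

  structure(
    list(grid = grid, synapses = synapses, external_drive = ext,
         bookkeeping = bookkeeping, sln = sln, bundle = bundle),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome>", length(unique(x$grid$area)), "areas,",
      format(sum(x$grid$size), big.mark = ","), "neurons,",
      format(sum(x$synapses$n_synapses), big.mark = ","),
      "internal synapses\n")
  invisible(x)
}
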