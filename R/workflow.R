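#' Resolve a run configuration
#'
#' Merges user settings (a YAML/JSON file path or a named list) over the
#' package defaults. Every pipeline run writes its resolved configuration
#' next to its outputs so any artifact can be regenerated.
#'
#' @param config path to a YAML/JSON file, a named list, or `NULL` for the
#'   defaults.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    anatomy = list(
      source = "synthetic", seed = 1, n_areas = 34,
      paths = NULL, constants = list()
    ),
    simulation = list(
      chi = 1, chi_I = 2, scale = 0.01, duration_ms = 10000,
      net_seed = 1, sim_seed = 1, eta_mode = "verbatim", dt = 0.1
    ),
    analysis = list(
      transient_ms = 2500, bin_ms = 1, min_rate = 0.5, min_spikes = 10,
      refractoriness_ms = 5
    ),
    output_dir = "mesocortex_out"
  )
  user <- list()
  if (is.character(config)) {
    user <- yaml::read_yaml(config)
  } else if (is.list(config)) {
    user <- config
  } else if (!is.null(config)) {
    stop("config must be a file path, a list, or NULL")
  }
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_lists(defaults, user), class = "run_config")
}

#' Write a connectome to CSV files
#'
#' Writes the long synapse table, the external-drive table, the bookkeeping
#' budgets, the predicted SLN matrix, and the anatomy bundle (under
#' `anatomy/`) so that [read_connectome()] can reconstruct the object.
#'
#' @param conn a `connectome`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_connectome <- function(conn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(conn$synapses, file.path(dir, "synapses.csv"),
                   progress = FALSE)
  readr::write_csv(conn$external_drive, file.path(dir, "external_drive.csv"),
                   progress = FALSE)
  readr::write_csv(conn$bookkeeping, file.path(dir, "bookkeeping.csv"),
                   progress = FALSE)
  sln <- tibble::as_tibble(as.data.frame(conn$sln))
  sln <- dplyr::bind_cols(tibble::tibble(area = rownames(conn$sln)), sln)
  readr::write_csv(sln, file.path(dir, "sln.csv"), progress = FALSE)
  write_anatomy_bundle(conn$bundle, file.path(dir, "anatomy"))
  invisible(dir)
}

#' Read a connectome written by [write_connectome()]
#'
#' @param dir directory containing the connectome files.
#' @return A `connectome`.
#' @export
read_connectome <- function(dir) {
  adir <- file.path(dir, "anatomy")
  bundle <- load_anatomy_bundle(list(
    areas = file.path(adir, "areas.csv"),
    nos = file.path(adir, "nos.csv"),
    fiber_length = file.path(adir, "fiber_length_mm.csv"),
    blueprint = file.path(adir, "blueprint.csv"),
    k_ext = file.path(adir, "k_ext.csv"),
    dendrites = file.path(adir, "dendrites.csv")
  ))
  syn <- readr::read_csv(file.path(dir, "synapses.csv"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           target_layer = "c", source_layer = "c"
                         ))
  ext <- readr::read_csv(file.path(dir, "external_drive.csv"),
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(layer = "c"))
  book <- readr::read_csv(file.path(dir, "bookkeeping.csv"),
                          show_col_types = FALSE, progress = FALSE)
  slndf <- readr::read_csv(file.path(dir, "sln.csv"),
                           show_col_types = FALSE, progress = FALSE)
  sln <- as.matrix(slndf[, -1])
  rownames(sln) <- slndf$area
  structure(
    list(grid = compute_population_sizes(bundle), synapses = syn,
         external_drive = ext, bookkeeping = book, sln = sln,
         bundle = bundle),
    class = "connectome"
  )
}

#' Write a spike record to disk
#'
#' Spikes go to a whitespace-separated `spikes.gdf` (`neuron_id time_ms`, one
#' event per line), the population index to `populations.csv`, BOLD-proxy
#' traces (if recorded) to `probes.csv`.
#'
#' @param record a `spike_record`.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_spike_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(record$spikes, file.path(dir, "spikes.gdf"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  readr::write_csv(record$populations, file.path(dir, "populations.csv"),
                   progress = FALSE)
  if (!is.null(record$probes)) {
    readr::write_csv(record$probes, file.path(dir, "probes.csv"),
                     progress = FALSE)
  }
  meta <- list(duration_ms = record$duration_ms, dt = record$dt,
               seed = record$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a spike record written by [write_spike_record()]
#'
#' @param dir directory with `spikes.gdf`, `populations.csv`, `meta.json`.
#' @return A `spike_record`.
#' @export
read_spike_record <- function(dir) {
  sp <- utils::read.table(file.path(dir, "spikes.gdf"),
                          col.names = c("neuron_id", "time_ms"))
  pops <- readr::read_csv(file.path(dir, "populations.csv"),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(layer = "c"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  probes <- NULL
  if (file.exists(file.path(dir, "probes.csv"))) {
    probes <- readr::read_csv(file.path(dir, "probes.csv"),
                              show_col_types = FALSE, progress = FALSE)
  }
  structure(
    list(spikes = tibble::as_tibble(sp), populations = pops,
         duration_ms = meta$duration_ms, dt = meta$dt, probes = probes,
         vm = NULL, seed = meta$seed, perturbation = NULL),
    class = "spike_record"
  )
}

#' Sweep the inter-areal scaling factor
#'
#' Simulates the network for each value of the inter-areal synaptic scaling
#' factor `chi` (and each seed), computes the five similarity measures
#' against reference activity data — firing rate, CV ISI, and LvR
#' distributions (Kolmogorov-Smirnov similarity) and functional connectivity
#' (Pearson and RMSE-based) — and reports their across-seed mean and SD per
#' `chi`.
#'
#' @param conn a `connectome`.
#' @param chi_values numeric vector of scaling factors.
#' @param seeds integer vector of seeds (network and simulation).
#' @param reference list with numeric vectors `rates`, `cv_isi`, `lvr` and a
#'   matrix `fc` (experimental comparisons).
#' @param scale network down-scaling factor.
#' @param duration_ms simulated time per run.
#' @param transient_ms discarded initial interval.
#' @param area optional area whose spiking is compared (all areas pooled if
#'   `NULL`).
#' @param n_snippets number of snippets the analysis window is divided into.
#' @param drive [external_drive_params()].
#' @param synapse base [synapse_model_params()] (its `chi` is overridden).
#' @return A tibble with one row per `chi`: mean and SD of the five
#'   similarity measures over seeds.
#' @export
run_chi_sweep <- function(conn, chi_values, seeds = 1,
                          reference, scale = 0.01, duration_ms = 10000,
                          transient_ms = 2500, area = NULL, n_snippets = 5,
                          drive = external_drive_params(),
                          synapse = synapse_model_params()) {
  stopifnot(length(chi_values) >= 1)
  rows <- list()
  for (chi in chi_values) {
    syn <- synapse
    syn$chi <- chi
    per_seed <- lapply(seeds, function(s) {
      net <- realize_network(conn, scale = scale, net_seed = s, synapse = syn)
      rec <- simulate_network(net, duration_ms, drive = drive, seed = s,
                              probes = TRUE)
      stats <- snippet_statistics(rec, transient_ms = transient_ms,
                                  area = area, n = n_snippets)
      fc <- bold_proxy_fc(rec$probes, transient_ms = transient_ms)
      fcs <- fc_similarity(fc, reference$fc)
      tibble::tibble(
        rate_similarity = ks_similarity(stats$rate[stats$included],
                                        reference$rates),
        cv_isi_similarity = ks_similarity(stats$cv_isi[!is.na(stats$cv_isi)],
                                          reference$cv_isi),
        lvr_similarity = ks_similarity(stats$lvr[!is.na(stats$lvr)],
                                       reference$lvr),
        fc_pearson = fcs$pearson,
        fc_rmse_based = fcs$rmse_based
      )
    })
    per_seed <- dplyr::bind_rows(per_seed)
    agg <- dplyr::bind_cols(
      dplyr::summarise(per_seed, dplyr::across(dplyr::everything(), mean)) |>
        dplyr::rename_with(~ paste0(.x, "_mean")),
      dplyr::summarise(
        per_seed,
        dplyr::across(dplyr::everything(),
                      ~ if (length(.x) > 1) stats::sd(.x) else NA_real_)
      ) |>
        dplyr::rename_with(~ paste0(.x, "_sd"))
    )
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(chi = chi, n_seeds = length(seeds)), agg
    )
  }
  dplyr::bind_rows(rows)
}

#' Per-neuron statistics over analysis snippets
#'
#' Divides the post-transient window into `n` equal snippets and computes
#' rates, CV ISI, and LvR per neuron and snippet (mirroring comparisons with
#' short experimental recordings), pooled into one table.
#'
#' @param record a `spike_record`.
#' @param transient_ms discarded initial interval, ms.
#' @param area optional single area (all areas pooled if `NULL`).
#' @param n number of snippets.
#' @param min_rate,min_spikes,refractoriness analysis filters.
#' @return Tibble with `snippet`, `neuron_id`, `rate`, `included`, `cv_isi`,
#'   `lvr`.
#' @export
snippet_statistics <- function(record, transient_ms = 2500, area = NULL,
                               n = 5, min_rate = 0.5, min_spikes = 10,
                               refractoriness = 5) {
  idx <- neuron_index(record)
  if (!is.null(area)) idx <- idx[idx$area %in% area, ]
  sp <- record$spikes[record$spikes$time_ms > transient_ms &
                        record$spikes$neuron_id %in% idx$neuron_id, ]
  sp$time_ms <- sp$time_ms - transient_ms
  total <- record$duration_ms - transient_ms
  snippets <- snippet_split(sp, total_ms = total, n = n)
  len <- total / n
  out <- lapply(seq_len(n), function(i) {
    s <- snippets[[i]]
    rates <- compute_rates(s, idx$neuron_id, len, min_rate)
    by_neuron <- split(s$time_ms, factor(s$neuron_id, levels = idx$neuron_id))
    tibble::tibble(
      snippet = i,
      neuron_id = idx$neuron_id,
      rate = rates$rate,
      included = rates$included,
      cv_isi = vapply(by_neuron, cv_isi, 0, min_spikes = min_spikes),
      lvr = vapply(by_neuron, lvr, 0, refractoriness = refractoriness,
                   min_spikes = min_spikes)
    )
  })
  dplyr::bind_rows(out)
}
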