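#' Per-neuron firing rates
#'
#' Rates are spike counts over the analysis window. All neurons are reported
#' (silent neurons with rate 0); the `included` flag marks neurons passing
#' the minimum-rate filter used for comparisons with experimental data.
#'
#' @param spikes tibble with `neuron_id`, `time_ms` (e.g.
#'   `record$spikes`), already restricted to the analysis window.
#' @param neuron_ids integer vector of all recorded neurons (defines the
#'   silent ones).
#' @param window_ms analysis window length, ms (> 0).
#' @param min_rate minimum rate (spikes/s) for inclusion in comparison sets.
#' @return A tibble `neuron_id`, `n_spikes`, `rate`, `included`.
#' @export
compute_rates <- function(spikes, neuron_ids, window_ms, min_rate = 0.5) {
  if (window_ms <= 0) stop("window_ms must be positive")
  counts <- table(factor(spikes$neuron_id, levels = neuron_ids))
  rate <- as.numeric(counts) / (window_ms / 1000)
  tibble::tibble(
    neuron_id = neuron_ids,
    n_spikes = as.integer(counts),
    rate = rate,
    included = rate >= min_rate
  )
}

#' Coefficient of variation of the interspike intervals
#'
#' `CV = SD(ISI) / mean(ISI)`: 0 for a perfectly regular train, 1 for a
#' Poisson process. Trains with fewer than `min_spikes` spikes are excluded
#' (`NA`), not an error.
#'
#' @param times spike times of one neuron, ms.
#' @param min_spikes minimum number of spikes.
#' @return CV of the ISIs, or `NA` if excluded.
#' @export
cv_isi <- function(times, min_spikes = 10) {
  if (length(times) < min_spikes) return(NA_real_)
  isi <- diff(sort(times))
  stats::sd(isi) / mean(isi)
}

#' Revised local variation (LvR) of a spike train
#'
#' Spike-train irregularity from consecutive interspike-interval pairs,
#' corrected for rate fluctuations and refractoriness:
#' \deqn{LvR = \frac{3}{n-1} \sum_i \left(1 -
#'   \frac{4 I_i I_{i+1}}{(I_i + I_{i+1})^2}\right)
#'   \left(1 + \frac{4R}{I_i + I_{i+1}}\right),}
#' 0 for a regular train and 1 for a Poisson process (at `R = 0`).
#'
#' @param times spike times of one neuron, ms.
#' @param refractoriness refractoriness constant `R`, ms.
#' @param min_spikes minimum number of spikes (exclusion, not error).
#' @return LvR, or `NA` if excluded.
#' @export
lvr <- function(times, refractoriness = 5, min_spikes = 10) {
  if (length(times) < min_spikes) return(NA_real_)
  isi <- diff(sort(times))
  n <- length(isi)
  i1 <- isi[-n]
  i2 <- isi[-1]
  s <- i1 + i2
  3 / (n - 1) * sum((1 - 4 * i1 * i2 / s^2) * (1 + 4 * refractoriness / s))
}

#' Per-neuron spiking statistics of a simulation
#'
#' Applies the standard analysis conventions: the initial transient is
#' discarded; rates are compared only for neurons of at least `min_rate`
#' spikes/s; CV ISI and LvR only for neurons with at least `min_spikes`
#' spikes in the window.
#'
#' @param record a `spike_record`.
#' @param transient_ms initial interval to discard, ms.
#' @param min_rate,min_spikes filter settings.
#' @param refractoriness LvR refractoriness constant, ms.
#' @return A tibble with one row per neuron: `neuron_id`, `pop_index`,
#'   `area`, `layer`, `ei`, `n_spikes`, `rate`, `included`, `cv_isi`, `lvr`.
#' @export
spike_statistics <- function(record, transient_ms = 2500, min_rate = 0.5,
                             min_spikes = 10, refractoriness = 5) {
  window <- record$duration_ms - transient_ms
  if (window <= 0) stop("transient longer than the simulation")
  idx <- neuron_index(record)
  sp <- record$spikes[record$spikes$time_ms > transient_ms, ]
  rates <- compute_rates(sp, idx$neuron_id, window, min_rate)
  by_neuron <- split(sp$time_ms, factor(sp$neuron_id,
                                        levels = idx$neuron_id))
  dplyr::bind_cols(idx[, c("neuron_id", "pop_index", "area", "layer", "ei")],
                   rates[, c("n_spikes", "rate", "included")]) |>
    dplyr::mutate(
      cv_isi = vapply(by_neuron, cv_isi, 0, min_spikes = min_spikes),
      lvr = vapply(by_neuron, lvr, 0, refractoriness = refractoriness,
                   min_spikes = min_spikes)
    )
}

#' Pairwise spike-count correlations of a neuron subsample
#'
#' Pearson correlations of binned spike counts over all pairs of a random
#' subsample (without replacement; the whole set if smaller). Neurons with
#' zero count variance are dropped from the pairs and reported via the
#' `n_dropped` attribute.
#'
#' @param spikes tibble `neuron_id`, `time_ms`, restricted to the window.
#' @param neuron_ids neurons eligible for the subsample.
#' @param window_ms window length, ms.
#' @param bin_ms bin size, ms.
#' @param subsample_size subsample size (default 2000).
#' @param seed subsampling seed (deterministic).
#' @return Numeric vector of pair correlations, with attribute `n_dropped`.
#' @export
pairwise_correlations <- function(spikes, neuron_ids, window_ms, bin_ms = 1,
                                  subsample_size = 2000, seed = 1) {
  if (length(neuron_ids) < 2) stop("need at least 2 neurons")
  sel <- if (length(neuron_ids) > subsample_size) {
    with_seed(seed, function() sample(neuron_ids, subsample_size))
  } else {
    neuron_ids
  }
  sp <- spikes[spikes$neuron_id %in% sel, ]
  breaks <- seq(0, window_ms, by = bin_ms)
  counts <- table(
    factor(sp$neuron_id, levels = sel),
    cut(sp$time_ms, breaks = breaks, include.lowest = TRUE)
  )
  m <- t(matrix(as.numeric(counts), nrow = length(sel)))
  keep <- apply(m, 2, stats::sd) > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 2) {
    out <- numeric(0)
  } else {
    cm <- stats::cor(m[, keep, drop = FALSE])
    out <- cm[upper.tri(cm)]
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Split a spike set into equal-length snippets
#'
#' Divides the analysis window into `n` contiguous equal-length snippets with
#' re-zeroed times, mirroring the comparison of long simulations against
#' short experimental recordings (10 s into 5 snippets of 2 s by default).
#'
#' @param spikes tibble `neuron_id`, `time_ms` with times in `[0, total_ms]`.
#' @param total_ms total window to split, ms.
#' @param n number of snippets.
#' @return A list of `n` tibbles with times re-zeroed to each snippet start.
#' @export
snippet_split <- function(spikes, total_ms = 10000, n = 5) {
  if (max(c(0, spikes$time_ms)) > total_ms) {
    stop("spike times exceed total_ms; restrict the window first")
  }
  len <- total_ms / n
  lapply(seq_len(n), function(i) {
    lo <- (i - 1) * len
    s <- spikes[spikes$time_ms > lo & spikes$time_ms <= lo + len, ]
    s$time_ms <- s$time_ms - lo
    s
  })
}
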