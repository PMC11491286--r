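#' Temporal hierarchy from area-level spike rates
#'
#' Estimates the dominant order of activation across areas ("temporal
#' hierarchy"). Spike trains are aggregated across layers into per-area rate
#' signals in `bin_ms` bins. For each pair of areas the inter-areal delay is
#' the peak location of the cross-correlation of the mean-subtracted signals
#' (maximum lag `max_lag_ms`). When several peaks of similar height (within
#' `peak_tol` of the global maximum) exist, the delay closest to zero is
#' taken if all candidate delays share a sign, otherwise the pair is labeled
#' undecided. Each delay is re-estimated on `n_segments` contiguous segments;
#' if the median absolute deviation of the segment peaks exceeds
#' `mad_threshold_ms` the delay is rejected (undecided). The hierarchy is the
#' ordering of areas (most leading first) minimizing the squared mismatch
#' between the measured delays and delays predicted from rank differences,
#' with the scale per rank step fitted by least squares; the optimizer is
#' exhaustive for up to 8 areas and greedy insertion plus pairwise-swap
#' refinement beyond that.
#'
#' @param record a `spike_record`.
#' @param transient_ms initial interval to discard, ms.
#' @param bin_ms rate-signal bin, ms.
#' @param max_lag_ms maximum cross-correlation lag, ms.
#' @param peak_tol relative height tolerance defining "similar" peaks.
#' @param n_segments number of segments of the consistency check.
#' @param mad_threshold_ms rejection threshold on the segment MAD, ms.
#' @return A list of class `hierarchy_estimate`: `delay_ms` (antisymmetric
#'   matrix with `NA` for undecided pairs), `ordering` (area names, most
#'   leading first), `alpha_ms_per_rank`, `sse`, `n_undecided`.
#' @export
estimate_temporal_hierarchy <- function(record, transient_ms = 2500,
                                        bin_ms = 1, max_lag_ms = 100,
                                        peak_tol = 0.05, n_segments = 9,
                                        mad_threshold_ms = 3) {
  sp <- record$spikes[record$spikes$time_ms > transient_ms, ]
  idx <- neuron_index(record)
  areas <- unique(record$populations$area)
  window <- record$duration_ms - transient_ms
  breaks <- seq(0, window, by = bin_ms)
  area_of <- stats::setNames(idx$area, idx$neuron_id)
  signals <- vapply(areas, function(a) {
    t <- sp$time_ms[area_of[as.character(sp$neuron_id)] == a] - transient_ms
    graphics::hist(t, breaks = breaks, plot = FALSE)$counts
  }, numeric(length(breaks) - 1L))
  hierarchy_from_signals(signals, bin_ms = bin_ms, max_lag_ms = max_lag_ms,
                         peak_tol = peak_tol, n_segments = n_segments,
                         mad_threshold_ms = mad_threshold_ms)
}

#' Temporal hierarchy from already-binned rate signals
#'
#' Core of [estimate_temporal_hierarchy()] operating on a time-by-area signal
#' matrix; exposed for constructed signals and tests.
#'
#' @param signals numeric matrix, rows = time bins, named columns = areas.
#' @inheritParams estimate_temporal_hierarchy
#' @export
hierarchy_from_signals <- function(signals, bin_ms = 1, max_lag_ms = 100,
                                   peak_tol = 0.05, n_segments = 9,
                                   mad_threshold_ms = 3) {
  areas <- colnames(signals)
  n <- ncol(signals)
  if (n < 2) stop("need at least 2 areas")
  k <- floor(max_lag_ms / bin_ms)
  delay <- matrix(NA_real_, n, n, dimnames = list(areas, areas))
  diag(delay) <- 0

  seg_id <- cut(seq_len(nrow(signals)), n_segments, labels = FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d <- pair_delay(signals[, i], signals[, j], k, bin_ms, peak_tol)
      if (!is.na(d) && n_segments > 1) {
        seg_d <- vapply(seq_len(n_segments), function(s) {
          rows <- seg_id == s
          pair_delay(signals[rows, i], signals[rows, j], k, bin_ms,
                     peak_tol, multi_peak_rule = FALSE)
        }, 0)
        seg_d <- seg_d[is.finite(seg_d)]
        if (length(seg_d) < 2 ||
            stats::median(abs(seg_d - stats::median(seg_d))) >
            mad_threshold_ms) {
          d <- NA_real_
        }
      }
      delay[i, j] <- d
      delay[j, i] <- -d
    }
  }
  off <- row(delay) != col(delay)
  if (all(is.na(delay[off]))) {
    stop("all area pairs are undecided: no hierarchy can be estimated")
  }

  ord <- optimize_hierarchy_order(delay)
  structure(
    list(delay_ms = delay, ordering = areas[ord$perm],
         alpha_ms_per_rank = ord$alpha, sse = ord$sse,
         n_undecided = sum(is.na(delay[off])) / 2),
    class = "hierarchy_estimate"
  )
}

# Cross-correlation peak delay between two signals; positive = first signal
# leads. NA when undecided (ambiguous multi-peak) or degenerate.
pair_delay <- function(x, y, k, bin_ms, peak_tol, multi_peak_rule = TRUE) {
  x <- x - mean(x)
  y <- y - mean(y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  k_eff <- min(k, length(x) - 2L)
  cc <- stats::ccf(x, y, lag.max = k_eff, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lags <- seq(-k_eff, k_eff)
  top <- max(cc)
  # candidate peaks: local maxima (plus boundary maxima) of similar height
  loc <- which(diff(sign(diff(cc))) < 0) + 1L
  if (cc[1] > cc[2]) loc <- c(1L, loc)
  if (cc[length(cc)] > cc[length(cc) - 1L]) loc <- c(loc, length(cc))
  loc <- unique(c(loc, which.max(cc)))
  cand <- loc[cc[loc] >= top - peak_tol * abs(top)]
  # ccf(x, y) peaks at negative lag when x leads: flip the sign
  d <- -lags[cand] * bin_ms
  if (length(d) == 1L) return(d)
  if (!multi_peak_rule) return(d[which.min(abs(d))])
  if (all(d >= 0) || all(d <= 0)) return(d[which.min(abs(d))])
  NA_real_
}

# Ordering minimizing sum over decided pairs of
# (delay_ij - alpha * (rank_j - rank_i))^2, alpha >= 0 fitted per permutation.
optimize_hierarchy_order <- function(delay) {
  n <- nrow(delay)
  pairs <- which(upper.tri(delay) & !is.na(delay), arr.ind = TRUE)
  d <- delay[pairs]

  sse_of <- function(perm) {
    pos <- integer(n)
    pos[perm] <- seq_len(n)
    dr <- pos[pairs[, 2]] - pos[pairs[, 1]]
    denom <- sum(dr^2)
    alpha <- if (denom > 0) max(0, sum(d * dr) / denom) else 0
    list(sse = sum((d - alpha * dr)^2), alpha = alpha)
  }

  if (n <= 8) {
    perms <- all_permutations(n)
    best <- NULL
    for (p in perms) {
      r <- sse_of(p)
      if (is.null(best) || r$sse < best$sse - 1e-12) {
        best <- list(perm = p, sse = r$sse, alpha = r$alpha)
      }
    }
    return(best)
  }

  # greedy insertion seeded by mean lead, then pairwise-swap refinement
  lead <- rowMeans(delay, na.rm = TRUE)
  seed_order <- order(-lead, seq_len(n))
  perm <- seed_order[1]
  for (a in seed_order[-1]) {
    cand <- lapply(seq_len(length(perm) + 1), function(pos) {
      append(perm, a, after = pos - 1)
    })
    sses <- vapply(cand, function(p) {
      full <- c(p, setdiff(seq_len(n), p))
      sse_of(full)$sse
    }, 0)
    perm <- cand[[which.min(sses)]]
  }
  improved <- TRUE
  best <- sse_of(perm)
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        p2 <- perm
        p2[c(i, j)] <- p2[c(j, i)]
        r <- sse_of(p2)
        if (r$sse < best$sse - 1e-12) {
          perm <- p2
          best <- r
          improved <- TRUE
        }
      }
    }
  }
  list(perm = perm, sse = best$sse, alpha = best$alpha)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

#' @export
print.hierarchy_estimate <- function(x, ...) {
  cat("<hierarchy_estimate>", length(x$ordering), "areas,",
      x$n_undecided, "undecided pairs\n")
  cat("  ordering (leading -> lagging):",
      paste(x$ordering, collapse = " > "), "\n")
  invisible(x)
}
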