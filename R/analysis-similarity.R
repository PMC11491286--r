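#' Kolmogorov-Smirnov similarity of two samples
#'
#' `1 - sup |ECDF_a - ECDF_b|`: 1 for identical distributions, 0 for fully
#' disjoint supports. Symmetric and invariant under common strictly monotone
#' transforms of both samples.
#'
#' @param sample_a,sample_b nonempty numeric samples.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' ks_similarity(c(1, 2, 3, 4), c(3, 4, 5, 6)) # 0.5
ks_similarity <- function(sample_a, sample_b) {
  sample_a <- sample_a[is.finite(sample_a)]
  sample_b <- sample_b[is.finite(sample_b)]
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be nonempty")
  }
  d <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = FALSE)$statistic
  )
  unname(1 - d)
}

#' Functional connectivity from the summed-|current| BOLD proxy
#'
#' Pearson correlation matrix of the per-area summed absolute synaptic
#' currents (the simulation's BOLD proxy), after removal of the initial
#' transient.
#'
#' @param probe_traces tibble with a `time_ms` column and one column per area
#'   (as produced by [simulate_network()] with `probes = TRUE`).
#' @param transient_ms initial interval to discard, ms.
#' @return A symmetric correlation matrix of class `functional_connectivity`
#'   with unit diagonal.
#' @export
bold_proxy_fc <- function(probe_traces, transient_ms = 2500) {
  m <- as.matrix(probe_traces[probe_traces$time_ms > transient_ms,
                              names(probe_traces) != "time_ms"])
  if (ncol(m) < 2) stop("need at least 2 areas")
  if (nrow(m) < 3) stop("trace too short after transient removal")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant BOLD-proxy trace for area ",
         colnames(m)[which(sds == 0)[1]],
         ": correlation undefined")
  }
  fc <- stats::cor(m)
  class(fc) <- c("functional_connectivity", class(fc))
  fc
}

#' Similarity between two functional-connectivity matrices
#'
#' The Pearson correlation of the off-diagonal entries, and the RMSE-based
#' similarity `exp(-RMSE / sigma_exp)` where `sigma_exp` is the SD of the
#' off-diagonal experimental FC. The Pearson measure captures the linear
#' relationship of relative values; the RMSE-based one also penalizes
#' absolute differences.
#'
#' @param fc_sim,fc_exp square matrices of equal shape (simulated and
#'   experimental FC).
#' @return A tibble with `pearson` and `rmse_based`.
#' @export
fc_similarity <- function(fc_sim, fc_exp) {
  if (!all(dim(fc_sim) == dim(fc_exp))) {
    stop("FC matrices must have the same shape")
  }
  off <- row(fc_sim) != col(fc_sim)
  s <- fc_sim[off]
  e <- fc_exp[off]
  rmse <- sqrt(mean((s - e)^2))
  tibble::tibble(
    pearson = stats::cor(s, e),
    rmse_based = if (rmse == 0) 1 else exp(-rmse / stats::sd(e))
  )
}
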