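test_that("rates count spikes over the window and apply the filter", {
  sp <- tibble::tibble(neuron_id = c(rep(1L, 10), rep(2L, 1)),
                       time_ms = c(seq(100, 1900, length.out = 10), 500))
  r <- compute_rates(sp, 1:3, window_ms = 2000, min_rate = 0.5)
  expect_equal(r$rate, c(5, 0.5, 0))
  expect_equal(r$included, c(TRUE, TRUE, FALSE))
  r2 <- compute_rates(sp[sp$neuron_id == 2, ], 1:2, 2500)
  expect_false(r2$included[r2$neuron_id == 2]) # 0.4 spikes/s excluded
  expect_equal(r2$rate[1], 0)                  # silent neuron reported raw
  expect_error(compute_rates(sp, 1:2, 0), "positive")
})

test_that("CV ISI separates regular from Poisson trains", {
  expect_equal(cv_isi(seq(0, 990, by = 10)), 0)
  expect_true(is.na(cv_isi(1:9)))
  set.seed(11)
  train <- cumsum(stats::rexp(10000, 0.01))
  expect_lt(abs(cv_isi(train) - 1), 0.03)
})

test_that("LvR matches its closed forms and the Poisson limit", {
  expect_equal(lvr(seq(0, 990, by = 10), refractoriness = 0), 0)
  a <- 2; b <- 8
  alt <- cumsum(rep(c(a, b), 60))
  expect_equal(lvr(alt, refractoriness = 0),
               3 * (1 - 4 * a * b / (a + b)^2), tolerance = 1e-12)
  set.seed(12)
  train <- cumsum(stats::rexp(10000, 0.01))
  expect_lt(abs(lvr(train, refractoriness = 0) - 1), 0.05)
  expect_true(is.na(lvr(1:9)))
})

test_that("pairwise correlations detect identity and independence", {
  t0 <- seq(10, 4990, by = 7)
  sp <- tibble::tibble(neuron_id = rep(1:2, each = length(t0)),
                       time_ms = rep(t0, 2))
  cc <- pairwise_correlations(sp, 1:2, window_ms = 5000, seed = 1)
  expect_equal(as.numeric(cc), 1)

  set.seed(13)
  trains <- lapply(1:40, function(i) poisson_train(20, 10000))
  sp <- tibble::tibble(
    neuron_id = rep(seq_along(trains), lengths(trains)),
    time_ms = unlist(trains)
  )
  cc <- pairwise_correlations(sp, 1:40, window_ms = 10000, seed = 2)
  expect_lt(abs(mean(cc)), 0.01)

  # deterministic subsample
  cc2 <- pairwise_correlations(sp, 1:40, window_ms = 10000,
                               subsample_size = 10, seed = 5)
  cc3 <- pairwise_correlations(sp, 1:40, window_ms = 10000,
                               subsample_size = 10, seed = 5)
  expect_identical(cc2, cc3)

  # zero-variance train dropped and logged
  sp0 <- dplyr::bind_rows(sp, tibble::tibble(neuron_id = 41L,
                                             time_ms = numeric(0)))
  cc4 <- pairwise_correlations(sp0, 1:41, window_ms = 10000, seed = 1)
  expect_equal(attr(cc4, "n_dropped"), 1)
})

test_that("KS similarity matches hand-computed ECDF distances", {
  expect_equal(ks_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ks_similarity(1:5, 101:105), 0)
  expect_equal(ks_similarity(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  # symmetry and invariance under a common monotone transform
  set.seed(14)
  a <- stats::rnorm(200); b <- stats::rnorm(200, 0.5)
  expect_equal(ks_similarity(a, b), ks_similarity(b, a))
  expect_equal(ks_similarity(exp(a), exp(b)), ks_similarity(a, b))
  expect_error(ks_similarity(numeric(0), 1:3), "nonempty")
})

test_that("snippet splitting conserves spikes and re-zeroes times", {
  set.seed(15)
  sp <- tibble::tibble(neuron_id = 1L, time_ms = sort(runif(500, 0, 10000)))
  sn <- snippet_split(sp, total_ms = 10000, n = 5)
  expect_length(sn, 5)
  expect_equal(sum(vapply(sn, nrow, 0L)), nrow(sp))
  expect_true(all(vapply(sn, function(s) all(s$time_ms <= 2000), TRUE)))
  one <- snippet_split(sp, total_ms = 10000, n = 1)
  expect_equal(one[[1]]$time_ms, sp$time_ms)
})

test_that("the BOLD-proxy FC is a valid correlation matrix", {
  set.seed(16)
  n <- 10000
  x <- stats::rnorm(n)
  traces <- tibble::tibble(
    time_ms = seq_len(n), a = x, b = x, c = stats::rnorm(n)
  )
  fc <- bold_proxy_fc(traces, transient_ms = 0)
  expect_equal(unname(fc["a", "b"]), 1)
  expect_lt(abs(fc["a", "c"]), 0.05)
  expect_equal(fc, t(fc))
  expect_equal(unname(diag(fc)), rep(1, 3))

  traces$c <- 1
  expect_error(bold_proxy_fc(traces, transient_ms = 0), "area c")
})

test_that("FC of surrogate signals recovers a known correlation", {
  set.seed(17)
  n <- 20000
  rho <- 0.6
  common <- stats::rnorm(n)
  traces <- tibble::tibble(
    time_ms = seq_len(n),
    a = sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n),
    b = sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n)
  )
  fc <- bold_proxy_fc(traces, transient_ms = 0)
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(fc["a", "b"] - rho), 3 * se)
})

test_that("FC similarity has the stated closed forms", {
  set.seed(18)
  m <- matrix(stats::runif(25, -0.2, 0.8), 5)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  s <- fc_similarity(m, m)
  expect_equal(s$pearson, 1)
  expect_equal(s$rmse_based, 1)

  off <- row(m) != col(m)
  m2 <- m
  m2[off] <- m[off] + 0.1
  s <- fc_similarity(m2, m)
  expect_equal(s$pearson, 1)
  expect_equal(s$rmse_based, exp(-0.1 / stats::sd(m[off])))

  s <- fc_similarity(-m, m)
  expect_equal(s$pearson, -1)
  expect_error(fc_similarity(m[1:4, 1:4], m), "shape")
})

test_that("a constructed shift is recovered as a hierarchy delay", {
  set.seed(19)
  x <- stats::filter(stats::rnorm(9000), rep(1, 25), sides = 1)
  x[is.na(x)] <- 0
  shift <- 7
  sig <- cbind(lead = x[(1 + shift):8900], lag = x[1:(8900 - shift)])
  h <- hierarchy_from_signals(sig, bin_ms = 1)
  expect_equal(h$delay_ms["lead", "lag"], 7)
  expect_equal(h$delay_ms["lag", "lead"], -7)
  expect_equal(h$ordering, c("lead", "lag"))

  # antisymmetry on decided pairs for a multi-area constructed cascade
  sig3 <- cbind(a = x[11:8000], b = x[6:7995], c = x[1:7990])
  h3 <- hierarchy_from_signals(sig3, bin_ms = 1)
  d <- h3$delay_ms
  expect_equal(d, -t(d))
  expect_equal(h3$ordering, c("a", "b", "c"))

  # pure common signal with no shift: zero delays, ordering by index
  sig0 <- cbind(b1 = x[1:8000], a2 = x[1:8000])
  h0 <- hierarchy_from_signals(sig0, bin_ms = 1)
  expect_equal(unname(h0$delay_ms["b1", "a2"]), 0)
  expect_equal(h0$ordering, c("b1", "a2"))

  # degenerate signals: every pair undecided
  flat <- cbind(a = rep(0, 900), b = rep(0, 900))
  expect_error(hierarchy_from_signals(flat, bin_ms = 1), "undecided")
})

test_that("perturbation propagation reports first differences per area", {
  pops <- tibble::tibble(area = c("A", "B"), layer = "2/3", ei = "E",
                         size = 5)
  net <- lif_network(pops, net_seed = 1)
  pair <- paired_perturbation_simulate(net, 100, seed = 2,
                                       perturbation = NULL)
  tr <- perturbation_propagation(pair)
  expect_true(tr$no_propagation)
  expect_true(all(is.na(tr$per_area$first_diff_ms)))

  pair <- paired_perturbation_simulate(
    net, 100, seed = 2, perturbation = list(neuron_id = 2, time_ms = 30)
  )
  tr <- perturbation_propagation(pair)
  expect_equal(tr$per_area$first_diff_ms[tr$per_area$area == "A"], 30)
  expect_equal(tr$n_unreached, 1) # no synapses: B is never reached
})
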