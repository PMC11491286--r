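test_that("PSP-to-PSC conversion matches the model's synaptic strengths", {
  expect_equal(round(psp_to_psc(0.1, 220, 10, 2), 1), 16.4)
  expect_equal(round(psp_to_psc(0.1, 100, 10, 2), 1), 7.5)
  expect_error(psp_to_psc(0.1, 220, 10, 10), "singular")
})

test_that("the converted current produces the stated PSP peak (ODE oracle)", {
  skip_if_not_installed("deSolve")
  j <- psp_to_psc(0.1, 220, 10, 2)
  deriv <- function(t, y, p) {
    list(c(-y[1] / 10 + (j * exp(-t / 2)) / 220))
  }
  sol <- deSolve::ode(c(v = 0), seq(0, 40, by = 0.001), deriv, NULL)
  expect_lt(abs(max(sol[, "v"]) / 0.1 - 1), 0.005)
})

test_that("external Poisson rates satisfy the mean-input contract", {
  d <- external_drive_params()
  n <- neuron_params()
  expect_equal(external_poisson_rate(d, n, 1000), 27.5)
  d0 <- external_drive_params(eta_ext = 1e-12)
  expect_lt(external_poisson_rate(d0, n, 1000), 1e-10)
  # nu * K * w * tau_m = eta * (V_th - E_L) for any indegree
  for (k in c(100, 1000, 5000)) {
    nu <- external_poisson_rate(d, n, k) / 1000
    expect_equal(nu * k * d$w_ext * n$tau_m, d$eta_ext * (n$V_th - n$E_L))
  }
  expect_error(external_poisson_rate(d, n, 0), "positive")
})

test_that("weight draws are truncated normals with the right moments", {
  expect_true(all(draw_weights(100, 16.4, 0, seed = 1) == 16.4))
  w <- draw_weights(1e6, 16.4, 0.1, seed = 2)
  expect_true(all(w > 0))
  se <- 0.1 * 16.4 / sqrt(1e6)
  expect_lt(abs(mean(w) - 16.4), 3 * se)
  wi <- draw_weights(1e5, -82, 0.1, seed = 3)
  expect_true(all(wi < 0))
})

test_that("delay draws respect truncation, rounding, and the mean", {
  expect_true(all(draw_delays(100, 1.5, 0, dt = 0.1, seed = 1) == 15))
  d <- draw_delays(1e6, 0.15, 0.5, dt = 0.1, seed = 2)
  expect_true(all(d >= 1))
  d15 <- draw_delays(1e6, 15, 0.5, dt = 0.1, seed = 3)
  expect_lt(abs(mean(d15) * 0.1 / 15 - 1), 0.02)
})

test_that("network realization applies all weight and delay rules", {
  b <- toy_bundle(fiber = 35)
  conn <- assemble_connectome(b)
  syn <- synapse_model_params(chi = 1)
  net <- realize_network(conn, scale = 2e-4, net_seed = 5, synapse = syn)
  proj <- net$projections
  pops <- net$populations
  inter <- pops$area[proj$src] != pops$area[proj$tgt]
  exc_src <- pops$ei[proj$src] == "E"
  onto_e <- pops$ei[proj$tgt] == "E"

  # chi = 1: inter- and intra-areal weights onto a class coincide (except the
  # doubled within-area 4E -> 2/3E projection)
  doubled <- !inter & pops$layer[proj$src] == "4" & exc_src &
    pops$layer[proj$tgt] == "2/3" & onto_e
  expect_equal(unique(proj$w_mean_pA[exc_src & onto_e & !doubled]),
               psp_to_psc(0.1, 220, 10, 2))
  expect_equal(unique(proj$w_mean_pA[doubled]),
               2 * psp_to_psc(0.1, 220, 10, 2))
  # chi_I = 2 doubles inter-areal weights onto inhibitory targets
  expect_equal(unique(proj$w_mean_pA[inter & !onto_e]),
               2 * psp_to_psc(0.1, 100, 10, 2))
  # inhibitory sources: factor -g
  expect_equal(unique(proj$w_mean_pA[!exc_src & onto_e]),
               -5 * psp_to_psc(0.1, 220, 10, 2))
  # inter-areal sources are excitatory only
  expect_true(all(exc_src[inter]))
  # delays: fiber length 35 mm at 3.5 m/s -> 10 ms; local 1.5 / 0.75 ms
  expect_equal(unique(proj$d_mean_ms[inter]), 10)
  expect_equal(unique(proj$d_mean_ms[!inter & exc_src]), 1.5)
  expect_equal(unique(proj$d_mean_ms[!inter & !exc_src]), 0.75)

  # fixed-total-number rule: realized counts equal the specification exactly
  synlist <- get_synapses(net)
  cnt <- table(factor(synlist$projection, levels = seq_len(nrow(proj))))
  expect_equal(as.numeric(cnt), proj$n_synapses)
  # excitatory weights positive, inhibitory negative, delays >= one step
  src_ei <- pops$ei[proj$src][synlist$projection]
  expect_true(all(synlist$weight_pA[src_ei == "E"] > 0))
  expect_true(all(synlist$weight_pA[src_ei == "I"] < 0))
  expect_true(all(synlist$delay_ms >= net$delays$dt))

  # chi = 2.5 scales only the inter-areal weights
  net25 <- realize_network(conn, scale = 2e-4, net_seed = 5,
                           synapse = synapse_model_params(chi = 2.5))
  expect_equal(net25$projections$w_mean_pA[inter],
               2.5 * proj$w_mean_pA[inter])
  expect_equal(net25$projections$w_mean_pA[!inter], proj$w_mean_pA[!inter])
})

test_that("an unstimulated neuron stays silent and relaxes to the leak", {
  net <- lif_network(tibble::tibble(area = "A", layer = "2/3", ei = "E",
                                    size = 1))
  rec <- simulate_network(net, 300, seed = 2, probes = FALSE, record_vm = 1)
  expect_equal(nrow(rec$spikes), 0)
  expect_lt(abs(utils::tail(rec$vm$v_mV, 1) + 70), 1e-6)
})

test_that("constant suprathreshold current matches the closed-form period", {
  for (mu in c(28, 35, 60)) {
    net <- lif_network(tibble::tibble(area = "A", layer = "2/3", ei = "E",
                                      size = 1, i_const_pA = mu * 220 / 10))
    rec <- simulate_network(net, 3000, seed = 1, probes = FALSE)
    period <- 2 + 10 * log(mu / (mu - 25))
    isis <- diff(rec$spikes$time_ms)
    expect_true(all(abs(isis - period) <= 0.1 + 1e-9))
  }
})

test_that("simulations are bit-identical given the seeds", {
  conn <- assemble_connectome(toy_bundle())
  net <- realize_network(conn, scale = 2e-4, net_seed = 3)
  r1 <- simulate_network(net, 500, seed = 4)
  r2 <- simulate_network(net, 500, seed = 4)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$probes, r2$probes)
  r3 <- simulate_network(net, 500, seed = 5)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a single presynaptic spike produces the nominal PSP peak", {
  pops <- tibble::tibble(area = "A", layer = c("2/3", "4"), ei = "E",
                         size = 1)
  proj <- tibble::tibble(src = 1, tgt = 2, n_synapses = 1,
                         w_mean_pA = psp_to_psc(0.1, 220, 10, 2),
                         w_sd_pA = 0, d_mean_ms = 1.5, d_rel_sd = 0)
  net <- lif_network(pops, proj)
  rec <- simulate_network(net, 200, seed = 3, probes = FALSE,
                          perturbation = list(neuron_id = 1, time_ms = 120),
                          record_vm = 2)
  base <- rec$vm$v_mV[rec$vm$time_ms == 120]
  peak <- max(rec$vm$v_mV[rec$vm$time_ms > 120]) - base
  expect_lt(abs(peak / 0.1 - 1), 0.005)
})

test_that("the isolated neuron's rate is invariant under the indegree", {
  drive <- external_drive_params(mode = "strict")
  rates <- vapply(c(1000, 4000), function(k) {
    net <- lif_network(tibble::tibble(area = "A", layer = "2/3", ei = "E",
                                      size = 1, k_ext = k))
    rec <- simulate_network(net, 20000, drive = drive, seed = 8,
                            probes = FALSE)
    nrow(rec$spikes) / 20
  }, 0)
  expect_lt(abs(rates[1] / rates[2] - 1), 0.06)
})

test_that("paired runs share every random number", {
  conn <- assemble_connectome(toy_bundle())
  net <- realize_network(conn, scale = 2e-4, net_seed = 7)
  pair <- paired_perturbation_simulate(net, 400, seed = 9,
                                       perturbation = NULL)
  expect_identical(pair$unperturbed$spikes, pair$perturbed$spikes)

  # perturbation in an otherwise silent network: exactly one extra spike
  pops <- tibble::tibble(area = "A", layer = "2/3", ei = "E", size = 50)
  silent <- lif_network(pops)
  pair <- paired_perturbation_simulate(
    silent, 100, seed = 1, perturbation = list(neuron_id = 17, time_ms = 40)
  )
  expect_equal(nrow(pair$unperturbed$spikes), 0)
  expect_equal(nrow(pair$perturbed$spikes), 1)
  expect_equal(pair$perturbed$spikes$time_ms, 40)
  expect_equal(pair$perturbed$spikes$neuron_id, 17)

  expect_error(
    simulate_network(silent, 100, seed = 1,
                     perturbation = list(neuron_id = 99, time_ms = 10)),
    "valid neuron_id"
  )
})

test_that("population rates match a self-consistent mean-field estimate", {
  n_e <- 1600; n_i <- 400; k_e <- 160; k_i <- 40; g <- 5
  j_e_on_e <- psp_to_psc(0.1, 220, 10, 2)
  j_e_on_i <- psp_to_psc(0.1, 100, 10, 2)
  pops <- tibble::tibble(area = "A", layer = "2/3", ei = c("E", "I"),
                         size = c(n_e, n_i), k_ext = 800)
  proj <- tibble::tibble(
    src = c(1, 1, 2, 2), tgt = c(1, 2, 1, 2),
    n_synapses = c(k_e * n_e, k_e * n_i, k_i * n_e, k_i * n_i),
    w_mean_pA = c(j_e_on_e, j_e_on_i, -g * j_e_on_e, -g * j_e_on_i),
    w_sd_pA = 0.1 * abs(c(j_e_on_e, j_e_on_i, g * j_e_on_e, g * j_e_on_i)),
    d_mean_ms = c(1.5, 1.5, 0.75, 0.75), d_rel_sd = 0.5
  )
  net <- lif_network(pops, proj, net_seed = 2)
  drive <- external_drive_params(eta_ext = 1.0, mode = "strict")
  rec <- simulate_network(net, 6000, drive = drive, seed = 3, probes = FALSE)
  idx <- neuron_index(rec)
  sp <- rec$spikes[rec$spikes$time_ms > 1500, ]
  sim <- c(sum(idx$ei[sp$neuron_id] == "E") / n_e,
           sum(idx$ei[sp$neuron_id] == "I") / n_i) / 4.5
  rate_ext <- external_poisson_rate(drive, neuron_params(), 800) * 800 / 1000
  mf <- meanfield_rates(k_e, k_i, g, rate_ext, neuron_params())
  expect_lt(abs(sim[1] / mf[1] - 1), 0.2)
  expect_lt(abs(sim[2] / mf[2] - 1), 0.2)
})

test_that("optional down-scaling variants and distributed parameters work", {
  conn <- assemble_connectome(toy_bundle())
  base <- realize_network(conn, scale = 2e-4, net_seed = 3)
  fluct <- realize_network(conn, scale = 2e-4, net_seed = 3,
                           fluctuation_scaling = TRUE)
  expect_equal(fluct$projections$w_mean_pA,
               base$projections$w_mean_pA / sqrt(2e-4))

  # distributed neuron parameters behind the CV flag, default off
  nr <- neuron_params(cv = list(V_th = c(E = 0.21, I = 0.22),
                                C_m = c(E = 0.22, I = 0.34),
                                tau_m = c(E = 0.55, I = 0.43)))
  net <- lif_network(tibble::tibble(area = "A", layer = "2/3", ei = "E",
                                    size = 200, k_ext = 2000),
                     neuron = nr)
  rec <- simulate_network(net, 2000, seed = 4, probes = FALSE)
  net0 <- lif_network(tibble::tibble(area = "A", layer = "2/3", ei = "E",
                                     size = 200, k_ext = 2000))
  rec0 <- simulate_network(net0, 2000, seed = 4, probes = FALSE)
  expect_false(identical(rec$spikes, rec0$spikes))
  # distributed thresholds spread the per-neuron rates
  r <- compute_rates(rec$spikes, 1:200, 2000)
  r0 <- compute_rates(rec0$spikes, 1:200, 2000)
  expect_gt(stats::sd(r$rate), stats::sd(r0$rate))
})
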