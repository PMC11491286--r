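test_that("population sizes follow density x thickness x column area", {
  b <- toy_bundle(density = 5e4, thickness = c("2/3" = 0.5, "4" = 0,
                                               "5" = 0.4, "6" = 0.4))
  # force a clean excitatory fraction for the hand computation
  b$areas$exc_fraction[b$areas$layer == "2/3"] <- 0.8
  grid <- compute_population_sizes(b)
  g1 <- grid[grid$area == "A01", ]
  expect_equal(g1$size[g1$population == "2/3E"], 20000)
  expect_equal(g1$size[g1$population == "2/3I"], 5000)
  # absent layer: zero neurons, populations retained but flagged
  expect_equal(g1$size[g1$layer == "4"], c(0, 0))
  expect_false(any(g1$present[g1$layer == "4"]))
  # boundary: fully excitatory layer
  b$areas$exc_fraction[b$areas$layer == "5"] <- 1
  g2 <- compute_population_sizes(b)
  expect_equal(g2$size[g2$area == "A01" & g2$population == "5I"], 0)
})

test_that("synapse budgets scale with column volume and density", {
  b <- toy_bundle(thickness = c("2/3" = 1, "4" = 0.5, "5" = 0.5, "6" = 0.5))
  expect_equal(compute_area_synapse_budget(b, "A01"), 6.6e8 * 2.5)
  bh <- toy_bundle(constants = model_constants(rho_synapse = 3.3e8))
  expect_equal(compute_area_synapse_budget(bh, "A01") * 2,
               compute_area_synapse_budget(toy_bundle(), "A01"))
})

test_that("the white-matter scaling rule reproduces its calibration", {
  expect_equal(round(nonlocal_fraction(model_constants()), 2), 0.14)
  expect_equal(nonlocal_fraction(model_constants(human_neurons = 1.4e9)),
               0.21)
  expect_equal(
    nonlocal_fraction(model_constants(scaling_exponent = 1e-12)), 0.21,
    tolerance = 1e-9
  )
})

test_that("budget splitting conserves synapses exactly", {
  s <- split_synapse_budget(1000, 0, 1, 0)
  expect_equal(s$n_internal, 1000)
  expect_equal(s$n_external + s$n_nonlocal, 0)

  s <- split_synapse_budget(1e6, 0.14, 2.5, 2.5)
  expect_equal(s$n_nonlocal, 140000)
  expect_lte(abs(s$n_internal - s$n_external), 1)
  expect_equal(s$n_internal + s$n_external, s$n_local)

  s <- split_synapse_budget(1.65e9, 0.14, 1, 1)
  expect_equal(s$n_nonlocal, 2.31e8)

  # largest-remainder apportionment is exact for arbitrary weights
  set.seed(1)
  for (i in 1:20) {
    w <- stats::runif(8)
    n <- sample.int(1e6, 1)
    out <- largest_remainder(w, n)
    expect_equal(sum(out), n)
    expect_true(all(out == round(out)))
    expect_true(all(abs(out - w / sum(w) * n) <= 1))
  }
})

test_that("internal synapses follow the blueprint weights", {
  bp <- blueprint_pd()
  sizes <- stats::setNames(rep(1000, 8), mesocortex:::.pops8)

  uniform <- bp
  uniform$q <- matrix(1, 8, 8, dimnames = dimnames(bp$q))
  out <- distribute_internal(uniform, sizes, 64000)
  expect_true(all(out == 1000))

  single <- bp
  single$q <- matrix(0, 8, 8, dimnames = dimnames(bp$q))
  single$q["4E", "2/3E"] <- 2
  out <- distribute_internal(single, sizes, 12345)
  expect_equal(out["4E", "2/3E"], 12345)
  expect_equal(sum(out), 12345)

  # zero-size populations send and receive nothing; budget still conserved
  sizes0 <- sizes
  sizes0[c("4E", "4I")] <- 0
  out <- distribute_internal(bp, sizes0, 1e6)
  expect_equal(sum(out), 1e6)
  expect_true(all(out[c("4E", "4I"), ] == 0))
  expect_true(all(out[, c("4E", "4I")] == 0))

  expect_error(distribute_internal(single, sizes0 * 0, 10), "population pair")
})

test_that("external drive splits by indegree times population size", {
  bp <- blueprint_pd()
  sizes <- stats::setNames(rep(500, 8), mesocortex:::.pops8)
  equal <- bp
  equal$k_ext <- stats::setNames(rep(2000, 8), mesocortex:::.pops8)
  out <- distribute_external_drive(equal, sizes, 8000)
  expect_true(all(out == 1000))

  two <- bp
  two$k_ext <- stats::setNames(c(2000, 1000, rep(0, 6)), mesocortex:::.pops8)
  sizes2 <- stats::setNames(c(100, 200, rep(0, 6)), mesocortex:::.pops8)
  out <- distribute_external_drive(two, sizes2, 400000)
  expect_equal(unname(out[1:2]), c(200000, 200000))
  expect_true(all(out[3:8] == 0))
})

test_that("long-range synapses follow relative streamline counts", {
  nm <- c("w", "x", "y", "z")
  nos <- matrix(1, 4, 4, dimnames = list(nm, nm))
  diag(nos) <- 0
  out <- allocate_longrange_sources(nos, "x", 300)
  expect_equal(unname(out), c(100, 100, 100))
  expect_false("x" %in% names(out))

  nos["w", "x"] <- 0
  out <- allocate_longrange_sources(nos, "x", 301)
  expect_equal(unname(out["w"]), 0)
  expect_equal(sum(out), 301)

  nos[, "x"] <- 0
  expect_error(allocate_longrange_sources(nos, "x", 10), "x is isolated")
})

test_that("SLN prediction matches the probit model", {
  expect_equal(round(predict_sln(5e4, 5e4), 4), 0.4396)
  # strictly decreasing in the density ratio, bounded in (0, 1)
  ratios <- exp(seq(-3, 3, length.out = 50))
  s <- predict_sln(4e4 * ratios, 4e4)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s < 1))
  expect_lt(predict_sln(4e4 * 1e4, 4e4), 1e-6)
  expect_error(predict_sln(-1, 10), "positive")
})

test_that("laminar origin splits by SLN and infragranular sizes", {
  sizes <- c("2/3E" = 100, "5E" = 300, "6E" = 100)
  expect_equal(unname(laminar_source_counts(1, sizes, 500)), c(500, 0, 0))
  expect_equal(
    unname(laminar_source_counts(0, c("2/3E" = 10, "5E" = 50, "6E" = 50),
                                 400)),
    c(0, 200, 200)
  )
  expect_equal(unname(laminar_source_counts(0.6, sizes, 1000)),
               c(600, 300, 100))
  expect_error(
    laminar_source_counts(0.5, c("2/3E" = 0, "5E" = 0, "6E" = 0), 10),
    "no excitatory"
  )
})

test_that("laminar target patterns follow the SLN classes", {
  th <- c("1" = 0.2, "2/3" = 0.8, "4" = 0.5, "5" = 0.6, "6" = 0.4)
  w <- laminar_target_distribution(0.9, th, agranular = FALSE)
  expect_equal(unname(w["4"]), 1)
  w <- laminar_target_distribution(0.9, th, agranular = TRUE)
  expect_equal(unname(w["2/3"]), 1)
  w <- laminar_target_distribution(0.2, c("1" = 0.2, "2/3" = 0.8,
                                          "5" = 0.6, "6" = 0.4))
  expect_equal(unname(w[c("1", "2/3", "5", "6")]), c(0.1, 0.4, 0.3, 0.2))
  expect_equal(unname(w["4"]), 0)
  w <- laminar_target_distribution(0.5, th)
  expect_equal(sum(w), 1)
  expect_true(all(w[c("1", "2/3", "4", "5", "6")] > 0))
  expect_error(laminar_target_distribution(0.5, th * 0), "zero total")
})

test_that("postsynaptic resolution routes through the dendrite profile", {
  sizes <- stats::setNames(rep(100, 8), mesocortex:::.pops8)
  # dendrites only in the soma layer: excitatory synapses stay in their layer
  diag_d <- matrix(0, 5, 4, dimnames = list(mesocortex:::.syn_layers,
                                            mesocortex:::.layers))
  diag_d["2/3", "2/3"] <- diag_d["4", "4"] <- 1
  diag_d["5", "5"] <- diag_d["6", "6"] <- 1
  diag_d["1", ] <- 0.25
  lw <- c("4" = 1)
  w <- resolve_postsynaptic_targets(lw, diag_d, sln = 0.9, sizes)
  expect_equal(unname(w["4E"] / (w["4E"] + w["4I"])), 0.85)
  expect_equal(unname(w["4E"] + w["4I"]), 1)

  # feedback: excitatory share fixed at exactly 0.93
  lw <- c("1" = 0.2, "2/3" = 0.4, "5" = 0.25, "6" = 0.15)
  w <- resolve_postsynaptic_targets(lw, dendritic_profile_synthetic(),
                                    sln = 0.2, sizes)
  expect_equal(sum(w[endsWith(names(w), "E")]), 0.93)
  expect_equal(sum(w), 1)

  # all weight in layer 1, uniform dendrite row, fully excitatory targets
  unif <- diag_d
  unif["1", ] <- 1
  const1 <- model_constants(
    ei_target_exc_share = stats::setNames(c(1, rep(0.85, 4)),
                                          mesocortex:::.syn_layers)
  )
  w <- resolve_postsynaptic_targets(c("1" = 1), unif, sln = 0.5, sizes,
                                    constants = const1)
  expect_equal(unname(w[paste0(mesocortex:::.layers, "E")]), rep(0.25, 4))
})

test_that("an assembled connectome conserves every budget", {
  conn <- assemble_connectome(synth_anatomy(seed = 9, n_areas = 3))
  book <- conn$bookkeeping
  syn <- conn$synapses

  local <- syn[syn$source_area == syn$target_area, ]
  by_area <- tapply(local$n_synapses, local$target_area, sum)
  expect_equal(as.numeric(by_area[book$area]), book$n_internal)

  ext <- tapply(conn$external_drive$n_synapses_ext,
                conn$external_drive$area, sum)
  expect_equal(as.numeric(ext[book$area]), book$n_external)

  lr <- syn[syn$source_area != syn$target_area, ]
  by_target <- tapply(lr$n_synapses, lr$target_area, sum)
  expect_equal(as.numeric(by_target[book$area]), book$n_nonlocal)

  expect_equal(book$n_internal + book$n_external, book$n_local)
  expect_equal(book$n_local + book$n_nonlocal, book$n_total)
})

test_that("agranular areas exchange no layer-4 synapses", {
  conn <- assemble_connectome(toy_bundle(l4_zero = TRUE))
  syn <- conn$synapses
  expect_equal(sum(syn$n_synapses[syn$target_area == "A02" &
                                    syn$target_layer == "4"]), 0)
  expect_equal(sum(syn$n_synapses[syn$source_area == "A02" &
                                    syn$source_layer == "4"]), 0)
  ext <- conn$external_drive
  expect_equal(sum(ext$n_synapses_ext[ext$area == "A02" & ext$layer == "4"]),
               0)
  # feedforward synapses into the agranular area are redirected to layer 2/3
  sln_in <- conn$sln[, "A02"]
  if (any(sln_in > 0.65)) {
    ff_src <- names(sln_in)[sln_in > 0.65][1]
    ff <- syn[syn$source_area == ff_src & syn$target_area == "A02", ]
    expect_true(all(ff$target_layer != "4"))
  }
})

test_that("isolated areas are rejected when nonlocal synapses exist", {
  b <- toy_bundle(nos_value = 0)
  expect_error(assemble_connectome(b), "isolated")
})

test_that("structural validation recovers the generating distance decay", {
  b <- synth_anatomy(seed = 31, n_areas = 34)
  conn <- assemble_connectome(b)
  rep <- validate_connectome(conn)
  expect_lt(abs(rep$distance_decay$lambda_mm / 45 - 1), 0.15)
  expect_gt(rep$lognormal_fit$sdlog10, 0)
  expect_true(all(c("FF", "LAT", "FB") %in%
                    as.character(rep$outdegree_stats$class)))
  expect_gte(rep$path_stats$max_unweighted, 1)
  expect_gt(rep$path_stats$max_delay_ms, 0)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 1)
})

test_that("boundary SLN values classify as lateral", {
  cls <- sln_class(c(0.66, 0.65, 0.5, 0.35, 0.34))
  expect_equal(as.character(cls), c("FF", "LAT", "LAT", "LAT", "FB"))
})

test_that("shortest paths are all 1 on a complete population graph", {
  n <- 5
  grid <- tibble::tibble(pop_id = 1:n, size = 10, present = TRUE)
  proj <- tidyr::expand_grid(src_pop_id = 1:n, tgt_pop_id = 1:n) |>
    dplyr::filter(src_pop_id != tgt_pop_id) |>
    dplyr::mutate(n_synapses = 5, d_mean_ms = 1.5)
  ps <- mesocortex:::population_path_stats(proj, grid)
  expect_equal(ps$max_unweighted, 1)
  expect_equal(ps$n_unreachable, 0)
})
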