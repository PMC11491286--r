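test_that("run configurations merge user settings over defaults", {
  cfg <- run_config()
  expect_equal(cfg$simulation$chi, 1)
  expect_equal(cfg$analysis$transient_ms, 2500)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(simulation = list(chi = 2.5, scale = 0.001)), f)
  cfg <- run_config(f)
  expect_equal(cfg$simulation$chi, 2.5)
  expect_equal(cfg$simulation$scale, 0.001)
  expect_equal(cfg$simulation$duration_ms, 10000) # untouched default
})

test_that("connectome and spike-record files round-trip", {
  conn <- assemble_connectome(synth_anatomy(seed = 21, n_areas = 3))
  dir <- withr::local_tempdir()
  write_connectome(conn, dir)
  conn2 <- read_connectome(dir)
  expect_equal(conn2$synapses, conn$synapses)
  expect_equal(conn2$bookkeeping, conn$bookkeeping)
  expect_equal(conn2$sln, conn$sln)
  expect_equal(conn2$grid$size, conn$grid$size)

  net <- suppressWarnings(realize_network(conn, scale = 2e-4, net_seed = 1))
  rec <- simulate_network(net, 300, seed = 1)
  rdir <- withr::local_tempdir()
  write_spike_record(rec, rdir)
  rec2 <- read_spike_record(rdir)
  expect_equal(rec2$spikes$neuron_id, rec$spikes$neuron_id)
  expect_equal(rec2$spikes$time_ms, rec$spikes$time_ms)
  expect_equal(rec2$duration_ms, rec$duration_ms)
  expect_equal(as.data.frame(rec2$probes), as.data.frame(rec$probes),
               tolerance = 1e-12)
})

test_that("the CLI chains gen-anatomy, build, validate, and simulate", {
  dir <- withr::local_tempdir()
  anat <- file.path(dir, "anat")
  connd <- file.path(dir, "conn")
  rund <- file.path(dir, "run")

  expect_equal(suppressMessages(
    cli(c("gen-anatomy", "--seed", "1", "--n-areas", "3", "--out", anat))
  ), 0L)
  expect_true(file.exists(file.path(anat, "areas.csv")))

  expect_equal(suppressMessages(
    cli(c("build-connectome", "--anatomy", anat, "--out", connd))
  ), 0L)
  expect_true(file.exists(file.path(connd, "synapses.csv")))

  vfile <- file.path(dir, "validation.json")
  expect_equal(suppressMessages(
    cli(c("validate-connectome", "--connectome", connd, "--out", vfile))
  ), 0L)
  expect_true(file.exists(vfile))

  expect_equal(suppressMessages(
    cli(c("simulate", "--connectome", connd, "--chi", "2.5",
          "--scale", "2e-4", "--duration", "300", "--out", rund))
  ), 0L)
  expect_true(file.exists(file.path(rund, "spikes.gdf")))
  expect_true(file.exists(file.path(rund, "probes.csv")))
  expect_true(file.exists(file.path(rund, "resolved_config.yaml")))

  adir <- file.path(dir, "analysis")
  expect_equal(suppressMessages(
    cli(c("analyze", "--spikes", rund, "--transient", "100", "--out", adir))
  ), 0L)
  expect_true(file.exists(file.path(adir, "per_neuron.csv")))

  pdir <- file.path(dir, "pert")
  expect_equal(suppressMessages(
    cli(c("perturb", "--connectome", connd, "--scale", "2e-4",
          "--duration", "100", "--neuron", "1", "--time", "20",
          "--out", pdir))
  ), 0L)
  expect_true(file.exists(file.path(pdir, "propagation.json")))

  # unknown subcommand and missing inputs exit nonzero
  expect_equal(suppressMessages(cli("frobnicate")), 1L)
  expect_equal(suppressMessages(cli(c("build-connectome", "--anatomy",
                                      file.path(dir, "missing")))), 1L)
})

test_that("a truncated streamline matrix fails the CLI with nonzero status", {
  dir <- withr::local_tempdir()
  anat <- file.path(dir, "anat")
  suppressMessages(cli(c("gen-anatomy", "--seed", "2", "--n-areas", "4",
                         "--out", anat)))
  nos <- readr::read_csv(file.path(anat, "nos.csv"), show_col_types = FALSE)
  readr::write_csv(nos[-1, ], file.path(anat, "nos.csv"))
  expect_equal(suppressMessages(
    cli(c("build-connectome", "--anatomy", anat,
          "--out", file.path(dir, "conn")))
  ), 1L)
})

test_that("the chi sweep reports all five similarity measures", {
  conn <- assemble_connectome(synth_anatomy(seed = 23, n_areas = 3))
  areas <- bundle_area_names(conn$bundle)
  set.seed(24)
  fc_ref <- matrix(stats::runif(9, -0.2, 0.8), 3,
                   dimnames = list(areas, areas))
  fc_ref <- (fc_ref + t(fc_ref)) / 2
  diag(fc_ref) <- 1
  reference <- list(
    rates = stats::rexp(200, 1 / 5),
    cv_isi = stats::rnorm(200, 1, 0.2),
    lvr = stats::rnorm(200, 1, 0.3),
    fc = fc_ref
  )
  tab <- run_chi_sweep(conn, chi_values = 1, seeds = 1,
                       reference = reference, scale = 3e-4,
                       duration_ms = 3000, transient_ms = 500,
                       n_snippets = 1)
  expect_equal(nrow(tab), 1)
  need <- paste0(c("rate_similarity", "cv_isi_similarity", "lvr_similarity",
                   "fc_pearson", "fc_rmse_based"), "_mean")
  expect_true(all(need %in% names(tab)))
  expect_true(all(is.finite(unlist(tab[need]))))

  tab2 <- run_chi_sweep(conn, chi_values = 1, seeds = 1,
                        reference = reference, scale = 3e-4,
                        duration_ms = 3000, transient_ms = 500,
                        n_snippets = 1)
  expect_identical(tab, tab2)
})
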