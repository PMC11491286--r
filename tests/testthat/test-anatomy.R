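test_that("a written bundle loads back exactly (round trip)", {
  b <- synth_anatomy(seed = 42, n_areas = 5)
  dir <- withr::local_tempdir()
  paths <- write_anatomy_bundle(b, dir)
  b2 <- load_anatomy_bundle(paths)
  expect_equal(b2$areas, b$areas)
  expect_identical(b2$nos, b$nos)
  expect_identical(b2$fiber_length_mm, b$fiber_length_mm)
  expect_equal(b2$blueprint$q, b$blueprint$q)
  expect_identical(unname(b2$blueprint$k_ext), unname(b$blueprint$k_ext))
  expect_identical(b2$dendrites, b$dendrites)
})

test_that("the loader rejects malformed inputs with descriptive errors", {
  b <- synth_anatomy(seed = 7, n_areas = 3)
  dir <- withr::local_tempdir()
  paths <- write_anatomy_bundle(b, dir)

  # drop one row of the NoS matrix: dimension mismatch
  nos <- readr::read_csv(paths$nos, show_col_types = FALSE)
  readr::write_csv(nos[-2, ], paths$nos)
  expect_error(load_anatomy_bundle(paths), "3x3")

  # negative density names area and layer
  paths <- write_anatomy_bundle(b, dir)
  areas <- readr::read_csv(paths$areas, show_col_types = FALSE)
  i <- which(areas$area == "A02" & areas$layer == "5")
  areas$density_per_mm3[i] <- -1
  readr::write_csv(areas, paths$areas)
  err <- tryCatch(load_anatomy_bundle(paths), error = conditionMessage)
  expect_match(err, "density")
  expect_match(err, "A02")
  expect_match(err, "5")

  # unknown area name in a matrix header
  paths <- write_anatomy_bundle(b, dir)
  nos <- readr::read_csv(paths$nos, show_col_types = FALSE)
  names(nos)[2] <- "nowhere"
  readr::write_csv(nos, paths$nos)
  expect_error(load_anatomy_bundle(paths), "area")
})

test_that("sub-area aggregation averages thicknesses and weights densities", {
  # single sub-area: identity
  one <- tibble::tibble(sub_area = "a", layer = c("2/3", "4"),
                        thickness_mm = c(1, 0.5),
                        density_per_mm3 = c(40, 80))
  out <- aggregate_vek_to_dk(one)
  expect_equal(out$thickness_mm[out$layer == "2/3"], 1)
  expect_equal(out$density_per_mm3[out$layer == "4"], 80)

  # two sub-areas, thicknesses 1 and 3, equal densities -> thickness 2
  two <- tibble::tibble(sub_area = c("a", "b"), layer = "5",
                        thickness_mm = c(1, 3), density_per_mm3 = 50)
  out <- aggregate_vek_to_dk(two)
  expect_equal(out$thickness_mm, 2)
  expect_equal(out$density_per_mm3, 50)

  # thickness-weighted density: equal thicknesses, densities 10 and 30 -> 20
  w <- tibble::tibble(sub_area = c("a", "b"), layer = "4",
                      thickness_mm = c(1, 1), density_per_mm3 = c(10, 30))
  expect_equal(aggregate_vek_to_dk(w)$density_per_mm3, 20)

  # sub-layers of one sub-area: thicknesses summed, densities weighted
  sl <- tibble::tibble(sub_area = "a", layer = "2/3",
                       thickness_mm = c(0.25, 0.75),
                       density_per_mm3 = c(100, 20))
  out <- aggregate_vek_to_dk(sl)
  expect_equal(out$thickness_mm, 1)
  expect_equal(out$density_per_mm3, 0.25 * 100 + 0.75 * 20)

  expect_error(aggregate_vek_to_dk(one[0, ]), "empty")
  bad <- tibble::tibble(sub_area = "a", layer = "4", thickness_mm = 0,
                        density_per_mm3 = 10)
  expect_error(aggregate_vek_to_dk(bad), "zero thickness")
})

test_that("the synthetic generator is reproducible and validates", {
  b1 <- synth_anatomy(seed = 3, n_areas = 6)
  b2 <- synth_anatomy(seed = 3, n_areas = 6)
  expect_identical(b1$areas, b2$areas)
  expect_identical(b1$nos, b2$nos)
  expect_identical(b1$fiber_length_mm, b2$fiber_length_mm)
  b3 <- synth_anatomy(seed = 4, n_areas = 6)
  expect_false(identical(b1$nos, b3$nos))

  # output always passes load-time validation (constructor validates; also
  # survives a disk round trip)
  dir <- withr::local_tempdir()
  expect_s3_class(load_anatomy_bundle(write_anatomy_bundle(b1, dir)),
                  "anatomy_bundle")

  # 34-area default uses the standard parcellation names
  b34 <- synth_anatomy(seed = 1)
  expect_identical(bundle_area_names(b34), dk_areas()$area)

  expect_error(synth_anatomy(seed = 1, n_areas = 1), "at least 2")
  expect_error(synth_anatomy_spec(nos_sdlog = -1), "nonnegative")
  expect_error(synth_anatomy_spec(lambda_mm = 0), "positive")
})

test_that("generating parameters are recovered from synthetic streamlines", {
  spec <- synth_anatomy_spec()
  fits <- dplyr::bind_rows(lapply(1:5, function(s) {
    b <- synth_anatomy(seed = s, n_areas = 34)
    fit_distance_decay(b$nos, b$fiber_length_mm)
  }))
  expect_lt(abs(mean(fits$lambda_mm) / spec$lambda_mm - 1), 0.15)
  expect_lt(abs(mean(fits$meanlog) / spec$nos_meanlog - 1), 0.15)
  expect_lt(abs(mean(fits$sdlog) / spec$nos_sdlog - 1), 0.15)
})
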