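#' Parameters of the synthetic anatomy generator
#'
#' The generator emulates the statistical structure of the real anatomical
#' inputs: streamline counts are log-normally distributed and decay
#' exponentially with inter-areal distance; layer thicknesses, neuron
#' densities, and surface areas are drawn uniformly within ranges typical of
#' human cytoarchitectonic measurements; inter-areal distances come from
#' random points on a sphere at human-brain scale.
#'
#' @param nos_meanlog,nos_sdlog meanlog/sdlog of the log-normal streamline
#'   factor (before the distance decay is applied).
#' @param lambda_mm exponential distance-decay constant of the streamline
#'   counts, mm.
#' @param radius_mm radius of the sphere on which area centers are placed.
#' @param thickness_ranges_mm named list of `c(lo, hi)` per layer (`"1"`,
#'   `"2/3"`, `"4"`, `"5"`, `"6"`).
#' @param density_range_per_mm3 range of per-layer neuron volume densities.
#' @param surface_range_mm2 range of area surfaces.
#' @param include_layer1 generate a layer-1 thickness row per area?
#' @return A list of class `synth_anatomy_spec`.
#' @export
synth_anatomy_spec <- function(nos_meanlog = 8, nos_sdlog = 1,
                               lambda_mm = 45, radius_mm = 60,
                               thickness_ranges_mm = list(
                                 "1" = c(0.10, 0.30),
                                 "2/3" = c(0.40, 1.00),
                                 "4" = c(0.10, 0.40),
                                 "5" = c(0.30, 0.70),
                                 "6" = c(0.40, 0.90)
                               ),
                               density_range_per_mm3 = c(3e4, 1e5),
                               surface_range_mm2 = c(500, 5000),
                               include_layer1 = TRUE) {
  if (nos_sdlog < 0) stop("nos_sdlog must be nonnegative")
  if (lambda_mm <= 0 || radius_mm <= 0) {
    stop("lambda_mm and radius_mm must be positive")
  }
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) &&
    r[1] >= 0 && r[2] >= r[1]
  if (!all(vapply(thickness_ranges_mm, rng_ok, TRUE)) ||
      !rng_ok(density_range_per_mm3) || !rng_ok(surface_range_mm2)) {
    stop("invalid range in synthetic anatomy spec")
  }
  structure(
    list(
      nos_meanlog = nos_meanlog, nos_sdlog = nos_sdlog,
      lambda_mm = lambda_mm, radius_mm = radius_mm,
      thickness_ranges_mm = thickness_ranges_mm,
      density_range_per_mm3 = density_range_per_mm3,
      surface_range_mm2 = surface_range_mm2,
      include_layer1 = include_layer1
    ),
    class = "synth_anatomy_spec"
  )
}

# Evaluate fn() under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic anatomy bundle
#'
#' Produces a fully valid [anatomy_bundle()] with known generating parameters,
#' so that the complete pipeline (connectome construction, validation
#' statistics, simulation, analysis) can run and be tested without any data
#' download. Given the same `seed`, the result is bit-identical.
#'
#' @param seed integer RNG seed.
#' @param n_areas number of areas (>= 2). With the default 34 the
#'   Desikan-Killiany names are used; otherwise areas are named `A01`, ...
#' @param spec a [synth_anatomy_spec()].
#' @param constants [model_constants()] for the bundle.
#' @return An `anatomy_bundle` whose `generator` attribute records `seed` and
#'   `spec`.
#' @export
#' @examples
#' b <- synth_anatomy(seed = 1, n_areas = 4)
#' attr(b, "generator")$spec$lambda_mm
synth_anatomy <- function(seed, n_areas = 34, spec = synth_anatomy_spec(),
                          constants = model_constants()) {
  stopifnot(inherits(spec, "synth_anatomy_spec"))
  if (!is.numeric(n_areas) || n_areas < 2) {
    stop("n_areas must be at least 2")
  }
  n_areas <- as.integer(n_areas)
  nm <- if (n_areas == 34L) dk_areas()$area else sprintf("A%02d", seq_len(n_areas))

  bundle <- with_seed(seed, function() {
    # area centers on a sphere: normalized Gaussian triples
    xyz <- matrix(stats::rnorm(3L * n_areas), ncol = 3L)
    xyz <- xyz / sqrt(rowSums(xyz^2)) * spec$radius_mm
    dist <- as.matrix(stats::dist(xyz))
    dimnames(dist) <- list(nm, nm)

    nos <- matrix(
      stats::rlnorm(n_areas^2, spec$nos_meanlog, spec$nos_sdlog) *
        exp(-dist / spec$lambda_mm),
      n_areas, n_areas, dimnames = list(nm, nm)
    )
    diag(nos) <- 0

    layers <- if (spec$include_layer1) .syn_layers else .layers
    grid <- tidyr::expand_grid(area = nm, layer = layers)
    lo <- vapply(spec$thickness_ranges_mm[grid$layer], `[`, 0, 1L)
    hi <- vapply(spec$thickness_ranges_mm[grid$layer], `[`, 0, 2L)
    thick <- stats::runif(nrow(grid), lo, hi)
    dens <- stats::runif(nrow(grid), spec$density_range_per_mm3[1],
                         spec$density_range_per_mm3[2])
    dens[grid$layer == "1"] <- 0
    surf <- stats::setNames(
      stats::runif(n_areas, spec$surface_range_mm2[1],
                   spec$surface_range_mm2[2]),
      nm
    )
    areas <- tibble::tibble(
      area = grid$area, layer = grid$layer,
      thickness_mm = thick, density_per_mm3 = dens,
      exc_fraction = NA_real_,
      surface_mm2 = unname(surf[grid$area])
    ) |>
      fill_exc_fraction()

    anatomy_bundle(areas, nos, dist, constants = constants)
  })
  attr(bundle, "generator") <- list(seed = seed, spec = spec)
  bundle
}

#' Fit the distance decay and log-normal spread of a streamline matrix
#'
#' Ordinary least squares of `log(NoS)` on inter-areal distance over the
#' ordered off-diagonal pairs with positive counts. The decay constant is
#' `-1/slope`; the log-normal location/spread are the mean and SD of the
#' decay-corrected log counts. Used for parameter-recovery checks on
#' synthetic bundles and (with synapse counts) for connectome validation.
#'
#' @param values nonnegative matrix (e.g. `bundle$nos`).
#' @param distance_mm matching distance matrix, mm.
#' @return A tibble with one row: `lambda_mm`, `meanlog`, `sdlog`, `n_pairs`,
#'   `r_squared`.
#' @export
fit_distance_decay <- function(values, distance_mm) {
  keep <- row(values) != col(values) & values > 0
  if (sum(keep) < 3L) stop("need at least 3 positive off-diagonal pairs")
  y <- log(values[keep])
  d <- distance_mm[keep]
  fit <- stats::lm(y ~ d)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0) {
    lambda <- NA_real_
  } else {
    lambda <- -1 / slope
  }
  corrected <- if (is.na(lambda)) y else y + d / lambda
  tibble::tibble(
    lambda_mm = lambda,
    meanlog = mean(corrected),
    sdlog = stats::sd(corrected),
    n_pairs = sum(keep),
    r_squared = summary(fit)$r.squared
  )
}
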