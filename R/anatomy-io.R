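#' Load an anatomy bundle from CSV files
#'
#' Reads the tabular anatomical inputs of the connectome builder and returns a
#' validated [anatomy_bundle()]. Expected files (named entries of `paths`):
#'
#' * `areas`: columns `area`, `layer`, `thickness_mm`, `density_per_mm3`,
#'   `exc_fraction`, `surface_mm2`. One row per (area, layer); layer `"1"`
#'   rows are optional (thickness only). Missing `exc_fraction` values are
#'   filled with the per-layer defaults (0.65 / 0.79 / 0.78 / 0.86 for layers
#'   2/3, 4, 5, 6).
#' * `nos`, `fiber_length`: square matrices with an `area` header column and
#'   one column per area, in the same order as `areas`.
#' * `blueprint` (optional): 8x8 matrix with a `source` header column,
#'   columns/rows ordered 2/3E ... 6I. Defaults to [blueprint_pd()].
#' * `k_ext` (optional): columns `population`, `k_ext`.
#' * `dendrites` (optional): 5x4 matrix with a `synapse_layer` header column
#'   and one column per soma layer. Defaults to
#'   [dendritic_profile_synthetic()].
#'
#' @param paths named list or character vector of file paths.
#' @param constants_override named list of [model_constants()] overrides.
#' @param sln_fit SLN probit parameters, see [sln_fit_params()].
#' @return A validated `anatomy_bundle`.
#' @export
load_anatomy_bundle <- function(paths, constants_override = list(),
                                sln_fit = sln_fit_params()) {
  paths <- as.list(paths)
  for (nm in c("areas", "nos", "fiber_length")) {
    if (is.null(paths[[nm]])) stop("paths must include '", nm, "'")
    if (!file.exists(paths[[nm]])) stop("file not found: ", paths[[nm]])
  }
  # numeric columns are parsed from text with strtod (exact round trip of
  # the 17-significant-digit writer)
  areas <- readr::read_csv(paths$areas, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  for (nm in c("thickness_mm", "density_per_mm3", "exc_fraction",
               "surface_mm2")) {
    if (nm %in% names(areas)) areas[[nm]] <- as.numeric(areas[[nm]])
  }
  areas <- fill_exc_fraction(areas)

  read_square <- function(path) {
    m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
    rn <- m[[1L]]
    m <- as.matrix(m[, -1L, drop = FALSE])
    rownames(m) <- rn
    m <- apply(m, c(1, 2), as.numeric)
    m
  }
  nos <- read_square(paths$nos)
  fib <- read_square(paths$fiber_length)

  blueprint <- blueprint_pd()
  if (!is.null(paths$blueprint)) {
    q <- read_square(paths$blueprint)
    if (!all(dim(q) == c(8L, 8L))) {
      stop("blueprint file must contain an 8x8 matrix")
    }
    dimnames(q) <- list(.pops8, .pops8)
    blueprint$q <- q
  }
  if (!is.null(paths$k_ext)) {
    k <- readr::read_csv(paths$k_ext, show_col_types = FALSE, progress = FALSE)
    blueprint$k_ext <- stats::setNames(k$k_ext, k$population)[.pops8]
  }
  dendrites <- dendritic_profile_synthetic()
  if (!is.null(paths$dendrites)) {
    d <- read_square(paths$dendrites)
    if (!all(dim(d) == c(5L, 4L))) {
      stop("dendrites file must contain a 5x4 matrix")
    }
    dimnames(d) <- list(.syn_layers, .layers)
    dendrites <- d
  }

  constants <- do.call(model_constants, constants_override)
  anatomy_bundle(areas, nos, fib, blueprint = blueprint,
                 dendrites = dendrites, sln_fit = sln_fit,
                 constants = constants)
}

#' Write an anatomy bundle to CSV files
#'
#' Inverse of [load_anatomy_bundle()]: writes `areas.csv`, `nos.csv`,
#' `fiber_length_mm.csv`, `blueprint.csv`, `k_ext.csv`, and `dendrites.csv`
#' into `dir`. Numeric values are written with 17 significant digits so that
#' a load round-trip reproduces the bundle exactly.
#'
#' @param bundle an `anatomy_bundle`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of written paths (suitable for
#'   [load_anatomy_bundle()]).
#' @export
write_anatomy_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  areas <- bundle$areas
  areas_out <- tibble::tibble(
    area = areas$area, layer = areas$layer,
    thickness_mm = fmt(areas$thickness_mm),
    density_per_mm3 = fmt(areas$density_per_mm3),
    exc_fraction = fmt(areas$exc_fraction),
    surface_mm2 = fmt(areas$surface_mm2)
  )
  paths <- list(
    areas = file.path(dir, "areas.csv"),
    nos = file.path(dir, "nos.csv"),
    fiber_length = file.path(dir, "fiber_length_mm.csv"),
    blueprint = file.path(dir, "blueprint.csv"),
    k_ext = file.path(dir, "k_ext.csv"),
    dendrites = file.path(dir, "dendrites.csv")
  )
  readr::write_csv(areas_out, paths$areas, progress = FALSE)
  write_square <- function(m, path, key) {
    df <- tibble::as_tibble(as.data.frame(apply(m, 2, fmt)))
    df <- dplyr::bind_cols(tibble::tibble(!!key := rownames(m)), df)
    readr::write_csv(df, path, progress = FALSE)
  }
  write_square(bundle$nos, paths$nos, "area")
  write_square(bundle$fiber_length_mm, paths$fiber_length, "area")
  write_square(bundle$blueprint$q, paths$blueprint, "source")
  readr::write_csv(
    tibble::tibble(population = .pops8,
                   k_ext = fmt(unname(bundle$blueprint$k_ext))),
    paths$k_ext, progress = FALSE
  )
  write_square(bundle$dendrites, paths$dendrites, "synapse_layer")
  invisible(paths)
}
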