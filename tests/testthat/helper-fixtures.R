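# Shared fixtures and independent oracles.

# A minimal hand-built anatomy bundle with fully controlled numbers.
# `l4_zero` empties layer 4 of the second area (agranular case).
toy_bundle <- function(n_areas = 2, l4_zero = FALSE, fiber = 35,
                       density = 5e4, thickness = c("2/3" = 0.8, "4" = 0.3,
                                                    "5" = 0.5, "6" = 0.6),
                       surface = 800, nos_value = 100,
                       constants = model_constants()) {
  nm <- sprintf("A%02d", seq_len(n_areas))
  grid <- expand.grid(area = nm, layer = names(thickness),
                      stringsAsFactors = FALSE)
  areas <- tibble::tibble(
    area = grid$area, layer = grid$layer,
    thickness_mm = unname(thickness[grid$layer]),
    density_per_mm3 = density,
    exc_fraction = NA_real_,
    surface_mm2 = surface
  )
  if (l4_zero) {
    areas$thickness_mm[areas$area == nm[2] & areas$layer == "4"] <- 0
  }
  nos <- matrix(nos_value, n_areas, n_areas, dimnames = list(nm, nm))
  diag(nos) <- 0
  fib <- matrix(fiber, n_areas, n_areas, dimnames = list(nm, nm))
  diag(fib) <- 0
  anatomy_bundle(mesocortex:::fill_exc_fraction(areas), nos, fib,
                 constants = constants)
}

# Monte-Carlo oracle for the column connection-density integrals.
# Internal: plain sampling over both cylinders. External: importance sampling
# of the annular radial coordinate with an exponential proposal (the kernel
# only sees the first few decay lengths beyond the column wall).
mc_column_integrals <- function(h, area_surface, lambda, column_area,
                                n = 2e6, chunks = 3, seed = 1) {
  set.seed(seed)
  r_col <- sqrt(column_area / pi)
  r_area <- sqrt(area_surface / pi)
  acc_i <- 0
  acc_e <- 0
  for (ch in seq_len(chunks)) {
    r2 <- r_col * sqrt(stats::runif(n))
    dphi <- stats::runif(n, 0, 2 * pi)
    dz <- stats::runif(n, 0, h) - stats::runif(n, 0, h)
    r1 <- r_col * sqrt(stats::runif(n))
    d <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(dphi) + dz^2)
    acc_i <- acc_i + mean(exp(-d / lambda)) * (column_area * h)^2
    tr <- r_area - r_col
    z_norm <- lambda * (1 - exp(-tr / lambda))
    t <- -lambda * log(1 - stats::runif(n) * (1 - exp(-tr / lambda)))
    r1 <- r_col + t
    d <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(dphi) + dz^2)
    acc_e <- acc_e +
      mean(exp(-d / lambda) * 2 * pi * h * r1 * z_norm / exp(-t / lambda)) *
      column_area * h
  }
  list(rho_internal = acc_i / chunks, rho_external = acc_e / chunks)
}

# Homogeneous Poisson spike train on [0, duration_ms].
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}

# Self-consistent diffusion (Siegert) rate estimate for a 2-population E-I
# network with exponential-PSC LIF neurons; charge-equivalent white-noise
# approximation.
meanfield_rates <- function(k_e, k_i, g, rate_ext_per_ms, neuron, tau_s = 2,
                            iterations = 300) {
  siegert <- function(mu, sigma, taum = neuron$tau_m, taur = neuron$tau_r,
                      theta = neuron$V_th - neuron$E_L, vr = 0) {
    f <- function(u) pracma::erfcx(-u)
    v <- stats::integrate(f, (vr - mu) / sigma, (theta - mu) / sigma,
                          rel.tol = 1e-9)$value
    1000 / (taur + taum * sqrt(pi) * v)
  }
  r <- c(5, 5)
  for (it in seq_len(iterations)) {
    rn <- vapply(1:2, function(t) {
      cm <- if (t == 1) neuron$C_m[["E"]] else neuron$C_m[["I"]]
      j_e <- psp_to_psc(0.1, cm, neuron$tau_m, tau_s)
      j_i <- -g * j_e
      w_ext <- j_e
      mu <- neuron$tau_m / cm * tau_s *
        (k_e * r[1] / 1000 * j_e + k_i * r[2] / 1000 * j_i +
           rate_ext_per_ms * w_ext)
      s2 <- neuron$tau_m / (2 * cm^2) * tau_s^2 *
        (k_e * r[1] / 1000 * j_e^2 + k_i * r[2] / 1000 * j_i^2 +
           rate_ext_per_ms * w_ext^2)
      siegert(mu, sqrt(s2))
    }, 0)
    r <- 0.7 * r + 0.3 * rn
  }
  r
}
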