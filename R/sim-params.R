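#' Neuron parameters of the LIF model
#'
#' Leaky integrate-and-fire neurons with exponential postsynaptic currents.
#' Capacitances differ between excitatory and inhibitory cells; all other
#' defaults are shared. Optional coefficients of variation put log-normal
#' distributions on the threshold, capacitance, and membrane time constant
#' (per neuron); they default to zero, i.e. point values.
#'
#' @param tau_m membrane time constant, ms.
#' @param C_m membrane capacitance, pF; named vector `c(E = , I = )`.
#' @param V_th spike threshold, mV.
#' @param E_L leak (= reset) potential, mV.
#' @param tau_r absolute refractory period, ms.
#' @param tau_s synaptic current time constant, ms.
#' @param cv list of per-parameter CVs, each a named `c(E = , I = )` vector,
#'   for `V_th`, `C_m`, `tau_m`.
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 10, C_m = c(E = 220, I = 100),
                          V_th = -45, E_L = -70, tau_r = 2, tau_s = 2,
                          cv = list(V_th = c(E = 0, I = 0),
                                    C_m = c(E = 0, I = 0),
                                    tau_m = c(E = 0, I = 0))) {
  stopifnot(tau_m > 0, all(C_m > 0), tau_r > 0, tau_s > 0, V_th > E_L)
  if (any(unlist(cv) < 0)) stop("coefficients of variation must be >= 0")
  structure(
    list(tau_m = tau_m, C_m = C_m, V_th = V_th, E_L = E_L,
         V_reset = E_L, tau_r = tau_r, tau_s = tau_s, cv = cv),
    class = "neuron_params"
  )
}

#' Synapse-strength parameters
#'
#' Postsynaptic potentials are truncated-normal with mean `psp_mean` and
#' relative SD `psp_rel_sd`; inhibitory weights are `g` times stronger (and
#' negative). Within a column, 4E to 2/3E weights are doubled. Inter-areal
#' weights are scaled by `chi` (onto all targets) and additionally by `chi_I`
#' onto inhibitory targets; `chi = 1` is the base version of the model and
#' `chi = 2.5` the best-fitting version. External drive onto excitatory
#' neurons in layers 5 and 6 is scaled by `ext_scale_5E` / `ext_scale_6E`.
#'
#' @param psp_mean mean excitatory PSP amplitude, mV.
#' @param psp_rel_sd relative SD of PSP amplitudes.
#' @param g relative inhibitory synaptic strength.
#' @param l4e_to_l23e_factor within-area 4E to 2/3E weight factor.
#' @param chi inter-areal synaptic scaling factor.
#' @param chi_I additional inter-areal scaling onto inhibitory neurons.
#' @param ext_scale_5E,ext_scale_6E external-drive weight scalings.
#' @return A list of class `synapse_model_params`.
#' @export
synapse_model_params <- function(psp_mean = 0.1, psp_rel_sd = 0.1, g = 5,
                                 l4e_to_l23e_factor = 2, chi = 1, chi_I = 2,
                                 ext_scale_5E = 1.05, ext_scale_6E = 1.15) {
  stopifnot(psp_mean > 0, psp_rel_sd >= 0, g > 0, l4e_to_l23e_factor > 0,
            chi > 0, chi_I > 0, ext_scale_5E > 0, ext_scale_6E > 0)
  structure(
    list(psp_mean = psp_mean, psp_rel_sd = psp_rel_sd, g = g,
         l4e_to_l23e_factor = l4e_to_l23e_factor, chi = chi, chi_I = chi_I,
         ext_scale_5E = ext_scale_5E, ext_scale_6E = ext_scale_6E),
    class = "synapse_model_params"
  )
}

#' Transmission-delay parameters
#'
#' Local delays have fixed means (`d_e` for excitatory, `d_i` for inhibitory
#' sources); inter-areal delays have mean fiber length / conduction velocity.
#' All delays are drawn from a truncated log-normal with relative SD
#' `rel_sd`, redrawn below the simulation resolution `dt`, rounded to the dt
#' grid. The engine additionally redraws delays above `cap_ms` to bound its
#' event queue; the cap is far beyond any mean inter-areal delay.
#'
#' @param d_e,d_i local excitatory/inhibitory mean delay, ms.
#' @param rel_sd relative SD of the delay distribution.
#' @param v_t inter-areal conduction velocity, m/s (= mm/ms).
#' @param dt simulation step, ms.
#' @param cap_ms upper truncation of realized delays, ms.
#' @return A list of class `delay_params`.
#' @export
delay_params <- function(d_e = 1.5, d_i = 0.75, rel_sd = 0.5, v_t = 3.5,
                         dt = 0.1, cap_ms = 100) {
  stopifnot(d_e > 0, d_i > 0, rel_sd >= 0, v_t > 0, dt > 0, cap_ms > dt)
  structure(
    list(d_e = d_e, d_i = d_i, rel_sd = rel_sd, v_t = v_t, dt = dt,
         cap_ms = cap_ms),
    class = "delay_params"
  )
}

#' External Poisson-drive parameters
#'
#' Each neuron receives independent Poisson input through its external
#' indegree with PSP amplitude `w_ext`. The rate is set so that the mean
#' input, measured relative to rheobase, equals `eta_ext`. In `"verbatim"`
#' mode the textbook delta-synapse expression is used, under which each PSP
#' contributes `w * tau_m` to the mean potential; with exponential
#' postsynaptic currents the realized mean input is then about 1.5x rheobase
#' for the default time constants. In `"strict"` mode the rate is rescaled so
#' that the true mean current of the exponential PSCs equals
#' `eta_ext` times rheobase.
#'
#' @param eta_ext mean input relative to rheobase.
#' @param w_ext mean external PSP amplitude, mV.
#' @param rel_sd relative SD of external PSP amplitudes.
#' @param mode `"verbatim"` or `"strict"`.
#' @return A list of class `external_drive_params`.
#' @export
external_drive_params <- function(eta_ext = 1.1, w_ext = 0.1, rel_sd = 0.1,
                                  mode = c("verbatim", "strict")) {
  stopifnot(eta_ext >= 0, w_ext > 0, rel_sd >= 0)
  structure(
    list(eta_ext = eta_ext, w_ext = w_ext, rel_sd = rel_sd,
         mode = match.arg(mode)),
    class = "external_drive_params"
  )
}

#' Convert a postsynaptic potential to a postsynaptic current amplitude
#'
#' For the LIF neuron with exponential postsynaptic currents, the current
#' amplitude producing a PSP peak of `psp` is
#' `PSC = psp * (C_m / tau_m) * eps^(-1 / (1 - eps))` with
#' `eps = tau_s / tau_m`. The factor depends on the synaptic time constant
#' and on the postsynaptic neuron's `tau_m` and `C_m`.
#'
#' @param psp PSP peak amplitude, mV.
#' @param C_m membrane capacitance of the target neuron, pF.
#' @param tau_m membrane time constant, ms.
#' @param tau_s synaptic time constant, ms (must differ from `tau_m`).
#' @return PSC amplitude, pA.
#' @export
#' @examples
#' round(psp_to_psc(0.1, 220, 10, 2), 1) # 16.4 pA onto excitatory neurons
#' round(psp_to_psc(0.1, 100, 10, 2), 1) #  7.5 pA onto inhibitory neurons
psp_to_psc <- function(psp, C_m, tau_m, tau_s) {
  stopifnot(C_m > 0, tau_m > 0, tau_s > 0)
  if (any(abs(tau_s - tau_m) < 1e-12)) {
    stop("tau_s = tau_m: the conversion factor is singular; use distinct ",
         "time constants")
  }
  eps <- tau_s / tau_m
  psp * (C_m / tau_m) * eps^(-1 / (1 - eps))
}

#' Rate of the external Poisson sources
#'
#' Rate per external synapse such that the mean input of a neuron with
#' indegree `k_ext` equals `eta_ext` times rheobase:
#' `nu = (V_th - E_L) * eta / (tau_m * w_ext * k_ext)` (in `"verbatim"` mode);
#' in `"strict"` mode this is multiplied by `eps^(eps / (1 - eps))`
#' (`eps = tau_s / tau_m`) so that the mean current of the exponential PSCs
#' equals `eta` times rheobase exactly.
#'
#' @param drive [external_drive_params()].
#' @param neuron [neuron_params()].
#' @param k_ext external indegree (> 0).
#' @return Rate per source, spikes/s.
#' @export
#' @examples
#' external_poisson_rate(external_drive_params(), neuron_params(),
#'                       k_ext = 1000) # 27.5 spikes/s
external_poisson_rate <- function(drive, neuron, k_ext) {
  if (any(k_ext <= 0)) stop("k_ext must be positive")
  nu <- (neuron$V_th - neuron$E_L) * drive$eta_ext /
    (neuron$tau_m * drive$w_ext * k_ext) * 1000 # 1/ms -> spikes/s
  if (drive$mode == "strict") {
    eps <- neuron$tau_s / neuron$tau_m
    nu <- nu * eps^(eps / (1 - eps))
  }
  nu
}

#' Draw synaptic weights
#'
#' Truncated normal weights with the stated sign: draws of the wrong sign are
#' redrawn. Deterministic given `seed` (counter-based generator shared with
#' the simulation engine).
#'
#' @param n number of draws.
#' @param mean_pA mean weight (sign sets the truncation side).
#' @param rel_sd relative standard deviation.
#' @param seed integer seed.
#' @return Numeric vector of weights.
#' @export
draw_weights <- function(n, mean_pA, rel_sd, seed) {
  if (rel_sd < 0) stop("rel_sd must be >= 0")
  cpp_draw_weights(n, mean_pA, rel_sd * abs(mean_pA), as.numeric(seed))
}

#' Draw transmission delays (in simulation steps)
#'
#' Log-normal delays parameterized by mean and relative SD; draws below the
#' resolution `dt` (or above `cap_ms`, if finite) are redrawn, then rounded
#' to the nearest step. All delays are at least one step.
#'
#' @param n number of draws.
#' @param mean_ms mean delay, ms.
#' @param rel_sd relative standard deviation.
#' @param dt simulation step, ms.
#' @param seed integer seed.
#' @param cap_ms upper truncation (default none).
#' @return Integer vector of delays in steps.
#' @export
draw_delays <- function(n, mean_ms, rel_sd, dt = 0.1, seed = 1,
                        cap_ms = Inf) {
  stopifnot(mean_ms > 0, rel_sd >= 0, dt > 0)
  cpp_draw_delays(n, mean_ms, rel_sd, dt,
                  if (is.finite(cap_ms)) cap_ms else -1,
                  as.numeric(seed))
}
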