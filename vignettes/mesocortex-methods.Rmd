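---
title: "Methods: building and simulating a human cortical mesoconnectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and simulating a human cortical mesoconnectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesocortex)
```

mesocortex builds a population-resolved synapse-count connectome
("mesoconnectome") for the 34 areas of one hemisphere of human cortex in the
Desikan–Killiany parcellation, realizes it as an explicit network of leaky
integrate-and-fire (LIF) neurons, simulates it with a deterministic compiled
engine, and analyzes the resulting activity. This vignette documents the
model, its assumptions, the tunable parameters, the numerical choices, and
the design decisions taken where the construction was genuinely open.

## The model

Each area is represented by a column of 1 mm² surface (`column_area`) with
layers 2/3, 4, 5 and 6, each split into an excitatory and an inhibitory
population (layer 1 carries synapses but no somata). All neurons are LIF
units with exponential postsynaptic currents,

$$\tau_m \dot V = -(V - E_L) + \tau_m I_s(t)/C_m, \qquad
  I_s(t) = \sum_k J_k e^{-(t - t_k)/\tau_s}\,\Theta(t - t_k),$$

with a fixed threshold, voltage clamp at reset during the absolute
refractory period, and independent Poisson background driving every neuron.

### Neuron and synapse counts

Per layer, the neuron count is `N = round(rho_neuron * h_layer *
column_area)`, split by the layer's excitatory fraction (defaults 0.65,
0.79, 0.78, 0.86 for layers 2/3–6, from electron-microscopic reconstruction
of human temporal cortex). The synapse budget of an area is `rho_synapse *
column_area * h_total` with `rho_synapse = 6.6e8 /mm³` taken as constant
across cortex; the layer-1 thickness contributes to the column volume.

### Local vs. long-range split

The fraction of synapses arriving through the white matter follows an
allometric scaling rule: the fraction of neurons sending axons into the
white matter falls off as a power law (exponent 0.16) of the total
gray-matter neuron count, calibrated at a macaque tracing estimate (0.21 at
1.4×10⁹ neurons). At the human count of 16×10⁹ this gives 0.14. We assume,
as the construction requires, that the neuron fraction equals the synapse
fraction.

Local synapses are split between presynaptic neurons inside the simulated
column and the remainder of the area using an isotropic exponential
connection probability (decay `lambda_conn` = 160 µm). With cylindrical
column and area, the reduced four-dimensional integrals

$$\rho \propto 4\int dr_1 \int_0^{r_{col}} dr_2\, r_1 r_2
  \int_0^{2\pi} d\phi\,(2\pi-\phi) \int_0^h dz\,(h-z)\,
  e^{-d(r_1,r_2,\phi,z)/\lambda}$$

are evaluated by panelled Gauss–Legendre quadrature (see *Numerical
choices*). Only the ratio of the two integrals is used.

Within the column, synapses are distributed over the 8×8 population pairs in
proportion to `N_src * q * N_tgt`, where `q` is the mean number of synapses
per neuron pair of the layered microcircuit blueprint; under the
fixed-total-number rule a connection probability `p` maps to
`q = -log(1 - p)`. This automatically assigns no synapses to layer 4 of
agranular areas. Synapses from local-but-outside-the-column neurons are kept
as excitatory Poisson drive, distributed over populations by the blueprint's
relative external indegrees.

### Long-range projections

Long-range synapses of each target area are allocated to source areas in
proportion to diffusion-tractography streamline counts (NoS). The laminar
origin uses predictive connectomics: the fraction of supragranular labeled
neurons is `SLN = pnorm(a0 + a1 * log(rho_target/rho_source))` with the
macaque fit `a0 = -0.152`, `a1 = -1.534` applied to human area-level
densities (total neurons over column volume, layer 1 included). The SLN
share originates in layer 2/3 E; the rest is split over 5E and 6E by
population size; layer 4 and inhibitory neurons do not project between
areas. Target patterns by SLN class: feedforward (> 0.65) targets layer 4
(layer 2/3 in agranular areas); feedback (< 0.35) targets layers 1, 2/3, 5,
6; lateral targets all five layers; multi-layer patterns are weighted by
relative layer thickness. A cortex-wide excitatory target share per synapse
layer (default 0.85, a configurable placeholder for a laminar aggregate not
published in tabular form) splits synapses between classes; excitatory
targets are routed to soma layers through a dendritic-length profile and the
synapse layer is marginalized; inhibitory targets stay in the synapse's
layer. For feedback projections the excitatory target share is fixed at
0.93.

Every allocation stage uses largest-remainder rounding, so each stage
conserves its parent budget *exactly*; the per-area bookkeeping makes this
assertable, and the test suite asserts it.

## Simulator

`realize_network()` scales neuron and synapse counts by a common factor
(preserving indegrees) and draws, per projection, exactly the specified
number of synapses with source and target neurons sampled uniformly with
replacement (autapses and multapses allowed). Weights are truncated normal
(relative SD 0.1) around the PSP mean of 0.1 mV with the multipliers: −g
(g = 5) for inhibitory sources, ×2 for within-area 4E→2/3E, ×χ for
inter-areal synapses (χ = 1 base version, χ = 2.5 best-fitting version), and
additionally ×χ_I (default 2, applied for every χ) onto inhibitory targets.
PSPs convert to current amplitudes via
`PSC/PSP = (C_m/tau_m) * eps^(-1/(1-eps))`, `eps = tau_s/tau_m`, using the
*target* population's capacitance (16.4 pA onto excitatory, 7.5 pA onto
inhibitory neurons for the defaults). Delays are truncated log-normal
(relative SD 0.5) around 1.5/0.75 ms for local excitatory/inhibitory
sources and around fiber length over 3.5 m/s between areas, rounded to the
0.1 ms grid with a minimum of one step.

Integration uses the exact propagator of the linear (V, I) system at fixed
`dt = 0.1` ms; spike times live on the grid. Initial membrane potentials are
drawn uniformly between reset and threshold (the reference publications are
silent on initialization; this avoids a synchronous startup artifact).

### External drive and the two η modes

The Poisson rate per external synapse is set from the mean-input contract
`nu = (V_th - E_L) * eta / (tau_m * w_ext * k_ext)` with `eta = 1.1`. As
written, this expression assumes each PSP contributes `w * tau_m` to the
mean potential (delta-synapse approximation); with exponential PSCs and the
default time constants the realized mean input is ≈1.5× rheobase. Both
readings are provided: `mode = "verbatim"` (default for network simulations)
applies the expression as printed, `mode = "strict"` rescales the rate by
`eps^(eps/(1-eps))` so that the true mean current equals η × rheobase. The
isolated-neuron firing-rate check (35–50 spikes/s) holds in strict mode,
which is what its defining statement describes. The 1.05/1.15 scalings of
external input onto 5E/6E multiply only the synaptic weight (raising the
mean input), not the rate.

### Deterministic, exactly paired randomness

All randomness in the engine comes from a counter-based generator
(splitmix64 finalizer) keyed by (seed, stream, id): one stream per
projection for synapse multiplicities and targets, one per synapse for its
weight and delay, one per neuron for its parameters, initial state, and
Poisson drive. Per-synapse weights and delays are regenerated from their
keys at delivery time rather than stored, which bounds memory at about
4 bytes per synapse and makes the desk-scale profile (scale 0.01 of a
34-area bundle, ≈3.5×10⁸ synapses) feasible on a laptop-class machine.
Because a neuron's stream is consumed independently of network activity, two
runs with identical seeds use exactly the same random numbers whether or not
a single-neuron perturbation is applied — the paired-run contract holds
draw-for-draw, and the control pair is event-identical.

Distributed neuron parameters (log-normal `V_th`, `C_m`, `tau_m` with
per-class CVs) are available behind the `cv` field of `neuron_params()`,
default off: the reference simulations use point values.

## Analysis suite

Spiking statistics discard a 2500 ms transient by default; rates are
compared only for neurons with ≥ 0.5 spikes/s, CV ISI and LvR only for
neurons with ≥ 10 spikes; LvR uses a refractoriness constant of 5 ms (the
convention of its defining reference), exposed as an argument. Long
simulations are split into 5 equal snippets when compared against short
experimental recordings. Distribution similarity is `1 - KS distance`.
Functional connectivity is the Pearson correlation of the per-area summed
absolute synaptic current (the BOLD proxy), compared to an experimental FC
matrix via off-diagonal Pearson correlation and `exp(-RMSE/sigma_exp)`. The
probe current includes the external-drive synapses: the proxy represents
total synaptic input, and the stationary Poisson drive adds a flat,
structure-free component, so no exclusion flag is provided.

The temporal hierarchy bins area-level spike counts at 1 ms, takes the
cross-correlation peak (±100 ms, mean-subtracted signals) per area pair,
treats peaks within 5% of the global maximum as "similar" (the defining
description does not quantify similarity; 5% is our choice), resolves
same-sign candidates to the delay closest to zero and labels mixed signs
undecided, re-estimates each delay on 9 segments and rejects it when the raw
median absolute deviation exceeds 3 ms. The ordering minimizes the squared
mismatch between measured delays and rank-difference-predicted delays with a
least-squares scale per rank step; the optimizer is exhaustive up to 8
areas and greedy insertion plus pairwise-swap refinement beyond, with ties
resolved toward the index order (so an unshifted common signal yields the
input order).

Perturbation tracking bins each population's spikes at the simulation
resolution and subtracts the paired runs; the first nonzero bin per
population (minimum over populations per area) is the arrival time. As a
consistency check, arrivals are compared against the Dijkstra shortest path
computed on the *minimum realized delay* per projection
(`projection_min_delays()`): no effect can causally arrive earlier, and the
test suite asserts exactly that. A bound built from mean delays would not be
valid — realized log-normal delays undershoot their means, and multi-hop
arrivals can beat a mean-delay Dijkstra path by more than one local delay —
so the causal version is used. `validate_connectome()` still reports the
mean-delay Dijkstra statistics, which are the published summary of the
network's temporal reach.

## Synthetic anatomy: what it emulates and what it does not

`synth_anatomy()` makes the full pipeline testable without any download. It
reproduces the statistical structure of the real inputs: log-normal
streamline counts (meanlog 8, sdlog 1) with exponential distance decay
(default 45 mm, the scale found when validating the real connectome),
distances from random points on a 60 mm sphere (human-brain scale,
comparable to tractography fiber lengths), layer thicknesses and densities
uniform within cytoarchitectonic ranges (densities 3×10⁴–10⁵ /mm³,
thicknesses per layer as in `synth_anatomy_spec()`), and surfaces of
500–5000 mm². These defaults were fixed once as the package's study
conditions.

Synthetic bundles do *not* reproduce: cytoarchitectonic gradients that
correlate density with position (so the synthetic SLN matrix has no spatial
organization), asymmetries and sparsity of real tractography (synthetic NoS
is dense), agranular areas (all four layers are present unless a user
empties one), or realistic dendritic morphologies (the shipped profile is a
synthetic pyramidal-cell-shaped stand-in). Passing tests therefore
demonstrate that the construction rules, conservation laws, statistics, and
dynamics behave as specified — not that the synthetic connectome is a
faithful human connectome. Reproducing the published structural numbers
(45.6 mm decay, 352/554 mean FF/FB outdegrees, 3.47 million neurons)
requires the real cytoarchitectonic and tractography tables, which must be
obtained externally.

## Numerical choices

* **Quadrature.** Panelled Gauss–Legendre on the reduced 4D kernel; panels
  concentrate within a few decay lengths of the kernel ridge (near φ = 0 and
  2π, z = 0, and the column wall), radial node counts grow as `r_col/λ`, and
  the result must agree with a 1.5×-refined grid to a relative 10⁻³ or an
  error reporting the achieved tolerance is raised. A Monte-Carlo estimate
  of the same integrals (plain sampling for the internal domain,
  importance-sampled radial coordinate for the external one) serves as the
  independent oracle in the tests, with 2% agreement required.
* **Rounding.** Every apportionment uses nearest-integer largest-remainder
  rounding with ties by index, so budgets are conserved exactly at every
  stage (the defining construction only states that results are rounded).
* **Delay cap.** The engine redraws delays above `cap_ms` (default 100 ms,
  ≈3× the largest mean inter-areal delay; < 1% of the mass of the longest
  projections) to bound its delivery ring buffer. The exposed
  `draw_delays()` applies no cap by default.
* **SLN boundaries.** SLN values of exactly 0.35 or 0.65 classify as
  lateral.
* **Outdegree surface correction.** The source/target surface ratio is
  applied per projection and then averaged (the alternative — correcting the
  averages — is not what the per-projection geometry implies); the
  uncorrected means are reported alongside.
* **Target-area statistic.** The outdegree > 100 filter is applied first,
  then projections are classified by direction.
* **Test problem sizes.** The suite exercises the full pipeline at 2–4
  synthetic areas, parameter recovery at 34 areas over 20 seeds, and the
  perturbation-propagation property on a 34-area network at scale 0.01
  (≈50,000 neurons, ≈3.5×10⁸ synapses) over 100 ms with the perturbation at
  5 ms — large enough for every area to be reached, as the paired-run
  analysis shows.

## Known limitations

* No spatially explicit neuron positions, no inter-hemispheric or
  subcortical projections, no plasticity, conductance-based synapses, or
  adaptation.
* The E/I target share of long-range synapses is a cortex-wide placeholder
  until a laminar table is supplied.
* The verbatim η mode over-drives neurons relative to the nominal η (see
  above); both modes are explicit rather than silently reinterpreted.
* Full-density simulations of the complete 3.47-million-neuron model are
  outside the scope of the native engine on a single machine; the package
  targets down-scaled instantiations and structural analysis at full scale.
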