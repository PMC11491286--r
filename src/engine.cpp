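// Deterministic LIF network engine with exponential postsynaptic currents.
//
// All randomness comes from a counter-based generator (splitmix64 finalizer)
// keyed by (seed, stream tag, id). Network structure is keyed per projection
// and per synapse, simulation noise per neuron. Consequences:
//  * identical seeds give bit-identical results on any platform;
//  * per-synapse weights and delays are regenerated on delivery instead of
//    being stored, bounding memory at ~4 bytes per synapse;
//  * a single-neuron perturbation cannot shift any other neuron's random
//    draws, so paired (perturbed, unperturbed) runs use exactly the same
//    random numbers.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t z) {
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31; return z;
}

static const uint64_t PHI64 = 0x9E3779B97F4A7C15ULL;

enum StreamTag {
  TAG_CNT = 1,  // per projection: multiplicity of each source neuron
  TAG_TGT = 2,  // per projection: target neuron of each synapse
  TAG_W   = 3,  // per synapse: weight
  TAG_D   = 4,  // per synapse: delay
  TAG_NRN = 5,  // per neuron: parameters, initial state, external drive
  TAG_FREE = 6  // free-standing draws (exported draw_* helpers)
};

static inline uint64_t stream_key(uint64_t seed, uint64_t tag, uint64_t id) {
  return mix64(seed * PHI64 ^ mix64(tag * 0xD1B54A32D192ED03ULL + id));
}

struct Ctr {
  uint64_t key, ctr;
  explicit Ctr(uint64_t k) : key(k), ctr(0) {}
  inline uint64_t u64() { return mix64(key + PHI64 * (++ctr)); }
  inline double unif() {
    return ((u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) *
      std::cos(6.283185307179586476925287 * u2);
  }
};

// Lemire bounded integer without modulo bias
static inline uint64_t bounded(uint64_t x, uint64_t n) {
  return (uint64_t)(((unsigned __int128)x * n) >> 64);
}

// Normal truncated to the sign of its mean; wrong-sign draws are redrawn.
static inline double trunc_normal(Ctr& r, double mean, double sd) {
  if (sd <= 0.0) return mean;
  const bool pos = mean > 0.0;
  for (int i = 0; i < 10000; ++i) {
    double x = mean + sd * r.normal();
    if (pos ? (x > 0.0) : (x < 0.0)) return x;
  }
  return mean; // unreachable for any sane rel_sd
}

// Truncated log-normal delay in integer steps: redraw below dt (and above
// cap_ms if cap_ms > 0), round to the step grid, at least one step.
static inline int delay_steps(Ctr& r, double mean_ms, double rel_sd,
                              double dt, double cap_ms) {
  double d = mean_ms;
  if (rel_sd > 0.0) {
    const double s2 = std::log1p(rel_sd * rel_sd);
    const double mu = std::log(mean_ms) - 0.5 * s2;
    const double sig = std::sqrt(s2);
    for (int i = 0; i < 10000; ++i) {
      d = std::exp(mu + sig * r.normal());
      if (d >= dt && (cap_ms <= 0.0 || d <= cap_ms)) break;
    }
  }
  long s = std::lround(d / dt);
  return s < 1 ? 1 : (int)s;
}

// [[Rcpp::export]]
NumericVector cpp_draw_weights(double n, double mean, double sd, double seed) {
  R_xlen_t N = (R_xlen_t)n;
  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    Ctr r(stream_key((uint64_t)seed, TAG_FREE, (uint64_t)i));
    out[i] = trunc_normal(r, mean, sd);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_draw_delays(double n, double mean_ms, double rel_sd,
                              double dt, double cap_ms, double seed) {
  R_xlen_t N = (R_xlen_t)n;
  IntegerVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) {
    Ctr r(stream_key((uint64_t)seed, TAG_FREE, (uint64_t)i));
    out[i] = delay_steps(r, mean_ms, rel_sd, dt, cap_ms);
  }
  return out;
}

// Weighted sum of the reduced 4D column-connectivity kernel over a tensor
// quadrature grid (see column_density_integrals()).
// [[Rcpp::export]]
double cpp_quad_kernel(NumericVector r1, NumericVector w1,
                       NumericVector r2, NumericVector w2,
                       NumericVector phi, NumericVector wphi,
                       NumericVector z, NumericVector wz,
                       double h, double lambda) {
  const int n1 = r1.size(), n2 = r2.size(), np = phi.size(), nz = z.size();
  std::vector<double> cp(np), wp(np);
  for (int k = 0; k < np; ++k) {
    cp[k] = std::cos(phi[k]);
    wp[k] = wphi[k] * (2.0 * M_PI - phi[k]);
  }
  std::vector<double> zz(nz), wzz(nz);
  for (int l = 0; l < nz; ++l) {
    zz[l] = z[l] * z[l];
    wzz[l] = wz[l] * (h - z[l]);
  }
  double acc = 0.0;
  for (int i = 0; i < n1; ++i) {
    const double a = r1[i] * r1[i], wa = r1[i] * w1[i];
    for (int j = 0; j < n2; ++j) {
      const double b = a + r2[j] * r2[j];
      const double c = 2.0 * r1[i] * r2[j];
      const double wb = wa * r2[j] * w2[j];
      for (int k = 0; k < np; ++k) {
        double d2 = b - c * cp[k];
        if (d2 < 0.0) d2 = 0.0;
        const double wc = wb * wp[k];
        double s = 0.0;
        for (int l = 0; l < nz; ++l) {
          s += wzz[l] * std::exp(-std::sqrt(d2 + zz[l]) / lambda);
        }
        acc += wc * s;
      }
    }
  }
  return 4.0 * acc;
}

// ---------------------------------------------------------------------------
// network construction (fixed-total-number rule)

struct Net {
  int n_pop = 0;
  std::vector<int64_t> pop_off;         // neuron offset per population
  int64_t n_neurons = 0;
  int n_proj = 0;
  std::vector<int> src, tgt;
  std::vector<int64_t> K;
  std::vector<uint64_t> base;           // global synapse base per projection
  std::vector<size_t> projptr;          // offset into srcoff per projection
  std::vector<uint32_t> srcoff;         // per-source cumulative synapse counts
  std::vector<uint32_t> targets;        // global target neuron per synapse
  std::vector<std::vector<int>> projs_of_pop;
  uint64_t total_syn = 0;
  uint64_t net_seed = 0;
};

static void build_net(Net& net, const IntegerVector& pop_size,
                      const IntegerVector& proj_src,
                      const IntegerVector& proj_tgt,
                      const NumericVector& proj_k, double net_seed) {
  net.n_pop = pop_size.size();
  net.n_proj = proj_src.size();
  net.net_seed = (uint64_t)net_seed;
  net.pop_off.assign(net.n_pop + 1, 0);
  for (int p = 0; p < net.n_pop; ++p) {
    if (pop_size[p] <= 0) stop("engine populations must have size >= 1");
    net.pop_off[p + 1] = net.pop_off[p] + pop_size[p];
  }
  net.n_neurons = net.pop_off[net.n_pop];
  if (net.n_neurons > 4294967000.0) stop("too many neurons for the engine");

  net.src.assign(net.n_proj, 0);
  net.tgt.assign(net.n_proj, 0);
  net.K.assign(net.n_proj, 0);
  net.base.assign(net.n_proj, 0);
  net.projptr.assign(net.n_proj, 0);
  net.projs_of_pop.assign(net.n_pop, {});

  size_t srcoff_len = 0;
  uint64_t tot = 0;
  for (int p = 0; p < net.n_proj; ++p) {
    net.src[p] = proj_src[p];
    net.tgt[p] = proj_tgt[p];
    if (net.src[p] < 0 || net.src[p] >= net.n_pop ||
        net.tgt[p] < 0 || net.tgt[p] >= net.n_pop) {
      stop("projection references an unknown population");
    }
    double k = proj_k[p];
    if (k < 0 || k > 2147483647.0) stop("projection synapse count out of range");
    net.K[p] = (int64_t)std::llround(k);
    net.base[p] = tot;
    tot += (uint64_t)net.K[p];
    net.projptr[p] = srcoff_len;
    srcoff_len += (size_t)pop_size[net.src[p]] + 1;
    net.projs_of_pop[net.src[p]].push_back(p);
  }
  net.total_syn = tot;

  // pass 1: source multiplicities -> cumulative offsets per projection
  net.srcoff.assign(srcoff_len, 0);
  for (int p = 0; p < net.n_proj; ++p) {
    const uint64_t nsrc = (uint64_t)pop_size[net.src[p]];
    uint32_t* off = net.srcoff.data() + net.projptr[p];
    Ctr rc(stream_key(net.net_seed, TAG_CNT, (uint64_t)p));
    for (int64_t k = 0; k < net.K[p]; ++k) {
      off[bounded(rc.u64(), nsrc) + 1]++;
    }
    for (uint64_t i = 0; i < nsrc; ++i) off[i + 1] += off[i];
  }

  // pass 2: targets
  net.targets.assign(tot, 0);
  for (int p = 0; p < net.n_proj; ++p) {
    const uint64_t ntgt = (uint64_t)pop_size[net.tgt[p]];
    const uint32_t toff = (uint32_t)net.pop_off[net.tgt[p]];
    Ctr rt(stream_key(net.net_seed, TAG_TGT, (uint64_t)p));
    uint32_t* dst = net.targets.data() + net.base[p];
    for (int64_t k = 0; k < net.K[p]; ++k) {
      dst[k] = toff + (uint32_t)bounded(rt.u64(), ntgt);
    }
  }
}

// Explicit synapse list; intended for small networks (tests, inspection).
// [[Rcpp::export]]
List cpp_materialize_network(IntegerVector pop_size, IntegerVector proj_src,
                             IntegerVector proj_tgt, NumericVector proj_k,
                             NumericVector w_mean, NumericVector w_sd,
                             NumericVector d_mean, NumericVector d_rel_sd,
                             double dt, double cap_ms, double net_seed) {
  Net net;
  build_net(net, pop_size, proj_src, proj_tgt, proj_k, net_seed);
  if (net.total_syn > 50000000.0) {
    stop("refusing to materialize more than 5e7 synapses");
  }
  const R_xlen_t M = (R_xlen_t)net.total_syn;
  IntegerVector source(M), target(M), proj(M), dstep(M);
  NumericVector weight(M);
  for (int p = 0; p < net.n_proj; ++p) {
    const uint32_t* off = net.srcoff.data() + net.projptr[p];
    const int64_t nsrc = pop_size[net.src[p]];
    const int64_t soff = net.pop_off[net.src[p]];
    for (int64_t i = 0; i < nsrc; ++i) {
      for (uint32_t k = off[i]; k < off[i + 1]; ++k) {
        const uint64_t g = net.base[p] + k;
        Ctr rw(stream_key(net.net_seed, TAG_W, g));
        Ctr rd(stream_key(net.net_seed, TAG_D, g));
        source[g] = (int)(soff + i);
        target[g] = (int)net.targets[g];
        proj[g] = p;
        weight[g] = trunc_normal(rw, w_mean[p], w_sd[p]);
        dstep[g] = delay_steps(rd, d_mean[p], d_rel_sd[p], dt, cap_ms);
      }
    }
  }
  return List::create(_["source"] = source, _["target"] = target,
                      _["projection"] = proj, _["weight"] = weight,
                      _["delay_steps"] = dstep);
}

// Minimum realized delay (steps) per projection: exact causal lower bound for
// perturbation propagation.
// [[Rcpp::export]]
NumericVector cpp_projection_min_delays(NumericVector proj_k,
                                        NumericVector d_mean,
                                        NumericVector d_rel_sd,
                                        double dt, double cap_ms,
                                        double net_seed) {
  const int n_proj = proj_k.size();
  NumericVector out(n_proj);
  uint64_t base = 0;
  for (int p = 0; p < n_proj; ++p) {
    const int64_t K = (int64_t)std::llround(proj_k[p]);
    int mn = INT32_MAX;
    for (int64_t k = 0; k < K; ++k) {
      Ctr rd(stream_key((uint64_t)net_seed, TAG_D, base + (uint64_t)k));
      int s = delay_steps(rd, d_mean[p], d_rel_sd[p], dt, cap_ms);
      if (s < mn) mn = s;
    }
    out[p] = (K > 0) ? mn * dt : NA_REAL;
    base += (uint64_t)K;
  }
  return out;
}

// ---------------------------------------------------------------------------
// simulation

// pop_par columns: 0 Cm[pF], 1 tau_m[ms], 2 V_th[mV], 3 E_L[mV], 4 V_reset[mV],
//                  5 tau_r[ms], 6 tau_s[ms], 7 I_const[pA]
// cv_par  columns: 0 cv_V_th, 1 cv_C_m, 2 cv_tau_m
// [[Rcpp::export]]
List cpp_simulate(IntegerVector pop_size, NumericMatrix pop_par,
                  IntegerVector pop_area,
                  IntegerVector proj_src, IntegerVector proj_tgt,
                  NumericVector proj_k,
                  NumericVector w_mean, NumericVector w_sd,
                  NumericVector d_mean, NumericVector d_rel_sd,
                  NumericVector lam_ext, NumericVector wext_mean,
                  NumericVector wext_sd,
                  double duration_ms, double dt, double cap_ms,
                  double net_seed, double sim_seed,
                  double perturb_neuron, double perturb_ms,
                  bool probes, int n_areas, double vm_neuron,
                  NumericMatrix cv_par, bool distributed) {
  Net net;
  build_net(net, pop_size, proj_src, proj_tgt, proj_k, net_seed);
  const int64_t N = net.n_neurons;
  const int n_pop = net.n_pop;
  const int64_t nsteps = (int64_t)std::llround(duration_ms / dt);
  const int cap_steps = (int)std::llround(cap_ms / dt);
  const int64_t L = (int64_t)cap_steps + 2;
  const int per_ms = (int)std::llround(1.0 / dt);
  const uint64_t sseed = (uint64_t)sim_seed;

  // per-population precomputation
  std::vector<double> eI(n_pop), lamv(n_pop), wem(n_pop), wes(n_pop);
  std::vector<double> expneg(n_pop);
  std::vector<int> taur_steps(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    eI[p] = std::exp(-dt / pop_par(p, 6));
    taur_steps[p] = (int)std::llround(pop_par(p, 5) / dt);
    lamv[p] = lam_ext[p];
    expneg[p] = std::exp(-lamv[p]);
    wem[p] = wext_mean[p];
    wes[p] = wext_sd[p];
  }

  // per-neuron state and coefficients
  std::vector<int32_t> pop_of(N);
  for (int p = 0; p < n_pop; ++p) {
    for (int64_t g = net.pop_off[p]; g < net.pop_off[p + 1]; ++g) {
      pop_of[g] = p;
    }
  }
  std::vector<double> V(N), I(N, 0.0), eV(N), prop(N), vinf(N), vth(N),
      vr(N);
  std::vector<int64_t> refrac_end(N, -1);
  std::vector<uint64_t> nkey(N), nctr(N, 0);

  for (int64_t g = 0; g < N; ++g) {
    const int p = pop_of[g];
    double Cm = pop_par(p, 0), taum = pop_par(p, 1), Vth = pop_par(p, 2);
    const double EL = pop_par(p, 3), Vr = pop_par(p, 4);
    const double taus = pop_par(p, 6), Ic = pop_par(p, 7);
    nkey[g] = stream_key(sseed, TAG_NRN, (uint64_t)g);
    Ctr r(nkey[g]);
    if (distributed) {
      // log-normal parameters with the given CVs; three draws always happen
      // so the stream layout is fixed
      auto ln = [&](double mean, double cv, double zdraw) {
        if (cv <= 0.0) return mean;
        double s2 = std::log1p(cv * cv);
        return mean * std::exp(std::sqrt(s2) * zdraw - 0.5 * s2);
      };
      double z1 = r.normal(), z2 = r.normal(), z3 = r.normal();
      // thresholds are distributed relative to the leak potential
      Vth = EL + ln(Vth - EL, cv_par(p, 0), z1);
      Cm = ln(Cm, cv_par(p, 1), z2);
      taum = ln(taum, cv_par(p, 2), z3);
    }
    if (std::abs(taus - taum) < 1e-9) stop("tau_s must differ from tau_m");
    eV[g] = std::exp(-dt / taum);
    prop[g] = (std::exp(-dt / taus) - std::exp(-dt / taum)) /
      (Cm * (1.0 / taum - 1.0 / taus));
    vinf[g] = EL + Ic * taum / Cm;
    vth[g] = Vth;
    vr[g] = Vr;
    V[g] = Vr + r.unif() * (Vth - Vr); // initial condition
    nctr[g] = r.ctr;
  }

  std::vector<float> ring((size_t)L * (size_t)N, 0.0f);
  std::vector<int> spk_n, spk_t;
  spk_n.reserve(1 << 16);
  spk_t.reserve(1 << 16);

  const int64_t pstep = (perturb_neuron >= 0)
    ? (int64_t)std::llround(perturb_ms / dt) : -1;
  const int64_t pneuron = (int64_t)perturb_neuron;
  const int64_t vmn = (int64_t)vm_neuron;
  const int64_t n_ms = probes ? nsteps / per_ms : 0;
  NumericMatrix probe(probes ? n_ms : 0, probes ? n_areas : 0);
  NumericVector vm(vmn >= 0 ? nsteps : 0);

  for (int64_t s = 0; s < nsteps; ++s) {
    float* slot = ring.data() + (size_t)(s % L) * (size_t)N;
    const int64_t e = s + 1; // index of the step end
    for (int64_t g = 0; g < N; ++g) {
      const int p = pop_of[g];
      double inc = slot[g];
      slot[g] = 0.0f;
      if (lamv[p] > 0.0) {
        Ctr r(nkey[g]);
        r.ctr = nctr[g];
        // Poisson count of external events in this step
        int nev = 0;
        double pr = 1.0;
        do { pr *= r.unif(); ++nev; } while (pr > expneg[p]);
        --nev;
        for (int j = 0; j < nev; ++j) inc += trunc_normal(r, wem[p], wes[p]);
        nctr[g] = r.ctr;
      }
      const double Inew = I[g] + inc;
      if (e > refrac_end[g]) {
        V[g] = vinf[g] + (V[g] - vinf[g]) * eV[g] + Inew * prop[g];
      } else {
        V[g] = vr[g];
      }
      I[g] = Inew * eI[p];
      if (!std::isfinite(V[g]) || !std::isfinite(I[g])) {
        stop("non-finite state at neuron %d, t = %.1f ms", (int)g + 1,
             (double)(e * dt));
      }
      bool fire = (e == pstep && g == pneuron);
      if (!fire && e > refrac_end[g] && V[g] >= vth[g]) fire = true;
      if (fire) {
        spk_n.push_back((int)g);
        spk_t.push_back((int)e);
        V[g] = vr[g];
        refrac_end[g] = e + taur_steps[p];
        // deliver
        const int64_t li = g - net.pop_off[p];
        for (int pr_ : net.projs_of_pop[p]) {
          const uint32_t* off = net.srcoff.data() + net.projptr[pr_] + li;
          const uint64_t b0 = net.base[pr_];
          const double wm = w_mean[pr_], ws = w_sd[pr_];
          const double dm = d_mean[pr_], dr = d_rel_sd[pr_];
          for (uint32_t k = off[0]; k < off[1]; ++k) {
            const uint64_t gs = b0 + k;
            Ctr rw(stream_key(net.net_seed, TAG_W, gs));
            const double w = trunc_normal(rw, wm, ws);
            Ctr rd(stream_key(net.net_seed, TAG_D, gs));
            const int ds = delay_steps(rd, dm, dr, dt, cap_ms);
            ring[(size_t)((e + ds) % L) * (size_t)N + net.targets[gs]] +=
              (float)w;
          }
        }
      }
    }
    if (vmn >= 0) vm[s] = V[vmn];
    if (probes && (e % per_ms == 0)) {
      const int64_t row = e / per_ms - 1;
      if (row < n_ms) {
        for (int64_t g = 0; g < N; ++g) {
          probe(row, pop_area[pop_of[g]]) += std::fabs(I[g]);
        }
      }
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_neuron"] = wrap(spk_n),
    _["spike_step"] = wrap(spk_t),
    _["probes"] = probe,
    _["vm"] = vm
  );
}
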