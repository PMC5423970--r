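#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// torus geometry
// ---------------------------------------------------------------------------

static inline double torus_d2(double dx, double dy, double L) {
  dx = std::fabs(dx);
  if (dx > 0.5 * L) dx = L - dx;
  dy = std::fabs(dy);
  if (dy > 0.5 * L) dy = L - dy;
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
NumericVector torus_distance_cpp(NumericVector px, NumericVector py,
                                 NumericVector qx, NumericVector qy,
                                 double L) {
  R_xlen_t n = px.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::sqrt(torus_d2(px[i] - qx[i], py[i] - qy[i], L));
  return out;
}

// ---------------------------------------------------------------------------
// kernel-weighted sampling without replacement (fixed in-degree)
//
// For each target neuron, K sources per population are drawn without
// replacement with probability proportional to exp(-d^2 / (2 sigma^2)),
// self-connections excluded.  Uses exponential keys (Efraimidis-Spirakis):
// the K sources with the smallest -log(u)/w are exactly a weighted sample
// without replacement.  Draws come from R's RNG so topologies are
// reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sample_connections_cpp(NumericVector x, NumericVector y,
                            IntegerVector pop,  // 0 = E, 1 = I
                            double L, double sigmaE, double sigmaI,
                            int KE, int KI) {
  int n = x.size();
  std::vector<int> eidx, iidx;
  for (int j = 0; j < n; ++j) (pop[j] == 0 ? eidx : iidx).push_back(j);
  int nE = (int)eidx.size(), nI = (int)iidx.size();
  // self-connections are excluded, so a target can draw at most n-1 sources
  // from its own population
  if (KE > nE - 1 || KI > nI - 1)
    stop("in-degree exceeds the number of eligible source neurons");

  int ktot = KE + KI;
  IntegerVector src((R_xlen_t)n * ktot);
  NumericVector dist((R_xlen_t)n * ktot);

  std::vector<std::pair<double, int> > keys;
  keys.reserve(std::max(nE, nI));
  double twoSE2 = 2.0 * sigmaE * sigmaE, twoSI2 = 2.0 * sigmaI * sigmaI;

  for (int i = 0; i < n; ++i) {
    R_xlen_t off = (R_xlen_t)i * ktot;
    // excitatory sources
    keys.clear();
    for (int k = 0; k < nE; ++k) {
      int j = eidx[k];
      if (j == i) continue;
      double d2 = torus_d2(x[i] - x[j], y[i] - y[j], L);
      double w = std::exp(-d2 / twoSE2);
      double key = (w > 0.0) ? -std::log(unif_rand()) / w : R_PosInf;
      keys.push_back(std::make_pair(key, j));
    }
    std::partial_sort(keys.begin(), keys.begin() + KE, keys.end());
    for (int k = 0; k < KE; ++k) {
      int j = keys[k].second;
      src[off + k] = j;
      dist[off + k] = std::sqrt(torus_d2(x[i] - x[j], y[i] - y[j], L));
    }
    // inhibitory sources
    keys.clear();
    for (int k = 0; k < nI; ++k) {
      int j = iidx[k];
      if (j == i) continue;
      double d2 = torus_d2(x[i] - x[j], y[i] - y[j], L);
      double w = std::exp(-d2 / twoSI2);
      double key = (w > 0.0) ? -std::log(unif_rand()) / w : R_PosInf;
      keys.push_back(std::make_pair(key, j));
    }
    std::partial_sort(keys.begin(), keys.begin() + KI, keys.end());
    for (int k = 0; k < KI; ++k) {
      int j = keys[k].second;
      src[off + KE + k] = j;
      dist[off + KE + k] = std::sqrt(torus_d2(x[i] - x[j], y[i] - y[j], L));
    }
  }
  return List::create(_["src"] = src, _["dist"] = dist, _["k_tot"] = ktot);
}

// ---------------------------------------------------------------------------
// fast internal RNG (xoshiro256+), seeded from R's RNG so that runs are
// reproducible under set.seed().  Used for afferent Poisson draws and the
// initial membrane voltages, which dominate the per-step random-number cost.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  void seed_from_r() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    for (int i = 0; i < 16; ++i) next();
  }
  uint64_t next() {
    uint64_t res = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  double runif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Poisson draw for small lambda via CDF inversion; exp(-lambda) precomputed.
static inline int rpois_small(Xoshiro &rng, double lambda, double exp_neg) {
  double u = rng.runif();
  if (u <= exp_neg) return 0;
  int k = 0;
  double p = exp_neg, c = exp_neg;
  while (u > c && k < 200) {
    ++k;
    p *= lambda / k;
    c += p;
  }
  return k;
}

// ---------------------------------------------------------------------------
// AEIF network integration
//
// Membrane:  C dV/dt = -gL (V-EL) + gL DT exp((V-VT)/DT) - w + I_syn + I_ext
// Adaptation: tauw dw/dt = a (V-EL) - w;  on spike V -> Vreset, w += b
// Synapses: conductance-based, AMPA/GABA_A single-exponential decay, NMDA
// bi-exponential (difference of exponentials normalised to unit peak).
// Spikes are delivered through per-neuron circular delay buffers quantised
// to the integration step.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_net_cpp(int n, int nE,
                 IntegerVector out_ptr,      // CSR by source, length n+1
                 IntegerVector out_tgt,      // target indices (0-based)
                 IntegerVector out_delay,    // delay in steps (>= 1)
                 NumericMatrix np,           // 11 x 2 neuron params [,pop]
                 List syn,                   // synapse params
                 NumericVector aff_rate,     // per-neuron total afferent rate (Hz)
                 NumericVector g_aff,        // nS per afferent event (length 1 or n)
                 double stim_end,            // s; afferents off afterwards
                 NumericVector I_ext,        // pA per neuron (length n or 1)
                 double duration,            // s
                 double dt,                  // ms
                 NumericVector init_V) {     // length n, or 0 => random
  // neuron params rows: C gL EL VT DT a b tauw Vreset Vcut tref
  const int C_ = 0, GL_ = 1, EL_ = 2, VT_ = 3, DT_ = 4, A_ = 5, B_ = 6,
            TW_ = 7, VR_ = 8, VC_ = 9, TR_ = 10;

  double gEE = as<double>(syn["g_EE"]), gIE = as<double>(syn["g_IE"]);
  double gEI = as<double>(syn["g_EI"]), gII = as<double>(syn["g_II"]);
  double frac_a = as<double>(syn["frac_ampa"]);
  double tau_a = as<double>(syn["tau_ampa"]), tau_g = as<double>(syn["tau_gaba"]);
  double tau_nr = as<double>(syn["tau_nmda_rise"]), tau_nd = as<double>(syn["tau_nmda_decay"]);
  double E_ex = as<double>(syn["E_ex"]), E_in = as<double>(syn["E_in"]);

  int nsteps = (int)std::llround(duration * 1000.0 / dt);
  double dec_a = std::exp(-dt / tau_a), dec_g = std::exp(-dt / tau_g);
  double dec_nr = std::exp(-dt / tau_nr), dec_nd = std::exp(-dt / tau_nd);
  // normalise NMDA difference-of-exponentials to unit peak
  double tp = tau_nr * tau_nd / (tau_nd - tau_nr) * std::log(tau_nd / tau_nr);
  double nmda_norm = 1.0 / (std::exp(-tp / tau_nd) - std::exp(-tp / tau_nr));

  // per (source pop -> target pop) strengths: E source splits AMPA/NMDA
  // index by target pop: 0 = E target, 1 = I target
  double wA_from_E[2] = {frac_a * gEE, frac_a * gIE};
  double wN_from_E[2] = {(1.0 - frac_a) * gEE, (1.0 - frac_a) * gIE};
  double wG_from_I[2] = {gEI, gII};

  // delay ring buffers, slot-major so each step touches contiguous memory
  int maxd = 1;
  for (R_xlen_t s = 0; s < out_delay.size(); ++s)
    if (out_delay[s] > maxd) maxd = out_delay[s];
  int B = 1;
  while (B < maxd + 1) B <<= 1;
  int mask = B - 1;
  std::vector<double> qa((size_t)n * B, 0.0), qn((size_t)n * B, 0.0),
      qg((size_t)n * B, 0.0);

  std::vector<double> V(n), W(n, 0.0), gA(n, 0.0), gG(n, 0.0), xR(n, 0.0),
      xD(n, 0.0);
  std::vector<int> ref(n, 0);
  std::vector<unsigned char> popv(n);
  for (int i = 0; i < n; ++i) popv[i] = (i < nE) ? 0 : 1;

  // hoist per-population constants
  double Cm[2], gL[2], EL[2], VT[2], DTs[2], aa[2], bb[2], tw[2], Vr[2],
      Vc[2], trf[2];
  for (int p = 0; p < 2; ++p) {
    Cm[p] = np(C_, p); gL[p] = np(GL_, p); EL[p] = np(EL_, p);
    VT[p] = np(VT_, p); DTs[p] = np(DT_, p); aa[p] = np(A_, p);
    bb[p] = np(B_, p); tw[p] = np(TW_, p); Vr[p] = np(VR_, p);
    Vc[p] = np(VC_, p); trf[p] = np(TR_, p);
  }
  int tref_steps[2];
  for (int p = 0; p < 2; ++p)
    tref_steps[p] = (int)std::llround(trf[p] / dt);

  Xoshiro rng;
  rng.seed_from_r();

  for (int i = 0; i < n; ++i) {
    int p = popv[i];
    if (init_V.size() == n) V[i] = init_V[i];
    else V[i] = EL[p] + (VT[p] - EL[p]) * rng.runif();
  }

  bool scalar_I = (I_ext.size() == 1);
  bool scalar_gaff = (g_aff.size() == 1);
  std::vector<double> lam(n), elam(n);
  bool any_aff = false;
  for (int i = 0; i < n; ++i) {
    lam[i] = aff_rate[i] * dt * 1e-3;  // events per step
    elam[i] = std::exp(-lam[i]);
    if (lam[i] > 0) any_aff = true;
  }
  int stim_end_step = (stim_end >= duration) ? nsteps
                      : (int)std::llround(stim_end * 1000.0 / dt);

  std::vector<int> sp_n;
  std::vector<double> sp_t;
  sp_n.reserve(1 << 16);
  sp_t.reserve(1 << 16);

  const int *optr = INTEGER(out_ptr), *otgt = INTEGER(out_tgt),
            *odel = INTEGER(out_delay);
  const double *Ie = REAL(I_ext), *ga_w = REAL(g_aff);

  for (int step = 0; step < nsteps; ++step) {
    int slot = step & mask;
    bool aff_on = any_aff && (step < stim_end_step);
    double *qa_s = &qa[(size_t)slot * n];
    double *qn_s = &qn[(size_t)slot * n];
    double *qg_s = &qg[(size_t)slot * n];
    for (int i = 0; i < n; ++i) {
      gA[i] += qa_s[i]; qa_s[i] = 0.0;
      double inc = qn_s[i]; qn_s[i] = 0.0;
      xR[i] += inc; xD[i] += inc;
      gG[i] += qg_s[i]; qg_s[i] = 0.0;
      if (aff_on && lam[i] > 0) {
        int k = rpois_small(rng, lam[i], elam[i]);
        if (k) gA[i] += k * (scalar_gaff ? ga_w[0] : ga_w[i]);
      }
      gA[i] *= dec_a; gG[i] *= dec_g; xR[i] *= dec_nr; xD[i] *= dec_nd;

      int p = popv[i];
      double v = V[i];
      double gN = nmda_norm * (xD[i] - xR[i]);
      double Isyn = (gA[i] + gN) * (E_ex - v) + gG[i] * (E_in - v);
      double Ii = scalar_I ? Ie[0] : Ie[i];

      if (ref[i] > 0) {
        --ref[i];
        W[i] += dt / tw[p] * (aa[p] * (v - EL[p]) - W[i]);
        continue;
      }
      double arg = (v - VT[p]) / DTs[p];
      if (arg > 16.0) arg = 16.0;  // spike upswing; cap to keep Euler finite
      double dV = dt / Cm[p] *
                  (-gL[p] * (v - EL[p]) + gL[p] * DTs[p] * std::exp(arg) -
                   W[i] + Isyn + Ii);
      double vn = v + dV;
      W[i] += dt / tw[p] * (aa[p] * (v - EL[p]) - W[i]);

      if (!std::isfinite(vn))
        stop("non-finite membrane voltage at step %d (neuron %d)", step, i + 1);

      if (vn >= Vc[p]) {
        sp_n.push_back(i + 1);
        sp_t.push_back((step + 1) * dt * 1e-3);
        V[i] = Vr[p];
        W[i] += bb[p];
        ref[i] = tref_steps[p];
        if (p == 0) {
          for (int s = optr[i]; s < optr[i + 1]; ++s) {
            int j = otgt[s];
            size_t qj = (size_t)((step + odel[s]) & mask) * n + j;
            int jp = popv[j];
            qa[qj] += wA_from_E[jp];
            qn[qj] += wN_from_E[jp];
          }
        } else {
          for (int s = optr[i]; s < optr[i + 1]; ++s) {
            int j = otgt[s];
            size_t qj = (size_t)((step + odel[s]) & mask) * n + j;
            qg[qj] += wG_from_I[popv[j]];
          }
        }
      } else {
        V[i] = vn;
      }
    }
    if ((step & 2047) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron"] = wrap(sp_n), _["time"] = wrap(sp_t),
                      _["V_final"] = wrap(V));
}

// ---------------------------------------------------------------------------
// single-neuron voltage trace (same update rule as the network loop); used
// for EPSP calibration and single-cell oracles.  A single presynaptic event
// of given AMPA/NMDA/GABA weight arrives at t_spike.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List single_neuron_cpp(NumericVector prm,  // C gL EL VT DT a b tauw Vreset Vcut tref
                       List syn, double w_ampa, double w_nmda, double w_gaba,
                       double t_spike,     // ms, < 0 for none
                       double I_const,     // pA
                       double duration,    // ms
                       double dt, double V0) {
  double C = prm[0], gL = prm[1], EL = prm[2], VT = prm[3], DT = prm[4],
         a = prm[5], b = prm[6], tauw = prm[7], Vr = prm[8], Vc = prm[9],
         tref = prm[10];
  double tau_a = as<double>(syn["tau_ampa"]), tau_g = as<double>(syn["tau_gaba"]);
  double tau_nr = as<double>(syn["tau_nmda_rise"]), tau_nd = as<double>(syn["tau_nmda_decay"]);
  double E_ex = as<double>(syn["E_ex"]), E_in = as<double>(syn["E_in"]);
  double dec_a = std::exp(-dt / tau_a), dec_g = std::exp(-dt / tau_g);
  double dec_nr = std::exp(-dt / tau_nr), dec_nd = std::exp(-dt / tau_nd);
  double tp = tau_nr * tau_nd / (tau_nd - tau_nr) * std::log(tau_nd / tau_nr);
  double nmda_norm = 1.0 / (std::exp(-tp / tau_nd) - std::exp(-tp / tau_nr));

  int nsteps = (int)std::llround(duration / dt);
  int spike_step = t_spike < 0 ? -1 : (int)std::llround(t_spike / dt);
  NumericVector Vtr(nsteps);
  std::vector<double> spikes;
  double V = V0, W = 0, gA = 0, gG = 0, xR = 0, xD = 0;
  int ref = 0;
  for (int step = 0; step < nsteps; ++step) {
    if (step == spike_step) {
      gA += w_ampa; gG += w_gaba; xR += w_nmda; xD += w_nmda;
    }
    gA *= dec_a; gG *= dec_g; xR *= dec_nr; xD *= dec_nd;
    double gN = nmda_norm * (xD - xR);
    double Isyn = (gA + gN) * (E_ex - V) + gG * (E_in - V);
    if (ref > 0) {
      --ref;
      W += dt / tauw * (a * (V - EL) - W);
      Vtr[step] = V;
      continue;
    }
    double arg = (V - VT) / DT;
    if (arg > 16.0) arg = 16.0;
    double vn = V + dt / C * (-gL * (V - EL) + gL * DT * std::exp(arg) - W + Isyn + I_const);
    W += dt / tauw * (a * (V - EL) - W);
    if (vn >= Vc) {
      spikes.push_back((step + 1) * dt);
      V = Vr;
      W += b;
      ref = (int)std::llround(tref / dt);
    } else {
      V = vn;
    }
    Vtr[step] = V;
  }
  return List::create(_["V"] = Vtr, _["spikes"] = wrap(spikes));
}
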