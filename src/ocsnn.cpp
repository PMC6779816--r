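// Simulation core: exact linear propagators for EGLIF/LIF point neurons,
// proximity-constrained connectivity sampling, and the clock-driven network
// engine with alpha-conductance receptors and per-synapse delay queues.
// All randomness goes through R's RNG so set.seed() governs every draw.
#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Subthreshold EGLIF dynamics are linear in x = (V, Iadap, Idep):
//   V'     = -V/tau_m - Iadap/Cm + Idep/Cm + (EL/tau_m + (Ie + Isyn)/Cm)
//   Iadap' = kadap * (V - EL) - k2 * Iadap
//   Idep'  = -k1 * Idep
// so x' = M x + b with b constant within a step (Isyn frozen at step start).
// The exact update is x(t+dt) = A x + Q b with A = expm(M dt) and
// Q = int_0^dt expm(M s) ds, both read off the augmented matrix exponential
// expm([[M, I], [0, 0]] dt). This is step-size invariant for the
// subthreshold flow, whatever the sign pattern or rank of M.
static void propagator(double Cm, double tau_m, double kadap, double k2,
                       double k1, double dt, arma::mat& A, arma::mat& Q) {
  arma::mat M(3, 3, arma::fill::zeros);
  M(0, 0) = -1.0 / tau_m; M(0, 1) = -1.0 / Cm; M(0, 2) = 1.0 / Cm;
  M(1, 0) = kadap;        M(1, 1) = -k2;
  M(2, 2) = -k1;
  arma::mat aug(6, 6, arma::fill::zeros);
  aug.submat(0, 0, 2, 2) = M;
  aug.submat(0, 3, 2, 5) = arma::eye(3, 3);
  arma::mat E = arma::expmat(aug * dt);
  A = E.submat(0, 0, 2, 2);
  Q = E.submat(0, 3, 2, 5);
}

// [[Rcpp::export(name = ".propagator_matrices")]]
List propagator_matrices(double Cm, double tau_m, double kadap, double k2,
                         double k1, double dt) {
  arma::mat A, Q;
  propagator(Cm, tau_m, kadap, k2, k1, dt, A, Q);
  return List::create(_["A"] = wrap(A), _["Q"] = wrap(Q));
}

struct NeuronParams {
  double Cm, tau_m, EL, Vth, Vr, tref, Ie;
  double kadap, k2, k1, A1, A2, lambda0, deltaV;
  int model; // 0 = LIF (deterministic threshold), 1 = EGLIF (escape noise),
             // 2 = external spike source (no dynamics)
};

static std::vector<NeuronParams> read_params(const NumericMatrix& pp) {
  std::vector<NeuronParams> out(pp.nrow());
  for (int i = 0; i < pp.nrow(); ++i) {
    NeuronParams& p = out[i];
    p.Cm = pp(i, 0); p.tau_m = pp(i, 1); p.EL = pp(i, 2); p.Vth = pp(i, 3);
    p.Vr = pp(i, 4); p.tref = pp(i, 5); p.Ie = pp(i, 6); p.kadap = pp(i, 7);
    p.k2 = pp(i, 8); p.k1 = pp(i, 9); p.A1 = pp(i, 10); p.A2 = pp(i, 11);
    p.lambda0 = pp(i, 12); p.deltaV = pp(i, 13);
    p.model = (int)pp(i, 14);
  }
  return out;
}

// Escape-noise spike probability over one step of dt ms: the instantaneous
// rate lambda(V) = lambda0 * exp((V - Vth) / deltaV) (Hz) integrated over dt.
static inline bool escape_spike(double V, const NeuronParams& p, double dt) {
  double arg = (V - p.Vth) / p.deltaV;
  if (arg > 30.0) return true;
  double lambda = p.lambda0 * std::exp(arg); // Hz
  double prob = -std::expm1(-lambda * dt * 1e-3);
  return R::unif_rand() < prob;
}

// Isolated neuron under a constant synaptic current; used by the
// autorhythm-tuning routine and single-neuron statistics.
// [[Rcpp::export(name = ".simulate_neuron_cpp")]]
List simulate_neuron_cpp(NumericVector par, double I_syn, double T, double dt,
                         double V0, bool record_vm) {
  NumericMatrix pp(1, 15);
  for (int j = 0; j < 15; ++j) pp(0, j) = par[j];
  NeuronParams p = read_params(pp)[0];
  arma::mat A, Q;
  propagator(p.Cm, p.tau_m, p.kadap, p.k2, p.k1, dt, A, Q);
  // refractory-phase closed forms with V clamped at Vr
  double e2 = (p.k2 > 0) ? std::exp(-p.k2 * dt) : 1.0;
  double cad = (p.k2 > 0) ? p.kadap * (p.Vr - p.EL) / p.k2 * (1.0 - e2)
                          : p.kadap * (p.Vr - p.EL) * dt;
  double e1 = std::exp(-p.k1 * dt);
  int n_steps = (int)std::lround(T / dt);
  int ref_steps_total = (int)std::ceil(p.tref / dt);
  double V = NumericVector::is_na(V0) ? p.EL : V0;
  double Iadap = 0.0, Idep = 0.0;
  int refr = 0;
  std::vector<double> spikes;
  NumericVector vm(record_vm ? n_steps : 0);
  double b1c = p.EL / p.tau_m + p.Ie / p.Cm;
  double b2 = -p.kadap * p.EL;
  for (int t = 0; t < n_steps; ++t) {
    if (record_vm) vm[t] = V;
    if (refr > 0) {
      Iadap = Iadap * e2 + cad;
      Idep *= e1;
      V = p.Vr;
      --refr;
      continue;
    }
    double b1 = b1c + I_syn / p.Cm;
    double Vn = A(0,0)*V + A(0,1)*Iadap + A(0,2)*Idep + Q(0,0)*b1 + Q(0,1)*b2;
    double An = A(1,0)*V + A(1,1)*Iadap + A(1,2)*Idep + Q(1,0)*b1 + Q(1,1)*b2;
    double Dn = A(2,2)*Idep; // Idep is decoupled and input-free
    V = Vn; Iadap = An; Idep = Dn;
    if (!std::isfinite(V)) stop("non-finite membrane potential");
    bool spk = (p.model == 1) ? escape_spike(V, p, dt) : (V >= p.Vth);
    if (spk) {
      spikes.push_back((t + 1) * dt);
      V = p.Vr;
      Idep = p.A1;
      Iadap += p.A2;
      refr = ref_steps_total;
    }
  }
  return List::create(_["spikes"] = wrap(spikes), _["vm"] = vm,
                      _["state"] = NumericVector::create(V, Iadap, Idep));
}

// ---------------------------------------------------------------------------
// Connectivity sampling: candidate presynaptic pools by axis-aligned
// proximity, then sampling without replacement to a fixed or Gaussian-drawn
// convergence.
// mode 0: radial distance in the x-z plane <= reach
// mode 1: |x_pre - x_post| <= reach (parallel-fiber geometry)
// [[Rcpp::export(name = ".connect_geometric_cpp")]]
List connect_geometric_cpp(NumericMatrix pre_xz, NumericMatrix post_xz,
                           double reach, int mode, double conv_mean,
                           double conv_sd, bool fixed, bool allow_clip,
                           bool same_pop, std::string row_name) {
  int n_pre = pre_xz.nrow(), n_post = post_xz.nrow();
  std::vector<int> out_pre, out_post;
  if (n_pre == 0 || n_post == 0)
    return List::create(_["pre"] = IntegerVector(0),
                        _["post"] = IntegerVector(0));
  out_pre.reserve((size_t)n_post * (size_t)std::max(1.0, conv_mean));
  out_post.reserve(out_pre.capacity());

  // spatial index
  std::vector<int> order(n_pre);
  for (int i = 0; i < n_pre; ++i) order[i] = i;
  // grid for radial mode
  double xmin = 0, zmin = 0, cell = std::max(reach, 1e-9);
  int nx = 1, nz = 1;
  std::vector<std::vector<int>> grid;
  if (mode == 0) {
    double xmax = pre_xz(0, 0), zmax = pre_xz(0, 1);
    xmin = xmax; zmin = zmax;
    for (int i = 0; i < n_pre; ++i) {
      xmin = std::min(xmin, pre_xz(i, 0)); xmax = std::max(xmax, pre_xz(i, 0));
      zmin = std::min(zmin, pre_xz(i, 1)); zmax = std::max(zmax, pre_xz(i, 1));
    }
    nx = std::max(1, (int)((xmax - xmin) / cell) + 1);
    nz = std::max(1, (int)((zmax - zmin) / cell) + 1);
    grid.assign((size_t)nx * nz, {});
    for (int i = 0; i < n_pre; ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)((pre_xz(i, 0) - xmin) / cell)));
      int cz = std::min(nz - 1, std::max(0, (int)((pre_xz(i, 1) - zmin) / cell)));
      grid[(size_t)cx * nz + cz].push_back(i);
    }
  } else {
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      return pre_xz(a, 0) < pre_xz(b, 0);
    });
  }

  std::vector<int> cand;
  for (int j = 0; j < n_post; ++j) {
    cand.clear();
    double px = post_xz(j, 0), pz = post_xz(j, 1);
    if (mode == 0) {
      int cx = (int)((px - xmin) / cell), cz = (int)((pz - zmin) / cell);
      double r2 = reach * reach;
      for (int ax = std::max(0, cx - 1); ax <= std::min(nx - 1, cx + 1); ++ax)
        for (int az = std::max(0, cz - 1); az <= std::min(nz - 1, cz + 1); ++az)
          for (int i : grid[(size_t)ax * nz + az]) {
            if (same_pop && i == j) continue;
            double dx = pre_xz(i, 0) - px, dz = pre_xz(i, 1) - pz;
            if (dx * dx + dz * dz <= r2) cand.push_back(i);
          }
    } else {
      // binary search over pre sorted by x
      int lo = 0, hi = n_pre;
      {
        int a = 0, b = n_pre;
        while (a < b) { int m = (a + b) / 2;
          if (pre_xz(order[m], 0) < px - reach) a = m + 1; else b = m; }
        lo = a; a = lo; b = n_pre;
        while (a < b) { int m = (a + b) / 2;
          if (pre_xz(order[m], 0) <= px + reach) a = m + 1; else b = m; }
        hi = a;
      }
      for (int k = lo; k < hi; ++k) {
        int i = order[k];
        if (same_pop && i == j) continue;
        cand.push_back(i);
      }
    }
    int pool = (int)cand.size();
    int want = fixed ? (int)std::lround(conv_mean)
                     : (int)std::lround(R::rnorm(conv_mean, conv_sd));
    if (want < 1) want = 1;
    if (want > pool) {
      if (fixed && !allow_clip)
        stop("connection '" + row_name + "': candidate pool (" +
             std::to_string(pool) + ") smaller than required convergence (" +
             std::to_string(want) + ") for target " + std::to_string(j + 1));
      want = pool;
    }
    // partial Fisher-Yates draw without replacement
    for (int k = 0; k < want; ++k) {
      int idx = k + (int)std::floor(R::unif_rand() * (pool - k));
      if (idx >= pool) idx = pool - 1;
      std::swap(cand[k], cand[idx]);
      out_pre.push_back(cand[k] + 1);
      out_post.push_back(j + 1);
    }
  }
  return List::create(_["pre"] = wrap(out_pre), _["post"] = wrap(out_post));
}

// ---------------------------------------------------------------------------
// Network engine. Alpha-conductance receptors are kept per (connection row,
// postsynaptic neuron) — the alpha kernel is linear, so one filter per row
// carries any number of converging synapses while distinct rows keep their
// own tau_alpha and reversal potential. Filter states (g, h):
//   h' = -h/tau,  g' = -g/tau + h
// give g(t) = A t exp(-t/tau) after an impulse h += A; with A = w e / tau the
// kernel peaks at exactly w at t = tau. Exact per-step propagation:
//   g <- e (g + dt h),  h <- e h,  e = exp(-dt/tau)
// handles sub-step time constants without loss.
// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(
    IntegerVector pop_of,        // 0-based population index per neuron
    NumericMatrix pop_params,    // one row per population (15 columns)
    IntegerVector pop_offset,    // 0-based first global index per population
    IntegerVector pop_size,
    IntegerVector src_ptr,       // CSR over sources, length n_neurons + 1
    IntegerVector syn_target,    // 0-based global target ids
    IntegerVector syn_row,       // 0-based connection-row index
    NumericVector syn_weight,    // nS (peak conductance)
    IntegerVector syn_delay,     // delay in steps, >= 1
    IntegerVector row_post_pop,  // 0-based population index per row
    NumericVector row_tau,
    NumericVector row_erev,
    IntegerVector ext_id,        // 0-based ids of external source spikes
    IntegerVector ext_step,      // emission step of each, sorted ascending
    IntegerVector forced_id,     // 0-based ids of forced neuron spikes
    IntegerVector forced_step,   // sorted ascending
    NumericVector V0,            // initial membrane potential per neuron
    double T, double dt,
    IntegerVector record_vm_ids  // 0-based ids whose V(t) is recorded
) {
  const int n = pop_of.size();
  const int n_pop = pop_params.nrow();
  const int n_rows = row_tau.size();
  const int n_steps = (int)std::lround(T / dt);
  std::vector<NeuronParams> P = read_params(pop_params);

  // Per-population propagators and refractory closed forms. Conductance
  // synapses make the voltage equation stiff for small-capacitance neurons
  // when the total conductance G is large (the frozen-current step can
  // overshoot the reversal potentials); whenever G dt / Cm exceeds a fixed
  // margin the neuron's step is split into 2^k exact sub-steps with the
  // synaptic current re-evaluated from the updated voltage. Propagators for
  // dt / 2^k are precomputed per population.
  const int KMAX = 6;
  const double STIFF = 0.2; // largest admissible G dt_sub / Cm
  std::vector<std::array<arma::mat, KMAX + 1>> A(n_pop), Q(n_pop);
  std::vector<double> e2(n_pop), cad(n_pop), e1(n_pop), b1c(n_pop), b2(n_pop);
  std::vector<int> refsteps(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    if (P[p].model == 2) continue;
    for (int k = 0; k <= KMAX; ++k) {
      propagator(P[p].Cm, P[p].tau_m, P[p].kadap, P[p].k2, P[p].k1,
                 dt / (1 << k), A[p][k], Q[p][k]);
    }
    e2[p] = (P[p].k2 > 0) ? std::exp(-P[p].k2 * dt) : 1.0;
    cad[p] = (P[p].k2 > 0)
      ? P[p].kadap * (P[p].Vr - P[p].EL) / P[p].k2 * (1.0 - e2[p])
      : P[p].kadap * (P[p].Vr - P[p].EL) * dt;
    e1[p] = std::exp(-P[p].k1 * dt);
    refsteps[p] = (int)std::ceil(P[p].tref / dt);
    b1c[p] = P[p].EL / P[p].tau_m + P[p].Ie / P[p].Cm;
    b2[p] = -P[p].kadap * P[p].EL;
  }

  // receptor blocks and delay ring buffers per row
  std::vector<std::vector<double>> g(n_rows), h(n_rows), ring(n_rows);
  std::vector<double> edec(n_rows), hscale(n_rows);
  std::vector<int> ringlen(n_rows), rowbase(n_rows), rowsize(n_rows);
  {
    std::vector<int> maxdel(n_rows, 0);
    for (int k = 0; k < syn_row.size(); ++k)
      maxdel[syn_row[k]] = std::max(maxdel[syn_row[k]], syn_delay[k]);
    for (int r = 0; r < n_rows; ++r) {
      int p = row_post_pop[r];
      rowbase[r] = pop_offset[p];
      rowsize[r] = pop_size[p];
      g[r].assign(rowsize[r], 0.0);
      h[r].assign(rowsize[r], 0.0);
      ringlen[r] = maxdel[r] + 1;
      ring[r].assign((size_t)ringlen[r] * rowsize[r], 0.0);
      edec[r] = std::exp(-dt / row_tau[r]);
      hscale[r] = std::exp(1.0) / row_tau[r];
    }
  }

  std::vector<double> V(n), Iadap(n, 0.0), Idep(n, 0.0);
  std::vector<double> Gsum(n), GE(n); // total conductance, sum g * E_rev
  std::vector<int> refr(n, 0);
  for (int i = 0; i < n; ++i) V[i] = V0[i];

  std::vector<int> rec_id, rec_step;
  rec_id.reserve(1 << 20); rec_step.reserve(1 << 20);
  NumericMatrix vm_out(record_vm_ids.size() > 0 ? n_steps : 0,
                       record_vm_ids.size());
  NumericMatrix g_out(record_vm_ids.size() > 0 ? n_steps : 0,
                      record_vm_ids.size());

  int ext_pos = 0, forced_pos = 0;
  auto route = [&](int src, int t_step) {
    for (int k = src_ptr[src]; k < src_ptr[src + 1]; ++k) {
      int r = syn_row[k];
      int slot = (t_step + syn_delay[k]) % ringlen[r];
      int local = syn_target[k] - rowbase[r];
      ring[r][(size_t)slot * rowsize[r] + local] += syn_weight[k] * hscale[r];
    }
  };

  for (int t = 0; t < n_steps; ++t) {
    // 1. deliver spikes scheduled for this step into the h filters
    for (int r = 0; r < n_rows; ++r) {
      int slot = t % ringlen[r];
      double* buf = ring[r].data() + (size_t)slot * rowsize[r];
      double* hr = h[r].data();
      for (int j = 0; j < rowsize[r]; ++j) {
        hr[j] += buf[j];
        buf[j] = 0.0;
      }
    }
    // 2. external source spikes emitted now
    while (ext_pos < ext_id.size() && ext_step[ext_pos] == t) {
      int i = ext_id[ext_pos];
      rec_id.push_back(i); rec_step.push_back(t);
      route(i, t);
      ++ext_pos;
    }
    if (ext_pos < ext_id.size() && ext_step[ext_pos] < t)
      stop("external spike scheduled in the past");
    // 3. conductance totals at step start: I_syn(V) = GE - Gsum * V
    std::fill(Gsum.begin(), Gsum.end(), 0.0);
    std::fill(GE.begin(), GE.end(), 0.0);
    for (int r = 0; r < n_rows; ++r) {
      const double er = row_erev[r];
      const double* gr = g[r].data();
      const int base = rowbase[r], sz = rowsize[r];
      for (int j = 0; j < sz; ++j) {
        Gsum[base + j] += gr[j];
        GE[base + j] += gr[j] * er;
      }
    }
    // 4. record requested membrane potentials and total conductances
    //    (values at step start)
    for (int c = 0; c < record_vm_ids.size(); ++c) {
      vm_out(t, c) = V[record_vm_ids[c]];
      g_out(t, c) = Gsum[record_vm_ids[c]];
    }
    // 5. advance neurons
    for (int i = 0; i < n; ++i) {
      int p = pop_of[i];
      const NeuronParams& pr = P[p];
      if (pr.model == 2) continue;
      if (refr[i] > 0) {
        Iadap[i] = Iadap[i] * e2[p] + cad[p];
        Idep[i] *= e1[p];
        V[i] = pr.Vr;
        --refr[i];
        continue;
      }
      int k = 0;
      double stiff = Gsum[i] * dt / pr.Cm;
      if (stiff > STIFF) {
        k = (int)std::ceil(std::log2(stiff / STIFF));
        if (k > KMAX) k = KMAX;
      }
      const int nsub = 1 << k;
      const double dtsub = dt / nsub;
      const arma::mat& Ap = A[p][k];
      const arma::mat& Qp = Q[p][k];
      bool spk = false;
      for (int s = 0; s < nsub; ++s) {
        double b1 = b1c[p] + (GE[i] - Gsum[i] * V[i]) / pr.Cm;
        double Vn = Ap(0,0)*V[i] + Ap(0,1)*Iadap[i] + Ap(0,2)*Idep[i]
                  + Qp(0,0)*b1 + Qp(0,1)*b2[p];
        double An = Ap(1,0)*V[i] + Ap(1,1)*Iadap[i] + Ap(1,2)*Idep[i]
                  + Qp(1,0)*b1 + Qp(1,1)*b2[p];
        double Dn = Ap(2,2)*Idep[i];
        if (!std::isfinite(Vn))
          stop("non-finite membrane potential at neuron " +
               std::to_string(i + 1));
        V[i] = Vn; Iadap[i] = An; Idep[i] = Dn;
        spk = (pr.model == 1) ? escape_spike(V[i], pr, dtsub)
                              : (V[i] >= pr.Vth);
        if (spk) break;
      }
      if (spk) {
        rec_id.push_back(i); rec_step.push_back(t + 1);
        V[i] = pr.Vr;
        Idep[i] = pr.A1;
        Iadap[i] += pr.A2;
        refr[i] = refsteps[p];
        route(i, t);
      }
    }
    // 6. forced spikes (e.g., the unconditioned-stimulus drive on IO)
    while (forced_pos < forced_id.size() && forced_step[forced_pos] == t) {
      int i = forced_id[forced_pos];
      const NeuronParams& pr = P[pop_of[i]];
      rec_id.push_back(i); rec_step.push_back(t);
      V[i] = pr.Vr;
      Idep[i] = pr.A1;
      Iadap[i] += pr.A2;
      refr[i] = refsteps[pop_of[i]];
      route(i, t);
      ++forced_pos;
    }
    // 7. advance receptor filters to t + dt
    for (int r = 0; r < n_rows; ++r) {
      const double e = edec[r];
      double* gr = g[r].data();
      double* hr = h[r].data();
      for (int j = 0; j < rowsize[r]; ++j) {
        gr[j] = e * (gr[j] + dt * hr[j]);
        hr[j] = e * hr[j];
      }
    }
  }

  IntegerVector out_id(rec_id.begin(), rec_id.end());
  NumericVector out_t(rec_step.size());
  for (size_t k = 0; k < rec_step.size(); ++k) out_t[k] = rec_step[k] * dt;
  return List::create(_["id"] = out_id, _["time"] = out_t, _["vm"] = vm_out,
                      _["g"] = g_out);
}
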