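// Fixed-step midpoint (second-order Runge-Kutta) integrator for networks of
// Hodgkin-Huxley compartments coupled by internal conductances and
// gap junctions with independent directional conductances.
//
// Units throughout: mV, ms, mS/cm2, uA/cm2, uF/cm2.
//
// Gating kinetics: Traub-lineage thalamic reticular (nRT) formulations for
// the six currents NaT, Kd, Kt, K2, AR, CaT. x_inf are Boltzmann functions,
// taus the corresponding published voltage-dependent forms; constants are
// listed per gate in trn_kinetics_table() on the R side.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// gate layout per compartment:
// 0 NaT.m  1 NaT.h  2 Kd.m  3 Kt.m  4 Kt.h  5 K2.m  6 K2.h  7 AR.m  8 CaT.m  9 CaT.h
static const int NGATE = 10;
static const int NCHAN = 6; // NaT Kd Kt K2 AR CaT

static inline void gate_rates(double v, double* xinf, double* tau) {
  // NaT: m^3 h (half-activation shifted -1 mV within the lineage range so
  // the single-compartment cell fires regular tonic spikes at its
  // operating drives)
  xinf[0] = 1.0 / (1.0 + std::exp((-v - 39.0) / 10.0));
  tau[0]  = (v < -30.0) ? 0.0125 + 0.1525 * std::exp((v + 30.0) / 10.0)
                        : 0.02   + 0.145  * std::exp((-v - 30.0) / 10.0);
  xinf[1] = 1.0 / (1.0 + std::exp((v + 63.9) / 10.7));
  tau[1]  = 0.225 + 1.125 / (1.0 + std::exp((v + 37.0) / 15.0));
  // Kd: m^4
  xinf[2] = 1.0 / (1.0 + std::exp((-v - 27.0) / 11.5));
  tau[2]  = (v < -10.0) ? 0.25 + 4.35 * std::exp((v + 10.0) / 10.0)
                        : 0.25 + 4.35 * std::exp((-v - 10.0) / 10.0);
  // Kt (transient A): m^4 h
  xinf[3] = 1.0 / (1.0 + std::exp((-v - 60.0) / 8.5));
  tau[3]  = 0.185 + 0.5 / (std::exp((v + 35.8) / 19.7) + std::exp((-v - 79.7) / 12.7));
  xinf[4] = 1.0 / (1.0 + std::exp((v + 78.0) / 6.0));
  tau[4]  = (v < -63.0) ? 0.5 / (std::exp((v + 46.0) / 5.0) + std::exp((-v - 238.0) / 37.5))
                        : 9.12;
  // K2 (slowly inactivating): m h
  xinf[5] = 1.0 / (1.0 + std::exp((-v - 10.0) / 17.0));
  tau[5]  = 4.95 + 0.5 / (std::exp((v - 81.0) / 25.6) + std::exp((-v - 132.0) / 18.0));
  xinf[6] = 1.0 / (1.0 + std::exp((v + 58.0) / 10.6));
  tau[6]  = 60.0 + 0.5 / (std::exp((v - 1.33) / 200.0) + std::exp((-v - 130.0) / 7.1));
  // AR (anomalous rectifier, hyperpolarization-activated): m
  xinf[7] = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
  tau[7]  = 1.0 / (std::exp(-14.59 - 0.086 * v) + std::exp(-1.87 + 0.0701 * v));
  // CaT (low-threshold transient): m^2 h
  xinf[8] = 1.0 / (1.0 + std::exp((-v - 52.0) / 7.4));
  tau[8]  = 1.0 + 0.33 / (std::exp((v + 27.0) / 10.0) + std::exp((-v - 102.0) / 15.0));
  xinf[9] = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
  tau[9]  = 28.3 + 0.33 / (std::exp((v + 48.0) / 4.0) + std::exp((-v - 407.0) / 50.0));
}

// Evaluate steady-state activation and time constant of every gate at each v.
// Returns a list of two length(v) x 10 matrices (x_inf, tau_ms).
// [[Rcpp::export]]
List gate_kinetics_cpp(NumericVector v) {
  int nv = v.size();
  NumericMatrix xinf(nv, NGATE), tau(nv, NGATE);
  double xi[NGATE], ta[NGATE];
  for (int i = 0; i < nv; ++i) {
    gate_rates(v[i], xi, ta);
    for (int k = 0; k < NGATE; ++k) { xinf(i, k) = xi[k]; tau(i, k) = ta[k]; }
  }
  return List::create(_["x_inf"] = xinf, _["tau"] = tau);
}

struct ChemSyn {
  int comp;        // 0-based target compartment
  int mode;        // 0 = current injection, 1 = conductance
  double e_syn, tau_rise, tau_fall, norm;
  std::vector<double> times, amps;
  double waveform(double t) const {
    double w = 0.0;
    double cutoff = 40.0 * tau_fall;
    for (size_t k = 0; k < times.size(); ++k) {
      double dtk = t - times[k];
      if (dtk < 0.0) break;           // times strictly increasing
      if (dtk > cutoff) continue;
      w += amps[k] * (std::exp(-dtk / tau_fall) - std::exp(-dtk / tau_rise));
    }
    return w / norm;
  }
};

struct Engine {
  int n;
  const double *cm, *gleak, *eleak;
  const double *gmax, *erev;      // NCHAN x n, column-major per compartment
  const double *ie;  int n_ie;    // internal edges: (i, j, g) 0-based rows
  const double *ge;  int n_ge;    // gj edges directed: (target, source, g)
  const double *pu;  int n_pu;    // pulses: (comp, onset, end, amp)
  std::vector<ChemSyn> chem;
  std::vector<char> active;       // any channel present in compartment

  // y layout: [V_0..V_{n-1}, gates comp 0 (10), gates comp 1 (10), ...]
  void rhs(double t, const double* y, double* dy, double* iext) const {
    for (int i = 0; i < n; ++i) iext[i] = 0.0;
    for (int p = 0; p < n_pu; ++p) {
      const double* row = pu + 4 * p;
      if (t >= row[1] && t < row[2]) iext[(int)row[0]] += row[3];
    }
    for (size_t s = 0; s < chem.size(); ++s) {
      double w = chem[s].waveform(t);
      if (w != 0.0) {
        if (chem[s].mode == 0) iext[chem[s].comp] += w;
        else iext[chem[s].comp] += w * (chem[s].e_syn - y[chem[s].comp]);
      }
    }
    for (int e = 0; e < n_ie; ++e) {
      const double* row = ie + 3 * e;
      int i = (int)row[0], j = (int)row[1];
      iext[i] += row[2] * (y[j] - y[i]);
      iext[j] += row[2] * (y[i] - y[j]);
    }
    for (int e = 0; e < n_ge; ++e) {
      const double* row = ge + 3 * e;
      int tgt = (int)row[0], src = (int)row[1];
      iext[tgt] += row[2] * (y[src] - y[tgt]);
    }
    double xi[NGATE], ta[NGATE];
    for (int i = 0; i < n; ++i) {
      double v = y[i];
      double cur = gleak[i] * (eleak[i] - v) + iext[i];
      const double* gm = gmax + NCHAN * i;
      const double* er = erev + NCHAN * i;
      const double* g = y + n + NGATE * i;
      double* dg = dy + n + NGATE * i;
      if (active[i]) {
        gate_rates(v, xi, ta);
        for (int k = 0; k < NGATE; ++k) dg[k] = 0.0;
        if (gm[0] > 0.0) { // NaT m^3 h
          cur += gm[0] * g[0] * g[0] * g[0] * g[1] * (er[0] - v);
          dg[0] = (xi[0] - g[0]) / ta[0];
          dg[1] = (xi[1] - g[1]) / ta[1];
        }
        if (gm[1] > 0.0) { // Kd m^4
          double m2 = g[2] * g[2];
          cur += gm[1] * m2 * m2 * (er[1] - v);
          dg[2] = (xi[2] - g[2]) / ta[2];
        }
        if (gm[2] > 0.0) { // Kt m^4 h
          double m2 = g[3] * g[3];
          cur += gm[2] * m2 * m2 * g[4] * (er[2] - v);
          dg[3] = (xi[3] - g[3]) / ta[3];
          dg[4] = (xi[4] - g[4]) / ta[4];
        }
        if (gm[3] > 0.0) { // K2 m h
          cur += gm[3] * g[5] * g[6] * (er[3] - v);
          dg[5] = (xi[5] - g[5]) / ta[5];
          dg[6] = (xi[6] - g[6]) / ta[6];
        }
        if (gm[4] > 0.0) { // AR m
          cur += gm[4] * g[7] * (er[4] - v);
          dg[7] = (xi[7] - g[7]) / ta[7];
        }
        if (gm[5] > 0.0) { // CaT m^2 h
          cur += gm[5] * g[8] * g[8] * g[9] * (er[5] - v);
          dg[8] = (xi[8] - g[8]) / ta[8];
          dg[9] = (xi[9] - g[9]) / ta[9];
        }
      } else {
        for (int k = 0; k < NGATE; ++k) dg[k] = 0.0;
      }
      dy[i] = cur / cm[i];
    }
  }
};

// [[Rcpp::export]]
List sim_core(NumericVector cm, NumericVector gleak, NumericVector eleak,
              NumericMatrix gmax, NumericMatrix erev,
              NumericMatrix internal_edges, NumericMatrix gj_edges,
              NumericMatrix pulses, List chem,
              double dt, double duration, double settle,
              bool record_gates, double v_abort) {
  int n = cm.size();
  if (gmax.nrow() != NCHAN || gmax.ncol() != n)
    stop("gmax must be a 6 x n_compartment matrix");

  Engine eng;
  eng.n = n;
  eng.cm = REAL(cm); eng.gleak = REAL(gleak); eng.eleak = REAL(eleak);
  eng.gmax = REAL(gmax); eng.erev = REAL(erev);

  // copy edge tables into row-major contiguous buffers
  std::vector<double> iebuf(internal_edges.nrow() * 3);
  for (int r = 0; r < internal_edges.nrow(); ++r)
    for (int c = 0; c < 3; ++c) iebuf[3 * r + c] = internal_edges(r, c);
  std::vector<double> gebuf(gj_edges.nrow() * 3);
  for (int r = 0; r < gj_edges.nrow(); ++r)
    for (int c = 0; c < 3; ++c) gebuf[3 * r + c] = gj_edges(r, c);
  std::vector<double> pubuf(pulses.nrow() * 4);
  for (int r = 0; r < pulses.nrow(); ++r)
    for (int c = 0; c < 4; ++c) pubuf[4 * r + c] = pulses(r, c);
  eng.ie = iebuf.data(); eng.n_ie = internal_edges.nrow();
  eng.ge = gebuf.data(); eng.n_ge = gj_edges.nrow();
  eng.pu = pubuf.data(); eng.n_pu = pulses.nrow();

  for (int s = 0; s < chem.size(); ++s) {
    List cs = chem[s];
    ChemSyn c;
    c.comp = as<int>(cs["comp"]);
    c.mode = as<int>(cs["mode"]);
    c.e_syn = as<double>(cs["e_syn"]);
    c.tau_rise = as<double>(cs["tau_rise"]);
    c.tau_fall = as<double>(cs["tau_fall"]);
    c.norm = as<double>(cs["norm"]);
    c.times = as<std::vector<double> >(cs["times"]);
    c.amps = as<std::vector<double> >(cs["amps"]);
    eng.chem.push_back(c);
  }

  eng.active.resize(n);
  for (int i = 0; i < n; ++i) {
    bool a = false;
    for (int k = 0; k < NCHAN; ++k) if (gmax(k, i) > 0.0) a = true;
    eng.active[i] = a;
  }

  int nstate = n * (1 + NGATE);
  std::vector<double> y(nstate), k1(nstate), k2(nstate), ymid(nstate), iext(n);

  // initial condition: leak reversal, gates at their steady state there
  double xi[NGATE], ta[NGATE];
  for (int i = 0; i < n; ++i) {
    y[i] = eleak[i];
    gate_rates(eleak[i], xi, ta);
    for (int k = 0; k < NGATE; ++k) y[n + NGATE * i + k] = xi[k];
  }

  int settle_steps = (int)std::lround(settle / dt);
  int n_steps = (int)std::lround(duration / dt);
  NumericMatrix vm(n_steps + 1, n);
  NumericMatrix gm_out;
  if (record_gates) gm_out = NumericMatrix(n_steps + 1, n * NGATE);

  for (int s = 0; s <= settle_steps + n_steps; ++s) {
    double t = (s - settle_steps) * dt;
    if (s >= settle_steps) {
      int row = s - settle_steps;
      for (int i = 0; i < n; ++i) vm(row, i) = y[i];
      if (record_gates)
        for (int k = 0; k < n * NGATE; ++k) gm_out(row, k) = y[n + k];
      if (row == n_steps) break;
    }
    eng.rhs(t, y.data(), k1.data(), iext.data());
    for (int k = 0; k < nstate; ++k) ymid[k] = y[k] + 0.5 * dt * k1[k];
    eng.rhs(t + 0.5 * dt, ymid.data(), k2.data(), iext.data());
    for (int k = 0; k < nstate; ++k) y[k] += dt * k2[k];
    // gating variables are confined to [0,1]
    for (int k = n; k < nstate; ++k) {
      if (y[k] < 0.0) y[k] = 0.0;
      else if (y[k] > 1.0) y[k] = 1.0;
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(y[i]) || std::fabs(y[i]) > v_abort)
        stop("numerical blow-up: |V| exceeded %.0f mV in compartment %d at t = %.3f ms",
             v_abort, i + 1, t + dt);
    }
  }

  List out = List::create(_["vm"] = vm);
  if (record_gates) out["gates"] = gm_out;
  return out;
}
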