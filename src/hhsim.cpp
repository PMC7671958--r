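// Fixed-step RK4 integrator for small conductance-based networks with
// pulsatile external drives. State layout: per compartment
// [V, mK, hNa, mAR, mKM, mCaH], then one s per chemical synapse, then one
// V_ext per drive. Pulse resets (V_ext -> 25 mV) are applied at exact pulse
// times by splitting integration steps at those times.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int NPC = 6; // state variables per compartment

// column indices into the compartment parameter matrix
enum {
  P_C, P_J, P_GL, P_VL, P_GNA, P_VNA, P_GK, P_VK, P_GAR, P_VAR,
  P_GKM, P_VKM, P_GCAH, P_VCAH,
  P_NAF_M_V12, P_NAF_M_K,
  P_NAF_H_V12, P_NAF_H_K, P_NAF_H_T0, P_NAF_H_T1, P_NAF_H_TV, P_NAF_H_TK,
  P_KDR_V12, P_KDR_K, P_KDR_T0, P_KDR_T1, P_KDR_TV,
  P_AR_V12, P_AR_K, P_AR_TSC,
  P_KM_SC,
  P_CAH_V12, P_CAH_K, P_CAH_TAU,
  NPARAM
};

struct Net {
  int n_comp, n_syn, n_gap, n_drv;
  const double* cp;   // n_comp x NPARAM, column-major from R
  int nrow;
  std::vector<int> syn_kind, syn_src, syn_tgt;
  std::vector<double> syn_g, syn_v0, syn_td, syn_tr;
  std::vector<int> gap_i, gap_j;
  std::vector<double> gap_g;
  double p(int comp, int col) const { return cp[col * nrow + comp]; }
};

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void rhs(const Net& net, const double* y, double* dy) {
  const int nc = net.n_comp;
  const int syn0 = nc * NPC;
  const int drv0 = syn0 + net.n_syn;

  // synaptic and gap currents accumulated per compartment
  std::vector<double> Isyn(nc, 0.0), Iel(nc, 0.0);
  for (int j = 0; j < net.n_syn; ++j) {
    double vt = y[net.syn_tgt[j] * NPC];
    Isyn[net.syn_tgt[j]] += y[syn0 + j] * net.syn_g[j] * (vt - net.syn_v0[j]);
  }
  for (int g = 0; g < net.n_gap; ++g) {
    double vi = y[net.gap_i[g] * NPC], vj = y[net.gap_j[g] * NPC];
    Iel[net.gap_i[g]] += net.gap_g[g] * (vi - vj);
    Iel[net.gap_j[g]] += net.gap_g[g] * (vj - vi);
  }

  for (int i = 0; i < nc; ++i) {
    const double V = y[i * NPC];
    const double mK = y[i * NPC + 1], hNa = y[i * NPC + 2];
    const double mAR = y[i * NPC + 3], mKM = y[i * NPC + 4],
                 mCaH = y[i * NPC + 5];
    double I = net.p(i, P_J) + Isyn[i] + Iel[i];
    I += net.p(i, P_GL) * (V - net.p(i, P_VL));
    const double gNa = net.p(i, P_GNA);
    if (gNa > 0) {
      double m0 = sigm((V - net.p(i, P_NAF_M_V12)) / net.p(i, P_NAF_M_K));
      I += gNa * m0 * m0 * m0 * hNa * (V - net.p(i, P_VNA));
      double hinf = sigm(-(V - net.p(i, P_NAF_H_V12)) / net.p(i, P_NAF_H_K));
      double tauh = net.p(i, P_NAF_H_T0) +
        net.p(i, P_NAF_H_T1) *
          sigm(-(V - net.p(i, P_NAF_H_TV)) / net.p(i, P_NAF_H_TK));
      dy[i * NPC + 2] = (hinf - hNa) / tauh;
    } else dy[i * NPC + 2] = 0.0;
    const double gK = net.p(i, P_GK);
    if (gK > 0) {
      I += gK * mK * mK * mK * mK * (V - net.p(i, P_VK));
      double minf = sigm((V - net.p(i, P_KDR_V12)) / net.p(i, P_KDR_K));
      double taum = net.p(i, P_KDR_T0) +
        net.p(i, P_KDR_T1) * std::exp(-std::fabs(V - net.p(i, P_KDR_TV)) / 10.0);
      dy[i * NPC + 1] = (minf - mK) / taum;
    } else dy[i * NPC + 1] = 0.0;
    const double gAR = net.p(i, P_GAR);
    if (gAR > 0) {
      I += gAR * mAR * (V - net.p(i, P_VAR));
      double minf = sigm(-(V - net.p(i, P_AR_V12)) / net.p(i, P_AR_K));
      double tau = net.p(i, P_AR_TSC) /
        (std::exp(-14.59 - 0.086 * V) + std::exp(-1.87 + 0.0701 * V));
      dy[i * NPC + 3] = (minf - mAR) / tau;
    } else dy[i * NPC + 3] = 0.0;
    const double gKM = net.p(i, P_GKM);
    if (gKM > 0) {
      I += gKM * mKM * (V - net.p(i, P_VKM));
      double a = net.p(i, P_KM_SC) * 0.02 / (1.0 + std::exp((-20.0 - V) / 5.0));
      double b = net.p(i, P_KM_SC) * 0.01 * std::exp((-43.0 - V) / 18.0);
      dy[i * NPC + 4] = a * (1.0 - mKM) - b * mKM;
    } else dy[i * NPC + 4] = 0.0;
    const double gCaH = net.p(i, P_GCAH);
    if (gCaH > 0) {
      I += gCaH * mCaH * mCaH * (V - net.p(i, P_VCAH));
      double minf = sigm((V - net.p(i, P_CAH_V12)) / net.p(i, P_CAH_K));
      dy[i * NPC + 5] = (minf - mCaH) / net.p(i, P_CAH_TAU);
    } else dy[i * NPC + 5] = 0.0;
    dy[i * NPC] = -I / net.p(i, P_C);
  }

  // synapse states: presynaptic potential is a compartment V or a drive V_ext
  for (int j = 0; j < net.n_syn; ++j) {
    double vpre = (net.syn_kind[j] == 0)
      ? y[net.syn_src[j] * NPC] : y[drv0 + net.syn_src[j]];
    double s = y[syn0 + j];
    dy[syn0 + j] = -s / net.syn_td[j] +
      (1.0 - s) / net.syn_tr[j] * (1.0 + std::tanh(vpre / 10.0));
  }
  // external potentials decay toward -70 mV with unit time constant
  for (int d = 0; d < net.n_drv; ++d)
    dy[drv0 + d] = -70.0 - y[drv0 + d];
}

static Net make_net(const NumericMatrix& comp, const NumericMatrix& syn,
                    const NumericMatrix& gap, int n_drv) {
  Net net;
  net.n_comp = comp.nrow();
  net.nrow = comp.nrow();
  net.cp = comp.begin();
  net.n_syn = syn.nrow();
  net.n_gap = gap.nrow();
  net.n_drv = n_drv;
  for (int j = 0; j < net.n_syn; ++j) {
    net.syn_kind.push_back((int)syn(j, 0));
    net.syn_src.push_back((int)syn(j, 1));
    net.syn_tgt.push_back((int)syn(j, 2));
    net.syn_g.push_back(syn(j, 3));
    net.syn_v0.push_back(syn(j, 4));
    net.syn_td.push_back(syn(j, 5));
    net.syn_tr.push_back(syn(j, 6));
  }
  for (int g = 0; g < net.n_gap; ++g) {
    net.gap_i.push_back((int)gap(g, 0));
    net.gap_j.push_back((int)gap(g, 1));
    net.gap_g.push_back(gap(g, 2));
  }
  return net;
}

static void rk4_step(const Net& net, std::vector<double>& y, double h,
                     std::vector<double>& k1, std::vector<double>& k2,
                     std::vector<double>& k3, std::vector<double>& k4,
                     std::vector<double>& tmp) {
  const int n = (int)y.size();
  rhs(net, y.data(), k1.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
  rhs(net, tmp.data(), k2.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
  rhs(net, tmp.data(), k3.data());
  for (int i = 0; i < n; ++i) tmp[i] = y[i] + h * k3[i];
  rhs(net, tmp.data(), k4.data());
  for (int i = 0; i < n; ++i)
    y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export(name = ".hh_rhs")]]
NumericVector hh_rhs(NumericVector state, NumericMatrix comp,
                     NumericMatrix syn, NumericMatrix gap, int n_drives) {
  Net net = make_net(comp, syn, gap, n_drives);
  NumericVector dy(state.size());
  rhs(net, state.begin(), dy.begin());
  return dy;
}

// [[Rcpp::export(name = ".hh_simulate")]]
List hh_simulate(NumericMatrix comp, NumericMatrix syn, NumericMatrix gap,
                 List drive_times, NumericVector init, double duration,
                 double dt, int store_every, double spike_threshold,
                 double spike_min_sep) {
  const int n_drv = drive_times.size();
  Net net = make_net(comp, syn, gap, n_drv);
  const int nc = net.n_comp;
  const int nstate = nc * NPC + net.n_syn + n_drv;
  if ((int)init.size() != nstate)
    stop("init state has length %d, expected %d", (int)init.size(), nstate);

  std::vector<double> y(init.begin(), init.end());
  std::vector<double> k1(nstate), k2(nstate), k3(nstate), k4(nstate),
      tmp(nstate);

  // merged, sorted pulse events: (time, drive)
  std::vector<std::pair<double, int>> events;
  for (int d = 0; d < n_drv; ++d) {
    NumericVector tv = drive_times[d];
    for (double t : tv)
      if (t >= 0 && t <= duration) events.push_back({t, d});
  }
  std::sort(events.begin(), events.end());
  const int drv0 = nc * NPC + net.n_syn;

  // apply resets for pulses at exactly t = 0
  size_t ev = 0;
  while (ev < events.size() && events[ev].first <= 0.0)
    y[drv0 + events[ev++].second] = 25.0;

  const long nsteps = (long)std::llround(duration / dt);
  const int n_store = (int)(nsteps / store_every) + 1;
  NumericMatrix traces(n_store, nstate);
  NumericVector tgrid(n_store);
  int is = 0;
  for (int v = 0; v < nstate; ++v) traces(0, v) = y[v];
  tgrid[0] = 0.0;
  is = 1;

  std::vector<std::vector<double>> spikes(nc);
  std::vector<double> last_spike(nc, -1e18), vprev(nc);
  for (int i = 0; i < nc; ++i) vprev[i] = y[i * NPC];

  double fail_time = -1.0;
  for (long k = 0; k < nsteps; ++k) {
    const double t0 = k * dt, t1 = (k + 1) * dt;
    double tcur = t0;
    // split the step at pulse times falling in (t0, t1]
    while (ev < events.size() && events[ev].first <= t1 + 1e-12) {
      double te = events[ev].first;
      if (te > tcur + 1e-12)
        rk4_step(net, y, te - tcur, k1, k2, k3, k4, tmp);
      tcur = te;
      y[drv0 + events[ev].second] = 25.0;
      ++ev;
    }
    if (t1 > tcur + 1e-12)
      rk4_step(net, y, t1 - tcur, k1, k2, k3, k4, tmp);

    // spike detection: upward crossings of the threshold, interpolated
    for (int i = 0; i < nc; ++i) {
      double v = y[i * NPC];
      if (vprev[i] < spike_threshold && v >= spike_threshold &&
          t1 - last_spike[i] >= spike_min_sep) {
        double tc = t0 + dt * (spike_threshold - vprev[i]) / (v - vprev[i]);
        spikes[i].push_back(tc);
        last_spike[i] = tc;
      }
      if (std::fabs(v) > 200.0 && fail_time < 0) fail_time = t1;
      vprev[i] = v;
    }
    if (fail_time >= 0) break;

    if ((k + 1) % store_every == 0 && is < n_store) {
      for (int v = 0; v < nstate; ++v) traces(is, v) = y[v];
      tgrid[is] = t1;
      ++is;
    }
  }

  List spk(nc);
  for (int i = 0; i < nc; ++i) spk[i] = NumericVector(spikes[i].begin(),
                                                      spikes[i].end());
  return List::create(_["time"] = tgrid[Range(0, is - 1)],
                      _["traces"] = traces(Range(0, is - 1), _),
                      _["spikes"] = spk,
                      _["fail_time"] = fail_time);
}
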