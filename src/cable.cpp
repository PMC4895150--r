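// Multi-compartment cable equation under extracellular potential forcing.
// Voltage step: backward Euler on the tree (Hines elimination, O(n));
// gating: exponential Euler at the current voltage. Channel family: fast Na,
// delayed-rectifier K, slow non-inactivating K (muscarinic), high-voltage-
// activated Ca, Ca-dependent K, and leak, with q10 temperature scaling.
// Units: mV, ms, nF, uS, nA; densities S/cm2; areas cm2; [Ca] mM.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double efun(double x) {
  // x / (1 - exp(-x)), stable near 0
  if (std::fabs(x) < 1e-6) return 1.0 + x / 2.0;
  return x / (1.0 - std::exp(-x));
}

struct Rates {
  double minf, taum, hinf, tauh;       // na
  double ninf_kv, taun_kv;
  double ninf_km, taun_km;
  double minf_ca, taum_ca, hinf_ca, tauh_ca;
};

static inline Rates channel_rates(double v, double tadj) {
  Rates r;
  // extreme extracellular forcing (tens of volts at 100 mA) can transiently
  // polarize compartments far outside the physiological range; saturate the
  // rate evaluations to keep the integration finite
  if (v > 150.0) v = 150.0;
  if (v < -250.0) v = -250.0;
  // fast Na (kinetics referenced to 23 C)
  {
    double x = (v + 35.0) / 9.0;
    double am = 0.182 * 9.0 * efun(x);
    double bm = 0.124 * 9.0 * efun(-x);
    r.minf = am / (am + bm);
    r.taum = 1.0 / (tadj * (am + bm));
    double ah = 0.024 * 5.0 * efun((v + 50.0) / 5.0);
    double bh = 0.0091 * 5.0 * efun(-(v + 75.0) / 5.0);
    r.tauh = 1.0 / (tadj * (ah + bh));
    r.hinf = 1.0 / (1.0 + std::exp((v + 65.0) / 6.2));
  }
  // delayed-rectifier K
  {
    double x = (v - 25.0) / 9.0;
    double a = 0.02 * 9.0 * efun(x);
    double b = 0.002 * 9.0 * efun(-x);
    r.ninf_kv = a / (a + b);
    r.taun_kv = 1.0 / (tadj * (a + b));
  }
  // slow non-inactivating K
  {
    double x = (v + 30.0) / 9.0;
    double a = 0.001 * 9.0 * efun(x);
    double b = 0.001 * 9.0 * efun(-x);
    r.ninf_km = a / (a + b);
    r.taun_km = 1.0 / (tadj * (a + b));
  }
  // high-voltage-activated Ca
  {
    double am = 0.055 * 3.8 * efun((v + 27.0) / 3.8);
    double bm = 0.94 * std::exp((-75.0 - v) / 17.0);
    r.minf_ca = am / (am + bm);
    r.taum_ca = 1.0 / (tadj * (am + bm));
    double ah = 0.000457 * std::exp((-13.0 - v) / 50.0);
    double bh = 0.0065 / (std::exp((-v - 15.0) / 28.0) + 1.0);
    r.hinf_ca = ah / (ah + bh);
    r.tauh_ca = 1.0 / (tadj * (ah + bh));
  }
  return r;
}

// [[Rcpp::export(name = ".cable_sim_cpp")]]
List cable_sim_cpp(IntegerVector parent,      // 0-based, -1 for root; sorted
                   NumericVector area,        // cm2
                   NumericVector cm,          // uF/cm2
                   NumericVector g_pas,       // S/cm2
                   NumericVector e_pas,
                   NumericVector gna, NumericVector gkv, NumericVector gkm,
                   NumericVector gca, NumericVector gkca,  // S/cm2
                   NumericVector g_ax,        // uS to parent
                   NumericVector ve,          // mV per unit amplitude
                   double amp, double onset, double width,
                   double dt, double dur, double dt_coarse, double t_switch,
                   double v_init, double celsius, double q10, double temp_base,
                   double ena, double ek, double eca,
                   bool balance, int record_every) {
  const int n = parent.size();
  // two-phase stepping: fine dt through the pulse window, coarse afterwards
  if (t_switch > dur) t_switch = dur;
  const int n1 = (int)std::ceil(t_switch / dt - 1e-9);
  const int n2 = (int)std::ceil((dur - n1 * dt) / dt_coarse - 1e-9);
  const int nsteps = n1 + (n2 > 0 ? n2 : 0);
  const double tadj = std::pow(q10, (celsius - temp_base) / 10.0);
  const double ca_inf = 1e-4, ca_tau = 200.0;
  const double ca_drive = 10000.0 / (2.0 * 96480.0 * 0.1);  // depth 0.1 um

  std::vector<double> v(n, v_init), m(n), h(n), nkv(n), nkm(n),
      mca(n), hca(n), nkca(n), cai(n, ca_inf), epas(n);
  std::vector<double> C(n), d(n), b(n), off(n);
  for (int i = 0; i < n; ++i) {
    C[i] = cm[i] * area[i] * 1e3;  // nF
    Rates r = channel_rates(v_init, tadj);
    m[i] = r.minf; h[i] = r.hinf; nkv[i] = r.ninf_kv; nkm[i] = r.ninf_km;
    mca[i] = r.minf_ca; hca[i] = r.hinf_ca;
    double akca = 0.01 * cai[i], bkca = 0.02;
    nkca[i] = akca / (akca + bkca);
    epas[i] = e_pas[i];
    if (balance && g_pas[i] > 0) {
      double gca_i = gca[i] * mca[i] * mca[i] * hca[i];
      double j = gna[i] * m[i] * m[i] * m[i] * h[i] * (v_init - ena) +
                 (gkv[i] * nkv[i] + gkm[i] * nkm[i] + gkca[i] * nkca[i]) *
                     (v_init - ek) +
                 gca_i * (v_init - eca);
      epas[i] = v_init + j / g_pas[i];
    }
  }

  const int nrec = nsteps / record_every + 1;
  NumericMatrix vout(nrec, n);
  NumericVector tout(nrec);
  for (int i = 0; i < n; ++i) vout(0, i) = v[i];
  tout[0] = 0.0;
  int rec = 1;

  double tcur = 0.0;
  for (int step = 1; step <= nsteps; ++step) {
    const double dtk = (step <= n1) ? dt : dt_coarse;
    const double tnew = tcur + dtk;
    tcur = tnew;
    const double drive = (tnew > onset && tnew <= onset + width) ? amp : 0.0;
    // gating + calcium update (exponential Euler at current v)
    for (int i = 0; i < n; ++i) {
      Rates r = channel_rates(v[i], tadj);
      m[i] = r.minf + (m[i] - r.minf) * std::exp(-dtk / r.taum);
      h[i] = r.hinf + (h[i] - r.hinf) * std::exp(-dtk / r.tauh);
      nkv[i] = r.ninf_kv + (nkv[i] - r.ninf_kv) * std::exp(-dtk / r.taun_kv);
      nkm[i] = r.ninf_km + (nkm[i] - r.ninf_km) * std::exp(-dtk / r.taun_km);
      mca[i] = r.minf_ca + (mca[i] - r.minf_ca) * std::exp(-dtk / r.taum_ca);
      hca[i] = r.hinf_ca + (hca[i] - r.hinf_ca) * std::exp(-dtk / r.tauh_ca);
      if (gca[i] > 0 || gkca[i] > 0) {
        double ica = gca[i] * mca[i] * mca[i] * hca[i] * (v[i] - eca); // mA/cm2
        double A = -ca_drive * ica + ca_inf / ca_tau;
        double target = A * ca_tau;
        cai[i] = target + (cai[i] - target) * std::exp(-dtk / ca_tau);
        if (cai[i] < 1e-9) cai[i] = 1e-9;
        double akca = 0.01 * cai[i] * tadj, bkca = 0.02 * tadj;
        double ninf = akca / (akca + bkca), tau = 1.0 / (akca + bkca);
        nkca[i] = ninf + (nkca[i] - ninf) * std::exp(-dtk / tau);
      }
    }
    // assemble backward-Euler system on the tree
    for (int i = 0; i < n; ++i) {
      const double a6 = area[i] * 1e6;  // cm2 -> uS scaling for S/cm2
      const double gNa = gna[i] * m[i] * m[i] * m[i] * h[i] * a6;
      const double gKv = gkv[i] * nkv[i] * a6;
      const double gKm = gkm[i] * nkm[i] * a6;
      const double gKca = gkca[i] * nkca[i] * a6;
      const double gCa = gca[i] * mca[i] * mca[i] * hca[i] * a6;
      const double gL = g_pas[i] * a6;
      d[i] = C[i] / dtk + gNa + gKv + gKm + gKca + gCa + gL;
      b[i] = C[i] / dtk * v[i] + gNa * ena + (gKv + gKm + gKca) * ek +
             gCa * eca + gL * epas[i];
    }
    for (int i = 0; i < n; ++i) {
      int p = parent[i];
      if (p >= 0) {
        d[i] += g_ax[i];
        d[p] += g_ax[i];
        off[i] = -g_ax[i];
        double df = drive * (ve[p] - ve[i]) * g_ax[i];
        b[i] += df;
        b[p] -= df;
      }
    }
    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double f = off[i] / d[i];
      d[p] -= f * off[i];
      b[p] -= f * b[i];
    }
    v[0] = b[0] / d[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      v[i] = (b[i] - off[i] * v[p]) / d[i];
      if (!std::isfinite(v[i]))
        stop("integration error: divergence at t = %f ms (dt = %f ms)", tnew, dt);
    }
    if (step % record_every == 0 && rec < nrec) {
      for (int i = 0; i < n; ++i) vout(rec, i) = v[i];
      tout[rec] = tnew;
      ++rec;
    }
  }
  return List::create(_["v"] = vout, _["t"] = tout);
}
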