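// Hybrid stochastic-deterministic simulator for the GAL network.
//
// Stochastic layer: 17 Gillespie reaction channels (6 synthesis bursts, 11
// first-order degradations) over the 11 protein species.  Deterministic
// layer: algebraic galactose transport plus the five fast reversible
// signal-transduction reactions solved to steady state (a single scalar
// root in the free Gal80p amount, since the reaction graph is a tree).
// The deterministic step may be executed only every n-th iteration, with n
// proportional to the number of molecules it involves.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Species indices (order matches GAL_SPECIES on the R side)
enum Species { GAL1P, GAL2P, GAL3PI, GAL3PA, GAL4P, GAL80P,
               GAL13PI, GAL13PA, GAL380P, GAL1380P, GAL480P, NSPECIES };

// Gene order matches GAL_GENES; product[g] is the synthesized species.
static const int PRODUCT[6] = { GAL1P, GAL2P, GAL3PI, GAL4P, GAL80P, GAL13PI };

struct EqConst {
  double K3, K13, K380, K1380, K480;  // forward/reverse rate ratios
};

// Solve the repressor balance r + bound80(r) = T80 by safeguarded Newton.
static double solve_free80(double T3, double T13, double T80, double T4,
                           double A3, double A13, const EqConst &kc,
                           double r0) {
  if (T80 <= 0.0) return 0.0;
  double lo = 0.0, hi = T80;
  double r = (r0 > 0.0 && r0 < T80) ? r0 : 0.5 * T80;
  for (int it = 0; it < 200; ++it) {
    double d3 = 1.0 + A3 + A3 * kc.K380 * r;
    double d13 = 1.0 + A13 + A13 * kc.K1380 * r;
    double d4 = 1.0 + kc.K480 * r;
    double b3 = T3 * A3 * kc.K380 * r / d3;
    double b13 = T13 * A13 * kc.K1380 * r / d13;
    double b4 = T4 * kc.K480 * r / d4;
    double g = r + b3 + b13 + b4 - T80;
    if (std::fabs(g) < 1e-12 * (T80 + 1.0)) return r;
    if (g > 0.0) hi = r; else lo = r;
    double gp = 1.0
      + T3 * A3 * kc.K380 * (1.0 + A3) / (d3 * d3)
      + T13 * A13 * kc.K1380 * (1.0 + A13) / (d13 * d13)
      + T4 * kc.K480 / (d4 * d4);
    double step = g / gp;
    double rn = r - step;
    if (!(rn > lo && rn < hi)) rn = 0.5 * (lo + hi);  // bisection safeguard
    double tol = 1e-13 * (T80 > 1.0 ? T80 : 1.0);
    if (std::fabs(rn - r) < tol) { r = rn; break; }
    r = rn;
  }
  return r;
}

// Equilibrate the signaling species in place; returns free Gal80p (warm
// start for the next call).
static double equilibrate_pool(double *x, double gal_in, const EqConst &kc,
                               double r0) {
  double T3 = x[GAL3PI] + x[GAL3PA] + x[GAL380P];
  double T13 = x[GAL13PI] + x[GAL13PA] + x[GAL1380P];
  double T80 = x[GAL80P] + x[GAL380P] + x[GAL1380P] + x[GAL480P];
  double T4 = x[GAL4P] + x[GAL480P];
  double A3 = kc.K3 * gal_in, A13 = kc.K13 * gal_in;
  double r = solve_free80(T3, T13, T80, T4, A3, A13, kc, r0);
  double d3 = 1.0 + A3 + A3 * kc.K380 * r;
  double d13 = 1.0 + A13 + A13 * kc.K1380 * r;
  double x3i = T3 / d3, x13i = T13 / d13;
  double c480 = T4 * kc.K480 * r / (1.0 + kc.K480 * r);
  x[GAL3PI] = x3i;
  x[GAL3PA] = A3 * x3i;
  x[GAL380P] = T3 - x3i - A3 * x3i;
  x[GAL13PI] = x13i;
  x[GAL13PA] = A13 * x13i;
  x[GAL1380P] = T13 - x13i - A13 * x13i;
  x[GAL80P] = r;
  x[GAL480P] = c480;
  x[GAL4P] = T4 - c480;
  if (x[GAL380P] < 0.0) x[GAL380P] = 0.0;
  if (x[GAL1380P] < 0.0) x[GAL1380P] = 0.0;
  return r;
}

struct PromoterTab {
  std::vector<int> n4, n480;
  std::vector<double> boltz, K;
};

// Occupancy-weighted transcription propensity; exponents are at most the
// number of UAS (<= 3), so powers are looked up from small tables.
static double promoter_f(const PromoterTab &p, double x4, double x480) {
  double p4[4] = {1.0, x4, x4 * x4, x4 * x4 * x4};
  double p80[4] = {1.0, x480, x480 * x480, x480 * x480 * x480};
  double num = 0.0, den = 0.0;
  for (size_t c = 0; c < p.K.size(); ++c) {
    double w = p4[p.n4[c]] * p80[p.n480[c]] * p.boltz[c];
    num += p.K[c] * w;
    den += w;
  }
  double f = num / den;
  return f > 0.0 ? f : 0.0;
}

// [[Rcpp::export]]
double cpp_promoter_f(NumericMatrix m, double x4, double x480) {
  PromoterTab p;
  int ns = m.nrow();
  p.n4.resize(ns); p.n480.resize(ns); p.boltz.resize(ns); p.K.resize(ns);
  for (int i = 0; i < ns; ++i) {
    p.n4[i] = (int)m(i, 0); p.n480[i] = (int)m(i, 1);
    p.boltz[i] = m(i, 2); p.K[i] = m(i, 3);
  }
  return promoter_f(p, x4, x480);
}

// [[Rcpp::export]]
NumericVector cpp_equilibrate(NumericVector pool, double gal_in,
                              NumericVector kratios) {
  EqConst kc = { kratios[0], kratios[1], kratios[2], kratios[3], kratios[4] };
  NumericVector out = clone(pool);
  equilibrate_pool(REAL(out), gal_in, kc, -1.0);
  return out;
}

// [[Rcpp::export]]
List cpp_run_simulation(NumericVector init, NumericVector copies,
                        double gal_out, List promoter_tabs,
                        NumericVector kratios, double transport_a,
                        double transport_b, double burst, double gamma,
                        double t_end, double det_skip_scale,
                        double synthesis_scale, double conc_factor,
                        bool fractional_burst, int n_sample) {
  EqConst kc = { kratios[0], kratios[1], kratios[2], kratios[3], kratios[4] };
  std::vector<PromoterTab> prom(6);
  for (int g = 0; g < 6; ++g) {
    NumericMatrix m = promoter_tabs[g];
    PromoterTab &p = prom[g];
    int ns = m.nrow();
    p.n4.resize(ns); p.n480.resize(ns); p.boltz.resize(ns); p.K.resize(ns);
    for (int i = 0; i < ns; ++i) {
      p.n4[i] = (int)m(i, 0);
      p.n480[i] = (int)m(i, 1);
      p.boltz[i] = m(i, 2);
      p.K[i] = m(i, 3);
    }
  }

  double x[NSPECIES];
  for (int i = 0; i < NSPECIES; ++i) x[i] = init[i];

  NumericMatrix traj;
  NumericVector traj_t;
  int isample = 0;
  double dt_sample = 0.0;
  if (n_sample > 0) {
    traj = NumericMatrix(n_sample, NSPECIES);
    traj_t = NumericVector(n_sample);
    dt_sample = t_end / n_sample;
  }

  double t = 0.0;
  long n_events = 0, n_equil = 0;
  std::vector<double> syn_count(6, 0.0), deg_count(NSPECIES, 0.0);
  double syn[6];
  double r_warm = -1.0;
  long until_det = 0, skip_n = 1;

  if (t_end > 0.0) {
    while (t < t_end) {
      if (until_det <= 0) {
        double gal_in = gal_out * (transport_a + transport_b * x[GAL2P]);
        r_warm = equilibrate_pool(x, gal_in, kc, r_warm);
        ++n_equil;
        double x4 = x[GAL4P] * conc_factor;
        double x480 = x[GAL480P] * conc_factor;
        for (int g = 0; g < 6; ++g)
          syn[g] = copies[g] > 0.0
            ? copies[g] * synthesis_scale * promoter_f(prom[g], x4, x480)
            : 0.0;
        double det_mol = 0.0;
        for (int i = GAL3PI; i < NSPECIES; ++i) det_mol += x[i];
        skip_n = (long)(det_mol / det_skip_scale);
        if (skip_n < 1) skip_n = 1;
        until_det = skip_n;
      }
      double syn_tot = 0.0;
      for (int g = 0; g < 6; ++g) syn_tot += syn[g];
      double mol_tot = 0.0;
      for (int i = 0; i < NSPECIES; ++i) mol_tot += x[i];
      double deg_tot = gamma * mol_tot;
      double a0 = syn_tot + deg_tot;
      if (a0 <= 0.0) break;  // quiescent: no channel can fire

      double tau = R::exp_rand() / a0;
      if (t + tau >= t_end) { t = t_end; break; }
      t += tau;

      // record any sample points passed
      while (n_sample > 0 && isample < n_sample &&
             t >= (isample + 1) * dt_sample) {
        traj_t[isample] = (isample + 1) * dt_sample;
        for (int i = 0; i < NSPECIES; ++i) traj(isample, i) = x[i];
        ++isample;
      }

      double u = R::unif_rand() * a0;
      if (u < syn_tot) {
        int g = 0;
        double acc = syn[0];
        while (u > acc && g < 5) acc += syn[++g];
        double nb = fractional_burst
          ? burst
          : std::floor(burst) + ((R::unif_rand() < burst - std::floor(burst)) ? 1.0 : 0.0);
        x[PRODUCT[g]] += nb;
        syn_count[g] += nb;
      } else {
        double v = u - syn_tot;
        int i = 0;
        double acc = gamma * x[0];
        while (v > acc && i < NSPECIES - 1) acc += gamma * x[++i];
        x[i] -= 1.0;
        if (x[i] < 0.0) x[i] = 0.0;
        deg_count[i] += 1.0;
      }
      ++n_events;
      --until_det;
    }
    // endpoint: re-equilibrate so the reported state is consistent with the
    // (instantaneous) deterministic layer
    double gal_in = gal_out * (transport_a + transport_b * x[GAL2P]);
    r_warm = equilibrate_pool(x, gal_in, kc, r_warm);
    ++n_equil;
  }

  while (n_sample > 0 && isample < n_sample) {
    traj_t[isample] = (isample + 1) * dt_sample;
    for (int i = 0; i < NSPECIES; ++i) traj(isample, i) = x[i];
    ++isample;
  }

  NumericVector endpoint(NSPECIES);
  for (int i = 0; i < NSPECIES; ++i) endpoint[i] = x[i];

  List out = List::create(
    _["endpoint"] = endpoint,
    _["time"] = t_end > 0.0 ? t_end : 0.0,
    _["n_events"] = (double)n_events,
    _["n_equilibrations"] = (double)n_equil,
    _["syn_molecules"] = NumericVector(syn_count.begin(), syn_count.end()),
    _["deg_events"] = NumericVector(deg_count.begin(), deg_count.end()));
  if (n_sample > 0) {
    out["traj_time"] = traj_t;
    out["traj"] = traj;
  }
  return out;
}
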