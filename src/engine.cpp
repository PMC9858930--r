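// Fixed-step stochastic integration engine for the local-control myocyte
// model: explicit Euler for the continuous variables, frozen-rate
// binomial/multinomial sampling for the Markov channel clusters.  Mirrors
// the R-level operations in R/currents.R and R/gating.R; the R functions
// are the documented reference, this is the production path.
//
// Units: ms, mV, uM (Na/K mM), uA/uF, litres.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Pars {
  // geometry
  double v_myo, v_nsr, v_jsr_unit, v_ds_unit;
  int n_cru, n_cru_full, n_ryr, n_lcc;
  // buffers
  double casq_btot, casq_kd, trpn_btot, trpn_kd, cmdn_btot, cmdn_kd,
      ds_btot, ds_kd;
  // channels
  double p_dhpr, phi_m, phi_b;
  double ryr_k_open_max, ryr_hill, ryr_k_ca, ryr_k_close, ryr_k_adapt,
      ryr_k_recover;
  double lcc_act_max, lcc_v_act, lcc_k_act, lcc_deact_max, lcc_v_deact,
      lcc_k_deact, lcc_f_oo, lcc_g_oo, lcc_ca_slope, lcc_ca_max, lcc_ca_recover,
      lcc_vi_max, lcc_vi_vhalf, lcc_vi_k, lcc_vi_recover, lcc_c6_max,
      lcc_c6_vhalf, lcc_c6_k, lcc_c6_recover;
  // pumps
  double serca_ap, serca_vmax, serca_km, serca_hill, serca_k_nsr, serca_hill_nsr;
  double ncx_k, ncx_km_na, ncx_km_ca, ncx_eta, ncx_ksat;
  double nak_imax, nak_km_nai, nak_km_ko;
  double g_cab, g_nab, g_leak;
  // membrane
  double cm, acap, g_na, g_k, g_k1, g_kp, x_rate_scale, x_beta_scale, pr_nak;
  // transport
  double g_rel, g_xfer, g_tr;
  // milieu
  double ca_o, na_o, k_o;  // mM
  double faraday, r_gas, temperature;
};

double num(const List& l, const char* a, const char* b) {
  List sub = l[a];
  return as<double>(sub[b]);
}
double num(const List& l, const char* a, const char* b, const char* c) {
  List s1 = l[a];
  List s2 = s1[b];
  return as<double>(s2[c]);
}

Pars read_pars(const List& p) {
  Pars q;
  q.v_myo = num(p, "geometry", "v_myo");
  q.v_nsr = num(p, "geometry", "v_nsr");
  q.v_jsr_unit = num(p, "geometry", "v_jsr_unit");
  q.v_ds_unit = num(p, "geometry", "v_ds_unit");
  q.n_cru = (int)num(p, "geometry", "n_cru");
  q.n_cru_full = (int)num(p, "geometry", "n_cru_full");
  q.n_ryr = (int)num(p, "geometry", "n_ryr_per_cru");
  q.n_lcc = (int)num(p, "geometry", "n_lcc_per_cru");
  q.casq_btot = num(p, "buffers", "casq", "btot");
  q.casq_kd = num(p, "buffers", "casq", "kd");
  q.trpn_btot = num(p, "buffers", "troponin", "btot");
  q.trpn_kd = num(p, "buffers", "troponin", "kd");
  q.cmdn_btot = num(p, "buffers", "calmodulin", "btot");
  q.cmdn_kd = num(p, "buffers", "calmodulin", "kd");
  q.ds_btot = num(p, "buffers", "subspace", "btot");
  q.ds_kd = num(p, "buffers", "subspace", "kd");
  q.p_dhpr = num(p, "channels", "p_dhpr");
  q.phi_m = num(p, "channels", "phi_m");
  q.phi_b = num(p, "channels", "phi_b");
  q.ryr_k_open_max = num(p, "channels", "ryr2", "k_open_max");
  q.ryr_hill = num(p, "channels", "ryr2", "hill_ca_ds");
  q.ryr_k_ca = num(p, "channels", "ryr2", "k_ca");
  q.ryr_k_close = num(p, "channels", "ryr2", "k_close");
  q.ryr_k_adapt = num(p, "channels", "ryr2", "k_adapt");
  q.ryr_k_recover = num(p, "channels", "ryr2", "k_recover");
  q.lcc_act_max = num(p, "channels", "lcc", "act_max");
  q.lcc_v_act = num(p, "channels", "lcc", "v_act");
  q.lcc_k_act = num(p, "channels", "lcc", "k_act");
  q.lcc_deact_max = num(p, "channels", "lcc", "deact_max");
  q.lcc_v_deact = num(p, "channels", "lcc", "v_deact");
  q.lcc_k_deact = num(p, "channels", "lcc", "k_deact");
  q.lcc_f_oo = num(p, "channels", "lcc", "f_oo");
  q.lcc_g_oo = num(p, "channels", "lcc", "g_oo");
  q.lcc_ca_slope = num(p, "channels", "lcc", "ca_inact_slope");
  q.lcc_ca_max = num(p, "channels", "lcc", "ca_inact_max");
  q.lcc_ca_recover = num(p, "channels", "lcc", "ca_inact_recover");
  q.lcc_vi_max = num(p, "channels", "lcc", "v_inact_max");
  q.lcc_vi_vhalf = num(p, "channels", "lcc", "v_inact_vhalf");
  q.lcc_vi_k = num(p, "channels", "lcc", "v_inact_k");
  q.lcc_vi_recover = num(p, "channels", "lcc", "v_inact_recover");
  q.lcc_c6_max = num(p, "channels", "lcc", "c6_entry_max");
  q.lcc_c6_vhalf = num(p, "channels", "lcc", "c6_vhalf");
  q.lcc_c6_k = num(p, "channels", "lcc", "c6_k");
  q.lcc_c6_recover = num(p, "channels", "lcc", "c6_recover");
  q.serca_ap = num(p, "pumps", "serca", "ap");
  q.serca_vmax = num(p, "pumps", "serca", "vcycle_max");
  q.serca_km = num(p, "pumps", "serca", "km_fwd");
  q.serca_hill = num(p, "pumps", "serca", "hill");
  q.serca_k_nsr = num(p, "pumps", "serca", "k_nsr");
  q.serca_hill_nsr = num(p, "pumps", "serca", "hill_nsr");
  q.ncx_k = num(p, "pumps", "ncx", "k_ncx");
  q.ncx_km_na = num(p, "pumps", "ncx", "km_na");
  q.ncx_km_ca = num(p, "pumps", "ncx", "km_ca");
  q.ncx_eta = num(p, "pumps", "ncx", "eta");
  q.ncx_ksat = num(p, "pumps", "ncx", "ksat");
  q.nak_imax = num(p, "pumps", "nak", "i_max");
  q.nak_km_nai = num(p, "pumps", "nak", "km_nai");
  q.nak_km_ko = num(p, "pumps", "nak", "km_ko");
  q.g_cab = num(p, "pumps", "background", "g_cab");
  q.g_nab = num(p, "pumps", "background", "g_nab");
  {
    List pumps = p["pumps"];
    q.g_leak = as<double>(pumps["g_leak"]);
  }
  q.cm = num(p, "membrane", "cm");
  q.acap = num(p, "membrane", "acap");
  q.g_na = num(p, "membrane", "g_na");
  q.g_k = num(p, "membrane", "g_k");
  q.g_k1 = num(p, "membrane", "g_k1");
  q.g_kp = num(p, "membrane", "g_kp");
  q.x_rate_scale = num(p, "membrane", "x_rate_scale");
  q.x_beta_scale = num(p, "membrane", "x_beta_scale");
  q.pr_nak = num(p, "membrane", "pr_nak");
  q.g_rel = num(p, "transport", "g_rel");
  q.g_xfer = num(p, "transport", "g_xfer");
  q.g_tr = num(p, "transport", "g_tr");
  q.ca_o = num(p, "extracellular", "ca_o");
  q.na_o = num(p, "extracellular", "na_o");
  q.k_o = num(p, "extracellular", "k_o");
  q.faraday = num(p, "physical", "faraday");
  q.r_gas = num(p, "physical", "r_gas");
  q.temperature = num(p, "physical", "temperature");
  return q;
}

typedef std::mt19937_64 Rng;

inline double runif01(Rng& g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

// Binomial(n, p) by inversion; p is expected to be <= ~0.1 (the gating
// step cap), n small.  The tiny-np fast path costs one uniform.
inline int rbinom_inv(Rng& g, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  double np = n * (double)p;
  double u = runif01(g);
  if (np < 1e-4) {
    // P(k >= 2) ~ (np)^2/2 is negligible at this threshold
    return (u < np * (1.0 - 0.5 * (n - 1) * p)) ? 1 : 0;
  }
  double q = 1.0 - p, r = p / q;
  double t = std::pow(q, n), cum = t;
  int k = 0;
  while (u > cum && k < n) {
    ++k;
    t *= r * (double)(n - k + 1) / (double)k;
    cum += t;
  }
  return k;
}

struct Spark {
  int cru;
  double t_start, t_end;
  int peak_open;
  double peak_ca;
};

// cap on per-channel exit-probability mass per gating substep.  Exits are
// sampled exactly from the exponential with frozen rates, so the only
// neglected effect is a channel making a second transition inside one
// substep; the cap bounds that regime and the dt-refinement tests
// quantify it.
const double GATE_CAP = 0.6;

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List params, NumericVector stim_times, double stim_amp,
                double stim_width, double t_end, double dt,
                double record_every, int seed, bool sealed, bool clamp_na_k,
                bool record_cru, int spark_threshold, double spark_gap,
                List init, int cru_every) {
  Pars P = read_pars(params);
  const int n = P.n_cru;
  const double scale = (double)n / (double)P.n_cru_full;
  const double c_tot = P.acap * P.cm;            // uF
  const double c_tot_eff = c_tot * scale;
  const double rtf = P.r_gas * P.temperature / P.faraday * 1e3;  // mV
  const double kappa_ca = c_tot * 1e-3 / (2.0 * P.faraday * P.v_myo);
  const double kappa_q = c_tot * 1e-3 / (P.faraday * P.v_myo);
  const double v_myo_eff = P.v_myo * scale;
  const double v_nsr_eff = P.v_nsr * scale;

  // global state
  double v = as<double>(init["v"]);
  double ca_myo = as<double>(init["ca_myo"]);
  double ca_nsr = as<double>(init["ca_nsr"]);
  double gm = as<double>(init["m"]), gh = as<double>(init["h"]),
         gj = as<double>(init["j"]), gx = as<double>(init["x"]);
  double na_i = as<double>(init["na_i"]), k_i = as<double>(init["k_i"]);

  // per-CRU state
  std::vector<double> ca_jsr(n, as<double>(init["ca_jsr"]));
  std::vector<double> ca_ds(n, as<double>(init["ca_ds"]));
  std::vector<int> ry_c1(n, P.n_ryr), ry_o2(n, 0), ry_c3(n, 0);
  // LCC counts per state: C1 O2 O3 C4 C5 C6
  std::vector<int> lc(6 * n, 0);
  for (int i = 0; i < n; ++i) lc[6 * i] = P.n_lcc;

  // per-CRU RNG streams (reproducible and n_cru-extensible)
  std::vector<Rng> rng;
  rng.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::seed_seq ss{(unsigned)seed, (unsigned)(i + 1)};
    rng.emplace_back(ss);
  }

  // spark bookkeeping
  std::vector<Spark> sparks;
  std::vector<char> sp_active(n, 0);
  std::vector<double> sp_start(n, 0), sp_last(n, -1e18), sp_peakca(n, 0);
  std::vector<int> sp_peak(n, 0);

  const long n_steps = (long)std::lround(t_end / dt);
  const long k_rec = std::max(1L, (long)std::lround(record_every / dt));
  const long n_rec = n_steps / k_rec + 1;

  NumericVector rec_t(n_rec), rec_v(n_rec), rec_camyo(n_rec),
      rec_cansr(n_rec), rec_cajsr(n_rec), rec_cads(n_rec), rec_ina(n_rec),
      rec_ical(n_rec), rec_ik(n_rec), rec_ik1(n_rec), rec_ikp(n_rec),
      rec_incx(n_rec), rec_inak(n_rec), rec_ibg(n_rec), rec_istim(n_rec),
      rec_nai(n_rec), rec_ki(n_rec), rec_h(n_rec), rec_catot(n_rec);
  IntegerVector rec_oryr(n_rec), rec_olcc(n_rec);
  IntegerMatrix cru_mat = record_cru ? IntegerMatrix(n_rec, n)
                                     : IntegerMatrix(1, 1);

  int stim_idx = 0;
  const int n_stim = stim_times.size();
  long rec_i = 0;

  // step-invariant current values (computed each step, recorded on grid)
  double i_na = 0, i_ca_l = 0, i_k = 0, i_k1 = 0, i_kp = 0, i_ncx = 0,
         i_nak = 0, i_bg = 0, i_stim = 0;

  const double sigma_nak = (std::exp(P.na_o / 67.3) - 1.0) / 7.0;

  // caches refreshed at every CRU substep, consumed by every global step
  double S_cd = 0, S_cj = 0, S1 = 0;
  long S0 = 0;
  int S_oryr = 0, S_olcc = 0;
  for (int i = 0; i < n; ++i) {
    S_cd += ca_ds[i];
    S_cj += ca_jsr[i];
  }

  for (long step = 0; step <= n_steps; ++step) {
    const double t = step * dt;

    // ---- stimulus ----
    i_stim = 0;
    while (stim_idx < n_stim && t >= stim_times[stim_idx] + stim_width)
      ++stim_idx;
    if (!sealed && stim_idx < n_stim && t >= stim_times[stim_idx] &&
        t < stim_times[stim_idx] + stim_width)
      i_stim = stim_amp;

    // ---- deterministic membrane currents ----
    double e_na = rtf * std::log(P.na_o / na_i);
    double e_k =
        rtf * std::log((P.k_o + P.pr_nak * P.na_o) / (k_i + P.pr_nak * na_i));
    double e_k1 = rtf * std::log(P.k_o / k_i);
    double e_ca = 0.5 * rtf * std::log(P.ca_o * 1e3 / ca_myo);
    if (!sealed) {
      i_na = P.g_na * gm * gm * gm * gh * gj * (v - e_na);
      double xi = (v > -100.0)
                      ? 2.837 * (std::exp(0.04 * (v + 77.0)) - 1.0) /
                            ((v + 77.0) * std::exp(0.04 * (v + 35.0)))
                      : 1.0;
      i_k = P.g_k * std::sqrt(P.k_o / 5.4) * gx * xi * (v - e_k);
      double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (v - e_k1 - 59.215)));
      double bk1 = (0.49124 * std::exp(0.08032 * (v - e_k1 + 5.476)) +
                    std::exp(0.06175 * (v - e_k1 - 594.31))) /
                   (1.0 + std::exp(-0.5143 * (v - e_k1 + 4.753)));
      i_k1 = P.g_k1 * std::sqrt(P.k_o / 5.4) * ak1 / (ak1 + bk1) * (v - e_k1);
      i_kp = P.g_kp * (v - e_k1) / (1.0 + std::exp((7.488 - v) / 5.98));
      double vf = v * 1e-3 * P.faraday / (P.r_gas * P.temperature);
      double ca_mM = ca_myo * 1e-3;
      double ncx_num = std::exp(P.ncx_eta * vf) * na_i * na_i * na_i * P.ca_o -
                       std::exp((P.ncx_eta - 1.0) * vf) * P.na_o * P.na_o *
                           P.na_o * ca_mM;
      double ncx_den =
          (P.ncx_km_na * P.ncx_km_na * P.ncx_km_na + P.na_o * P.na_o * P.na_o) *
          (P.ncx_km_ca * 1e-3 + P.ca_o) *
          (1.0 + P.ncx_ksat * std::exp((P.ncx_eta - 1.0) * vf));
      i_ncx = P.ncx_k * ncx_num / ncx_den;
      double f_nak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * v / rtf) +
                            0.0365 * sigma_nak * std::exp(-v / rtf));
      i_nak = P.nak_imax * f_nak /
              (1.0 + std::pow(P.nak_km_nai / na_i, 1.5)) * P.k_o /
              (P.k_o + P.nak_km_ko);
      i_bg = P.g_cab * (v - e_ca) + P.g_nab * (v - e_na);
    } else {
      i_na = i_k = i_k1 = i_kp = i_ncx = i_nak = i_bg = 0;
    }

    // ---- GHK factors (shared across CRUs; linear in local ca_ds) ----
    double u_ghk = 2.0 * (v * 1e-3) * P.faraday / (P.r_gas * P.temperature);
    double uf = (std::fabs(u_ghk) < 1e-4)
                    ? 1.0 - 0.5 * u_ghk + u_ghk * u_ghk / 12.0
                    : u_ghk / std::expm1(u_ghk);
    double ghk_a = P.p_dhpr * 2.0 * P.faraday * uf;  // i = ghk_a*(ci e^u - g co)
    double eu = std::exp(u_ghk);
    double co_term = 0.341 * (P.ca_o * 1e-6);

    // whole-cell L-type current from the cached open-channel sums,
    // re-evaluated against the current voltage every global step
    i_ca_l = sealed ? 0.0
                    : ghk_a * (S1 * 1e-9 * eu - co_term * (double)S0) * 1e6 /
                          c_tot_eff;

    bool at_record = (step % k_rec == 0);

    if (step % cru_every == 0) {
      const double dtc = dt * cru_every;  // CRU (gating + local Ca) substep

      // per-CRU-step LCC voltage-dependent rates (same for all CRUs)
      double rest = 1.0 / (1.0 + std::exp((v + 40.0) / 6.0));
      double r_c1_o2 =
          P.lcc_act_max / (1.0 + std::exp(-(v - P.lcc_v_act) / P.lcc_k_act));
      double r_c1_c6 =
          P.lcc_c6_max / (1.0 + std::exp(-(v - P.lcc_c6_vhalf) / P.lcc_c6_k));
      double r_o2_c1 = P.lcc_deact_max /
                       (1.0 + std::exp((v - P.lcc_v_deact) / P.lcc_k_deact));
      double r_o2_c5 =
          P.lcc_vi_max / (1.0 + std::exp(-(v - P.lcc_vi_vhalf) / P.lcc_vi_k));
      double r_c4_c1 = P.lcc_ca_recover;
      double r_c5_c1 = P.lcc_vi_recover * rest;
      double r_c6_c1 = P.lcc_c6_recover * rest;
      double c1_exit = r_c1_o2 + r_c1_c6;
      double p_c1_leave = -std::expm1(-c1_exit * dtc);
      double p_c1_to_o2 = (c1_exit > 0) ? r_c1_o2 / c1_exit : 0.0;
      double p_o3_leave = -std::expm1(-P.lcc_g_oo * dtc);
      double p_c4_leave = -std::expm1(-r_c4_c1 * dtc);
      double p_c5_leave = -std::expm1(-r_c5_c1 * dtc);
      double p_c6_leave = -std::expm1(-r_c6_c1 * dtc);

      // RyR2 constant-rate exits
      double o2_exit = P.ryr_k_close + P.ryr_k_adapt;
      double p_ryr_o2_leave = -std::expm1(-o2_exit * dtc);
      double p_ryr_o2_to_c1 = P.ryr_k_close / o2_exit;
      double p_ryr_c3_leave = -std::expm1(-P.ryr_k_recover * dtc);

      if ((c1_exit * dtc > GATE_CAP) || (o2_exit * dtc > GATE_CAP)) {
        stop("gating step cap violated at t = %f ms (rate*dt too large); "
             "reduce dt or cru_every", t);
      }

      const double kca_h = (P.ryr_hill == 2.0)
                               ? P.ryr_k_ca * P.ryr_k_ca
                               : std::pow(P.ryr_k_ca, P.ryr_hill);

      S_cd = 0; S_cj = 0; S0 = 0; S1 = 0; S_oryr = 0; S_olcc = 0;

      for (int ic = 0; ic < n; ++ic) {
        Rng& g = rng[ic];
        double cj = ca_jsr[ic], cd = ca_ds[ic];
        int c1 = ry_c1[ic], o2 = ry_o2[ic], c3 = ry_c3[ic];
        int* L = &lc[6 * ic];
        int n_open_lcc = L[1] + L[2];

        // fluxes at the frozen state
        double j_rel = P.g_rel * o2 * (cj - cd);
        double j_xfer = P.g_xfer * (cd - ca_myo);
        double j_tr = P.g_tr * (ca_nsr - cj);
        double j_lcc = 0;
        if (!sealed && n_open_lcc > 0) {
          double i_amp = ghk_a * (cd * 1e-9 * eu - co_term) * n_open_lcc;
          j_lcc = -i_amp * 1e3 / (2.0 * P.faraday * P.v_ds_unit);
        }

        // gating with frozen rates
        if (c1 > 0) {
          double cad_h =
              (P.ryr_hill == 2.0) ? cd * cd : std::pow(cd, P.ryr_hill);
          double phi = P.phi_m * cj + P.phi_b;
          double k_open = phi * P.ryr_k_open_max * cad_h / (cad_h + kca_h);
          if (k_open * dtc > GATE_CAP)
            stop("gating step cap violated at t = %f ms (RyR2 opening rate "
                 "%f /ms); reduce dt or cru_every", t, k_open);
          double p_open = (k_open * dtc < 1e-3)
                              ? k_open * dtc * (1.0 - 0.5 * k_open * dtc)
                              : -std::expm1(-k_open * dtc);
          int k = rbinom_inv(g, c1, p_open);
          c1 -= k; o2 += k;
        }
        if (ry_o2[ic] > 0) {
          int k = rbinom_inv(g, ry_o2[ic], p_ryr_o2_leave);
          if (k > 0) {
            int to_c1 = rbinom_inv(g, k, p_ryr_o2_to_c1);
            o2 -= k; c1 += to_c1; c3 += (k - to_c1);
          }
        }
        if (ry_c3[ic] > 0) {
          int k = rbinom_inv(g, ry_c3[ic], p_ryr_c3_leave);
          c3 -= k; c1 += k;
        }
        ry_c1[ic] = c1; ry_o2[ic] = o2; ry_c3[ic] = c3;

        // LCC: transitions sampled from the frozen counts
        int L0 = L[0], L1 = L[1], L2 = L[2], L3 = L[3], L4 = L[4],
            L5 = L[5];
        if (L0 > 0 && p_c1_leave > 0) {
          int k = rbinom_inv(g, L0, p_c1_leave);
          if (k > 0) {
            int to_o2 = rbinom_inv(g, k, p_c1_to_o2);
            L[0] -= k; L[1] += to_o2; L[5] += (k - to_o2);
          }
        }
        if (L1 > 0) {
          double r_o2_c4 = std::min(P.lcc_ca_slope * cd, P.lcc_ca_max);
          double o2x = r_o2_c1 + P.lcc_f_oo + r_o2_c4 + r_o2_c5;
          if (o2x * dtc > GATE_CAP)
            stop("gating step cap violated at t = %f ms (L-type O2 exit "
                 "rate %f /ms); reduce dt or cru_every", t, o2x);
          double p_leave = -std::expm1(-o2x * dtc);
          int k = rbinom_inv(g, L1, p_leave);
          if (k > 0) {  // multinomial split by sequential binomials
            int to_c1 = rbinom_inv(g, k, r_o2_c1 / o2x);
            int rem = k - to_c1;
            double rx = o2x - r_o2_c1;
            int to_o3 = (rem > 0) ? rbinom_inv(g, rem, P.lcc_f_oo / rx) : 0;
            rem -= to_o3;
            rx -= P.lcc_f_oo;
            int to_c4 = (rem > 0) ? rbinom_inv(g, rem, r_o2_c4 / rx) : 0;
            int to_c5 = rem - to_c4;
            L[1] -= k; L[0] += to_c1; L[2] += to_o3; L[3] += to_c4;
            L[4] += to_c5;
          }
        }
        if (L2 > 0) {
          int k = rbinom_inv(g, L2, p_o3_leave);
          L[2] -= k; L[1] += k;
        }
        if (L3 > 0) {
          int k = rbinom_inv(g, L3, p_c4_leave);
          L[3] -= k; L[0] += k;
        }
        if (L4 > 0) {
          int k = rbinom_inv(g, L4, p_c5_leave);
          L[4] -= k; L[0] += k;
        }
        if (L5 > 0) {
          int k = rbinom_inv(g, L5, p_c6_leave);
          L[5] -= k; L[0] += k;
        }

        // Euler update of the local compartments (rapid buffering)
        double bden_ds =
            1.0 + P.ds_btot * P.ds_kd / ((P.ds_kd + cd) * (P.ds_kd + cd));
        double bden_jsr = 1.0 + P.casq_btot * P.casq_kd /
                                    ((P.casq_kd + cj) * (P.casq_kd + cj));
        double cd_new = cd + dtc * (j_rel + j_lcc - j_xfer) / bden_ds;
        double cj_new =
            cj + dtc * (j_tr - j_rel * P.v_ds_unit / P.v_jsr_unit) / bden_jsr;
        if (cd_new < 1e-9) cd_new = 1e-9;
        if (cj_new < 1e-9) cj_new = 1e-9;
        ca_ds[ic] = cd_new;
        ca_jsr[ic] = cj_new;

        // refresh caches
        S_cd += cd_new;
        S_cj += cj_new;
        int nol = L[1] + L[2];
        S0 += nol;
        S1 += nol * cd_new;
        S_oryr += ry_o2[ic];
        S_olcc += nol;

        // spark bookkeeping (post-update open count)
        int oc = ry_o2[ic];
        if (oc >= spark_threshold) {
          // a pending episode whose merge window has expired must close
          // before this step can begin a new one
          if (sp_active[ic] && (t - sp_last[ic] >= spark_gap)) {
            Spark s;
            s.cru = ic + 1;
            s.t_start = sp_start[ic];
            s.t_end = sp_last[ic];
            s.peak_open = sp_peak[ic];
            s.peak_ca = sp_peakca[ic];
            sparks.push_back(s);
            sp_active[ic] = 0;
          }
          if (!sp_active[ic]) {
            sp_active[ic] = 1;
            sp_start[ic] = t;
            sp_peak[ic] = 0;
            sp_peakca[ic] = 0;
          }
          if (oc > sp_peak[ic]) sp_peak[ic] = oc;
          if (cd_new > sp_peakca[ic]) sp_peakca[ic] = cd_new;
          sp_last[ic] = t;
        } else if (sp_active[ic]) {
          if (t - sp_last[ic] >= spark_gap) {
            Spark s;
            s.cru = ic + 1;
            s.t_start = sp_start[ic];
            s.t_end = sp_last[ic];
            s.peak_open = sp_peak[ic];
            s.peak_ca = sp_peakca[ic];
            sparks.push_back(s);
            sp_active[ic] = 0;
          }
        }
      }
    }

    // ---- record (state at time t, currents evaluated at t) ----
    if (at_record) {
      if (record_cru)
        for (int ic = 0; ic < n; ++ic) cru_mat(rec_i, ic) = ry_o2[ic];
      // exact total cell Ca (free + buffer-bound, volume-weighted), mol
      double tot = (ca_myo + P.trpn_btot * ca_myo / (P.trpn_kd + ca_myo) +
                    P.cmdn_btot * ca_myo / (P.cmdn_kd + ca_myo)) *
                       v_myo_eff +
                   ca_nsr * v_nsr_eff;
      for (int ic = 0; ic < n; ++ic) {
        tot += (ca_jsr[ic] +
                P.casq_btot * ca_jsr[ic] / (P.casq_kd + ca_jsr[ic])) *
               P.v_jsr_unit;
        tot += (ca_ds[ic] + P.ds_btot * ca_ds[ic] / (P.ds_kd + ca_ds[ic])) *
               P.v_ds_unit;
      }
      rec_catot[rec_i] = tot * 1e-6;
      rec_t[rec_i] = t;
      rec_v[rec_i] = v;
      rec_camyo[rec_i] = ca_myo;
      rec_cansr[rec_i] = ca_nsr;
      rec_cajsr[rec_i] = S_cj / n;
      rec_cads[rec_i] = S_cd / n;
      rec_ina[rec_i] = i_na;
      rec_ical[rec_i] = i_ca_l;
      rec_ik[rec_i] = i_k;
      rec_ik1[rec_i] = i_k1;
      rec_ikp[rec_i] = i_kp;
      rec_incx[rec_i] = i_ncx;
      rec_inak[rec_i] = i_nak;
      rec_ibg[rec_i] = i_bg;
      rec_istim[rec_i] = i_stim;
      rec_oryr[rec_i] = S_oryr;
      rec_olcc[rec_i] = S_olcc;
      rec_nai[rec_i] = na_i;
      rec_ki[rec_i] = k_i;
      rec_h[rec_i] = gh;
      if (!std::isfinite(v) || !std::isfinite(ca_myo) ||
          !std::isfinite(ca_nsr)) {
        stop("integration blow-up at t = %f ms (V = %f, ca_myo = %f, "
             "ca_nsr = %f)", t, v, ca_myo, ca_nsr);
      }
      ++rec_i;
    }
    if (step == n_steps) break;

    // ---- global Euler update ----
    double j_serca = 2.0 * P.serca_vmax * P.serca_ap *
                     std::pow(ca_myo, P.serca_hill) /
                     (std::pow(ca_myo, P.serca_hill) +
                      std::pow(P.serca_km, P.serca_hill)) /
                     (1.0 + std::pow(ca_nsr / P.serca_k_nsr, P.serca_hill_nsr));
    double j_leak = P.g_leak * (ca_nsr - ca_myo);
    // transfer fluxes from the cached subspace/JSR sums against the
    // current bulk concentrations
    double j_xfer_myo =
        P.g_xfer * (S_cd - n * ca_myo) * P.v_ds_unit / v_myo_eff;
    double j_tr_nsr =
        P.g_tr * (n * ca_nsr - S_cj) * P.v_jsr_unit / v_nsr_eff;
    double j_sarc = sealed ? 0.0
                           : (-(P.g_cab * (v - e_ca)) * kappa_ca +
                              i_ncx * kappa_q);
    double bden_myo =
        1.0 + P.trpn_btot * P.trpn_kd / ((P.trpn_kd + ca_myo) * (P.trpn_kd + ca_myo)) +
        P.cmdn_btot * P.cmdn_kd / ((P.cmdn_kd + ca_myo) * (P.cmdn_kd + ca_myo));
    ca_myo += dt * (j_xfer_myo - j_serca + j_leak + j_sarc) / bden_myo;
    ca_nsr += dt * ((j_serca - j_leak) * P.v_myo / P.v_nsr - j_tr_nsr);
    if (ca_myo < 1e-9) ca_myo = 1e-9;
    if (ca_nsr < 1e-9) ca_nsr = 1e-9;

    double i_sum =
        i_na + i_ca_l + i_k + i_k1 + i_kp + i_ncx + i_nak + i_bg + i_stim;
    v += -dt * i_sum;

    if (!sealed) {
      // HH gates, explicit Euler (same alpha/beta forms as lr_gate_rates)
      double am = (std::fabs(v + 47.13) < 1e-6)
                      ? 3.2
                      : 0.32 * (v + 47.13) / (1.0 - std::exp(-0.1 * (v + 47.13)));
      double bm = 0.08 * std::exp(-v / 11.0);
      double ah, bh, aj, bj;
      if (v >= -40.0) {
        ah = 0.0;
        bh = 1.0 / (0.13 * (1.0 + std::exp((v + 10.66) / -11.1)));
        aj = 0.0;
        bj = 0.3 * std::exp(-2.535e-7 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
      } else {
        ah = 0.135 * std::exp((80.0 + v) / -6.8);
        bh = 3.56 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.35 * v);
        aj = (-1.2714e5 * std::exp(0.2444 * v) -
              3.474e-5 * std::exp(-0.04391 * v)) *
             (v + 37.78) / (1.0 + std::exp(0.311 * (v + 79.23)));
        bj = 0.1212 * std::exp(-0.01052 * v) /
             (1.0 + std::exp(-0.1378 * (v + 40.14)));
      }
      double ax = P.x_rate_scale * 0.0005 * std::exp(0.083 * (v + 50.0)) /
                  (1.0 + std::exp(0.057 * (v + 50.0)));
      double bx = P.x_beta_scale * P.x_rate_scale * 0.0013 *
                  std::exp(-0.06 * (v + 20.0)) /
                  (1.0 + std::exp(-0.04 * (v + 20.0)));
      gm += dt * (am * (1.0 - gm) - bm * gm);
      gh += dt * (ah * (1.0 - gh) - bh * gh);
      gj += dt * (aj * (1.0 - gj) - bj * gj);
      gx += dt * (ax * (1.0 - gx) - bx * gx);
      if (gm < 0) gm = 0; if (gm > 1) gm = 1;
      if (gh < 0) gh = 0; if (gh > 1) gh = 1;
      if (gj < 0) gj = 0; if (gj > 1) gj = 1;
      if (gx < 0) gx = 0; if (gx > 1) gx = 1;
      if (!clamp_na_k) {
        na_i += dt * (-(i_na + P.g_nab * (v - e_na) + 3.0 * i_nak +
                        3.0 * i_ncx) * kappa_q * 1e-3);
        k_i += dt * (-(i_k + i_k1 + i_kp + i_stim - 2.0 * i_nak) *
                     kappa_q * 1e-3);
      }
    }
  }

  // finalize pending sparks
  for (int ic = 0; ic < n; ++ic) {
    if (sp_active[ic]) {
      Spark s;
      s.cru = ic + 1;
      s.t_start = sp_start[ic];
      s.t_end = sp_last[ic];
      s.peak_open = sp_peak[ic];
      s.peak_ca = sp_peakca[ic];
      sparks.push_back(s);
    }
  }
  int ns = sparks.size();
  IntegerVector sp_cru(ns), sp_po(ns);
  NumericVector sp_t0(ns), sp_t1(ns), sp_pc(ns);
  for (int i = 0; i < ns; ++i) {
    sp_cru[i] = sparks[i].cru;
    sp_t0[i] = sparks[i].t_start;
    sp_t1[i] = sparks[i].t_end;
    sp_po[i] = sparks[i].peak_open;
    sp_pc[i] = sparks[i].peak_ca;
  }

  List out = List::create(
      _["time"] = rec_t, _["v"] = rec_v, _["ca_myo"] = rec_camyo,
      _["ca_nsr"] = rec_cansr, _["ca_jsr_mean"] = rec_cajsr,
      _["ca_ds_mean"] = rec_cads, _["i_na"] = rec_ina, _["i_ca_l"] = rec_ical,
      _["i_k"] = rec_ik, _["i_k1"] = rec_ik1, _["i_kp"] = rec_ikp,
      _["i_ncx"] = rec_incx, _["i_nak"] = rec_inak, _["i_bg"] = rec_ibg,
      _["i_stim"] = rec_istim, _["open_ryr"] = rec_oryr,
      _["open_lcc"] = rec_olcc, _["na_i"] = rec_nai, _["k_i"] = rec_ki,
      _["h_gate"] = rec_h, _["total_ca"] = rec_catot);
  out["sparks"] = List::create(_["cru"] = sp_cru, _["t_start"] = sp_t0,
                               _["t_end"] = sp_t1, _["peak_open"] = sp_po,
                               _["peak_ca_ds"] = sp_pc);
  if (record_cru) out["cru_open"] = cru_mat;
  return out;
}
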