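#include <Rcpp.h>
using namespace Rcpp;

// Compiled right-hand side of the extended reactor model. The parameter
// vector layout is produced by pack_rhs() on the R side; the indices below
// must stay in step with that function.

enum ParIdx {
  iV_liq = 0, iV_gas, iT_op, iP_atm, ik_p, ik_L_a,
  iK_w, iKa_va, iKa_bu, iKa_pro, iKa_ac, iKa_co2, iKa_IN,
  iKH_h2, iKH_ch4, iKH_co2, ip_h2o, iRgas,
  ik_dis, ik_hyd_ch, ik_hyd_pr, ik_hyd_li,
  ik_m_su, iK_S_su, ik_m_aa, iK_S_aa, ik_m_fa, iK_S_fa, iK_Ih2_fa,
  ik_m_c4, iK_S_c4, iK_Ih2_c4,
  ik_m_pro1, iK_S_pro1, iK_I_nh3_pro1, ik_m_pro2, iK_S_pro2, iK_I_nh3_pro2,
  iK_Ih2_pro,
  ik_m_ac1, iK_S_ac1, iK_I_nh3_ac1, ik_m_ac2, iK_S_ac2, iK_I_nh3_ac2,
  ik_m_h2, iK_S_h2, iK_S_IN, ik_dec,
  iKpH_aa, in_aa, iKpH_ac, in_ac, iKpH_h2, in_h2,
  N_PAR
};

// state indices (layout of adm1_state_names)
enum StIdx {
  S_su = 0, S_aa, S_fa, S_va, S_bu, S_pro, S_ac, S_h2, S_ch4,
  S_IC, S_IN, S_I,
  X_c, X_ch, X_pr, X_li, X_su, X_aa, X_fa, X_c4,
  X_pro1, X_pro2, X_ac1, X_ac2, X_h2, X_I,
  S_cat, S_an, S_gas_h2, S_gas_ch4, S_gas_co2,
  N_STATE
};

static const int N_PROC = 23;

static inline double charge_balance(double Sh, const double *s,
                                    const double *p) {
  double nh4 = s[S_IN] * Sh / (p[iKa_IN] + Sh);
  double hco3 = s[S_IC] * p[iKa_co2] / (p[iKa_co2] + Sh);
  double vfa = s[S_ac] / 64.0 * p[iKa_ac] / (p[iKa_ac] + Sh) +
               s[S_pro] / 112.0 * p[iKa_pro] / (p[iKa_pro] + Sh) +
               s[S_bu] / 160.0 * p[iKa_bu] / (p[iKa_bu] + Sh) +
               s[S_va] / 208.0 * p[iKa_va] / (p[iKa_va] + Sh);
  return s[S_cat] + nh4 + Sh - s[S_an] - p[iK_w] / Sh - hco3 - vfa;
}

// bisection on the strictly increasing charge balance, pH in (2, 13)
static double solve_sh(const double *s, const double *p) {
  double lo = 1e-13, hi = 1e-2;
  if (charge_balance(lo, s, p) > 0 || charge_balance(hi, s, p) < 0)
    return NA_REAL;
  for (int it = 0; it < 100; ++it) {
    double mid = std::sqrt(lo * hi); // bisect on log scale
    if (charge_balance(mid, s, p) < 0) lo = mid; else hi = mid;
  }
  return std::sqrt(lo * hi);
}

static inline double monod(double S, double K) {
  return S <= 0 ? 0.0 : S / (K + S);
}

static inline double hill_ph(double Sh, double KpH, double n) {
  double a = std::pow(KpH, n);
  return a / (std::pow(Sh, n) + a);
}

static inline double inh(double S, double K) {
  return std::isfinite(K) ? 1.0 / (1.0 + S / K) : 1.0;
}

// [[Rcpp::export]]
List adm1_derivs_cpp(double t, NumericVector y, List pack) {
  NumericVector parv = pack["par"];
  NumericMatrix nu = pack["nu"];
  NumericVector uin = pack["uin"];
  double D = as<double>(pack["D"]);
  const double *p = parv.begin();

  double s[N_STATE]; // clipped copy for rates/speciation
  for (int i = 0; i < N_STATE; ++i) {
    double v = y[i];
    if (!std::isfinite(v)) {
      NumericVector dy(N_STATE, NA_REAL);
      return List::create(dy);
    }
    s[i] = v > 0 ? v : 0.0;
  }

  double Sh = solve_sh(s, p);
  NumericVector dy(N_STATE);
  if (!std::isfinite(Sh)) {
    std::fill(dy.begin(), dy.end(), NA_REAL);
    return List::create(dy);
  }
  double Snh3 = s[S_IN] * p[iKa_IN] / (p[iKa_IN] + Sh);
  double Sco2 = s[S_IC] * Sh / (p[iKa_co2] + Sh);

  double I_pH_aa = hill_ph(Sh, p[iKpH_aa], p[in_aa]);
  double I_pH_ac = hill_ph(Sh, p[iKpH_ac], p[in_ac]);
  double I_pH_h2 = hill_ph(Sh, p[iKpH_h2], p[in_h2]);
  double I_IN = monod(s[S_IN], p[iK_S_IN]);
  double I_h2_fa = inh(s[S_h2], p[iK_Ih2_fa]);
  double I_h2_c4 = inh(s[S_h2], p[iK_Ih2_c4]);
  double I_h2_pro = inh(s[S_h2], p[iK_Ih2_pro]);

  double sumc4 = s[S_va] + s[S_bu];
  double frac_va = sumc4 > 0 ? s[S_va] / sumc4 : 0.0;
  double frac_bu = sumc4 > 0 ? s[S_bu] / sumc4 : 0.0;

  double rho[N_PROC];
  rho[0] = p[ik_dis] * s[X_c];
  rho[1] = p[ik_hyd_ch] * s[X_ch];
  rho[2] = p[ik_hyd_pr] * s[X_pr];
  rho[3] = p[ik_hyd_li] * s[X_li];
  rho[4] = p[ik_m_su] * monod(s[S_su], p[iK_S_su]) * s[X_su] * I_pH_aa * I_IN;
  rho[5] = p[ik_m_aa] * monod(s[S_aa], p[iK_S_aa]) * s[X_aa] * I_pH_aa * I_IN;
  rho[6] = p[ik_m_fa] * monod(s[S_fa], p[iK_S_fa]) * s[X_fa] *
           I_pH_aa * I_IN * I_h2_fa;
  rho[7] = p[ik_m_c4] * monod(s[S_va], p[iK_S_c4]) * s[X_c4] * frac_va *
           I_pH_aa * I_IN * I_h2_c4;
  rho[8] = p[ik_m_c4] * monod(s[S_bu], p[iK_S_c4]) * s[X_c4] * frac_bu *
           I_pH_aa * I_IN * I_h2_c4;
  rho[9] = p[ik_m_pro1] * monod(s[S_pro], p[iK_S_pro1]) * s[X_pro1] *
           I_pH_aa * I_IN * I_h2_pro * inh(Snh3, p[iK_I_nh3_pro1]);
  rho[10] = p[ik_m_pro2] * monod(s[S_pro], p[iK_S_pro2]) * s[X_pro2] *
            I_pH_aa * I_IN * I_h2_pro * inh(Snh3, p[iK_I_nh3_pro2]);
  rho[11] = p[ik_m_ac1] * monod(s[S_ac], p[iK_S_ac1]) * s[X_ac1] *
            I_pH_ac * I_IN * inh(Snh3, p[iK_I_nh3_ac1]);
  rho[12] = p[ik_m_ac2] * monod(s[S_ac], p[iK_S_ac2]) * s[X_ac2] *
            I_pH_ac * I_IN * inh(Snh3, p[iK_I_nh3_ac2]);
  rho[13] = p[ik_m_h2] * monod(s[S_h2], p[iK_S_h2]) * s[X_h2] * I_pH_h2 * I_IN;
  const int dec_states[9] = {X_su, X_aa, X_fa, X_c4, X_pro1, X_pro2,
                             X_ac1, X_ac2, X_h2};
  for (int k = 0; k < 9; ++k) rho[14 + k] = p[ik_dec] * s[dec_states[k]];

  // gas phase
  double RT = p[iRgas] * p[iT_op];
  double p_h2 = s[S_gas_h2] * RT / 16.0;
  double p_ch4 = s[S_gas_ch4] * RT / 64.0;
  double p_co2 = s[S_gas_co2] * RT;
  double P_gas = p_h2 + p_ch4 + p_co2 + p[ip_h2o];
  double q_gas = p[ik_p] * (P_gas - p[iP_atm]);
  if (q_gas < 0) q_gas = 0;

  double rT_h2 = p[ik_L_a] * (s[S_h2] - 16.0 * p[iKH_h2] * p_h2);
  double rT_ch4 = p[ik_L_a] * (s[S_ch4] - 64.0 * p[iKH_ch4] * p_ch4);
  double rT_co2 = p[ik_L_a] * (Sco2 - p[iKH_co2] * p_co2);

  for (int i = 0; i < N_STATE; ++i) {
    double bio = 0.0;
    for (int j = 0; j < N_PROC; ++j) bio += nu(i, j) * rho[j];
    dy[i] = D * (uin[i] - y[i]) + bio;
  }
  dy[S_h2] -= rT_h2;
  dy[S_ch4] -= rT_ch4;
  dy[S_IC] -= rT_co2;
  double Vr = parv[iV_liq] / parv[iV_gas];
  dy[S_gas_h2] = -y[S_gas_h2] * q_gas / parv[iV_gas] + rT_h2 * Vr;
  dy[S_gas_ch4] = -y[S_gas_ch4] * q_gas / parv[iV_gas] + rT_ch4 * Vr;
  dy[S_gas_co2] = -y[S_gas_co2] * q_gas / parv[iV_gas] + rT_co2 * Vr;

  NumericVector aux = NumericVector::create(
    _["pH"] = -std::log10(Sh), _["S_nh3"] = Snh3,
    _["q_gas"] = q_gas, _["q_ch4"] = P_gas > 0 ? q_gas * p_ch4 / P_gas : 0.0,
    _["P_gas"] = P_gas);
  return List::create(dy, aux);
}
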