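// Neural-mass firing-rate model of the CA3-CA1-CX-CX'-MD-TRN-REU network.
// 17 state variables, fourth-order Runge-Kutta integration.
//
// State ordering (fixed, mirrored in R/model.R):
//  0 Ve_CA3  1 Vi_CA3  2 c_CA3
//  3 Ve_CA1  4 Vi_CA1  5 c_CA1
//  6 Ve_CX   7 c_CX    8 Vi_CX
//  9 Ve_CXp 10 c_CXp  11 Vi_CXp
// 12 Ve_MD  13 u_e    14 Vi_TRN 15 u_i
// 16 Ve_REU
//
// Units: V in mV, t in s, rates in Hz. u is clamped to u <= 0 (the burst
// switch b takes values {-200, 0}, so u is driven non-positive from rest).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  // global sigmoid rates
  double r0, r1;
  // per-population sigmoid sharpness / threshold
  double ge_CA3, Ve_CA3, gi_CA3, Vi_CA3;
  double ge_CA1, Ve_CA1, gi_CA1, Vi_CA1;
  double ge_CX, Ve_CX, gi_CX, Vi_CX;
  double ge_CXp, Ve_CXp, gi_CXp, Vi_CXp;
  double ge_REU, Ve_REU;
  // thalamic tonic/burst rate params
  double RT_MD, VT_MD, gT_MD, RB_MD, VB_MD, gB_MD, L_MD;
  double RT_TRN, VT_TRN, gT_TRN, RB_TRN, VB_TRN, gB_TRN, L_TRN;
  // burst drive / u dynamics
  double fmax_MD, fth_MD, q_MD, tau_u_MD, b_MD, Vb_MD;
  double fmax_TRN, fth_TRN, q_TRN, tau_u_TRN, b_TRN, Vb_TRN;
  // adaptation
  double gc, cstar, tau_c, dc_CA3, dc_CA1, dc_CX, dc_CXp;
  // membrane time constants
  double tau_e_CA3, tau_i_CA3, tau_e_CA1, tau_i_CA1;
  double tau_e_CX, tau_i_CX, tau_e_CXp, tau_i_CXp;
  double tau_MD, tau_TRN, tau_REU;
  // effective connection weights W = N * P * J (adapted E-E pathways keep
  // J as the maximal strength, multiplied at run time by the adaptation
  // sigmoid of the target network)
  double W_ee_CA3, W_ie_CA3, W_ei_CA3, W_ii_CA3, Wc_CA3;
  double W_ie_CA1, W_ei_CA1, W_ii_CA1;
  double W_ee_CA3_CA1, W_ei_CA3_CA1, W_ee_REU_CA1, W_ei_REU_CA1;
  double Wc_CA3_CA1, Wc_REU_CA1;
  double W_ee_CX, W_ie_CX, W_ei_CX, W_ii_CX, Wc_CX;
  double W_ee_CXp_CX, W_ei_CXp_CX, W_ee_REU_CX, W_ei_REU_CX;
  double W_ee_CA1_CX, W_ei_CA1_CX;
  double Wc_CXp_CX, Wc_REU_CX, Wc_CA1_CX;
  double W_ee_CXp, W_ie_CXp, W_ei_CXp, W_ii_CXp, Wc_CXp;
  double W_ee_CX_CXp, W_ei_CX_CXp, W_ee_MD_CXp, W_ei_MD_CXp;
  double Wc_CX_CXp, Wc_MD_CXp;
  double W_ie_TRN_MD, W_ee_CXp_MD;
  double W_ii_TRN, W_ei_MD_TRN, W_ei_CXp_TRN;
  double W_ie_TRN_REU, W_ee_CX_REU, W_ee_CA1_REU;
  // external tonic drives (mV/s), normally 0
  double I_CX, I_CXp, I_MD, I_TRN, I_REU, I_CA3, I_CA1;
};

static double getp(const List& p, const char* nm) {
  if (!p.containsElementNamed(nm))
    stop("parameter list is missing '%s'", nm);
  return as<double>(p[nm]);
}

static Pars fill_pars(const List& p) {
  Pars P;
  P.r0 = getp(p, "r0"); P.r1 = getp(p, "r1");
  P.ge_CA3 = getp(p, "g.e.CA3"); P.Ve_CA3 = getp(p, "Vstar.e.CA3");
  P.gi_CA3 = getp(p, "g.i.CA3"); P.Vi_CA3 = getp(p, "Vstar.i.CA3");
  P.ge_CA1 = getp(p, "g.e.CA1"); P.Ve_CA1 = getp(p, "Vstar.e.CA1");
  P.gi_CA1 = getp(p, "g.i.CA1"); P.Vi_CA1 = getp(p, "Vstar.i.CA1");
  P.ge_CX = getp(p, "g.e.CX"); P.Ve_CX = getp(p, "Vstar.e.CX");
  P.gi_CX = getp(p, "g.i.CX"); P.Vi_CX = getp(p, "Vstar.i.CX");
  P.ge_CXp = getp(p, "g.e.CXp"); P.Ve_CXp = getp(p, "Vstar.e.CXp");
  P.gi_CXp = getp(p, "g.i.CXp"); P.Vi_CXp = getp(p, "Vstar.i.CXp");
  P.ge_REU = getp(p, "g.e.REU"); P.Ve_REU = getp(p, "Vstar.e.REU");
  P.RT_MD = getp(p, "RT.MD"); P.VT_MD = getp(p, "VT.MD"); P.gT_MD = getp(p, "gT.MD");
  P.RB_MD = getp(p, "RB.MD"); P.VB_MD = getp(p, "VB.MD"); P.gB_MD = getp(p, "gB.MD");
  P.L_MD = getp(p, "L.MD");
  P.RT_TRN = getp(p, "RT.TRN"); P.VT_TRN = getp(p, "VT.TRN"); P.gT_TRN = getp(p, "gT.TRN");
  P.RB_TRN = getp(p, "RB.TRN"); P.VB_TRN = getp(p, "VB.TRN"); P.gB_TRN = getp(p, "gB.TRN");
  P.L_TRN = getp(p, "L.TRN");
  P.fmax_MD = getp(p, "f.max.MD"); P.fth_MD = getp(p, "f.th.MD");
  P.q_MD = getp(p, "q.MD"); P.tau_u_MD = getp(p, "tau.u.MD");
  P.b_MD = getp(p, "b.MD"); P.Vb_MD = getp(p, "Vb.MD");
  P.fmax_TRN = getp(p, "f.max.TRN"); P.fth_TRN = getp(p, "f.th.TRN");
  P.q_TRN = getp(p, "q.TRN"); P.tau_u_TRN = getp(p, "tau.u.TRN");
  P.b_TRN = getp(p, "b.TRN"); P.Vb_TRN = getp(p, "Vb.TRN");
  P.gc = getp(p, "gc"); P.cstar = getp(p, "cstar"); P.tau_c = getp(p, "tau.c");
  P.dc_CA3 = getp(p, "dc.CA3"); P.dc_CA1 = getp(p, "dc.CA1");
  P.dc_CX = getp(p, "dc.CX"); P.dc_CXp = getp(p, "dc.CXp");
  P.tau_e_CA3 = getp(p, "tau.e.CA3"); P.tau_i_CA3 = getp(p, "tau.i.CA3");
  P.tau_e_CA1 = getp(p, "tau.e.CA1"); P.tau_i_CA1 = getp(p, "tau.i.CA1");
  P.tau_e_CX = getp(p, "tau.e.CX"); P.tau_i_CX = getp(p, "tau.i.CX");
  P.tau_e_CXp = getp(p, "tau.e.CXp"); P.tau_i_CXp = getp(p, "tau.i.CXp");
  P.tau_MD = getp(p, "tau.MD"); P.tau_TRN = getp(p, "tau.TRN");
  P.tau_REU = getp(p, "tau.REU");
  P.W_ee_CA3 = getp(p, "W.ee.CA3"); P.W_ie_CA3 = getp(p, "W.ie.CA3");
  P.W_ei_CA3 = getp(p, "W.ei.CA3"); P.W_ii_CA3 = getp(p, "W.ii.CA3");
  P.Wc_CA3 = getp(p, "Wc.CA3");
  P.W_ie_CA1 = getp(p, "W.ie.CA1"); P.W_ei_CA1 = getp(p, "W.ei.CA1");
  P.W_ii_CA1 = getp(p, "W.ii.CA1");
  P.W_ee_CA3_CA1 = getp(p, "W.ee.CA3_CA1"); P.W_ei_CA3_CA1 = getp(p, "W.ei.CA3_CA1");
  P.W_ee_REU_CA1 = getp(p, "W.ee.REU_CA1"); P.W_ei_REU_CA1 = getp(p, "W.ei.REU_CA1");
  P.Wc_CA3_CA1 = getp(p, "Wc.CA3_CA1"); P.Wc_REU_CA1 = getp(p, "Wc.REU_CA1");
  P.W_ee_CX = getp(p, "W.ee.CX"); P.W_ie_CX = getp(p, "W.ie.CX");
  P.W_ei_CX = getp(p, "W.ei.CX"); P.W_ii_CX = getp(p, "W.ii.CX");
  P.Wc_CX = getp(p, "Wc.CX");
  P.W_ee_CXp_CX = getp(p, "W.ee.CXp_CX"); P.W_ei_CXp_CX = getp(p, "W.ei.CXp_CX");
  P.W_ee_REU_CX = getp(p, "W.ee.REU_CX"); P.W_ei_REU_CX = getp(p, "W.ei.REU_CX");
  P.W_ee_CA1_CX = getp(p, "W.ee.CA1_CX"); P.W_ei_CA1_CX = getp(p, "W.ei.CA1_CX");
  P.Wc_CXp_CX = getp(p, "Wc.CXp_CX"); P.Wc_REU_CX = getp(p, "Wc.REU_CX");
  P.Wc_CA1_CX = getp(p, "Wc.CA1_CX");
  P.W_ee_CXp = getp(p, "W.ee.CXp"); P.W_ie_CXp = getp(p, "W.ie.CXp");
  P.W_ei_CXp = getp(p, "W.ei.CXp"); P.W_ii_CXp = getp(p, "W.ii.CXp");
  P.Wc_CXp = getp(p, "Wc.CXp");
  P.W_ee_CX_CXp = getp(p, "W.ee.CX_CXp"); P.W_ei_CX_CXp = getp(p, "W.ei.CX_CXp");
  P.W_ee_MD_CXp = getp(p, "W.ee.MD_CXp"); P.W_ei_MD_CXp = getp(p, "W.ei.MD_CXp");
  P.Wc_CX_CXp = getp(p, "Wc.CX_CXp"); P.Wc_MD_CXp = getp(p, "Wc.MD_CXp");
  P.W_ie_TRN_MD = getp(p, "W.ie.TRN_MD"); P.W_ee_CXp_MD = getp(p, "W.ee.CXp_MD");
  P.W_ii_TRN = getp(p, "W.ii.TRN"); P.W_ei_MD_TRN = getp(p, "W.ei.MD_TRN");
  P.W_ei_CXp_TRN = getp(p, "W.ei.CXp_TRN");
  P.W_ie_TRN_REU = getp(p, "W.ie.TRN_REU"); P.W_ee_CX_REU = getp(p, "W.ee.CX_REU");
  P.W_ee_CA1_REU = getp(p, "W.ee.CA1_REU");
  P.I_CX = getp(p, "I.CX"); P.I_CXp = getp(p, "I.CXp");
  P.I_MD = getp(p, "I.MD"); P.I_TRN = getp(p, "I.TRN");
  P.I_REU = getp(p, "I.REU"); P.I_CA3 = getp(p, "I.CA3");
  P.I_CA1 = getp(p, "I.CA1");
  return P;
}

// sigmoid firing rate, increasing in V (Eq. 1 form)
static inline double srate(double V, double r0, double r1, double g, double Vs) {
  return r0 + r1 / (1.0 + std::exp(-(V - Vs) / g));
}

// tonic/burst blended rate of thalamic populations; u <= 0, weight exp(L*u)
static inline double brate(double V, double u,
                           double RT, double VT, double gT,
                           double RB, double VB, double gB, double L) {
  if (u > 0.0) u = 0.0;  // clamp (D5)
  double w = std::exp(L * u);
  double rt = RT / (1.0 + std::exp(-(V - VT) / gT));
  double rb = RB / (1.0 + std::exp(-(V - VB) / gB));
  return w * rt + (1.0 - w) * rb;
}

// adaptation factor in (0, 1): multiplies the maximal E-E strength
static inline double afac(double c, double cstar, double gc) {
  return 1.0 / (1.0 + std::exp((c - cstar) / gc));
}

static void deriv(const double* s, double* ds, const Pars& P) {
  const double Ve3 = s[0], Vi3 = s[1], c3 = s[2];
  const double Ve1 = s[3], Vi1 = s[4], c1 = s[5];
  const double Vex = s[6], cx = s[7], Vix = s[8];
  const double Vep = s[9], cp = s[10], Vip = s[11];
  const double Vmd = s[12], ue = s[13], Vtrn = s[14], ui = s[15];
  const double Vreu = s[16];

  const double re3 = srate(Ve3, P.r0, P.r1, P.ge_CA3, P.Ve_CA3);
  const double ri3 = srate(Vi3, P.r0, P.r1, P.gi_CA3, P.Vi_CA3);
  const double re1 = srate(Ve1, P.r0, P.r1, P.ge_CA1, P.Ve_CA1);
  const double ri1 = srate(Vi1, P.r0, P.r1, P.gi_CA1, P.Vi_CA1);
  const double rex = srate(Vex, P.r0, P.r1, P.ge_CX, P.Ve_CX);
  const double rix = srate(Vix, P.r0, P.r1, P.gi_CX, P.Vi_CX);
  const double rep = srate(Vep, P.r0, P.r1, P.ge_CXp, P.Ve_CXp);
  const double rip = srate(Vip, P.r0, P.r1, P.gi_CXp, P.Vi_CXp);
  const double rreu = srate(Vreu, P.r0, P.r1, P.ge_REU, P.Ve_REU);
  const double rmd = brate(Vmd, ue, P.RT_MD, P.VT_MD, P.gT_MD,
                           P.RB_MD, P.VB_MD, P.gB_MD, P.L_MD);
  const double rtrn = brate(Vtrn, ui, P.RT_TRN, P.VT_TRN, P.gT_TRN,
                            P.RB_TRN, P.VB_TRN, P.gB_TRN, P.L_TRN);

  const double a3 = afac(c3, P.cstar, P.gc);
  const double a1 = afac(c1, P.cstar, P.gc);
  const double ax = afac(cx, P.cstar, P.gc);
  const double ap = afac(cp, P.cstar, P.gc);

  // CA3 (Eqs. 4-6)
  ds[0] = -Ve3 / P.tau_e_CA3 + P.W_ee_CA3 * a3 * re3 - P.W_ie_CA3 * ri3 + P.I_CA3;
  ds[1] = -Vi3 / P.tau_i_CA3 + P.W_ei_CA3 * re3 - P.W_ii_CA3 * ri3;
  ds[2] = -c3 / P.tau_c + P.Wc_CA3 * P.dc_CA3 * re3;

  // CA1 (Eqs. 7-9); alpha.REU_CA1 is folded into W.ee.REU_CA1 upstream
  ds[3] = -Ve1 / P.tau_e_CA1 - P.W_ie_CA1 * ri1
        + P.W_ee_CA3_CA1 * a1 * re3 + P.W_ee_REU_CA1 * a1 * rreu + P.I_CA1;
  ds[4] = -Vi1 / P.tau_i_CA1 + P.W_ei_CA1 * re1 + P.W_ei_CA3_CA1 * re3
        - P.W_ii_CA1 * ri1 + P.W_ei_REU_CA1 * rreu;
  ds[5] = -c1 / P.tau_c
        + P.dc_CA1 * (P.Wc_CA3_CA1 * re3 + P.Wc_REU_CA1 * rreu);

  // CX (Eqs. 10-12)
  ds[6] = -Vex / P.tau_e_CX + P.W_ee_CX * ax * rex - P.W_ie_CX * rix
        + P.W_ee_CXp_CX * ax * rep + P.W_ee_REU_CX * ax * rreu
        + P.W_ee_CA1_CX * ax * re1 + P.I_CX;
  ds[7] = -cx / P.tau_c
        + P.dc_CX * (P.Wc_CX * rex + P.Wc_CXp_CX * rep
                     + P.Wc_REU_CX * rreu + P.Wc_CA1_CX * re1);
  ds[8] = -Vix / P.tau_i_CX - P.W_ii_CX * rix + P.W_ei_CX * rex
        + P.W_ei_CXp_CX * rep + P.W_ei_REU_CX * rreu + P.W_ei_CA1_CX * re1;

  // CX' (Eqs. 13-15; structural mirror of CX with MD input)
  ds[9] = -Vep / P.tau_e_CXp + P.W_ee_CXp * ap * rep - P.W_ie_CXp * rip
        + P.W_ee_CX_CXp * ap * rex + P.W_ee_MD_CXp * ap * rmd + P.I_CXp;
  ds[10] = -cp / P.tau_c
         + P.dc_CXp * (P.Wc_CXp * rep + P.Wc_CX_CXp * rex + P.Wc_MD_CXp * rmd);
  ds[11] = -Vip / P.tau_i_CXp + P.W_ei_CXp * rep - P.W_ii_CXp * rip
         + P.W_ei_CX_CXp * rex + P.W_ei_MD_CXp * rmd;

  // MD (Eqs. 16-17)
  ds[12] = -Vmd / P.tau_MD
         - P.fmax_MD / (1.0 + std::exp((ue + P.fth_MD) / P.q_MD))
         - P.W_ie_TRN_MD * rtrn + P.W_ee_CXp_MD * rep + P.I_MD;
  const double be = (Vmd > P.Vb_MD) ? 0.0 : P.b_MD;
  ds[13] = (be - ue) / P.tau_u_MD;

  // TRN (Eqs. 18-19)
  ds[14] = -Vtrn / P.tau_TRN
         - P.fmax_TRN / (1.0 + std::exp((ui + P.fth_TRN) / P.q_TRN))
         - P.W_ii_TRN * rtrn + P.W_ei_MD_TRN * rmd
         + P.W_ei_CXp_TRN * rep + P.I_TRN;
  const double bi = (Vtrn > P.Vb_TRN) ? 0.0 : P.b_TRN;
  ds[15] = (bi - ui) / P.tau_u_TRN;

  // REU (Eq. 20); alpha.CA1_REU folded into W.ee.CA1_REU upstream
  ds[16] = -Vreu / P.tau_REU - P.W_ie_TRN_REU * rtrn
         + P.W_ee_CX_REU * rex + P.W_ee_CA1_REU * re1 + P.I_REU;
}

static const char* STATE_NAMES[17] = {
  "Ve_CA3", "Vi_CA3", "c_CA3", "Ve_CA1", "Vi_CA1", "c_CA1",
  "Ve_CX", "c_CX", "Vi_CX", "Ve_CXp", "c_CXp", "Vi_CXp",
  "Ve_MD", "u_e", "Vi_TRN", "u_i", "Ve_REU"};

// [[Rcpp::export(name = ".model_deriv_cpp")]]
NumericVector model_deriv_cpp(NumericVector state, List pars) {
  if (state.size() != 17) stop("state must have 17 elements");
  Pars P = fill_pars(pars);
  NumericVector out(17);
  deriv(REAL(state), REAL(out), P);
  out.names() = CharacterVector(STATE_NAMES, STATE_NAMES + 17);
  return out;
}

// RK4 integration. Returns (n_keep x 17) matrix sampled every `thin` steps
// after discarding `n_burn` steps. Optional additive Gaussian input with
// standard deviation noise_sd * sqrt(dt) on the cortical and CA3
// membrane-potential states (background synaptic bombardment of the
// forebrain populations; thalamus, reuniens and CA1 receive their
// fluctuations through the connectivity). Uses R's RNG so set.seed()
// in R controls it.
// [[Rcpp::export(name = ".simulate_cpp")]]
NumericMatrix simulate_cpp(NumericVector state0, List pars, double dt,
                           int n_steps, int n_burn, int thin,
                           double noise_sd) {
  if (state0.size() != 17) stop("state0 must have 17 elements");
  Pars P = fill_pars(pars);
  double s[17], k1[17], k2[17], k3[17], k4[17], tmp[17];
  for (int i = 0; i < 17; ++i) s[i] = state0[i];
  const int n_keep = (n_steps - n_burn + thin - 1) / thin;
  NumericMatrix out(n_keep, 17);
  // noise targets: CA3 and cortical E/I membrane potentials
  const int vidx[6] = {0, 1, 6, 8, 9, 11};
  RNGScope scope;
  int row = 0;
  for (int step = 0; step < n_steps; ++step) {
    deriv(s, k1, P);
    for (int i = 0; i < 17; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
    deriv(tmp, k2, P);
    for (int i = 0; i < 17; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
    deriv(tmp, k3, P);
    for (int i = 0; i < 17; ++i) tmp[i] = s[i] + dt * k3[i];
    deriv(tmp, k4, P);
    for (int i = 0; i < 17; ++i)
      s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (noise_sd > 0.0) {
      double sd = noise_sd * std::sqrt(dt);
      for (int j = 0; j < 6; ++j) s[vidx[j]] += R::rnorm(0.0, sd);
    }
    // clamp burst variables at 0 from above (D5)
    if (s[13] > 0.0) s[13] = 0.0;
    if (s[15] > 0.0) s[15] = 0.0;
    if (step >= n_burn && ((step - n_burn) % thin) == 0) {
      for (int i = 0; i < 17; ++i) out(row, i) = s[i];
      ++row;
    }
    if ((step & 1023) == 0) {
      for (int i = 0; i < 17; ++i) {
        if (!std::isfinite(s[i]))
          stop("non-finite state: variable %s at t = %.3f s",
               STATE_NAMES[i], (step + 1) * dt);
      }
    }
  }
  colnames(out) = CharacterVector(STATE_NAMES, STATE_NAMES + 17);
  return out;
}
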