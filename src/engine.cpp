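// Fixed-step forward-Euler engine for the spine model. Mirrors the R-level
// reference functions in R/biophysics.R and R/cascade.R exactly; the test
// suite asserts trajectory agreement between the two.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96487.0;
static const double GASCONST = 8.314;

static inline double opioid_sat(double Op, int printed_form) {
  if (printed_form) return 1.0 / (1.0 + std::pow(0.1 * Op, 1.2));
  if (Op <= 0.0) return 0.0;
  double x = std::pow(Op, 1.2);
  return x / (x + std::pow(0.1, 1.2));
}

// [[Rcpp::export(name = ".engine_cpp")]]
List engine_cpp(NumericVector par, double dt, int n_steps, int stride) {
  // --- unpack (order fixed by .flatten_params in R/simulate.R) ---
  int k = 0;
  const double tau_post = par[k++], V_rest = par[k++], Rm = par[k++];
  const double gA0 = par[k++], V_AMPA = par[k++], alphaA = par[k++],
               betaA = par[k++], P_half = par[k++], k_half = par[k++];
  const double V_NMDA = par[k++], alphaN = par[k++], betaN = par[k++],
               g_VI = par[k++], tau_g = par[k++], k_slope = par[k++],
               V0 = par[k++], Mg_out = par[k++], k0 = par[k++],
               zchg = par[k++], delta = par[k++], Temp = par[k++];
  const double gR_pS = par[k++], V_R = par[k++];
  const int    Nch = (int) par[k++];
  const double Vh_open = par[k++], k_open = par[k++];
  const double eta = par[k++], gamma = par[k++], Zca = par[k++],
               Vspine = par[k++], bt = par[k++], Kendo = par[k++],
               Ks = par[k++], c_rest = par[k++];
  const double ep0 = par[k++], I0 = par[k++], k3 = par[k++], k4 = par[k++],
               vCaN = par[k++], vPKA = par[k++], KH2 = par[k++],
               k1 = par[k++], KH1 = par[k++], KM = par[k++], k2 = par[k++],
               camkii_total = par[k++];
  const double Op = par[k++];
  const int cond_on = (int) par[k++], mg_on = (int) par[k++],
            vgcc_on = (int) par[k++];
  const double nmdar_coeff = par[k++], vgcc_coeff = par[k++];
  const int printed_form = (int) par[k++];
  const double freq = par[k++], width = par[k++], amp = par[k++],
               dur_ms = par[k++] * 1000.0;

  // --- precomputation ---
  const double period = 1000.0 / freq;
  const double s_cond = cond_on ? opioid_sat(Op, printed_form) : 0.0;
  const double u_op = nmdar_coeff * 0.15 * s_cond;
  const double s_mg = opioid_sat(mg_on ? Op : 0.0, printed_form);
  const double k_eff = k0 + 15.58 * s_mg;
  const double delta_eff = delta + 0.1 * s_mg;
  const double FRT = FARADAY * 1e-3 / (GASCONST * Temp);   // per mV
  const double mgslope = zchg * delta_eff * FRT;
  const double kappa = 1e-12 / (Zca * FARADAY * Vspine * 1e-15) * 1e6 * 1e-3;
  const double gR_nS = gR_pS * 1e-3;
  const double Ks_ms = Ks * 1e-3;
  const bool draw_vgcc = vgcc_on && vgcc_coeff > 0.0 && Nch > 0;
  static const double ladder[9] = {1.0, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8,
                                   1.0};

  // --- initial state ---
  double V = V_rest, mA = 0.0, mN = 0.0, gVD = 0.0, c = c_rest;
  double P[11];
  P[0] = camkii_total;
  for (int i = 1; i < 11; ++i) P[i] = 0.0;
  double h3r = std::pow(c_rest / KH2, 3.0);
  double H3r = h3r / (1.0 + h3r);
  double I1P = vPKA * I0 / (vCaN * H3r);
  double ep = k4 * ep0 / (k4 + k3 * I1P);
  double Ph = 0.0;
  double gAMPA = gA0 * (1.0 + 1.0 / (1.0 + std::exp(-(Ph - P_half) / k_half)));

  // --- recording ---
  int n_rec = n_steps / stride + 1 + ((n_steps % stride) ? 1 : 0);
  NumericMatrix rec(n_rec, 14);
  int row = 0;
  double peak_ph = 0.0;
  long breach_steps = 0;

  RNGScope rngscope;

  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    // stimulus (manual modulo: piecewise-constant periodic pulse train)
    double phase = t - period * std::floor(t / period);
    double g_pre = (phase < width && t < dur_ms) ? amp : 0.0;
    // Mg block and conductances
    double Mg = 1.0 / (1.0 + Mg_out * std::exp(-mgslope * V) / k_eff);
    double gN = g_VI + u_op + gVD;
    // currents (incl. stochastic VGCC draw)
    double I_A = gAMPA * mA * (V - V_AMPA);
    double I_N = gN * mN * Mg * (V - V_NMDA);
    double I_R = 0.0;
    if (draw_vgcc) {
      double Popen = 1.0 / (1.0 + std::exp(-(V - Vh_open) / k_open));
      double n_open = R::rbinom((double) Nch, Popen);
      I_R = vgcc_coeff * gR_nS * n_open * (V - V_R);
    }

    if (i % stride == 0 || i == n_steps) {
      rec(row, 0) = t;     rec(row, 1) = g_pre;  rec(row, 2) = V;
      rec(row, 3) = I_A;   rec(row, 4) = I_N;    rec(row, 5) = I_R;
      rec(row, 6) = c;     rec(row, 7) = Ph;     rec(row, 8) = gAMPA;
      rec(row, 9) = ep;    rec(row, 10) = I1P;   rec(row, 11) = mA;
      rec(row, 12) = mN;   rec(row, 13) = gVD;
      ++row;
    }
    if (i == n_steps) break;

    // membrane & calcium derivatives
    double I_syn = -(I_A + I_N);
    double dV = (-(V - V_rest) + Rm * I_syn * 1e-3) / tau_post;
    double dmA = alphaA * g_pre * (1.0 - mA) - betaA * mA;
    double dmN = alphaN * g_pre * (1.0 - mN) - betaN * mN;
    double g_inf = k_slope * (V - V0);
    if (g_inf < 0.0) g_inf = 0.0;
    double dgVD = (g_inf - gVD) / tau_g;
    double theta = bt * Kendo / ((Kendo + c) * (Kendo + c));
    double flux = -(eta * I_A + gamma * I_N + I_R) * kappa
                  - Ks_ms * (c - c_rest);
    double dc = flux / (1.0 + theta);

    // cascade derivatives (per s)
    double r = c / KH1;
    double r2 = r * r;
    double r4 = r2 * r2;
    double r8 = r4 * r4;
    double denom = 1.0 + r4;
    double v1 = 10.0 * k1 * r8 * P[0] / (denom * denom);
    double v2 = k1 * r4 / denom;
    double weighted = 0.0;
    for (int j = 1; j < 11; ++j) weighted += j * P[j];
    double v3 = k2 * ep / (KM + weighted);
    double fwd[10], bwd[10];
    fwd[0] = v1;
    for (int j = 1; j < 10; ++j) fwd[j] = ladder[j - 1] * v2 * P[j];
    for (int j = 0; j < 10; ++j) bwd[j] = (j + 1) * v3 * P[j + 1];
    double dP[11];
    dP[0] = -fwd[0] + bwd[0];
    for (int j = 1; j < 10; ++j)
      dP[j] = fwd[j - 1] - bwd[j - 1] - fwd[j] + bwd[j];
    dP[10] = fwd[9] - bwd[9];
    double mass = -k3 * I1P * ep + k4 * (ep0 - ep);
    double h3 = std::pow(c / KH2, 3.0);
    double H3 = h3 / (1.0 + h3);
    double dI1P = mass + vPKA * I0 - vCaN * H3 * I1P;

    // Euler update (cascade rates are per second -> 1e-3 per ms)
    V += dt * dV;
    mA += dt * dmA;
    mN += dt * dmN;
    gVD += dt * dgVD;
    c += dt * dc;
    for (int j = 0; j < 11; ++j) P[j] += dt * 1e-3 * dP[j];
    ep += dt * 1e-3 * mass;
    I1P += dt * 1e-3 * dI1P;

    // clamp to invariant ranges, counting breached steps
    bool breached = false;
    if (mA < 0.0) { mA = 0.0; breached = true; }
    if (mA > 1.0) { mA = 1.0; breached = true; }
    if (mN < 0.0) { mN = 0.0; breached = true; }
    if (mN > 1.0) { mN = 1.0; breached = true; }
    if (gVD < 0.0) { gVD = 0.0; breached = true; }
    if (c < 0.0) { c = 0.0; breached = true; }
    if (ep < 0.0) { ep = 0.0; breached = true; }
    if (ep > ep0) { ep = ep0; breached = true; }
    if (I1P < 0.0) { I1P = 0.0; breached = true; }
    for (int j = 0; j < 11; ++j)
      if (P[j] < 0.0) { P[j] = 0.0; breached = true; }
    if (breached) ++breach_steps;

    if (!std::isfinite(V))
      stop("integration failure: non-finite membrane potential at t = %f ms",
           t + dt);
    if (!std::isfinite(c))
      stop("integration failure: non-finite calcium at t = %f ms", t + dt);

    // refresh readout and AMPAR conductance from the updated cascade state
    Ph = 0.0;
    for (int j = 1; j < 11; ++j) Ph += P[j];
    if (Ph > peak_ph) peak_ph = Ph;
    gAMPA = gA0 * (1.0 + 1.0 / (1.0 + std::exp(-(Ph - P_half) / k_half)));
  }

  NumericVector Pout(11);
  for (int j = 0; j < 11; ++j) Pout[j] = P[j];
  return List::create(
    _["traces"] = rec,
    _["peak_ph"] = peak_ph,
    _["breach_steps"] = (double) breach_steps,
    _["final"] = List::create(_["V"] = V, _["m_AMPA"] = mA, _["m_NMDA"] = mN,
                              _["g_VD"] = gVD, _["c_post"] = c,
                              _["g_AMPA"] = gAMPA, _["P"] = Pout,
                              _["ep"] = ep, _["I1P"] = I1P));
}
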