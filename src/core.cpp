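// Numerical core: blood gas chemistry and the multi-compartment V/Q lung model.
//
// Units follow blood-gas convention throughout: partial pressures in mm Hg,
// contents in mL/dL (STPD), hemoglobin in g/dL, flows in L/min, VO2/VCO2 in
// mL/min STPD.  The factor 10 converts mL/dL to mL/L in Fick arithmetic; the
// factor 0.863 converts (L/min BTPS x mm Hg) to mL/min STPD in alveolar gas
// transport.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Consts {
  double hufner;   // mL O2 per g Hb
  double aO2;      // O2 solubility, mL/dL/mmHg
  double sCO2;     // CO2 solubility, mmol/L/mmHg
  double PB;       // barometric pressure, mmHg
  double PH2O;     // water vapor pressure at 37C, mmHg
  double sevP50;   // P50 of the standard dissociation curve, mmHg
};

Consts make_consts(const NumericVector& k) {
  Consts K;
  K.hufner = k["hufner"];
  K.aO2    = k["alpha_o2"];
  K.sCO2   = k["s_co2"];
  K.PB     = k["pb"];
  K.PH2O   = k["ph2o"];
  K.sevP50 = 26.86;
  return K;
}

struct Blood { double Hb, P50st, BE; };

const double KCONV = 0.863;   // mmHg * L(BTPS) -> mL STPD conversion
const double LN10  = 2.302585092994046;

// Severinghaus standard-curve saturation at virtual PO2 x (standard pH 7.40,
// PCO2 40): S = (x^3 + 150 x) / (x^3 + 150 x + 23400), P50 = 26.86 mmHg.
inline double sev_sat(double x) {
  if (x <= 0.0) return 0.0;
  double t = x * x * x + 150.0 * x;
  return t / (t + 23400.0);
}

// Inverse of sev_sat: virtual PO2 giving saturation S.
inline double sev_x(double S) {
  if (S <= 0.0) return 0.0;
  if (S >= 1.0) S = 1.0 - 1e-12;
  double A = 23400.0 * S / (1.0 - S);
  double x = std::cbrt(A);
  for (int i = 0; i < 80; ++i) {
    double f  = x * x * x + 150.0 * x - A;
    double fp = 3.0 * x * x + 150.0;
    double d  = f / fp;
    x -= d;
    if (std::fabs(d) < 1e-13 * std::max(1.0, std::fabs(x))) break;
  }
  return x;
}

// In-vivo P50: standard P50 scaled by multiplicative Bohr corrections for pH
// and PCO2 (base excess acts through its effect on pH).
inline double p50_invivo(double pH, double PCO2, double P50st) {
  double pc = std::max(PCO2, 1e-3);
  return P50st * std::pow(10.0, -0.48 * (pH - 7.40) + 0.06 * std::log10(pc / 40.0));
}

inline double odc_sat(double PO2, double pH, double PCO2, const Blood& b, const Consts& K) {
  if (PO2 <= 0.0) return 0.0;
  double p50 = p50_invivo(pH, PCO2, b.P50st);
  return sev_sat(PO2 * K.sevP50 / p50);
}

inline double odc_po2(double S, double pH, double PCO2, const Blood& b, const Consts& K) {
  double p50 = p50_invivo(pH, PCO2, b.P50st);
  return sev_x(S) * p50 / K.sevP50;
}

inline double o2ct(double PO2, double S, const Blood& b, const Consts& K) {
  return K.hufner * b.Hb * S + K.aO2 * PO2;
}

inline double hco3_f(double PCO2, double pH, const Consts& K) {
  return K.sCO2 * PCO2 * std::pow(10.0, pH - 6.105);
}

// Van Slyke buffer relation (whole blood, Hb in g/dL).
inline double vanslyke_be(double pH, double PCO2, const Blood& b, const Consts& K) {
  double h = hco3_f(PCO2, pH, K);
  return (1.0 - 0.0143 * b.Hb) * ((h - 24.4) + (2.3 * b.Hb + 7.7) * (pH - 7.40));
}

// pH from PCO2 and base excess: root of vanslyke_be(pH) = BE (monotone
// increasing in pH), safeguarded Newton on [6.0, 8.4].
inline double ph_solve(double PCO2, const Blood& b, const Consts& K) {
  double lo = 6.0, hi = 8.4;
  double pH = 7.40 - 0.55 * std::log10(std::max(PCO2, 1.0) / 40.0);
  if (pH <= lo) pH = lo + 1e-3;
  if (pH >= hi) pH = hi - 1e-3;
  for (int i = 0; i < 100; ++i) {
    double f = vanslyke_be(pH, PCO2, b, K) - b.BE;
    if (f > 0.0) hi = pH; else lo = pH;
    double fp = (1.0 - 0.0143 * b.Hb) * (hco3_f(PCO2, pH, K) * LN10 + 2.3 * b.Hb + 7.7);
    double nxt = pH - f / fp;
    if (nxt <= lo || nxt >= hi) nxt = 0.5 * (lo + hi);
    if (std::fabs(nxt - pH) < 1e-12) { pH = nxt; break; }
    pH = nxt;
    if (hi - lo < 1e-12) break;
  }
  return pH;
}

// Whole-blood CO2 content (dissolved + bicarbonate + Haldane-dependent
// carriage), Douglas-style plasma content with a hemoglobin/saturation
// correction; mmol/L converted to mL/dL via 22.26 mL/mmol.
inline double co2ct(double PCO2, double pH, double S, const Blood& b, const Consts& K) {
  if (PCO2 <= 0.0) return 0.0;
  double plasma = K.sCO2 * PCO2 * (1.0 + std::pow(10.0, pH - 6.105));
  double fac = 1.0 - 0.0289 * b.Hb / ((3.352 - 0.456 * S) * (8.142 - pH));
  return plasma * fac * 2.226;
}

// PO2 from O2 content at given pH/PCO2 (monotone), safeguarded Newton.
inline double po2_from_o2ct(double ct, double pH, double PCO2, const Blood& b, const Consts& K) {
  if (ct <= 0.0) return 0.0;
  double lo = 0.0, hi = 2500.0;
  double cap = K.hufner * b.Hb;
  double S0 = std::min(ct / std::max(cap, 1e-9), 0.999);
  double x = std::max(1.0, odc_po2(S0, pH, PCO2, b, K));
  for (int i = 0; i < 100; ++i) {
    double f = o2ct(x, odc_sat(x, pH, PCO2, b, K), b, K) - ct;
    if (f > 0.0) hi = x; else lo = x;
    double h = std::max(1e-4, 1e-6 * x);
    double f2 = o2ct(x + h, odc_sat(x + h, pH, PCO2, b, K), b, K) - ct;
    double fp = (f2 - f) / h;
    double nxt = (fp > 0.0) ? x - f / fp : 0.5 * (lo + hi);
    if (nxt <= lo || nxt >= hi) nxt = 0.5 * (lo + hi);
    if (std::fabs(nxt - x) < 1e-10 * std::max(1.0, x)) { x = nxt; break; }
    x = nxt;
    if (hi - lo < 1e-11) break;
  }
  return x;
}

// PCO2 from CO2 content at given saturation, with pH coupled through the Van
// Slyke relation at fixed base excess (monotone in PCO2).
inline double pco2_from_co2ct(double ct, double S, const Blood& b, const Consts& K) {
  if (ct <= 0.0) return 0.0;
  double lo = 1e-6, hi = 900.0;
  double x = 40.0;
  for (int i = 0; i < 100; ++i) {
    double pH = ph_solve(x, b, K);
    double f = co2ct(x, pH, S, b, K) - ct;
    if (f > 0.0) hi = x; else lo = x;
    double h = std::max(1e-4, 1e-6 * x);
    double f2 = co2ct(x + h, ph_solve(x + h, b, K), S, b, K) - ct;
    double fp = (f2 - f) / h;
    double nxt = (fp > 0.0) ? x - f / fp : 0.5 * (lo + hi);
    if (nxt <= lo || nxt >= hi) nxt = 0.5 * (lo + hi);
    if (std::fabs(nxt - x) < 1e-11 * std::max(1.0, x)) { x = nxt; break; }
    x = nxt;
    if (hi - lo < 1e-11) break;
  }
  return x;
}

struct GasState { double PO2, PCO2, pH, S; };

// Invert (O2 content, CO2 content) -> full blood gas state, fixed point on
// saturation (weak Haldane coupling makes this a contraction).
inline GasState blood_from_contents(double tO2, double tCO2, const Blood& b, const Consts& K) {
  GasState g;
  double S = 0.7;
  for (int i = 0; i < 80; ++i) {
    double PCO2 = pco2_from_co2ct(tCO2, S, b, K);
    double pH = ph_solve(PCO2, b, K);
    double PO2 = po2_from_o2ct(tO2, pH, PCO2, b, K);
    double S2 = odc_sat(PO2, pH, PCO2, b, K);
    g.PO2 = PO2; g.PCO2 = PCO2; g.pH = pH; g.S = S2;
    if (std::fabs(S2 - S) < 1e-12) break;
    S = S2;
  }
  return g;
}

struct CompOut {
  double PAO2, PACO2, pH, S, CcO2, CcCO2;
  bool ok;
};

// Steady-state alveolar-capillary equilibration of one ventilated compartment.
// Unknowns (PAO2, PACO2); N2 closes total alveolar pressure to PB - PH2O and
// sets the inspired/expired ventilation ratio VI/VE = PAN2/PIN2.
// Solved as nested safeguarded Newton: outer on PACO2 (CO2 balance, monotone
// increasing), inner on PAO2 (O2 balance, monotone decreasing).
inline CompOut comp_solve(double vq, double PIO2, double PIN2,
                          double CvO2, double CvCO2,
                          const Blood& b, const Consts& K,
                          double paco2_init) {
  CompOut out; out.ok = false;
  const double Ptot = K.PB - K.PH2O;

  double pao2_warm = -1.0;

  // inner O2 balance at fixed PACO2 (pH precomputed); returns PAO2 and fluxes
  auto inner = [&](double PACO2, double pH, double& PAO2sol, double& S_out,
                   double& CcO2_out) {
    double lo = 0.0, hi = std::max(1e-9, Ptot - PACO2 - 1e-9);
    double x = (pao2_warm > 0.0 && pao2_warm < hi) ? pao2_warm : std::min(0.75 * hi, 100.0);
    double f = 0.0;
    for (int i = 0; i < 90; ++i) {
      double PAN2 = Ptot - x - PACO2;
      double S = odc_sat(x, pH, PACO2, b, K);
      double Cc = o2ct(x, S, b, K);
      f = vq * (PIO2 * PAN2 / PIN2 - x) / KCONV - 10.0 * (Cc - CvO2);
      if (f > 0.0) lo = x; else hi = x;
      double h = std::max(1e-5, 1e-6 * x);
      double x2 = std::min(x + h, Ptot - PACO2 - 1e-10);
      double PAN2b = Ptot - x2 - PACO2;
      double S2 = odc_sat(x2, pH, PACO2, b, K);
      double f2 = vq * (PIO2 * PAN2b / PIN2 - x2) / KCONV - 10.0 * (o2ct(x2, S2, b, K) - CvO2);
      double fp = (f2 - f) / (x2 - x);
      double nxt = (fp < 0.0) ? x - f / fp : 0.5 * (lo + hi);
      if (nxt <= lo || nxt >= hi) nxt = 0.5 * (lo + hi);
      if (std::fabs(nxt - x) < 1e-10 * std::max(1.0, x)) { x = nxt; break; }
      x = nxt;
      if (hi - lo < 1e-11) break;
    }
    double S = odc_sat(x, pH, PACO2, b, K);
    PAO2sol = x; S_out = S; CcO2_out = o2ct(x, S, b, K);
    pao2_warm = x;
  };

  // outer CO2 balance
  double hi_guess = pco2_from_co2ct(CvCO2, 1.0, b, K) + 2.0;
  double lo = 1e-8, hi = std::min(hi_guess, Ptot - 1.0);
  double x = (paco2_init > lo && paco2_init < hi) ? paco2_init : std::min(45.0 / (1.0 + vq) + 20.0, hi - 1e-6);
  double PAO2 = 0.0, S = 0.0, CcO2 = 0.0, pH = 7.4, G = 0.0;

  auto eval = [&](double PACO2) {
    pH = ph_solve(PACO2, b, K);
    inner(PACO2, pH, PAO2, S, CcO2);
    double Cc2 = co2ct(PACO2, pH, S, b, K);
    return vq * PACO2 / KCONV - 10.0 * (CvCO2 - Cc2);
  };

  bool converged = false;
  for (int i = 0; i < 90; ++i) {
    G = eval(x);
    if (std::fabs(G) < 1e-9 * std::max(1.0, vq)) { converged = true; break; }
    if (G > 0.0) hi = x; else lo = x;
    double h = std::max(1e-6, 1e-6 * x);
    double G2 = eval(std::min(x + h, Ptot - 0.5));
    double fp = (G2 - G) / h;
    double nxt = (fp > 0.0) ? x - G / fp : 0.5 * (lo + hi);
    if (nxt <= lo || nxt >= hi) nxt = 0.5 * (lo + hi);
    if (std::fabs(nxt - x) < 1e-11 * std::max(1.0, x)) { x = nxt; converged = true; break; }
    x = nxt;
    if (hi - lo < 1e-12) { converged = true; break; }
  }
  G = eval(x);

  out.PACO2 = x; out.PAO2 = PAO2; out.pH = pH; out.S = S;
  out.CcO2 = CcO2; out.CcCO2 = co2ct(x, pH, S, b, K);
  out.ok = converged || std::fabs(G) < 1e-6 * std::max(1.0, vq);
  return out;
}

// Log-normal perfusion grid: n log-equally-spaced V/Q centers spanning
// meanVQ * exp(+/- span*logSD), bin-integrated weights of the log-normal
// whose perfusion-weighted (arithmetic) mean V/Q equals meanVQ.
inline void perf_grid(double meanVQ, double logSD, int n, double span,
                      std::vector<double>& vq, std::vector<double>& w) {
  vq.resize(n); w.resize(n);
  double mu = std::log(meanVQ) - 0.5 * logSD * logSD;
  // half-width scales with the dispersion but never collapses below 1.2 log
  // units, so nearly-degenerate distributions concentrate into single bins
  double half = std::max(span * logSD, 1.2);
  double c0 = std::log(meanVQ) - half;
  double h = (n > 1) ? 2.0 * half / (n - 1) : 0.0;
  auto Phi = [](double z) { return 0.5 * std::erfc(-z / M_SQRT2); };
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double c = c0 + h * i;
    vq[i] = std::exp(c);
    double elo = c - 0.5 * h, ehi = c + 0.5 * h;
    w[i] = Phi((ehi - mu) / logSD) - Phi((elo - mu) / logSD);
    tot += w[i];
  }
  for (int i = 0; i < n; ++i) w[i] /= tot;
}

struct Ctrl {
  int ncomp; double span, damp, tol; int maxit;
};

Ctrl make_ctrl(const List& c) {
  Ctrl ct;
  ct.ncomp = as<int>(c["n_compartments"]);
  ct.span  = as<double>(c["grid_span"]);
  ct.damp  = as<double>(c["damping"]);
  ct.tol   = as<double>(c["venous_tol"]);
  ct.maxit = as<int>(c["max_iter"]);
  return ct;
}

struct FwdState {
  std::vector<double> paco2;   // warm starts per compartment
  double CvO2 = -1.0, CvCO2 = -1.0;
};

// Whole-lung forward run: fixed-point on mixed venous contents with Fick
// closure.  Returns everything needed to assemble a bedside record.
List fwd_core(double shunt, double logSD, double meanVQ,
              double VCO2, double Rq, double Hb, double P50st, double BE,
              double CO, double FiO2, const Consts& K, const Ctrl& C,
              FwdState* st) {
  Blood b; b.Hb = Hb; b.P50st = P50st; b.BE = BE;
  const double Ptot = K.PB - K.PH2O;
  const double PIO2 = FiO2 * Ptot;
  const double PIN2 = Ptot - PIO2;
  const double VO2 = VCO2 / Rq;

  std::vector<double> vq, w;
  perf_grid(meanVQ, logSD, C.ncomp, C.span, vq, w);
  // q fractions of total pulmonary blood flow
  std::vector<double> q(C.ncomp);
  for (int i = 0; i < C.ncomp; ++i) q[i] = w[i] * (1.0 - shunt);

  double CvO2, CvCO2;
  if (st && st->CvO2 > 0.0) { CvO2 = st->CvO2; CvCO2 = st->CvCO2; }
  else {
    double Sa0 = 0.95;
    double Ca0 = K.hufner * Hb * Sa0 + K.aO2 * 80.0;
    CvO2 = std::max(1.0, Ca0 - VO2 / (10.0 * CO));
    CvCO2 = co2ct(46.0, ph_solve(46.0, b, K), 0.75, b, K);
  }
  std::vector<double> warm(C.ncomp, -1.0);
  if (st && (int)st->paco2.size() == C.ncomp) warm = st->paco2;

  std::vector<CompOut> comp(C.ncomp);
  double CaO2 = 0.0, CaCO2 = 0.0;
  bool feasible = true, converged = false;
  int it = 0;
  double delta = NA_REAL;
  // residual history for secant acceleration of the damped fixed point
  double pvO2 = NA_REAL, pvCO2 = NA_REAL, pfO2 = NA_REAL, pfCO2 = NA_REAL;

  for (it = 1; it <= C.maxit; ++it) {
    CaO2 = shunt * CvO2; CaCO2 = shunt * CvCO2;
    bool allok = true;
    for (int i = 0; i < C.ncomp; ++i) {
      comp[i] = comp_solve(vq[i], PIO2, PIN2, CvO2, CvCO2, b, K, warm[i]);
      warm[i] = comp[i].PACO2;
      allok = allok && comp[i].ok;
      CaO2 += q[i] * comp[i].CcO2;
      CaCO2 += q[i] * comp[i].CcCO2;
    }
    double CvO2_t = CaO2 - VO2 / (10.0 * CO);
    double CvCO2_t = CaCO2 + VCO2 / (10.0 * CO);
    if (CvO2_t <= 0.02) { feasible = false; break; }
    double fO2 = CvO2_t - CvO2, fCO2 = CvCO2_t - CvCO2;
    delta = std::max(std::fabs(fO2), std::fabs(fCO2));
    if (delta < C.tol && allok) { converged = true; break; }
    // per-component secant step on the venous residual once history exists;
    // damped fixed-point step otherwise (and as fallback for unsafe steps)
    double nO2 = CvO2 + C.damp * fO2, nCO2 = CvCO2 + C.damp * fCO2;
    if (it > 2) {
      double dO2 = fO2 - pfO2, dCO2 = fCO2 - pfCO2;
      if (std::fabs(dO2) > 1e-14) {
        double s = CvO2 - fO2 * (CvO2 - pvO2) / dO2;
        if (std::fabs(s - CvO2) < 10.0 * std::fabs(fO2) + 1.0) nO2 = s;
      }
      if (std::fabs(dCO2) > 1e-14) {
        double s = CvCO2 - fCO2 * (CvCO2 - pvCO2) / dCO2;
        if (std::fabs(s - CvCO2) < 10.0 * std::fabs(fCO2) + 1.0) nCO2 = s;
      }
    }
    pvO2 = CvO2; pvCO2 = CvCO2; pfO2 = fO2; pfCO2 = fCO2;
    CvO2 = nO2; CvCO2 = nCO2;
  }

  if (st) { st->paco2 = warm; st->CvO2 = CvO2; st->CvCO2 = CvCO2; }

  if (!feasible) {
    return List::create(_["feasible"] = false, _["converged"] = false,
                        _["iterations"] = it);
  }

  // arterial and mixed venous gas states from contents
  GasState art = blood_from_contents(CaO2, CaCO2, b, K);
  GasState ven = blood_from_contents(CvO2, CvCO2, b, K);

  // ventilation-weighted mean alveolar PCO2 (expired alveolar ventilation)
  double vtot = 0.0, mpaco2 = 0.0;
  for (int i = 0; i < C.ncomp; ++i) { vtot += q[i] * vq[i]; mpaco2 += q[i] * vq[i] * comp[i].PACO2; }
  mpaco2 /= vtot;

  // whole-lung conservation diagnostics (mL/min)
  double upt = 0.0, out_co2 = 0.0;
  for (int i = 0; i < C.ncomp; ++i) {
    upt += CO * q[i] * 10.0 * (comp[i].CcO2 - CvO2);
    out_co2 += CO * q[i] * 10.0 * (CvCO2 - comp[i].CcCO2);
  }

  // venous admixture via the ideal-compartment construction: ideal alveolar
  // PO2 from the alveolar gas equation at arterial PCO2 and scenario R
  double pao2_ideal = PIO2 - art.PCO2 * (FiO2 + (1.0 - FiO2) / Rq);
  pao2_ideal = std::max(pao2_ideal, 1.0);
  double ph_id = ph_solve(art.PCO2, b, K);
  double S_id = odc_sat(pao2_ideal, ph_id, art.PCO2, b, K);
  double CcO2_id = o2ct(pao2_ideal, S_id, b, K);
  double venad = NA_REAL;
  if (CcO2_id > CvO2) venad = (CcO2_id - CaO2) / (CcO2_id - CvO2);

  NumericMatrix cm(C.ncomp, 9);
  for (int i = 0; i < C.ncomp; ++i) {
    cm(i, 0) = vq[i]; cm(i, 1) = q[i]; cm(i, 2) = q[i] * vq[i] / vtot;
    cm(i, 3) = comp[i].PAO2; cm(i, 4) = comp[i].PACO2;
    cm(i, 5) = Ptot - comp[i].PAO2 - comp[i].PACO2;
    cm(i, 6) = comp[i].CcO2; cm(i, 7) = comp[i].CcCO2; cm(i, 8) = comp[i].S;
  }
  colnames(cm) = CharacterVector::create("vq", "q_frac", "v_frac", "pao2",
            "paco2", "pan2", "cc_o2", "cc_co2", "so2");

  return List::create(
    _["feasible"] = true, _["converged"] = converged, _["iterations"] = it,
    _["delta"] = delta,
    _["fio2"] = FiO2,
    _["pao2"] = art.PO2, _["paco2"] = art.PCO2, _["ph"] = art.pH,
    _["sao2"] = art.S, _["cao2"] = CaO2, _["caco2"] = CaCO2,
    _["pvo2"] = ven.PO2, _["pvco2"] = ven.PCO2, _["svo2"] = ven.S,
    _["cvo2"] = CvO2, _["cvco2"] = CvCO2,
    _["mean_paco2"] = mpaco2,
    _["venad"] = venad, _["low_vq"] = venad - shunt,
    _["pao2_ideal"] = pao2_ideal, _["cc_o2_ideal"] = CcO2_id,
    _["o2_uptake"] = upt, _["co2_output"] = out_co2,
    _["va_total"] = CO * vtot,
    _["compartments"] = cm);
}

} // namespace

// [[Rcpp::export]]
double cpp_odc_sat(double po2, double ph, double pco2, double p50st, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = 15.0; b.P50st = p50st; b.BE = 0.0;
  return odc_sat(po2, ph, pco2, b, K);
}

// [[Rcpp::export]]
double cpp_odc_po2(double sat, double ph, double pco2, double p50st, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = 15.0; b.P50st = p50st; b.BE = 0.0;
  return odc_po2(sat, ph, pco2, b, K);
}

// [[Rcpp::export]]
double cpp_o2_content(double po2, double so2, double hb, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = K.sevP50; b.BE = 0.0;
  return o2ct(po2, so2, b, K);
}

// [[Rcpp::export]]
double cpp_co2_content(double pco2, double ph, double so2, double hb, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = K.sevP50; b.BE = 0.0;
  return co2ct(pco2, ph, so2, b, K);
}

// [[Rcpp::export]]
double cpp_vanslyke_be(double ph, double pco2, double hb, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = K.sevP50; b.BE = 0.0;
  return vanslyke_be(ph, pco2, b, K);
}

// [[Rcpp::export]]
double cpp_ph_from(double pco2, double be, double hb, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = K.sevP50; b.BE = be;
  return ph_solve(pco2, b, K);
}

// [[Rcpp::export]]
List cpp_blood_from_contents(double o2ct_t, double co2ct_t, double hb,
                             double p50st, double be, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = p50st; b.BE = be;
  GasState g = blood_from_contents(o2ct_t, co2ct_t, b, K);
  return List::create(_["po2"] = g.PO2, _["pco2"] = g.PCO2,
                      _["ph"] = g.pH, _["so2"] = g.S);
}

// [[Rcpp::export]]
List cpp_perfusion_dist(double mean_vq, double log_sd, int n, double span) {
  std::vector<double> vq, w;
  perf_grid(mean_vq, log_sd, n, span, vq, w);
  return List::create(_["vq"] = wrap(vq), _["q_frac"] = wrap(w));
}

// [[Rcpp::export]]
List cpp_equilibrate(double vq, double fio2, double cv_o2, double cv_co2,
                     double hb, double p50st, double be, NumericVector consts) {
  Consts K = make_consts(consts);
  Blood b; b.Hb = hb; b.P50st = p50st; b.BE = be;
  double Ptot = K.PB - K.PH2O;
  if (vq <= 0.0) {
    GasState g = blood_from_contents(cv_o2, cv_co2, b, K);
    return List::create(_["pao2"] = NA_REAL, _["paco2"] = NA_REAL,
                        _["pan2"] = NA_REAL,
                        _["po2"] = g.PO2, _["pco2"] = g.PCO2,
                        _["ph"] = g.pH, _["so2"] = g.S,
                        _["cc_o2"] = cv_o2, _["cc_co2"] = cv_co2,
                        _["o2_flux_gas"] = 0.0, _["o2_flux_blood"] = 0.0,
                        _["co2_flux_gas"] = 0.0, _["co2_flux_blood"] = 0.0,
                        _["converged"] = true);
  }
  double PIO2 = fio2 * Ptot, PIN2 = Ptot - PIO2;
  CompOut c = comp_solve(vq, PIO2, PIN2, cv_o2, cv_co2, b, K, -1.0);
  double PAN2 = Ptot - c.PAO2 - c.PACO2;
  double o2_gas = vq * (PIO2 * PAN2 / PIN2 - c.PAO2) / KCONV;
  double o2_blood = 10.0 * (c.CcO2 - cv_o2);
  double co2_gas = vq * c.PACO2 / KCONV;
  double co2_blood = 10.0 * (cv_co2 - c.CcCO2);
  return List::create(_["pao2"] = c.PAO2, _["paco2"] = c.PACO2,
                      _["pan2"] = PAN2,
                      _["po2"] = c.PAO2, _["pco2"] = c.PACO2,
                      _["ph"] = c.pH, _["so2"] = c.S,
                      _["cc_o2"] = c.CcO2, _["cc_co2"] = c.CcCO2,
                      _["o2_flux_gas"] = o2_gas, _["o2_flux_blood"] = o2_blood,
                      _["co2_flux_gas"] = co2_gas, _["co2_flux_blood"] = co2_blood,
                      _["converged"] = c.ok);
}

// [[Rcpp::export]]
List cpp_run_forward(double shunt, double log_sd, double mean_vq,
                     double vco2, double r, double hb, double p50st, double be,
                     double co, double fio2, NumericVector consts, List ctrl) {
  Consts K = make_consts(consts);
  Ctrl C = make_ctrl(ctrl);
  return fwd_core(shunt, log_sd, mean_vq, vco2, r, hb, p50st, be, co, fio2, K, C, nullptr);
}

// [[Rcpp::export]]
List cpp_titrate(double shunt, double log_sd, double mean_vq,
                 double vco2, double r, double hb, double p50st, double be,
                 double co, double band_lo, double band_hi, double target,
                 double fio2_lo, double fio2_hi,
                 NumericVector consts, List ctrl) {
  Consts K = make_consts(consts);
  Ctrl C = make_ctrl(ctrl);
  FwdState st;

  double best_fio2 = NA_REAL;
  List best;
  bool have_best = false;

  auto sat_at = [&](double f) -> List {
    List r_ = fwd_core(shunt, log_sd, mean_vq, vco2, r, hb, p50st, be, co, f, K, C, &st);
    if (as<bool>(r_["feasible"])) {
      double s = as<double>(r_["sao2"]);
      if (s >= band_lo && s <= band_hi && !have_best) { /* keep latest in-band */ }
    }
    return r_;
  };

  // a venous-infeasible run at a given FiO2 (arterial content too low to
  // sustain VO2) behaves like saturation below band: search higher FiO2
  List r_lo = sat_at(fio2_lo);
  if (as<bool>(r_lo["feasible"])) {
    double s_lo = as<double>(r_lo["sao2"]);
    if (s_lo > band_hi)
      return List::create(_["feasible"] = false, _["reason"] = "sat_above_band_at_min_fio2");
    if (s_lo >= band_lo)
      return List::create(_["feasible"] = true, _["fio2"] = fio2_lo, _["result"] = r_lo);
  }

  List r_hi = sat_at(fio2_hi);
  if (!as<bool>(r_hi["feasible"]))
    return List::create(_["feasible"] = false, _["reason"] = "infeasible_venous");
  double s_hi = as<double>(r_hi["sao2"]);
  if (s_hi < band_lo)
    return List::create(_["feasible"] = false, _["reason"] = "sat_below_band_at_max_fio2");
  if (s_hi <= target)
    return List::create(_["feasible"] = true, _["fio2"] = fio2_hi, _["result"] = r_hi);

  // bisection toward the target saturation on the monotone SaO2(FiO2) map
  double lo = fio2_lo, hi = fio2_hi;
  for (int i = 0; i < 60; ++i) {
    double mid = 0.5 * (lo + hi);
    List r_mid = sat_at(mid);
    if (!as<bool>(r_mid["feasible"])) { lo = mid; continue; }
    double s = as<double>(r_mid["sao2"]);
    if (s >= band_lo && s <= band_hi) { best_fio2 = mid; best = r_mid; have_best = true; }
    if (std::fabs(s - target) < 5e-4 && s >= band_lo && s <= band_hi) break;
    if (s < target) lo = mid; else hi = mid;
    if (hi - lo < 1e-5) break;
  }
  if (have_best)
    return List::create(_["feasible"] = true, _["fio2"] = best_fio2, _["result"] = best);
  return List::create(_["feasible"] = false, _["reason"] = "band_not_attained");
}
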