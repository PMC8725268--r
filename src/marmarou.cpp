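#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the single-compartment nonlinear
// pressure-volume dynamics
//
//   dP/dt = (ln10 * P / PVI) * ( I(t) - (P - Pr)/Rout ) / 60      [mmHg/s]
//
// with I(t) in mL/min composed of an externally prescribed rate and, where a
// finite per-sample pressure target is given, a proportional controller with
// steady-state feedforward:
//
//   I_ctrl = (target - Pr)/Rout + kp * (target - P),  clamped to [0, imax].
//
// Instantaneous bolus volume additions dV are applied as P -> P * 10^(dV/PVI)
// at the given sample indices (0-based) before that sample is integrated.
// `substeps` internal RK4 steps are taken per output sample.
//
// Returns per-sample pressure P, applied infusion rate Q (mL/min), an `ok`
// flag and the 1-based sample index at which P dropped to or below p0 (model
// domain violation), if any.
// [[Rcpp::export]]
List marmarou_integrate_cpp(double p_init, double pvi, double pr, double rout,
                            double p0, double fs, int substeps,
                            NumericVector inf_rate, NumericVector target,
                            double kp, double imax,
                            IntegerVector bolus_idx, NumericVector bolus_dv) {
  const int n = inf_rate.size();
  NumericVector P(n), Q(n);
  const double ln10 = M_LN10;
  const double h = 1.0 / (fs * substeps);
  double p = p_init;
  int bi = 0;
  bool ok = true;
  int bad_i = -1;

  for (int i = 0; i < n && ok; ++i) {
    while (bi < bolus_idx.size() && bolus_idx[bi] == i) {
      p *= std::pow(10.0, bolus_dv[bi] / pvi);
      ++bi;
    }
    const double tgt = target[i];
    const bool ctrl = R_finite(tgt);
    const double q_ext = inf_rate[i];
    const double ff = ctrl ? (tgt - pr) / rout : 0.0;
    double qsum = 0.0;

    for (int s = 0; s < substeps; ++s) {
      struct {
        double q_ext, ff, kp, imax, tgt, ln10, pvi, pr, rout;
        bool ctrl;
        double rate(double pp) const {
          double q = q_ext;
          if (ctrl) {
            double u = ff + kp * (tgt - pp);
            if (u < 0.0) u = 0.0;
            if (u > imax) u = imax;
            q += u;
          }
          return q;
        }
        double deriv(double pp) const {
          return (ln10 * pp / pvi) * (rate(pp) - (pp - pr) / rout) / 60.0;
        }
      } f = {q_ext, ff, kp, imax, tgt, ln10, pvi, pr, rout, ctrl};

      const double k1 = f.deriv(p);
      const double k2 = f.deriv(p + 0.5 * h * k1);
      const double k3 = f.deriv(p + 0.5 * h * k2);
      const double k4 = f.deriv(p + h * k3);
      p += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      qsum += f.rate(p);
      if (!(p > p0) || !R_finite(p)) {
        ok = false;
        bad_i = i;
        break;
      }
    }
    if (ok) {
      P[i] = p;
      Q[i] = qsum / substeps;
    }
  }
  return List::create(_["p"] = P, _["q"] = Q, _["ok"] = ok,
                      _["bad_index"] = bad_i + 1);
}
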