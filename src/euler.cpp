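#include <Rcpp.h>
using namespace Rcpp;

// Forward Euler integration of the single-sensor activation ODE
//   dP/dt = v * (Pss(V) - P)
//   v = k_on * Pss        if Pss > P   (activation)
//   v = k_off * (1 - Pss) if Pss < P   (deactivation)
// with Pss(V) = (1 / (1 + exp(-alpha * (V - v50))))^(1/4).
// The steady target and the branch are evaluated from the voltage at the
// current sample; P is clipped to [0, 1] after every step to guard against
// overshoot at coarse dt.

// [[Rcpp::export]]
NumericVector cav_sensor_path(NumericVector V, double dt, double v50,
                              double alpha, double kon, double koff,
                              double p0) {
  R_xlen_t n = V.size();
  NumericVector p(n);
  double pa = p0;
  p[0] = pa;
  for (R_xlen_t i = 1; i < n; ++i) {
    double pss = std::pow(1.0 / (1.0 + std::exp(-alpha * (V[i - 1] - v50))),
                          0.25);
    double v = (pss > pa) ? kon * pss : koff * (1.0 - pss);
    pa += dt * v * (pss - pa);
    if (pa < 0.0) pa = 0.0;
    else if (pa > 1.0) pa = 1.0;
    p[i] = pa;
  }
  return p;
}
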