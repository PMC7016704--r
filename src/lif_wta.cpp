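#include <Rcpp.h>
using namespace Rcpp;

// Two-layer spiking simulation: a leaky integrate-and-fire field driven by a
// constant input current (the noisy, scaled saliency map) excites a
// winner-take-all LIF layer; the first WTA unit to cross the shared firing
// threshold ends the run. Euler integration, dV = (dt/C) * (I - sum of
// conductance terms), matching the R-level euler_step() arithmetic exactly.
// No RNG here: the input current already carries the initialisation noise,
// so the loop is fully deterministic.
//
// Returns step = 0 when no WTA unit fires within max_steps (censored run).
// Ties within a step are broken by the larger membrane potential, then by
// row-major location order. Stability is checked by scanning for non-finite
// potentials every 128 steps (and at exit), keeping the inner loop free of
// per-cell fpclassify calls.

// [[Rcpp::export]]
List first_spike_cpp(NumericVector I, int nrow, int ncol,
                     double dt, double Eleak, double Eexc, double Einh,
                     double Gleak, double Gexc, double Ginh_sm,
                     double Vthresh, double C,
                     double wC, double wGleak,
                     int max_steps) {
  const int n = I.size();
  if (n != nrow * ncol) stop("input current does not match the grid");
  std::vector<double> V(n, Eleak), W(n, Eleak);
  const double *pI = REAL(I);
  const double aC = dt / C;
  const double aW = dt / wC;

  for (int step = 1; step <= max_steps; ++step) {
    int winner = -1;
    double wbest = 0.0;
    long rmbest = 0;
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      v += aC * (pI[i] - Gleak * (v - Eleak) - Ginh_sm * (v - Einh));
      const bool fired = v > Vthresh;
      double w = W[i];
      w += aW * (-wGleak * (w - Eleak) -
                 (fired ? Gexc * (w - Eexc) : 0.0));
      V[i] = fired ? Eleak : v;
      W[i] = w;
      if (w > Vthresh) {
        long rm = (long)(i % nrow) * ncol + (i / nrow);  // row-major key
        if (winner < 0 || w > wbest || (w == wbest && rm < rmbest)) {
          winner = i;
          wbest = w;
          rmbest = rm;
        }
      }
    }
    if ((step & 127) == 0 || winner >= 0 || step == max_steps) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(V[i]) || !std::isfinite(W[i])) {
          stop("numerical instability: non-finite membrane potential "
               "(check dt relative to C and the conductances)");
        }
      }
    }
    if (winner >= 0) {
      return List::create(_["step"] = step,
                          _["winner_row"] = winner % nrow + 1,
                          _["winner_col"] = winner / nrow + 1,
                          _["censored"] = false);
    }
  }
  return List::create(_["step"] = 0, _["winner_row"] = NA_INTEGER,
                      _["winner_col"] = NA_INTEGER, _["censored"] = true);
}
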