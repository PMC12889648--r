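#include <Rcpp.h>
using namespace Rcpp;

// Bin-by-bin forward simulation of a fitted pop-GLM for one trial.  The
// fixed part of the log rate (baseline + gain + coupling from given source
// trains) is supplied as `offset`; the self-history convolution and the
// damping term f_damp(Lambda) are updated online from the spikes emitted so
// far.  The rate is clipped at `ceiling_per_ms`; any clip sets the
// instability flag.  Lambda uses the strictly-before convention
// Lambda_{i+1} = exp(-dt/tau) * (Lambda_i + y_i / tau).
//
// self_filter: filter value at lags 1..D bins (already basis-combined)
// damp_grid:   f_damp evaluated on an equally spaced Lambda grid
//              [0, damp_lambda_max]; linear interpolation, clamped ends.
// [[Rcpp::export]]
List popglm_simulate_cpp(NumericVector offset, NumericVector self_filter,
                         NumericVector damp_grid, double damp_lambda_max,
                         double tau_ms, double bin_ms, double ceiling_per_ms) {
  const int n = offset.size();
  const int D = self_filter.size();
  const int ng = damp_grid.size();
  const double a = std::exp(-bin_ms / tau_ms);
  IntegerVector y(n);
  double lambda = 0.0;
  bool clipped = false;
  const double mu_max = ceiling_per_ms * bin_ms;

  for (int i = 0; i < n; ++i) {
    double eta = offset[i];
    for (int d = 1; d <= D && d <= i; ++d)
      if (y[i - d] > 0) eta += self_filter[d - 1] * y[i - d];
    if (ng > 0 && damp_lambda_max > 0) {
      double lam = std::min(lambda, damp_lambda_max);
      double pos = lam / damp_lambda_max * (ng - 1);
      int i0 = (int)std::floor(pos);
      if (i0 >= ng - 1) i0 = ng - 2;
      double f = pos - i0;
      eta += damp_grid[i0] * (1 - f) + damp_grid[i0 + 1] * f;
    }
    double mu = std::exp(eta) * bin_ms;
    if (mu > mu_max) { mu = mu_max; clipped = true; }
    y[i] = (int)R::rpois(mu);
    lambda = a * (lambda + y[i] / tau_ms);
  }
  return List::create(_["counts"] = y, _["clipped"] = clipped);
}
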