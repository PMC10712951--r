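// Settling engine: iterated net-input + k-winner-take-all sweeps.
// Mirrors the R reference implementation in R/network.R exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec kwta(const arma::vec& drives, int k, double gain,
                      double floor) {
  const int n = drives.n_elem;
  arma::vec ds = arma::sort(drives, "descend");
  double theta;
  if (k < n)
    theta = 0.5 * (ds[k - 1] + ds[k]);
  else
    theta = ds[n - 1] - 1.0 / gain;
  if (theta < floor) theta = floor;
  return 1.0 / (1.0 + arma::exp(-gain * (drives - theta)));
}

// [[Rcpp::export]]
List settle_core(List act0, List Ws, IntegerVector srcs, IntegerVector dsts,
                 NumericVector coefs, IntegerVector free_order,
                 NumericVector k, NumericVector gain, NumericVector floor,
                 int max_cycles, double tol, double step) {
  const int n_layers = act0.size();
  std::vector<arma::vec> act(n_layers);
  for (int i = 0; i < n_layers; ++i)
    act[i] = as<arma::vec>(act0[i]);

  const int n_proj = Ws.size();
  std::vector<arma::mat> W(n_proj);
  for (int p = 0; p < n_proj; ++p)
    W[p] = as<arma::mat>(Ws[p]);

  int cycles = 0;
  bool converged = false;
  while (cycles < max_cycles) {
    ++cycles;
    double delta = 0.0;
    for (int fi = 0; fi < free_order.size(); ++fi) {
      const int L = free_order[fi];
      arma::vec drive(act[L].n_elem, arma::fill::zeros);
      for (int p = 0; p < n_proj; ++p)
        if (dsts[p] == L)
          drive += coefs[p] * (W[p] * act[srcs[p]]);
      arma::vec nw = act[L] +
        step * (kwta(drive, (int)k[L], gain[L], floor[L]) - act[L]);
      double d = arma::abs(nw - act[L]).max();
      if (d > delta) delta = d;
      act[L] = nw;
    }
    if (delta < tol) { converged = true; break; }
  }

  List out(n_layers);
  for (int i = 0; i < n_layers; ++i)
    out[i] = NumericVector(act[i].begin(), act[i].end());
  return List::create(_["act"] = out, _["cycles"] = cycles,
                      _["converged"] = converged);
}
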