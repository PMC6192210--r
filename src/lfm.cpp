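#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// SGD for the latent factor model: minimizes
//   sum over all cells (A(l,m) - p_l . q_m)^2 + reg * (||P||^2 + ||Q||^2)
// visiting every cell once per epoch in the caller-supplied order.
// P (nl x k) and Q (nm x k) are updated in place; returns the per-epoch
// mean squared objective so callers can check monotone decrease.
// Factors are worked on in transposed (k-contiguous) scratch storage so the
// k-length inner loops stream over adjacent memory.
// [[Rcpp::export]]
NumericVector lfm_sgd(NumericMatrix A, NumericMatrix P, NumericMatrix Q,
                      IntegerVector order, double reg, double lr,
                      int epochs) {
  const int nl = A.nrow(), nm = A.ncol(), k = P.ncol();
  const int ncell = nl * nm;
  std::vector<double> Pt(static_cast<size_t>(nl) * k),
      Qt(static_cast<size_t>(nm) * k);
  for (int l = 0; l < nl; ++l)
    for (int f = 0; f < k; ++f) Pt[static_cast<size_t>(l) * k + f] = P(l, f);
  for (int m = 0; m < nm; ++m)
    for (int f = 0; f < k; ++f) Qt[static_cast<size_t>(m) * k + f] = Q(m, f);
  const double *a = A.begin();
  const int *ord = order.begin();
  NumericVector loss(epochs);
  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < ncell; ++t) {
      const int cell = ord[t];
      double *p = &Pt[static_cast<size_t>(cell % nl) * k];
      double *q = &Qt[static_cast<size_t>(cell / nl) * k];
      double pred = 0.0;
      for (int f = 0; f < k; ++f) pred += p[f] * q[f];
      const double err = a[cell] - pred;
      const double lre = lr * err, lrr = lr * reg;
      for (int f = 0; f < k; ++f) {
        const double pf = p[f], qf = q[f];
        p[f] += lre * qf - lrr * pf;
        q[f] += lre * pf - lrr * qf;
      }
    }
    double obj = 0.0;
    for (int m = 0; m < nm; ++m) {
      const double *q = &Qt[static_cast<size_t>(m) * k];
      const double *acol = a + static_cast<size_t>(m) * nl;
      for (int l = 0; l < nl; ++l) {
        const double *p = &Pt[static_cast<size_t>(l) * k];
        double pred = 0.0;
        for (int f = 0; f < k; ++f) pred += p[f] * q[f];
        const double err = acol[l] - pred;
        obj += err * err;
      }
    }
    double regterm = 0.0;
    for (size_t i = 0; i < Pt.size(); ++i) regterm += Pt[i] * Pt[i];
    for (size_t i = 0; i < Qt.size(); ++i) regterm += Qt[i] * Qt[i];
    loss[e] = (obj + reg * regterm) / ncell;
    if (!R_finite(loss[e]))
      stop("LFM training diverged (non-finite loss); try a smaller learning rate");
  }
  for (int l = 0; l < nl; ++l)
    for (int f = 0; f < k; ++f) P(l, f) = Pt[static_cast<size_t>(l) * k + f];
  for (int m = 0; m < nm; ++m)
    for (int f = 0; f < k; ++f) Q(m, f) = Qt[static_cast<size_t>(m) * k + f];
  return loss;
}
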