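// Hot loops of the Metropolis-within-Gibbs sampler. All randomness
// comes from R's RNG (GetRNGstate via Rcpp), so chains remain
// bit-reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// softplus(eta) and the binomial log-likelihood row sums in one pass:
//   sp = log(1 + exp(eta));  ll_i = sum_j [ y_ij * eta_ij - N_ij * sp_ij ]
// using log p = eta - sp and log(1 - p) = -sp.
// [[Rcpp::export(name = ".detect_ll")]]
List detect_ll(NumericMatrix eta, NumericMatrix y, NumericMatrix Nrep) {
  const int I = eta.nrow(), J = eta.ncol();
  NumericMatrix sp(I, J);
  NumericVector ll(I);
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < I; ++i) {
      const double e = eta(i, j);
      const double s = (e > 0 ? e : 0) + std::log1p(std::exp(-std::fabs(e)));
      sp(i, j) = s;
      ll[i] += y(i, j) * e - Nrep(i, j) * s;
    }
  }
  return List::create(_["sp"] = sp, _["ll"] = ll);
}

// Poisson part of the abundance log-likelihood (log lambda capped so
// exp() cannot overflow in rejected far-out proposals):
//   lam = exp(min(loglam, 300));  ll_i = sum_j w_ij (N_ij loglam - lam)
// [[Rcpp::export(name = ".abund_ll")]]
List abund_ll(NumericMatrix loglam, NumericMatrix N, NumericMatrix w) {
  const int I = loglam.nrow(), J = loglam.ncol();
  NumericMatrix lam(I, J);
  NumericMatrix ll_cap(I, J);
  NumericVector ll(I);
  for (int j = 0; j < J; ++j) {
    for (int i = 0; i < I; ++i) {
      double lg = loglam(i, j);
      if (lg > 300) lg = 300;
      ll_cap(i, j) = lg;
      const double la = std::exp(lg);
      lam(i, j) = la;
      if (w(i, j) != 0) ll[i] += N(i, j) * lg - la;
    }
  }
  return List::create(_["lam"] = lam, _["loglam"] = ll_cap, _["ll"] = ll);
}

// Exact categorical draw of N for cells with positive counts.
// Column r of Ct (support grid 0..L-1 in rows) holds the N-invariant
// part of the log weights (-Inf below max y); the full log weight is
// Ct(n, r) + a_r * n. One uniform per cell, inverse-CDF after a
// max-stabilized exp pass.
// [[Rcpp::export(name = ".sample_N_cells")]]
IntegerVector sample_N_cells(NumericMatrix Ct, NumericVector a) {
  const int L = Ct.nrow(), m = Ct.ncol();
  IntegerVector out(m);
  std::vector<double> wrow(L);
  RNGScope scope;
  for (int r = 0; r < m; ++r) {
    const double ar = a[r];
    const double *col = &Ct(0, r);
    double best = R_NegInf;
    for (int n = 0; n < L; ++n) {
      const double v = col[n] + ar * n;
      wrow[n] = v;
      if (v > best) best = v;
    }
    double tot = 0.0;
    for (int n = 0; n < L; ++n) {
      const double e = (wrow[n] == R_NegInf) ? 0.0 : std::exp(wrow[n] - best);
      wrow[n] = e;
      tot += e;
    }
    const double u = unif_rand() * tot;
    double cum = 0.0;
    int pick = L - 1;
    for (int n = 0; n < L; ++n) {
      cum += wrow[n];
      if (u <= cum) { pick = n; break; }
    }
    out[r] = pick;
  }
  return out;
}
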