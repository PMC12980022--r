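#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brute-force nearest neighbours from each query row to the reference rows.
// Ties broken by lowest reference index (strict < comparison keeps the
// first minimum). Returns 1-based indices and Euclidean distances.
// [[Rcpp::export]]
List nn_bruteforce_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow(), d = query.ncol();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < nr; ++j) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = query(i, k) - ref(j, k);
        acc += diff * diff;
      }
      if (acc < best) { best = acc; besti = j; }
    }
    idx[i] = besti + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Squared-distance matrix between two point sets (rows), used by the
// coherent point drift E-step.
// [[Rcpp::export]]
NumericMatrix dist2_matrix_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = A(i, k) - B(j, k);
        acc += diff * diff;
      }
      D(i, j) = acc;
    }
  return D;
}
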