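#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ML decoding of a label-count vector y against all offsets of
// all genome records, in forward and reversed-bin-vector orientation.
//
// logL is (cap+1) x (cap+1): logL(x, y) = log p(y | x). -Inf entries are
// allowed (zero likelihood without a floor); a window containing one scores
// -Inf and can never win unless every window does.
//
// Ties: candidates are visited in lexicographic (record, orientation
// forward-then-reverse, ascending start) order and a later candidate
// replaces the incumbent only if its score exceeds it by more than tie_tol.
// Scores are sums of a small set of log-likelihood values, so exact ties
// between repeated or permuted windows are common; the tolerance makes the
// tie-break robust to the non-associativity of floating-point addition.
//
// [[Rcpp::export]]
List decode_ml_cpp(List x_vecs, IntegerVector y, NumericMatrix logL,
                   double tie_tol = 1e-9) {
  const int n = y.size();
  const int n_rec = x_vecs.size();
  double best = R_NegInf;
  int best_rec = -1, best_start = -1, best_rev = 0;
  bool found = false;

  for (int k = 0; k < n_rec; ++k) {
    IntegerVector x = x_vecs[k];
    const int nb = x.size();
    if (nb < n) continue;
    for (int rev = 0; rev < 2; ++rev) {
      for (int i = 0; i + n <= nb; ++i) {
        double s = 0.0;
        if (rev == 0) {
          for (int j = 0; j < n; ++j) s += logL(x[i + j], y[j]);
        } else {
          for (int j = 0; j < n; ++j) s += logL(x[nb - 1 - i - j], y[j]);
        }
        if (!found || s > best + tie_tol) {
          found = true;
          best = s;
          best_rec = k;
          best_start = i;
          best_rev = rev;
        }
      }
    }
  }
  if (!found) stop("no record offers a valid offset for a fragment of %d bins", n);
  return List::create(_["record"] = best_rec + 1, _["start_bin"] = best_start,
                      _["reverse"] = (best_rev == 1), _["score"] = best);
}
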