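#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbour search from each query point to a reference
// cloud. Returns 1-based indices and squared distances (mm^2).
// [[Rcpp::export]]
List nn_search(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference cloud is empty");
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bj = 0;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = qx - ref(j, 0);
      const double dy = qy - ref(j, 1);
      const double dz = qz - ref(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["d2"] = d2);
}
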