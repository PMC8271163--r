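#include <Rcpp.h>
using namespace Rcpp;

// Maximum coverage of each null profile obtained by uniformly re-placing a
// transcript's read start positions (read widths preserved). Uses R's RNG,
// so results are reproducible under set.seed(). The inner loop touches
// n_perm * (n_reads + tx_len) elements, which is why it lives in C++.
// [[Rcpp::export]]
NumericVector null_max_coverage_cpp(IntegerVector widths, int tx_len,
                                    int n_perm) {
  const int R = widths.size();
  NumericVector out(n_perm);
  if (R == 0 || tx_len <= 0) return out;
  std::vector<int> delta(tx_len + 1, 0);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    std::fill(delta.begin(), delta.end(), 0);
    for (int r = 0; r < R; ++r) {
      int w = widths[r] > tx_len ? tx_len : widths[r];
      int span = tx_len - w + 1;
      int s = (int)(unif_rand() * span);
      if (s >= span) s = span - 1;
      delta[s] += 1;
      delta[s + w] -= 1;
    }
    int cum = 0, mx = 0;
    for (int i = 0; i < tx_len; ++i) {
      cum += delta[i];
      if (cum > mx) mx = cum;
    }
    out[p] = mx;
  }
  return out;
}
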