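#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximum absolute sum of t values over sign-consistent connected
// components, for each row of a permutation t matrix.  Columns are the
// flattened channel x point grid with the channel index varying fastest
// (column = k * n_ch + ch, 0-based), matching matrix(d, nrow = n) on an
// n x channel x point array.  Connectivity: same channel and adjacent
// points, or same point and neighboring channels.
// [[Rcpp::export]]
NumericVector cpp_max_cluster_stat(NumericMatrix t_rows, int n_ch, int n_k,
                                   List neighbors, double threshold) {
  int n_perm = t_rows.nrow();
  int n_pts = n_ch * n_k;
  if (t_rows.ncol() != n_pts) stop("t matrix does not match grid size");
  std::vector< std::vector<int> > nb(n_ch);
  for (int c = 0; c < n_ch; ++c) {
    IntegerVector v = neighbors[c];
    nb[c] = std::vector<int>(v.begin(), v.end());
  }
  NumericVector out(n_perm);
  std::vector<int> label(n_pts), queue(n_pts);
  for (int p = 0; p < n_perm; ++p) {
    std::fill(label.begin(), label.end(), 0);
    double best = 0.0;
    int next_id = 0;
    for (int start = 0; start < n_pts; ++start) {
      double t0 = t_rows(p, start);
      if (label[start] != 0 || !(std::fabs(t0) > threshold)) continue;
      int sgn = t0 > 0 ? 1 : -1;
      ++next_id;
      label[start] = next_id;
      int qh = 0, qt = 0;
      queue[qt++] = start;
      double sum = 0.0;
      while (qh < qt) {
        int cur = queue[qh++];
        int ch = cur % n_ch, k = cur / n_ch;
        sum += t_rows(p, cur);
        // along-axis neighbors
        for (int dk = -1; dk <= 1; dk += 2) {
          int kk = k + dk;
          if (kk < 0 || kk >= n_k) continue;
          int idx = kk * n_ch + ch;
          double tv = t_rows(p, idx);
          if (label[idx] == 0 && std::fabs(tv) > threshold &&
              ((tv > 0) == (sgn > 0))) {
            label[idx] = next_id;
            queue[qt++] = idx;
          }
        }
        // channel neighbors at the same point
        for (size_t j = 0; j < nb[ch].size(); ++j) {
          int idx = k * n_ch + nb[ch][j];
          double tv = t_rows(p, idx);
          if (label[idx] == 0 && std::fabs(tv) > threshold &&
              ((tv > 0) == (sgn > 0))) {
            label[idx] = next_id;
            queue[qt++] = idx;
          }
        }
      }
      if (std::fabs(sum) > best) best = std::fabs(sum);
    }
    out[p] = best;
  }
  return out;
}
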