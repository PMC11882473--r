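#include <Rcpp.h>
using namespace Rcpp;

// mean-depth sliding windows (width `window`, stride `step`) over a depth
// vector; the trailing partial window keeps its actual width
static double max_window_mean(const std::vector<double>& depth,
                              int window, int step) {
  int L = depth.size();
  if (L == 0) return 0.0;
  std::vector<double> cs(L + 1, 0.0);
  for (int i = 0; i < L; ++i) cs[i + 1] = cs[i] + depth[i];
  double best = R_NegInf;
  for (int s = 0; s < L; s += step) {
    int e = std::min(s + window, L);
    double m = (cs[e] - cs[s]) / (e - s);
    if (m > best) best = m;
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_window_means")]]
NumericVector cpp_window_means(NumericVector depth, int window, int step) {
  int L = depth.size();
  std::vector<double> cs(L + 1, 0.0);
  for (int i = 0; i < L; ++i) cs[i + 1] = cs[i] + depth[i];
  int nw = (L + step - 1) / step;
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    int s = w * step;
    int e = std::min(s + window, L);
    out[w] = (cs[e] - cs[s]) / (e - s);
  }
  return out;
}

// Max sliding-window mean depth for `n_shuffles` uniform re-placements of
// the given reads over a gene of length L.  Read starts are drawn uniformly
// over the gene span and reads are clipped at the right edge.  Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_perm_max_depth")]]
NumericVector cpp_perm_max_depth(IntegerVector read_lengths, int L,
                                 int window, int step, int n_shuffles) {
  int n = read_lengths.size();
  NumericVector out(n_shuffles);
  std::vector<double> diff(L + 1);
  std::vector<double> depth(L);
  RNGScope scope;
  for (int b = 0; b < n_shuffles; ++b) {
    std::fill(diff.begin(), diff.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int s = (int)std::floor(unif_rand() * L);
      if (s >= L) s = L - 1;
      int e = std::min(s + read_lengths[i], L);
      diff[s] += 1.0;
      diff[e] -= 1.0;
    }
    double acc = 0.0;
    for (int p = 0; p < L; ++p) { acc += diff[p]; depth[p] = acc; }
    out[b] = max_window_mean(depth, window, step);
  }
  return out;
}
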