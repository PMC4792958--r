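// k-nearest-neighbour imputation kernel. Probes are items, samples the
// feature axis; distances are squared Euclidean over co-observed samples,
// rescaled to the full sample count; missing entries are replaced by the
// inverse-distance-weighted mean of the k nearest probes observed at that
// sample, falling back to the probe mean.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>

using namespace arma;

// [[Rcpp::export(name = ".knn_impute_cpp")]]
arma::mat knn_impute_cpp(arma::mat X, int k) {
  const uword np = X.n_rows, ns = X.n_cols;
  umat obs(np, ns);
  vec row_mean(np, fill::zeros);
  uvec n_obs(np, fill::zeros);
  for (uword i = 0; i < np; ++i) {
    double s = 0.0; uword c = 0;
    for (uword j = 0; j < ns; ++j) {
      bool o = std::isfinite(X(i, j));
      obs(i, j) = o;
      if (o) { s += X(i, j); ++c; }
    }
    if (c == 0) Rcpp::stop("knn_impute: probe %d has no observed values", (int)(i + 1));
    row_mean[i] = s / c;
    n_obs[i] = c;
  }

  mat out = X;
  for (uword i = 0; i < np; ++i) {
    if (n_obs[i] == ns) continue;
    // distances to every other probe over co-observed samples
    // keep the k smallest in a max-heap
    typedef std::pair<double, uword> DP;
    std::priority_queue<DP> heap;
    for (uword j = 0; j < np; ++j) {
      if (j == i) continue;
      double d = 0.0; uword nco = 0;
      for (uword s = 0; s < ns; ++s) {
        if (obs(i, s) && obs(j, s)) {
          double dv = X(i, s) - X(j, s);
          d += dv * dv;
          ++nco;
        }
      }
      if (nco == 0) continue;
      d = d / nco * ns;  // rescale for comparability across overlap sizes
      if ((int)heap.size() < k) heap.push(DP(d, j));
      else if (d < heap.top().first) { heap.pop(); heap.push(DP(d, j)); }
    }
    std::vector<DP> nb;
    while (!heap.empty()) { nb.push_back(heap.top()); heap.pop(); }
    for (uword s = 0; s < ns; ++s) {
      if (obs(i, s)) continue;
      double wsum = 0.0, vsum = 0.0;
      for (size_t q = 0; q < nb.size(); ++q) {
        uword j = nb[q].second;
        if (obs(j, s)) {
          double w = 1.0 / (nb[q].first + 1e-8);
          wsum += w;
          vsum += w * X(j, s);
        }
      }
      out(i, s) = (wsum > 0) ? vsum / wsum : row_mean[i];
    }
  }
  return out;
}
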