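#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dijkstra shortest paths with path multiplicities plus Brandes betweenness
// accumulation on a signed weighted graph. Edge length is 1/|w|; ties in path
// length are resolved with fractional (Brandes) credit at tolerance `tol`.
//
// comm: integer community id per node. Bridge betweenness restricts the
// Brandes accumulation to source/target pairs in different communities;
// bridge closeness averages distances to out-community nodes only.
//
// Returns: dist (p x p, Inf if unreachable), sigma (shortest-path counts from
// each source, row-wise), and the per-node statistics matrix with columns
// strength, closeness, betweenness, bridge_strength, bridge_closeness,
// bridge_betweenness.
// [[Rcpp::export]]
Rcpp::List network_stats_cpp(const arma::mat& W, const arma::ivec& comm,
                             double tol = 1e-12) {
  const int p = W.n_rows;
  mat A = abs(W);
  mat D(p, p, fill::value(datum::inf));
  mat SIG(p, p, fill::zeros);
  vec btw(p, fill::zeros), bbtw(p, fill::zeros);

  std::vector<std::vector<int> > pred(p);
  std::vector<int> order;
  order.reserve(p);

  for (int s = 0; s < p; ++s) {
    vec d(p); d.fill(datum::inf); d(s) = 0.0;
    vec sigma(p, fill::zeros); sigma(s) = 1.0;
    std::vector<bool> settled(p, false);
    for (int i = 0; i < p; ++i) pred[i].clear();
    order.clear();

    for (int step = 0; step < p; ++step) {
      int u = -1; double best = datum::inf;
      for (int v = 0; v < p; ++v)
        if (!settled[v] && d(v) < best) { best = d(v); u = v; }
      if (u < 0) break;
      settled[u] = true;
      order.push_back(u);
      for (int v = 0; v < p; ++v) {
        if (settled[v] || A(u, v) <= 0.0) continue;
        const double alt = d(u) + 1.0 / A(u, v);
        const double eps = tol * std::max(1.0, std::abs(alt));
        if (alt < d(v) - eps) {
          d(v) = alt;
          sigma(v) = sigma(u);
          pred[v].clear();
          pred[v].push_back(u);
        } else if (std::abs(alt - d(v)) <= eps) {
          sigma(v) += sigma(u);
          pred[v].push_back(u);
        }
      }
    }

    D.row(s) = d.t();
    SIG.row(s) = sigma.t();

    // Brandes dependency accumulation, all pairs and cross-community pairs
    vec delta_all(p, fill::zeros), delta_br(p, fill::zeros);
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      const int w = order[i];
      if (w == s) continue;
      const double ind_br = (comm(w) != comm(s)) ? 1.0 : 0.0;
      for (size_t k = 0; k < pred[w].size(); ++k) {
        const int v = pred[w][k];
        const double c = sigma(v) / sigma(w);
        delta_all(v) += c * (1.0 + delta_all(w));
        delta_br(v)  += c * (ind_br + delta_br(w));
      }
    }
    for (int v = 0; v < p; ++v) {
      if (v == s) continue;
      btw(v) += delta_all(v);
      bbtw(v) += delta_br(v);
    }
  }
  btw *= 0.5;   // each unordered pair counted from both endpoints
  bbtw *= 0.5;

  mat stats(p, 6, fill::zeros);
  for (int i = 0; i < p; ++i) {
    double str = 0.0, bstr = 0.0, dsum = 0.0, bdsum = 0.0;
    int nreach = 0, breach = 0;
    for (int j = 0; j < p; ++j) {
      if (j == i) continue;
      str += A(i, j);
      if (comm(j) != comm(i)) bstr += A(i, j);
      if (std::isfinite(D(i, j))) {
        dsum += D(i, j);
        ++nreach;
        if (comm(j) != comm(i)) { bdsum += D(i, j); ++breach; }
      }
    }
    stats(i, 0) = str;
    stats(i, 1) = (nreach > 0 && dsum > 0) ? 1.0 / dsum : 0.0;
    stats(i, 2) = btw(i);
    stats(i, 3) = bstr;
    stats(i, 4) = (breach > 0 && bdsum > 0) ? 1.0 / (bdsum / breach) : 0.0;
    stats(i, 5) = bbtw(i);
  }

  return Rcpp::List::create(
    Rcpp::Named("dist") = D,
    Rcpp::Named("sigma") = SIG,
    Rcpp::Named("stats") = stats);
}
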