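#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Pairwise log-potential matrix for the two-sample energy statistic:
// L(i,j) = ln(max(|z_i - z_j|, eps)).  Precomputed once so that label
// permutations only re-read submatrices.
// [[Rcpp::export]]
NumericMatrix cpp_log_potential(NumericVector z, double eps) {
  int n = z.size();
  NumericMatrix L(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = std::abs(z[i] - z[j]);
      double v = std::log(d > eps ? d : eps);
      L(i, j) = v;
      L(j, i) = v;
    }
  }
  return L;
}

// Aslan-Zech logarithmic-potential energy between the samples indexed by
// idx_x (0-based) and the complement idx_y of the pooled vector behind L.
// Phi = -(1/n^2) sum_{i<j in x} L - (1/m^2) sum_{i<j in y} L
//       + (1/(n m)) sum_{i in x, j in y} L ; larger = more separated.
static double energy_from_L(const NumericMatrix &L,
                            const IntegerVector &idx_x,
                            const IntegerVector &idx_y) {
  int n = idx_x.size(), m = idx_y.size();
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b)
      sxx += L(idx_x[a], idx_x[b]);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b)
      syy += L(idx_y[a], idx_y[b]);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < m; ++b)
      sxy += L(idx_x[a], idx_y[b]);
  return -sxx / ((double)n * n) - syy / ((double)m * m) +
         sxy / ((double)n * m);
}

// [[Rcpp::export]]
double cpp_energy_from_L(NumericMatrix L, IntegerVector idx_x,
                         IntegerVector idx_y) {
  return energy_from_L(L, idx_x, idx_y);
}

// Permutation null of the energy statistic: re-split the pooled sample into
// groups of sizes n and m, n_perm times.  Uses R's RNG (seed via set.seed()).
// [[Rcpp::export]]
NumericVector cpp_energy_perm(NumericMatrix L, int n, int m, int n_perm) {
  int N = n + m;
  NumericVector null_vals(n_perm);
  IntegerVector all = seq(0, N - 1);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector perm = sample(all, N, false);
    IntegerVector ix(n), iy(m);
    for (int i = 0; i < n; ++i) ix[i] = perm[i];
    for (int i = 0; i < m; ++i) iy[i] = perm[n + i];
    null_vals[p] = energy_from_L(L, ix, iy);
  }
  return null_vals;
}

// Two-sample KS statistic sup|ECDF_x - ECDF_y| (ties handled by evaluating
// the ECDF difference after advancing through equal values).
static double ks_stat(std::vector<double> x, std::vector<double> y) {
  std::sort(x.begin(), x.end());
  std::sort(y.begin(), y.end());
  size_t n = x.size(), m = y.size(), i = 0, j = 0;
  double d = 0.0;
  while (i < n && j < m) {
    double v = std::min(x[i], y[j]);
    while (i < n && x[i] <= v) ++i;
    while (j < m && y[j] <= v) ++j;
    double diff = std::abs((double)i / n - (double)j / m);
    if (diff > d) d = diff;
  }
  return d;
}

// [[Rcpp::export]]
double cpp_ks_stat(NumericVector x, NumericVector y) {
  return ks_stat(as<std::vector<double> >(x), as<std::vector<double> >(y));
}

// [[Rcpp::export]]
NumericVector cpp_ks_perm(NumericVector z, int n, int m, int n_perm) {
  int N = n + m;
  NumericVector null_vals(n_perm);
  IntegerVector all = seq(0, N - 1);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector perm = sample(all, N, false);
    std::vector<double> x(n), y(m);
    for (int i = 0; i < n; ++i) x[i] = z[perm[i]];
    for (int i = 0; i < m; ++i) y[i] = z[perm[n + i]];
    null_vals[p] = ks_stat(x, y);
  }
  return null_vals;
}

// Maslov-Sneppen rewiring of a directed simple graph: repeatedly pick two
// edges (a->b, c->d) and swap targets to (a->d, c->b), rejecting swaps that
// would create self-loops or duplicate edges.  Preserves every node's in-
// and out-degree exactly.  edges: E x 2, 0-based.  Returns rewired edge
// list, or throws if n_accept swaps cannot be reached in max_tries attempts.
// [[Rcpp::export]]
IntegerMatrix cpp_edge_swap(IntegerMatrix edges, int n_nodes, int n_accept,
                            int max_tries) {
  int E = edges.nrow();
  std::vector<int> from(E), to(E);
  std::set<long long> present;
  for (int e = 0; e < E; ++e) {
    from[e] = edges(e, 0);
    to[e] = edges(e, 1);
    present.insert((long long)from[e] * n_nodes + to[e]);
  }
  int accepted = 0, tries = 0;
  while (accepted < n_accept && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * E);
    int e2 = (int)(unif_rand() * E);
    if (e1 == e2) continue;
    int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
    if (a == d || c == b) continue;               // would create self-loop
    long long k1 = (long long)a * n_nodes + d;
    long long k2 = (long long)c * n_nodes + b;
    if (present.count(k1) || present.count(k2)) continue;  // duplicate edge
    present.erase((long long)a * n_nodes + b);
    present.erase((long long)c * n_nodes + d);
    present.insert(k1);
    present.insert(k2);
    to[e1] = d;
    to[e2] = b;
    ++accepted;
  }
  if (accepted < n_accept)
    stop("degree-preserving rewiring failed: only %d of %d swaps accepted",
         accepted, n_accept);
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return out;
}
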