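#include <Rcpp.h>
using namespace Rcpp;

// Neighbour counts within Euclidean radius R, self included (so counts >= 1).
// [[Rcpp::export]]
IntegerVector ukd_counts_cpp(NumericMatrix X, double R) {
  const int n = X.nrow(), d = X.ncol();
  const double R2 = R * R;
  IntegerVector m(n, 1);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      bool within = true;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(j, c);
        s += diff * diff;
        if (s > R2) { within = false; break; }
      }
      if (within) { ++m[i]; ++m[j]; }
    }
  }
  return m;
}

// Ascent parent pointers: each point follows the eligible neighbour within
// R of maximal density, ties broken by lowest row index. A neighbour is
// eligible when strictly denser, or equally dense with a lower row index
// (so plateaus of tied density chain toward their lowest-index member and
// the walk stays acyclic). Points with no eligible neighbour are modes.
// Returns 1-based parent indices and 1-based root (mode) indices.
// [[Rcpp::export]]
List mode_assign_cpp(NumericMatrix X, NumericVector dens, double R) {
  const int n = X.nrow(), d = X.ncol();
  const double R2 = R * R;
  IntegerVector parent(n);
  for (int i = 0; i < n; ++i) {
    int best = -1;
    double bestd = R_NegInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const bool eligible = dens[j] > dens[i] ||
        (dens[j] == dens[i] && j < i);
      if (!eligible) continue;
      double s = 0.0;
      bool within = true;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(j, c);
        s += diff * diff;
        if (s > R2) { within = false; break; }
      }
      if (within && dens[j] > bestd) { bestd = dens[j]; best = j; }
    }
    parent[i] = best < 0 ? i : best;
  }
  IntegerVector root(n);
  for (int i = 0; i < n; ++i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    root[i] = r;
  }
  for (int i = 0; i < n; ++i) { parent[i] += 1; root[i] += 1; }
  return List::create(_["parent"] = parent, _["root"] = root);
}

// For each query row index (1-based, into X), the 1-based index into `cand`
// (also rows of X) of the nearest candidate; ties broken by lowest index.
// [[Rcpp::export]]
IntegerVector nearest_candidate_cpp(NumericMatrix X, IntegerVector from,
                                    IntegerVector cand) {
  const int d = X.ncol(), nf = from.size(), nc = cand.size();
  IntegerVector out(nf);
  for (int a = 0; a < nf; ++a) {
    const int i = from[a] - 1;
    int best = -1;
    double bestd = R_PosInf;
    for (int b = 0; b < nc; ++b) {
      const int j = cand[b] - 1;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = X(i, c) - X(j, c);
        s += diff * diff;
        if (s >= bestd) break;
      }
      if (s < bestd) { bestd = s; best = b; }
    }
    out[a] = best + 1;
  }
  return out;
}
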