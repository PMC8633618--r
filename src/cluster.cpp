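#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Spatio-temporal clustering of a thresholded t map.
//
// Cells are indexed p = ch + nch * t (channel fastest). Suprathreshold
// cells of the same sign are connected along time (t +/- 1, same
// channel) and across neighbouring channels (same time point). When
// min_neighbors > 0, a suprathreshold cell is retained only if at
// least that many of its spatial neighbours are suprathreshold with
// the same sign at the same time point (single pass on the original
// suprathreshold map).
static void cluster_map(const std::vector<double>& tv, int nch, int nt,
                        double thresh,
                        const std::vector<std::vector<int>>& nbrs,
                        int min_neighbors,
                        std::vector<int>& labels,
                        std::vector<double>& masses,
                        std::vector<int>& signs) {
  int p = nch * nt;
  std::vector<signed char> sgn(p, 0), keep(p, 0);
  for (int i = 0; i < p; ++i) {
    if (tv[i] > thresh) sgn[i] = 1;
    else if (tv[i] < -thresh) sgn[i] = -1;
  }
  if (min_neighbors > 0) {
    for (int t = 0; t < nt; ++t) {
      int base = t * nch;
      for (int c = 0; c < nch; ++c) {
        int i = base + c;
        if (!sgn[i]) continue;
        int cnt = 0;
        for (int nb : nbrs[c]) {
          if (sgn[base + nb] == sgn[i]) ++cnt;
        }
        keep[i] = (cnt >= min_neighbors) ? sgn[i] : 0;
      }
    }
  } else {
    keep = sgn;
  }
  labels.assign(p, 0);
  masses.clear();
  signs.clear();
  std::vector<int> stack;
  int next_id = 0;
  for (int start = 0; start < p; ++start) {
    if (!keep[start] || labels[start]) continue;
    ++next_id;
    signed char s = keep[start];
    double mass = 0.0;
    stack.clear();
    stack.push_back(start);
    labels[start] = next_id;
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      mass += tv[i];
      int t = i / nch, c = i % nch;
      // temporal neighbours
      if (t > 0) {
        int j = i - nch;
        if (keep[j] == s && !labels[j]) { labels[j] = next_id; stack.push_back(j); }
      }
      if (t < nt - 1) {
        int j = i + nch;
        if (keep[j] == s && !labels[j]) { labels[j] = next_id; stack.push_back(j); }
      }
      // spatial neighbours at the same time point
      int base = t * nch;
      for (int nb : nbrs[c]) {
        int j = base + nb;
        if (keep[j] == s && !labels[j]) { labels[j] = next_id; stack.push_back(j); }
      }
    }
    masses.push_back(mass);
    signs.push_back((int)s);
  }
}

static std::vector<std::vector<int>> convert_nbrs(const List& neighbors) {
  int nch = neighbors.size();
  std::vector<std::vector<int>> nbrs(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = neighbors[c];
    nbrs[c].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) nbrs[c].push_back(v[k] - 1);
  }
  return nbrs;
}

// [[Rcpp::export]]
List cpp_form_clusters(NumericMatrix tmap, double thresh, List neighbors,
                       int min_neighbors) {
  int nch = tmap.nrow(), nt = tmap.ncol();
  std::vector<double> tv(tmap.begin(), tmap.end());
  auto nbrs = convert_nbrs(neighbors);
  std::vector<int> labels, signs;
  std::vector<double> masses;
  cluster_map(tv, nch, nt, thresh, nbrs, min_neighbors, labels, masses, signs);
  IntegerMatrix lab(nch, nt);
  std::copy(labels.begin(), labels.end(), lab.begin());
  return List::create(_["labels"] = lab,
                      _["masses"] = NumericVector(masses.begin(), masses.end()),
                      _["signs"] = IntegerVector(signs.begin(), signs.end()));
}

// Permutation null of the maximum absolute cluster mass.
// d: subjects x (nch * nt) matrix of paired differences (cells indexed
// channel-fastest); flips: n_perm x subjects matrix of +/-1. For each
// permutation the paired t map of the sign-flipped differences is
// thresholded and clustered, and the largest absolute cluster mass is
// recorded (0 when no cluster survives).
// [[Rcpp::export]]
NumericVector cpp_null_max_mass(NumericMatrix d, IntegerMatrix flips,
                                int nch, int nt, double thresh,
                                List neighbors, int min_neighbors) {
  int n = d.nrow(), p = d.ncol(), n_perm = flips.nrow();
  if (p != nch * nt) stop("d has %d columns, expected nch*nt = %d", p, nch * nt);
  auto nbrs = convert_nbrs(neighbors);
  std::vector<double> ss(p, 0.0);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += d(i, j) * d(i, j);
    ss[j] = s;
  }
  NumericVector out(n_perm);
  std::vector<double> tv(p);
  std::vector<int> labels, signs;
  std::vector<double> masses;
  double sqrtn = std::sqrt((double)n);
  for (int r = 0; r < n_perm; ++r) {
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += flips(r, i) * d(i, j);
      double m = s / n;
      double var = (ss[j] - n * m * m) / (n - 1);
      tv[j] = (var > 0) ? m / (std::sqrt(var) / sqrtn) : 0.0;
    }
    cluster_map(tv, nch, nt, thresh, nbrs, min_neighbors, labels, masses, signs);
    double mx = 0.0;
    for (double mass : masses) {
      double a = std::fabs(mass);
      if (a > mx) mx = a;
    }
    out[r] = mx;
  }
  return out;
}
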