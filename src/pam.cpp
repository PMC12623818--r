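#include <Rcpp.h>
using namespace Rcpp;

// Partitioning Around Medoids, classical BUILD + SWAP on a precomputed
// dissimilarity matrix. Deterministic: all ties break toward the smallest
// index, so the result is a pure function of (d, k).

static double total_cost(const NumericMatrix& d, const IntegerVector& med,
                         int n) {
  double cost = 0.0;
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    for (int a = 0; a < med.size(); ++a) {
      double v = d(j, med[a]);
      if (v < best) best = v;
    }
    cost += best;
  }
  return cost;
}

// [[Rcpp::export(name = ".pam_rcpp")]]
List pam_rcpp(NumericMatrix d, int k) {
  const int n = d.nrow();
  if (d.ncol() != n) stop("dissimilarity matrix must be square");
  if (k < 1 || k > n) stop("k must lie in [1, n]");

  std::vector<bool> is_med(n, false);
  IntegerVector med(k);

  // BUILD: first medoid minimises the total dissimilarity; each subsequent
  // medoid maximises the decrease in cost.
  {
    double best = R_PosInf;
    int arg = 0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += d(j, i);
      if (s < best - 1e-12) { best = s; arg = i; }
    }
    med[0] = arg;
    is_med[arg] = true;
  }
  std::vector<double> d1(n);  // distance to nearest chosen medoid
  for (int j = 0; j < n; ++j) d1[j] = d(j, med[0]);

  for (int a = 1; a < k; ++a) {
    double best_gain = -1.0;
    int arg = -1;
    for (int i = 0; i < n; ++i) {
      if (is_med[i]) continue;
      double gain = 0.0;
      for (int j = 0; j < n; ++j) {
        double delta = d1[j] - d(j, i);
        if (delta > 0) gain += delta;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; arg = i; }
    }
    med[a] = arg;
    is_med[arg] = true;
    for (int j = 0; j < n; ++j)
      if (d(j, arg) < d1[j]) d1[j] = d(j, arg);
  }

  // SWAP: repeatedly apply the best strictly improving (medoid, non-medoid)
  // exchange until none exists.
  std::vector<double> d2(n);
  std::vector<int> nearest(n);
  bool improved = true;
  while (improved) {
    improved = false;
    // refresh nearest / second-nearest medoid distances
    for (int j = 0; j < n; ++j) {
      double b1 = R_PosInf, b2 = R_PosInf;
      int arg1 = -1;
      for (int a = 0; a < k; ++a) {
        double v = d(j, med[a]);
        if (v < b1) { b2 = b1; b1 = v; arg1 = med[a]; }
        else if (v < b2) b2 = v;
      }
      d1[j] = b1; d2[j] = b2; nearest[j] = arg1;
    }
    double best_T = -1e-10;
    int best_a = -1, best_h = -1;
    for (int a = 0; a < k; ++a) {
      int m = med[a];
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        double T = 0.0;
        for (int j = 0; j < n; ++j) {
          double djh = d(j, h);  // d(h,h)=0, so j==h needs no special case
          if (nearest[j] == m) {
            T += std::min(djh, d2[j]) - d1[j];
          } else if (djh < d1[j]) {
            T += djh - d1[j];
          }
        }
        if (T < best_T - 1e-12) { best_T = T; best_a = a; best_h = h; }
      }
    }
    if (best_a >= 0) {
      is_med[med[best_a]] = false;
      is_med[best_h] = true;
      med[best_a] = best_h;
      improved = true;
    }
  }

  std::sort(med.begin(), med.end());
  IntegerVector labels(n);
  for (int j = 0; j < n; ++j) {
    double best = R_PosInf;
    int arg = 0;
    for (int a = 0; a < k; ++a) {
      double v = d(j, med[a]);
      if (v < best - 1e-12) { best = v; arg = a; }
    }
    labels[j] = arg + 1;
  }
  for (int a = 0; a < k; ++a) med[a] = med[a] + 1;

  return List::create(_["medoids"] = med, _["labels"] = labels,
                      _["cost"] = total_cost(d, IntegerVector(med) - 1, n));
}
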