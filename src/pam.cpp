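#include <Rcpp.h>
using namespace Rcpp;

// Partitioning Around Medoids on a precomputed dissimilarity matrix.
// BUILD seeds the k medoids greedily; SWAP iterates single medoid <->
// non-medoid exchanges to a local optimum of the total dissimilarity.
// All ties break toward the lowest row index so results are reproducible
// across platforms.

static double total_cost(const NumericMatrix &d, const std::vector<int> &med,
                         std::vector<int> &assign_out) {
  int n = d.nrow(), k = (int)med.size();
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < k; ++c) {
      double v = d(i, med[c]);
      if (v < best - 1e-15) { best = v; bi = c; }
    }
    assign_out[i] = bi;
    tot += best;
  }
  return tot;
}

// [[Rcpp::export(name = ".pam_fit_cpp")]]
List pam_fit_cpp(NumericMatrix d, int k, int max_iter = 200) {
  int n = d.nrow();
  if (d.ncol() != n) stop("dissimilarity matrix must be square");
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n");

  std::vector<bool> is_med(n, false);
  std::vector<int> med;
  med.reserve(k);

  // BUILD: first medoid minimises the column sum; each later medoid
  // maximises the decrease in total cost, ties to the lowest index.
  std::vector<double> dnear(n, R_PosInf); // distance to nearest chosen medoid
  {
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += d(i, j);
      if (s < best - 1e-12) { best = s; bi = j; }
    }
    med.push_back(bi);
    is_med[bi] = true;
    for (int i = 0; i < n; ++i) dnear[i] = d(i, bi);
  }
  while ((int)med.size() < k) {
    double best_gain = -1.0;
    int bi = -1;
    for (int j = 0; j < n; ++j) {
      if (is_med[j]) continue;
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        double diff = dnear[i] - d(i, j);
        if (diff > 0) gain += diff;
      }
      if (gain > best_gain + 1e-12) { best_gain = gain; bi = j; }
    }
    if (bi < 0) { // all gains zero: take lowest-index non-medoid
      for (int j = 0; j < n; ++j) if (!is_med[j]) { bi = j; break; }
    }
    med.push_back(bi);
    is_med[bi] = true;
    for (int i = 0; i < n; ++i) if (d(i, bi) < dnear[i]) dnear[i] = d(i, bi);
  }

  std::vector<int> assign(n);
  double cost = total_cost(d, med, assign);

  // SWAP: best-improvement exchanges until a local optimum.
  for (int iter = 0; iter < max_iter; ++iter) {
    double best_delta = -1e-12;
    int best_m = -1, best_h = -1;
    for (int c = 0; c < k; ++c) {
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        // candidate medoid set: med with med[c] replaced by h
        double newcost = 0.0;
        for (int i = 0; i < n; ++i) {
          double bestd = d(i, h);
          for (int c2 = 0; c2 < k; ++c2) {
            if (c2 == c) continue;
            double v = d(i, med[c2]);
            if (v < bestd) bestd = v;
          }
          newcost += bestd;
        }
        double delta = newcost - cost;
        if (delta < best_delta) { best_delta = delta; best_m = c; best_h = h; }
      }
    }
    if (best_m < 0) break;
    is_med[med[best_m]] = false;
    med[best_m] = best_h;
    is_med[best_h] = true;
    cost = total_cost(d, med, assign);
  }

  // report medoids sorted ascending; labels follow that order
  std::vector<int> ord(k);
  for (int c = 0; c < k; ++c) ord[c] = c;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return med[a] < med[b]; });
  IntegerVector med_out(k);
  for (int c = 0; c < k; ++c) med_out[c] = med[ord[c]] + 1;
  // final assignment from sorted medoids: exact ties -> lowest cluster index
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bc = 0;
    for (int c = 0; c < k; ++c) {
      double v = d(i, med_out[c] - 1);
      if (v < best) { best = v; bc = c; }
    }
    lab[i] = bc + 1;
  }

  return List::create(_["medoids"] = med_out, _["labels"] = lab,
                      _["cost"] = cost);
}
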