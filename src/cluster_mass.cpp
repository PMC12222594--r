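#include <Rcpp.h>
using namespace Rcpp;

// Sign-homogeneous supra-threshold cluster labelling on a 1-D series
// (nr == 1) or a 2-D nr x nc grid under 4-connectivity, column-major
// flattening.  Positive and negative clusters are labelled separately.

static void labelGrid(const double *t, double thr, int nr, int nc,
                      std::vector<int> &lab, int &nClusters) {
  int n = nr * nc;
  lab.assign(n, 0);
  nClusters = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    int s = (t[i] > thr) ? 1 : (t[i] < -thr ? -1 : 0);
    if (s == 0) continue;
    ++nClusters;
    stack.clear();
    stack.push_back(i);
    lab[i] = nClusters;
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      int r = j % nr, c = j / nr;
      const int nb[4][2] = {{r - 1, c}, {r + 1, c}, {r, c - 1}, {r, c + 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (nr == 1 && k < 2) continue; // 1-D: temporal adjacency only
        int jj = cc * nr + rr;
        if (lab[jj] != 0) continue;
        int sj = (t[jj] > thr) ? 1 : (t[jj] < -thr ? -1 : 0);
        if (sj != s) continue;
        lab[jj] = nClusters;
        stack.push_back(jj);
      }
    }
  }
}

// [[Rcpp::export(name = ".labelClustersCpp")]]
IntegerVector labelClustersCpp(NumericVector t, double thr, int nr) {
  int nc = t.size() / nr;
  std::vector<int> lab;
  int nClusters;
  labelGrid(REAL(t), thr, nr, nc, lab, nClusters);
  IntegerVector out(t.size());
  std::copy(lab.begin(), lab.end(), out.begin());
  return out;
}

// Per-row maximum cluster mass (sum of |t| within a sign-homogeneous
// cluster) for a matrix of permutation t-maps, each row one flattened grid.
// [[Rcpp::export(name = ".permMaxClusterMassCpp")]]
NumericVector permMaxClusterMassCpp(NumericMatrix tmat, double thr, int nr) {
  int nPerm = tmat.nrow(), n = tmat.ncol();
  int nc = n / nr;
  NumericVector out(nPerm);
  std::vector<double> row(n);
  std::vector<int> lab;
  int nClusters;
  for (int p = 0; p < nPerm; ++p) {
    for (int i = 0; i < n; ++i) row[i] = tmat(p, i);
    labelGrid(row.data(), thr, nr, nc, lab, nClusters);
    double best = 0.0;
    if (nClusters > 0) {
      std::vector<double> mass(nClusters + 1, 0.0);
      for (int i = 0; i < n; ++i)
        if (lab[i] > 0) mass[lab[i]] += std::fabs(row[i]);
      for (int k = 1; k <= nClusters; ++k)
        if (mass[k] > best) best = mass[k];
    }
    out[p] = best;
  }
  return out;
}
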