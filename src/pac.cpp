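#include <Rcpp.h>
using namespace Rcpp;

// Haplotype-copying (PAC) composite likelihood machinery for piecewise-
// constant recombination-rate estimation.  Each haplotype is modeled as an
// imperfect mosaic of the haplotypes seen before it in a (random) ordering;
// the per-segment switching intensity is rho_j / k for k templates.
//
// For optimisation we exploit that changing the rate of one segment only
// changes one transition: with scaled forward (alpha) and backward (beta)
// vectors, the composite log likelihood as a function of segment j's total
// rho g is, up to a j-specific constant,
//     sum_h log( exp(-g/k_h) * A_{h,j} + (1 - exp(-g/k_h)) * B_{h,j} )
// where A = sum_y alpha_j(y) e_{j+1}(y) beta_{j+1}(y)  (alpha normalized)
// and   B = (1/k) sum_y e_{j+1}(y) beta_{j+1}(y).
// pac_grid_scores() returns those per-segment profile scores on a shared
// grid of candidate rates, summed over haplotypes and orderings, plus the
// composite log likelihood at the current rates.

// copy haplotypes in ordering order, column-major (n x L) for stride-1
// access over templates within a site
static void reorder_haps(const IntegerMatrix& haps, const IntegerMatrix& ord,
                         int o, std::vector<int>& H) {
  const int n = haps.nrow();
  const int L = haps.ncol();
  H.resize((size_t)n * L);
  for (int j = 0; j < L; ++j) {
    const int* col = &haps(0, j);
    int* out = &H[(size_t)j * n];
    for (int x = 0; x < n; ++x) out[x] = col[ord(x, o)];
  }
}

static double watterson_theta(int n) {
  double th_inv = 0.0;
  for (int i = 1; i < n; ++i) th_inv += 1.0 / i;
  return 1.0 / th_inv;
}

// [[Rcpp::export]]
List pac_grid_scores(const IntegerMatrix& haps,
                     const NumericVector& rho_seg,
                     const NumericMatrix& grid_seg,
                     const IntegerMatrix& orderings) {
  const int n = haps.nrow();
  const int L = haps.ncol();
  const int S = L - 1;
  const int V = grid_seg.ncol();
  const int n_ord = orderings.ncol();
  const double theta = watterson_theta(n);

  NumericMatrix scores(S, V);
  double loglik = 0.0;

  std::vector<int> H;
  std::vector<double> alpha(n), beta(n), beta_next(n);
  std::vector<double> alpha_store;
  std::vector<double> Avec(S), Bvec(S), expv(V);

  for (int o = 0; o < n_ord; ++o) {
    reorder_haps(haps, orderings, o, H);
    for (int t = 1; t < n; ++t) {
      const int k = t;
      const double lam = 0.5 * theta / (k + theta);
      const double dmatch = 1.0 - 2.0 * lam;  // e = lam + dmatch * match
      alpha_store.resize((size_t)L * k);
      // forward
      {
        const int* col = &H[0];
        const int y0 = col[t];
        double s = 0.0;
        for (int x = 0; x < k; ++x) {
          double e = lam + dmatch * (col[x] == y0);
          alpha[x] = e;
          s += e;
        }
        loglik += std::log(s / k) / n_ord;
        double inv = 1.0 / s;
        double* as = &alpha_store[0];
        for (int x = 0; x < k; ++x) { alpha[x] *= inv; as[x] = alpha[x]; }
      }
      for (int j = 0; j < S; ++j) {
        const double ns = std::exp(-rho_seg[j] / k);
        const double jp = (1.0 - ns) / k;
        const int* col = &H[(size_t)(j + 1) * n];
        const int yj = col[t];
        double s = 0.0;
        for (int x = 0; x < k; ++x) {
          double e = lam + dmatch * (col[x] == yj);
          double a = e * (ns * alpha[x] + jp);
          alpha[x] = a;
          s += a;
        }
        loglik += std::log(s) / n_ord;
        double inv = 1.0 / s;
        double* as = &alpha_store[(size_t)(j + 1) * k];
        for (int x = 0; x < k; ++x) { alpha[x] *= inv; as[x] = alpha[x]; }
      }
      // backward, collecting A_j and B_j per segment
      for (int x = 0; x < k; ++x) beta[x] = 1.0 / k;
      for (int j = S - 1; j >= 0; --j) {
        const int* col = &H[(size_t)(j + 1) * n];
        const int yj = col[t];
        const double* as = &alpha_store[(size_t)j * k];
        double A = 0.0, B = 0.0;
        for (int x = 0; x < k; ++x) {
          double e = lam + dmatch * (col[x] == yj);
          double eb = e * beta[x];
          A += as[x] * eb;
          B += eb;
        }
        B /= k;
        Avec[j] = A;
        Bvec[j] = B;
        const double ns = std::exp(-rho_seg[j] / k);
        double sb = 0.0;
        for (int x = 0; x < k; ++x) {
          double e = lam + dmatch * (col[x] == yj);
          double b = ns * e * beta[x] + (1.0 - ns) * B;
          beta_next[x] = b;
          sb += b;
        }
        double inv = 1.0 / sb;
        for (int x = 0; x < k; ++x) beta[x] = beta_next[x] * inv;
      }
      // profile scores on the shared grid
      for (int j = 0; j < S; ++j) {
        const double A = Avec[j], B = Bvec[j];
        double* sc = &scores(j, 0);
        for (int v = 0; v < V; ++v) {
          const double ns = std::exp(-grid_seg(j, v) / k);
          // scores is column-major: stride S between grid values
          sc[(size_t)v * S] += std::log(ns * A + (1.0 - ns) * B) / n_ord;
        }
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["scores"] = scores);
}

// Composite log likelihood only (cheap final evaluation / diagnostics).
// [[Rcpp::export]]
double pac_loglik(const IntegerMatrix& haps,
                  const NumericVector& rho_seg,
                  const IntegerMatrix& orderings) {
  const int n = haps.nrow();
  const int L = haps.ncol();
  const int S = L - 1;
  const int n_ord = orderings.ncol();
  const double theta = watterson_theta(n);
  double loglik = 0.0;
  std::vector<int> H;
  std::vector<double> alpha(n);
  for (int o = 0; o < n_ord; ++o) {
    reorder_haps(haps, orderings, o, H);
    for (int t = 1; t < n; ++t) {
      const int k = t;
      const double lam = 0.5 * theta / (k + theta);
      const double dmatch = 1.0 - 2.0 * lam;
      {
        const int* col = &H[0];
        const int y0 = col[t];
        double s = 0.0;
        for (int x = 0; x < k; ++x) {
          alpha[x] = lam + dmatch * (col[x] == y0);
          s += alpha[x];
        }
        loglik += std::log(s / k) / n_ord;
        double inv = 1.0 / s;
        for (int x = 0; x < k; ++x) alpha[x] *= inv;
      }
      for (int j = 0; j < S; ++j) {
        const double ns = std::exp(-rho_seg[j] / k);
        const double jp = (1.0 - ns) / k;
        const int* col = &H[(size_t)(j + 1) * n];
        const int yj = col[t];
        double s = 0.0;
        for (int x = 0; x < k; ++x) {
          double e = lam + dmatch * (col[x] == yj);
          alpha[x] = e * (ns * alpha[x] + jp);
          s += alpha[x];
        }
        loglik += std::log(s) / n_ord;
        double inv = 1.0 / s;
        for (int x = 0; x < k; ++x) alpha[x] *= inv;
      }
    }
  }
  return loglik;
}
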