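// Scoring kernels for greedy Gaussian segmentation.
//
// All bounds are 1-based half-open [i, j) row indices into the original
// N x d series; S1 and S2 are (N+1)-row cumulative sums of the rows and of
// their outer products (row k+1 = sums over rows 1..k), so segment moments
// are O(d^2) differences and the score is dominated by one d x d
// log-determinant.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double seg_score(const arma::mat& S1, const arma::mat& S2,
                        int i, int j, double lambda) {
  const int d = S1.n_cols;
  const double n = j - i;
  arma::rowvec s = S1.row(j - 1) - S1.row(i - 1);
  arma::rowvec cp = S2.row(j - 1) - S2.row(i - 1);
  arma::mat C(cp.memptr(), d, d);          // copies; column order matches R
  arma::vec m = s.t() / n;
  arma::mat Sigma = C / n - m * m.t();
  double load = lambda * arma::trace(Sigma) / d;
  if (load < 1e-12) load = 1e-12;
  Sigma.diag() += load;
  double ld, sign;
  bool ok = arma::log_det(ld, sign, Sigma);
  if (!ok || sign <= 0) {                  // borderline indefiniteness
    arma::vec ev;
    arma::eig_sym(ev, Sigma);
    ev.clamp(1e-12, arma::datum::inf);
    ld = arma::accu(arma::log(ev));
  }
  return -(n / 2.0) * ld;
}

// [[Rcpp::export]]
double cpp_seg_score(const arma::mat& S1, const arma::mat& S2,
                     int i, int j, double lambda) {
  return seg_score(S1, S2, i, j, lambda);
}

// Best single split of [s, e); returns 0-length t when infeasible.
// [[Rcpp::export]]
List cpp_best_split(const arma::mat& S1, const arma::mat& S2,
                    int s, int e, int m, double lambda) {
  int lo = s + m, hi = e - m;
  if (lo > hi) return List::create(_["t"] = IntegerVector(0));
  int best_t = lo;
  double best_v = R_NegInf;
  for (int t = lo; t <= hi; ++t) {
    double v = seg_score(S1, S2, s, t, lambda) +
               seg_score(S1, S2, t, e, lambda);
    if (v > best_v) { best_v = v; best_t = t; }   // keeps earliest tie
  }
  return List::create(_["t"] = best_t, _["val"] = best_v);
}

// Jointly optimal pair of splits of [s, e) into three segments. For long
// spans the O(L^2) search runs coarse-to-fine: a stride-g grid scan
// followed by full-resolution refinement around the grid optimum; short
// spans are scanned exhaustively.
// [[Rcpp::export]]
List cpp_best_pair(const arma::mat& S1, const arma::mat& S2,
                   int s, int e, int m, double lambda) {
  const int lo1 = s + m, hi2 = e - m;
  if (lo1 + m > hi2) return List::create(_["t"] = IntegerVector(0));
  const int L = e - s;
  const int g = L <= 150 ? 1 : L / 64;
  // cache the outer segment scores
  std::vector<double> left(hi2 + 1), right(hi2 + 1);
  for (int t = lo1; t <= hi2; ++t) {
    left[t] = seg_score(S1, S2, s, t, lambda);
    right[t] = seg_score(S1, S2, t, e, lambda);
  }
  int b1 = lo1, b2 = lo1 + m;
  double best_v = R_NegInf;
  for (int t1 = lo1; t1 + m <= hi2; t1 += g) {
    for (int t2 = t1 + m; t2 <= hi2; t2 += g) {
      double v = left[t1] + seg_score(S1, S2, t1, t2, lambda) + right[t2];
      if (v > best_v) { best_v = v; b1 = t1; b2 = t2; }
    }
  }
  if (g > 1) {          // refine around the coarse optimum
    const int w = g;
    int c1 = b1, c2 = b2;
    for (int t1 = std::max(lo1, c1 - w); t1 <= std::min(hi2 - m, c1 + w); ++t1) {
      for (int t2 = std::max(t1 + m, c2 - w); t2 <= std::min(hi2, c2 + w); ++t2) {
        double v = left[t1] + seg_score(S1, S2, t1, t2, lambda) + right[t2];
        if (v > best_v) { best_v = v; b1 = t1; b2 = t2; }
      }
    }
  }
  return List::create(_["t"] = IntegerVector::create(b1, b2),
                      _["val"] = best_v);
}

// Score of every feasible segment [i, j), j - i >= m, as a dense matrix
// (row i, column j; -Inf where infeasible). Used by the exact oracle.
// [[Rcpp::export]]
NumericMatrix cpp_score_matrix(const arma::mat& S1, const arma::mat& S2,
                               int m, double lambda) {
  const int J = S1.n_rows;                 // N + 1
  NumericMatrix out(J, J);
  std::fill(out.begin(), out.end(), R_NegInf);
  for (int i = 1; i + m <= J; ++i)
    for (int j = i + m; j <= J; ++j)
      out(i - 1, j - 1) = seg_score(S1, S2, i, j, lambda);
  return out;
}
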