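// Structural alignment inner loops: Kabsch superposition and iterative
// superposition + global dynamic programming over a CA distance score.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares rigid superposition of B onto A (rows = points).
// Returns rotation Q (apply as B * Q.t()), translation t, and rmsd.
// Requires >= 3 non-collinear points.
static void kabsch_core(const arma::mat& A, const arma::mat& B,
                        arma::mat& Q, arma::rowvec& t, double& rmsd) {
  const arma::uword n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Bc.t() * Ac;  // 3x3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failure in superposition");
  // collinearity: the two leading singular values must both be informative
  arma::mat cov = Ac.t() * Ac;
  arma::vec ev = arma::eig_sym(cov);
  if (ev(1) < 1e-8 * std::max(1.0, ev(2))) {
    stop("degenerate (collinear) point set: superposition is not unique");
  }
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  Q = V * D * U.t();
  arma::mat Bt = Bc * Q.t();
  rmsd = std::sqrt(arma::accu(arma::square(Ac - Bt)) / double(n));
  t = ca - cb * Q.t();
}

// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows) stop("coordinate sets differ in length");
  if (A.n_rows < 3) stop("need at least 3 points");
  arma::mat Q;
  arma::rowvec t;
  double rmsd;
  kabsch_core(A, B, Q, t, rmsd);
  return List::create(_["rotation"] = Q, _["translation"] = t, _["rmsd"] = rmsd);
}

// Global Needleman-Wunsch over a precomputed similarity matrix S with a
// linear gap penalty; traceback ties resolved toward the diagonal, then
// toward consuming a row. Returns 1-based pair indices.
static arma::imat nw_core(const arma::mat& S, double gap) {
  const int na = S.n_rows, nb = S.n_cols;
  arma::mat H(na + 1, nb + 1);
  arma::Mat<short> P(na + 1, nb + 1);  // 0 diag, 1 up (gap in b), 2 left
  for (int i = 0; i <= na; ++i) { H(i, 0) = -gap * i; P(i, 0) = 1; }
  for (int j = 0; j <= nb; ++j) { H(0, j) = -gap * j; P(0, j) = 2; }
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double u = H(i - 1, j) - gap;
      double l = H(i, j - 1) - gap;
      if (d >= u && d >= l)      { H(i, j) = d; P(i, j) = 0; }
      else if (u >= l)           { H(i, j) = u; P(i, j) = 1; }
      else                       { H(i, j) = l; P(i, j) = 2; }
    }
  }
  std::vector<int> ia, ib;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    short p = P(i, j);
    if (i > 0 && j > 0 && p == 0) { ia.push_back(i); ib.push_back(j); --i; --j; }
    else if (i > 0 && (p == 1 || j == 0)) { --i; }
    else { --j; }
  }
  const int k = ia.size();
  arma::imat pairs(k, 2);
  for (int r = 0; r < k; ++r) {
    pairs(r, 0) = ia[k - 1 - r];
    pairs(r, 1) = ib[k - 1 - r];
  }
  return pairs;
}

// [[Rcpp::export]]
arma::imat nw_pairs_cpp(const arma::mat& S, double gap) {
  return nw_core(S, gap);
}

// Iterate {superpose on current pairs -> score matrix -> DP -> re-pair}
// until the pair set stabilises or max_iter is reached. The superposition
// frame is fitted on the well-fitting pairs only (distance below 2*d0
// under the previous frame, when at least 20 such pairs exist), so a
// rigid core is matched at noise level even when another part of the
// chain has moved (hinge motions); the reported rmsd is the optimal
// superposition over the full final pair set.
// [[Rcpp::export]]
List align_iterate_cpp(const arma::mat& A, const arma::mat& B,
                       arma::imat pairs, double d0, double gap, int max_iter) {
  if (pairs.n_rows < 3) stop("need at least 3 seed pairs");
  const double d02 = d0 * d0;
  const double trim2 = 4.0 * d02;  // fit frame on pairs within 2*d0
  arma::mat Q;
  arma::rowvec t;
  double rmsd = NA_REAL;
  bool converged = false;
  int iter = 0;
  arma::vec an(A.n_rows), bn(B.n_rows);
  arma::vec pair_d2;  // distances of current pairs under the current frame
  for (iter = 1; iter <= max_iter; ++iter) {
    arma::uvec ia = arma::conv_to<arma::uvec>::from(pairs.col(0)) - 1;
    arma::uvec ib = arma::conv_to<arma::uvec>::from(pairs.col(1)) - 1;
    if (pair_d2.n_elem == pairs.n_rows) {
      arma::uvec core = arma::find(pair_d2 < trim2);
      if (core.n_elem >= 20) {
        ia = ia.elem(core);
        ib = ib.elem(core);
      }
    }
    kabsch_core(A.rows(ia), B.rows(ib), Q, t, rmsd);
    arma::mat Bt = B * Q.t();
    Bt.each_row() += t;
    // squared distance matrix
    for (arma::uword i = 0; i < A.n_rows; ++i) an(i) = arma::dot(A.row(i), A.row(i));
    for (arma::uword j = 0; j < Bt.n_rows; ++j) bn(j) = arma::dot(Bt.row(j), Bt.row(j));
    arma::mat D2 = arma::repmat(an, 1, Bt.n_rows) +
                   arma::repmat(bn.t(), A.n_rows, 1) - 2.0 * A * Bt.t();
    D2.transform([](double v) { return v < 0 ? 0.0 : v; });
    arma::mat S = 1.0 / (1.0 + D2 / d02);
    arma::imat np = nw_core(S, gap);
    pair_d2.set_size(np.n_rows);
    for (arma::uword r = 0; r < np.n_rows; ++r) {
      pair_d2(r) = D2(np(r, 0) - 1, np(r, 1) - 1);
    }
    if (np.n_rows == pairs.n_rows &&
        arma::accu(arma::abs(np - pairs)) == 0) {
      converged = true;
      pairs = np;
      break;
    }
    pairs = np;
  }
  // pairs that fit tightly under the last working frame: used to rank
  // alignments obtained from different seeds
  int n_close = 0;
  for (arma::uword r = 0; r < pair_d2.n_elem; ++r) {
    if (pair_d2(r) < d02) ++n_close;
  }
  // final superposition/rmsd over the final pair set
  arma::uvec ia = arma::conv_to<arma::uvec>::from(pairs.col(0)) - 1;
  arma::uvec ib = arma::conv_to<arma::uvec>::from(pairs.col(1)) - 1;
  kabsch_core(A.rows(ia), B.rows(ib), Q, t, rmsd);
  return List::create(_["pairs"] = pairs, _["rmsd"] = rmsd,
                      _["n_iter"] = iter, _["converged"] = converged,
                      _["n_close"] = n_close);
}
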