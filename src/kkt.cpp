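// Block-tridiagonal solver for the collocation KKT systems. In a node-
// interleaved ordering (states/controls of node k followed by the
// multipliers of the dynamics block ending at node k) the KKT matrix of the
// transcription is block tridiagonal, so one forward block-elimination sweep
// and a back substitution solve it in O(N) dense block operations instead
// of a general sparse LU.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// i, j: 0-based triplet indices into the permuted system; bstart: 0-based
// block boundaries (length nblk+1); fixed: 0-based indices of variables
// fixed to fixval (bound handling). Returns x and an ok flag.
// [[Rcpp::export]]
List cpp_block_tridiag_solve(IntegerVector ti, IntegerVector tj,
                             NumericVector tx, IntegerVector bstart,
                             NumericVector rhs, IntegerVector fixed,
                             NumericVector fixval) {
  int nblk = bstart.size() - 1;
  int dim = bstart[nblk];
  // block lookup per index
  std::vector<int> blk(dim);
  for (int b = 0; b < nblk; ++b)
    for (int p = bstart[b]; p < bstart[b + 1]; ++p) blk[p] = b;
  std::vector<arma::mat> D(nblk), E(nblk), F(nblk);  // diag, sub, super
  for (int b = 0; b < nblk; ++b) {
    int nb = bstart[b + 1] - bstart[b];
    D[b].zeros(nb, nb);
    if (b > 0) E[b].zeros(nb, bstart[b] - bstart[b - 1]);
    if (b < nblk - 1) F[b].zeros(nb, bstart[b + 2] - bstart[b + 1]);
  }
  int nnz = ti.size();
  for (int t = 0; t < nnz; ++t) {
    int r = ti[t], c = tj[t];
    int br = blk[r], bc = blk[c];
    int lr = r - bstart[br], lc = c - bstart[bc];
    if (br == bc) D[br](lr, lc) += tx[t];
    else if (br == bc + 1) E[br](lr, lc) += tx[t];
    else if (br + 1 == bc) F[br](lr, lc) += tx[t];
    else return List::create(_["ok"] = false);  // not block tridiagonal
  }
  arma::vec b(rhs.begin(), dim);
  // fix variables: move their columns to the rhs, clear row/col, unit diag
  for (int f = 0; f < fixed.size(); ++f) {
    int p = fixed[f];
    double v = fixval[f];
    int bp = blk[p], lp = p - bstart[bp];
    // column p in D[bp], E[bp+1], F[bp-1]
    for (int r = bstart[bp]; r < bstart[bp + 1]; ++r)
      b[r] -= D[bp](r - bstart[bp], lp) * v;
    D[bp].col(lp).zeros();
    if (bp + 1 < nblk) {
      for (int r = bstart[bp + 1]; r < bstart[bp + 2]; ++r)
        b[r] -= E[bp + 1](r - bstart[bp + 1], lp) * v;
      E[bp + 1].col(lp).zeros();
    }
    if (bp > 0) {
      for (int r = bstart[bp - 1]; r < bstart[bp]; ++r)
        b[r] -= F[bp - 1](r - bstart[bp - 1], lp) * v;
      F[bp - 1].col(lp).zeros();
    }
    D[bp].row(lp).zeros();
    if (bp > 0) E[bp].row(lp).zeros();
    if (bp < nblk - 1) F[bp].row(lp).zeros();
    D[bp](lp, lp) = 1.0;
    b[p] = v;
  }
  // forward elimination
  std::vector<arma::mat> S(nblk);
  S[0] = D[0];
  for (int k = 1; k < nblk; ++k) {
    arma::mat W;
    bool ok = arma::solve(W, S[k - 1].t(), E[k].t(),
                          arma::solve_opts::no_approx);
    if (!ok) return List::create(_["ok"] = false);
    arma::mat Wt = W.t();  // E_k * S_{k-1}^{-1}
    S[k] = D[k] - Wt * F[k - 1];
    b.subvec(bstart[k], bstart[k + 1] - 1) -=
      Wt * b.subvec(bstart[k - 1], bstart[k] - 1);
  }
  // back substitution
  arma::vec x(dim, arma::fill::zeros);
  arma::vec xk;
  bool ok = arma::solve(xk, S[nblk - 1],
                        b.subvec(bstart[nblk - 1], dim - 1),
                        arma::solve_opts::no_approx);
  if (!ok) return List::create(_["ok"] = false);
  x.subvec(bstart[nblk - 1], dim - 1) = xk;
  for (int k = nblk - 2; k >= 0; --k) {
    arma::vec r = b.subvec(bstart[k], bstart[k + 1] - 1) -
      F[k] * x.subvec(bstart[k + 1], bstart[k + 2] - 1);
    bool okk = arma::solve(xk, S[k], r, arma::solve_opts::no_approx);
    if (!okk) return List::create(_["ok"] = false);
    x.subvec(bstart[k], bstart[k + 1] - 1) = xk;
  }
  if (!x.is_finite()) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["x"] = NumericVector(x.begin(), x.end()));
}
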