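// SIMPLS for a single response (de Jong 1993), returning the cumulative
// coefficient vectors for every component count 1..A in one pass.  This is
// the inner engine of the CARS/UVE/GA selectors, which issue on the order of
// 1e5 cross-validated fits per experiment, hence compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core fit on pre-centered X, y.  B is p x A; column k holds the coefficient
// vector of the k-component model.  Returns the number of components
// actually extracted (may stop early on rank deficiency).
static int simpls_core(const mat& X, const vec& y, int ncomp, mat& B) {
  const uword p = X.n_cols;
  vec s = X.t() * y;                 // p x 1 cross-covariance
  mat V(p, ncomp, fill::zeros);      // orthonormal basis of loadings
  B.zeros(p, ncomp);
  vec b(p, fill::zeros);
  int a = 0;
  for (; a < ncomp; ++a) {
    vec w = s;
    vec t = X * w;
    double tn = norm(t);
    if (tn < 1e-12 * (1.0 + norm(y))) break;   // no signal left
    t /= tn;
    w /= tn;
    vec pl = X.t() * t;              // x-loading
    double q = dot(y, t);            // y-loading
    b += w * q;
    B.col(a) = b;
    // orthonormalize loading against previous, deflate s
    vec v = pl;
    if (a > 0) v -= V.cols(0, a - 1) * (V.cols(0, a - 1).t() * pl);
    double vn = norm(v);
    if (vn < 1e-12) { ++a; break; }
    v /= vn;
    V.col(a) = v;
    s -= v * dot(v, s);
  }
  // pad: models asking for more components than extractable reuse the last
  for (int k = a; k < ncomp; ++k) B.col(k) = (a > 0) ? B.col(a - 1) : b;
  return a;
}

// [[Rcpp::export]]
Rcpp::List simpls_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat B;
  int a = simpls_core(Xc, yc, ncomp, B);
  return Rcpp::List::create(
    Rcpp::Named("coefficients") = B,
    Rcpp::Named("x_means") = xm.t(),
    Rcpp::Named("y_mean") = ym,
    Rcpp::Named("ncomp_used") = a);
}

// Cross-validated RMSE for every component count 1..ncomp.  fold is a
// 1-based integer fold label per row.  Centering is redone inside each
// training split.
// [[Rcpp::export]]
arma::vec simpls_cv_rmse_cpp(const arma::mat& X, const arma::vec& y,
                             int ncomp, const arma::ivec& fold) {
  const uword n = X.n_rows;
  const int nf = fold.max();
  vec sse(ncomp, fill::zeros);
  for (int f = 1; f <= nf; ++f) {
    uvec te = find(fold == f);
    uvec tr = find(fold != f);
    if (te.n_elem == 0 || tr.n_elem < 2) continue;
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    rowvec xm = mean(Xtr, 0);
    double ym = mean(ytr);
    Xtr.each_row() -= xm;
    ytr -= ym;
    mat B;
    simpls_core(Xtr, ytr, ncomp, B);
    mat Xte = X.rows(te);
    Xte.each_row() -= xm;
    mat pred = Xte * B + ym;         // nte x ncomp
    for (int k = 0; k < ncomp; ++k) {
      vec r = y.elem(te) - pred.col(k);
      sse(k) += dot(r, r);
    }
  }
  return sqrt(sse / double(n));
}
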