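// Compiled kernels: available-case mass-univariate OLS over a block of
// features, and 3-D connected-component labeling for cluster extraction
// and threshold-free enhancement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fit y ~ X independently at every feature (row of Y), using only the
// subjects observed (finite) at that feature. Y is features x subjects with
// NA marking missing cells; X is subjects x p (shared design).
// Reason codes: 0 fitted, 1 insufficient_n, 2 degenerate.
// [[Rcpp::export(name = ".olsFitBlock")]]
List olsFitBlock(const NumericMatrix& Y, const arma::mat& X, int minN) {
  const int F = Y.nrow(), n = Y.ncol(), p = X.n_cols;
  arma::mat est(F, p), se(F, p);
  est.fill(NA_REAL); se.fill(NA_REAL);
  arma::vec nobs(F, arma::fill::zeros), rss(F), sst(F);
  rss.fill(NA_REAL); sst.fill(NA_REAL);
  arma::ivec reason(F, arma::fill::zeros);

  arma::mat XtX(p, p);
  arma::vec Xty(p);

  for (int f = 0; f < F; ++f) {
    XtX.zeros(); Xty.zeros();
    double yty = 0.0, ysum = 0.0;
    int m = 0;
    for (int s = 0; s < n; ++s) {
      const double y = Y(f, s);
      if (ISNAN(y)) continue;
      ++m;
      ysum += y; yty += y * y;
      for (int a = 0; a < p; ++a) {
        const double xa = X(s, a);
        Xty(a) += xa * y;
        for (int b = a; b < p; ++b) XtX(a, b) += xa * X(s, b);
      }
    }
    nobs(f) = m;
    if (m < minN) { reason(f) = 1; continue; }
    const double tss = yty - ysum * ysum / m;
    sst(f) = tss;
    if (tss <= 0.0) { reason(f) = 2; continue; }
    XtX = arma::symmatu(XtX);
    arma::mat R;
    if (!arma::chol(R, XtX)) { reason(f) = 2; continue; }
    // guard near-singular designs (e.g. a constant covariate)
    const arma::vec d = R.diag();
    if (d.min() < 1e-8 * (d.max() + 1e-300)) { reason(f) = 2; continue; }
    const arma::vec b = arma::solve(arma::trimatu(R),
                        arma::solve(arma::trimatl(R.t()), Xty));
    double r = yty - 2.0 * arma::dot(b, Xty) +
               arma::dot(b, arma::symmatu(XtX) * b);
    if (r < 0.0) r = 0.0;
    rss(f) = r;
    const double sigma2 = r / (m - p);
    const arma::mat Rinv = arma::inv(arma::trimatu(R));
    const arma::vec covd = arma::sum(arma::square(Rinv), 1); // diag of (X'X)^-1
    for (int a = 0; a < p; ++a) {
      est(f, a) = b(a);
      se(f, a) = std::sqrt(sigma2 * covd(a));
    }
  }
  return List::create(_["estimate"] = est, _["se"] = se, _["nobs"] = nobs,
                      _["rss"] = rss, _["sst"] = sst, _["reason"] = reason);
}

// 3-D connected components of a logical array under 6/18/26 connectivity.
// Returns integer labels (0 = background), labeled in scan order.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector labelComponents(const LogicalVector& mask,
                              const IntegerVector& dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N, 0);

  // neighbor offsets
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad > 1) continue;
        if (connectivity == 18 && ad > 2) continue;
        nb.push_back({dx, dy, dz});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t v = 0; v < N; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    stack.clear();
    stack.push_back(v);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (const auto& d : nb) {
        const int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("nClusters") = next;
  return lab;
}
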