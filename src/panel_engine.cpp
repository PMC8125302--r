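// Exhaustive panel evaluation kernel: per candidate panel, restrict to
// complete cases, fit the shared-covariance linear discriminant classifier
// (empirical priors, n - k pooled covariance, ridge fallback when
// singular), and return resubstitution accuracy and residual-probability
// loss. Mirrors the reference R implementation (fit_lda / predict /
// accuracy / residual_loss) exactly; the R test suite cross-checks the two.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
List panel_search_engine(const arma::mat& X, const arma::ivec& y,
                         const arma::imat& panels, const int n_classes,
                         const double ridge, const int min_per_class) {
  const arma::uword n = X.n_rows;
  const arma::uword d = panels.n_rows;
  const arma::uword np = panels.n_cols;
  const int k = n_classes;

  IntegerVector out_n(np);
  NumericVector out_acc(np), out_loss(np), out_ridge(np);
  LogicalVector out_eval(np);

  arma::uvec rows(n);
  arma::mat Xs(n, d), M(k, d), S(d, d), R(d, d), Sinv(d, d), A(d, k);
  arma::vec cnt(k), cst(k), delta(k);

  for (arma::uword jp = 0; jp < np; ++jp) {
    // complete cases: label defined and all panel features observed
    arma::uword m = 0;
    for (arma::uword i = 0; i < n; ++i) {
      if (y[i] < 0) continue;
      bool ok = true;
      for (arma::uword f = 0; f < d; ++f) {
        if (!arma::is_finite(X(i, panels(f, jp) - 1))) { ok = false; break; }
      }
      if (ok) rows[m++] = i;
    }
    out_n[jp] = (int) m;
    out_eval[jp] = false;
    out_acc[jp] = NA_REAL;
    out_loss[jp] = NA_REAL;
    out_ridge[jp] = ridge;
    if ((int) m <= k) continue;

    cnt.zeros();
    M.zeros();
    for (arma::uword r = 0; r < m; ++r) {
      const arma::uword i = rows[r];
      const int c = y[i];
      cnt[c] += 1.0;
      for (arma::uword f = 0; f < d; ++f) {
        const double v = X(i, panels(f, jp) - 1);
        Xs(r, f) = v;
        M(c, f) += v;
      }
    }
    if (cnt.min() < (double) min_per_class) continue;
    for (int c = 0; c < k; ++c) M.row(c) /= cnt[c];

    S.zeros();
    for (arma::uword r = 0; r < m; ++r) {
      const int c = y[rows[r]];
      for (arma::uword f1 = 0; f1 < d; ++f1) {
        const double r1 = Xs(r, f1) - M(c, f1);
        for (arma::uword f2 = f1; f2 < d; ++f2)
          S(f1, f2) += r1 * (Xs(r, f2) - M(c, f2));
      }
    }
    S /= (double) (m - k);
    for (arma::uword f1 = 0; f1 < d; ++f1)
      for (arma::uword f2 = f1 + 1; f2 < d; ++f2) S(f2, f1) = S(f1, f2);
    S.diag() += ridge;

    double ridge_used = ridge;
    bool ok = arma::chol(R, S);
    if (!ok && ridge == 0.0) {
      ridge_used = 1e-6 * arma::trace(S) / (double) d;
      if (ridge_used <= 0.0) ridge_used = 1e-6;
      S.diag() += ridge_used;
      ok = arma::chol(R, S);
    }
    if (!ok) continue;
    const arma::mat Ri = arma::inv(arma::trimatu(R));
    Sinv = Ri * Ri.t();

    A = Sinv * M.t();                       // d x k
    for (int c = 0; c < k; ++c)
      cst[c] = -0.5 * arma::dot(M.row(c).t(), A.col(c)) +
               std::log(cnt[c] / (double) m);

    arma::uword correct = 0;
    double loss_sum = 0.0;
    for (arma::uword r = 0; r < m; ++r) {
      double dmax = -arma::datum::inf;
      int argmax = 0;
      for (int c = 0; c < k; ++c) {
        double dc = cst[c];
        for (arma::uword f = 0; f < d; ++f) dc += Xs(r, f) * A(f, c);
        delta[c] = dc;
        if (dc > dmax) { dmax = dc; argmax = c; }
      }
      double denom = 0.0;
      for (int c = 0; c < k; ++c) denom += std::exp(delta[c] - dmax);
      const int truec = y[rows[r]];
      const double p_true = std::exp(delta[truec] - dmax) / denom;
      loss_sum += 1.0 - p_true;
      if (argmax == truec) ++correct;
    }
    out_eval[jp] = true;
    out_acc[jp] = 100.0 * (double) correct / (double) m;
    out_loss[jp] = 100.0 * loss_sum / (double) m;
    out_ridge[jp] = ridge_used;
  }

  return List::create(_["n"] = out_n, _["accuracy"] = out_acc,
                      _["loss"] = out_loss, _["evaluable"] = out_eval,
                      _["ridge"] = out_ridge);
}
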