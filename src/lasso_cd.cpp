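#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// L1-penalized logistic regression along a decreasing lambda path.
// Objective: -(1/n) loglik + lambda * ||beta||_1, intercept unpenalized.
//
// IRLS outer loop (weights floored at 1e-5). Each IRLS round solves the
// weighted-least-squares surrogate by cyclic coordinate descent with
// soft-thresholding, accelerated by an active-set Newton step: once a full
// sweep has fixed the active set and signs, the equality-constrained
// quadratic is solved exactly (augmented with the unpenalized intercept);
// coordinates whose sign flips are zeroed and the solve repeated. Full
// sweeps re-admit screened-out coordinates. Warm starts along the path.
// A lambda is declared converged only when the true-gradient KKT residual
// is below kkt_tol, so surrogate shortcuts can never bias the solution.

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List lasso_logistic_path_cpp(const arma::mat &X, const arma::vec &y,
                             const arma::vec &lambda, double tol,
                             int max_iter, double kkt_tol) {
  const int n = X.n_rows, p = X.n_cols, L = lambda.n_elem;
  arma::mat beta_out(p, L, arma::fill::zeros);
  arma::vec a0_out(L, arma::fill::zeros);
  IntegerVector iters_out(L);
  LogicalVector converged_out(L);

  arma::vec beta(p, arma::fill::zeros);
  const double ybar = arma::mean(y);
  double b0 = std::log(ybar / (1.0 - ybar));

  arma::vec eta(n, arma::fill::value(b0)), prob(n), w(n), r(n);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool done = false;
    double inner_tol = (tol > 1e-3) ? tol : 1e-3;

    while (!done && it < max_iter) {
      // IRLS: working weights and residuals at current (b0, beta)
      prob = 1.0 / (1.0 + arma::exp(-eta));
      w = prob % (1.0 - prob);
      w.transform([](double v) { return v < 1e-5 ? 1e-5 : v; });
      r = (y - prob) / w;

      // inner solve of the weighted LS surrogate
      int newton_left = 6; // Newton steps are a bounded accelerator only
      for (;;) {
        // one full cyclic CD sweep over all coordinates
        double dlmax = 0.0;
        const double *wp = w.memptr();
        double *rp = r.memptr();
        for (int j = 0; j < p; ++j) {
          const double *xj = X.colptr(j);
          double num = 0.0, den = 0.0;
          for (int i = 0; i < n; ++i) {
            const double wx = wp[i] * xj[i];
            num += wx * rp[i];
            den += wx * xj[i];
          }
          den /= n;
          if (den <= 0.0) continue;
          const double z = num / n + den * beta[j];
          const double bj = soft(z, lam) / den;
          const double diff = bj - beta[j];
          if (diff != 0.0) {
            for (int i = 0; i < n; ++i) rp[i] -= diff * xj[i];
            beta[j] = bj;
            if (std::fabs(diff) > dlmax) dlmax = std::fabs(diff);
          }
        }
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += wp[i]; swr += wp[i] * rp[i]; }
        const double d0 = swr / sw;
        if (d0 != 0.0) { b0 += d0; r -= d0; if (std::fabs(d0) > dlmax) dlmax = std::fabs(d0); }
        ++it;
        if (dlmax < inner_tol || it >= max_iter) break;

        if (newton_left <= 0) continue; // pure CD from here on (monotone)
        --newton_left;

        // active-set Newton refinement at the current signs; accepted only
        // if it decreases the surrogate objective (keeps the loop monotone)
        const arma::vec beta_save = beta;
        const arma::vec r_save = r;
        const double b0_save = b0;
        const double f_old = 0.5 * arma::dot(w, r % r) / n +
          lam * arma::accu(arma::abs(beta));
        arma::uvec act = arma::find(beta != 0.0);
        for (int nt = 0; nt < 12 && act.n_elem > 0; ++nt) {
          const int pa = act.n_elem;
          arma::mat Xa(n, pa + 1);
          Xa.col(0).ones();
          for (int k = 0; k < pa; ++k) Xa.col(k + 1) = X.col(act[k]);
          arma::mat G = Xa.t() * (Xa.each_col() % w) / n;
          // right-hand side at the full working response z = b0 + X beta + r
          arma::vec zfull = r + b0 * arma::ones(n);
          for (int k = 0; k < pa; ++k) zfull += beta[act[k]] * X.col(act[k]);
          arma::vec rhs = Xa.t() * (w % zfull) / n;
          for (int k = 0; k < pa; ++k) {
            rhs[k + 1] -= lam * (beta[act[k]] > 0 ? 1.0 : -1.0);
          }
          arma::vec sol;
          const bool ok = arma::solve(sol, G, rhs,
                                      arma::solve_opts::likely_sympd +
                                      arma::solve_opts::no_approx);
          if (!ok) break; // singular system: fall back to plain CD sweeps
          // zero any coordinate whose sign flipped, keep the rest
          arma::uvec keep(pa);
          int nk = 0;
          bool flipped = false;
          for (int k = 0; k < pa; ++k) {
            const double s_old = beta[act[k]] > 0 ? 1.0 : -1.0;
            if (sol[k + 1] * s_old <= 0.0) {
              beta[act[k]] = 0.0;
              flipped = true;
            } else {
              keep[nk++] = act[k];
            }
          }
          if (!flipped) {
            b0 = sol[0];
            for (int k = 0; k < pa; ++k) beta[act[k]] = sol[k + 1];
            break;
          }
          act = keep.head(nk);
          if (act.n_elem == 0) {
            // intercept-only weighted solve
            b0 = arma::dot(w, zfull) / arma::accu(w);
          }
        }
        // refresh the working residual after the Newton step
        r = (y - prob) / w; // z - (b0 + X beta) with z = eta_old + (y-p)/w
        {
          arma::vec fit_new = b0 * arma::ones(n);
          arma::uvec nz = arma::find(beta != 0.0);
          for (arma::uword k = 0; k < nz.n_elem; ++k) {
            fit_new += beta[nz[k]] * X.col(nz[k]);
          }
          r += eta - fit_new;
        }
        const double f_new = 0.5 * arma::dot(w, r % r) / n +
          lam * arma::accu(arma::abs(beta));
        if (f_new > f_old - 1e-14) { // no decrease: revert, rely on CD
          beta = beta_save;
          r = r_save;
          b0 = b0_save;
          newton_left = 0;
        }
        if (it >= max_iter) break;
      }

      // refresh eta from scratch and check true-gradient KKT conditions
      eta = b0 * arma::ones(n);
      {
        arma::uvec nz = arma::find(beta != 0.0);
        for (arma::uword k = 0; k < nz.n_elem; ++k) {
          eta += beta[nz[k]] * X.col(nz[k]);
        }
      }
      arma::vec resid = 1.0 / (1.0 + arma::exp(-eta)) - y;
      double kkt = std::fabs(arma::mean(resid));
      arma::vec g = X.t() * resid / n;
      for (int j = 0; j < p; ++j) {
        double v;
        if (beta[j] == 0.0) {
          v = std::fabs(g[j]) - lam;
          if (v < 0.0) v = 0.0;
        } else {
          v = std::fabs(g[j] + lam * (beta[j] > 0 ? 1.0 : -1.0));
        }
        if (v > kkt) kkt = v;
      }
      if (kkt <= kkt_tol) {
        done = true;
      } else {
        inner_tol = 0.1 * kkt;
        if (inner_tol < tol) inner_tol = tol;
      }
    }

    beta_out.col(l) = beta;
    a0_out[l] = b0;
    iters_out[l] = it;
    converged_out[l] = done;
  }

  return List::create(_["beta"] = NumericMatrix(wrap(beta_out)),
                      _["a0"] = NumericVector(wrap(a0_out)),
                      _["iters"] = iters_out, _["converged"] = converged_out);
}
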