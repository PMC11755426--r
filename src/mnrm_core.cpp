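// Computational core for the multidimensional nominal response model:
// cached-logit Metropolis sweeps over person parameters, complete-data
// derivatives for the Robbins-Monro update, Newton MAP scoring with
// Laplace quantities, and multinomial response sampling.  All randomness
// goes through R's RNG so set.seed() governs every draw.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double log_sum_exp(const rowvec& x) {
  double m = x.max();
  return m + std::log(accu(exp(x - m)));
}

// Effective category-weight matrix of item i: (K+1) x D with entries
// alpha_{id} * s_{idk}.
static mat eff_weights(const cube& W, const mat& alpha, uword i) {
  mat A = W.slice(i).t();            // (K+1) x D
  A.each_row() %= alpha.row(i);
  return A;
}

// N x (K+1) logit matrix of item i over all persons.
static mat item_logits(const cube& W, const mat& alpha, const mat& gamma,
                       const mat& Theta, uword i) {
  mat L = Theta * eff_weights(W, alpha, i).t();
  L.each_row() += gamma.row(i);
  return L;
}

// [[Rcpp::export]]
arma::vec cpp_loglik_persons(const arma::imat& Y, const arma::cube& W,
                             const arma::mat& alpha, const arma::mat& gamma,
                             const arma::mat& Theta) {
  uword N = Y.n_rows, I = Y.n_cols;
  vec ll(N, fill::zeros);
  for (uword i = 0; i < I; ++i) {
    mat L = item_logits(W, alpha, gamma, Theta, i);
    for (uword n = 0; n < N; ++n)
      ll(n) += L(n, (uword)Y(n, i)) - log_sum_exp(L.row(n));
  }
  return ll;
}

// Component-wise random-walk Metropolis sweeps on Theta given item and
// correlation parameters.  Logits are cached per (person, item) and
// updated incrementally on acceptance.
// [[Rcpp::export]]
Rcpp::List cpp_mh_sweeps(const arma::imat& Y, const arma::cube& W,
                         const arma::mat& alpha, const arma::mat& gamma,
                         arma::mat Theta, const arma::mat& SigmaInv,
                         const arma::vec& steps, const int nsweeps) {
  uword N = Y.n_rows, I = Y.n_cols, D = Theta.n_cols, K1 = gamma.n_cols;

  // items loading on each dimension (nonzero slope)
  std::vector<std::vector<uword>> items(D);
  for (uword d = 0; d < D; ++d)
    for (uword i = 0; i < I; ++i)
      if (alpha(i, d) != 0.0) items[d].push_back(i);

  // cached logits (N x K1 per item) and per-cell loglik contributions
  cube L(N, K1, I);
  mat C(N, I);
  for (uword i = 0; i < I; ++i) {
    L.slice(i) = item_logits(W, alpha, gamma, Theta, i);
    for (uword n = 0; n < N; ++n)
      C(n, i) = L(n, (uword)Y(n, i), i) - log_sum_exp(L.slice(i).row(n));
  }

  vec acc(D, fill::zeros);
  uword max_it = 0;
  for (uword d = 0; d < D; ++d) max_it = std::max(max_it, (uword)items[d].size());
  mat saved(K1, max_it);
  vec savedC(max_it);

  for (int s = 0; s < nsweeps; ++s) {
    for (uword d = 0; d < D; ++d) {
      const std::vector<uword>& it = items[d];
      const uword ni = it.size();
      for (uword n = 0; n < N; ++n) {
        double old = Theta(n, d);
        double prop = old + steps(d) * norm_rand();
        double dth = prop - old;
        // prior: -0.5 * theta' SigmaInv theta, only component d moves
        double cross = 0.0;
        for (uword dd = 0; dd < D; ++dd)
          if (dd != d) cross += SigmaInv(d, dd) * Theta(n, dd);
        double dprior = -0.5 * SigmaInv(d, d) * (prop * prop - old * old)
                        - dth * cross;
        double dll = 0.0;
        for (uword j = 0; j < ni; ++j) {
          uword i = it[j];
          const double* Lp = L.slice_memptr(i);
          const double* Wp = W.slice_memptr(i);
          double* sv = saved.colptr(j);
          double ad = alpha(i, d);
          double mx = -datum::inf;
          for (uword k = 0; k < K1; ++k) {
            double v = Lp[k * N + n] + ad * Wp[k * D + d] * dth;
            sv[k] = v;
            if (v > mx) mx = v;
          }
          double se = 0.0;
          for (uword k = 0; k < K1; ++k) se += std::exp(sv[k] - mx);
          double cn = sv[(uword)Y(n, i)] - mx - std::log(se);
          dll += cn - C(n, i);
          savedC(j) = cn;
        }
        if (std::log(unif_rand()) < dll + dprior) {
          Theta(n, d) = prop;
          for (uword j = 0; j < ni; ++j) {
            uword i = it[j];
            double* Lp = L.slice_memptr(i);
            const double* sv = saved.colptr(j);
            for (uword k = 0; k < K1; ++k) Lp[k * N + n] = sv[k];
            C(n, i) = savedC(j);
          }
          acc(d) += 1.0;
        }
      }
    }
  }
  acc /= (double)(N * nsweeps);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("accept") = acc);
}

// Complete-data gradient and Hessian blocks of each item's free
// parameters given imputed Theta.  Parameter order per item: free slopes
// (dimensions in `adims`, ascending), then free intercepts (categories in
// `gcats`, ascending, category 0 never free).
// [[Rcpp::export]]
Rcpp::List cpp_item_derivs(const arma::imat& Y, const arma::cube& W,
                           const arma::mat& alpha, const arma::mat& gamma,
                           const arma::mat& Theta, const arma::imat& amask,
                           const arma::imat& gmask) {
  uword N = Y.n_rows, I = Y.n_cols, D = Theta.n_cols, K1 = gamma.n_cols;
  Rcpp::List out(I);
  for (uword i = 0; i < I; ++i) {
    uvec adims = find(amask.row(i).t() == 1);
    uvec gcats = find(gmask.row(i).t() == 1);
    uword na = adims.n_elem, ng = gcats.n_elem, np = na + ng;
    mat L = item_logits(W, alpha, gamma, Theta, i);
    vec grad(np, fill::zeros);
    mat hess(np, np, fill::zeros);
    mat U(K1, np, fill::zeros);
    for (uword g = 0; g < ng; ++g) U(gcats(g), na + g) = 1.0;
    vec p(K1), pbar(np);
    const double* Wp = W.slice_memptr(i);
    for (uword n = 0; n < N; ++n) {
      const double* Lp = L.memptr();
      double mx = -datum::inf;
      for (uword k = 0; k < K1; ++k)
        if (Lp[k * N + n] > mx) mx = Lp[k * N + n];
      double se = 0.0;
      for (uword k = 0; k < K1; ++k) {
        p(k) = std::exp(Lp[k * N + n] - mx);
        se += p(k);
      }
      p /= se;
      // covariate matrix U: row k holds d logit_k / d param
      for (uword a = 0; a < na; ++a) {
        uword d = adims(a);
        double th = Theta(n, d);
        for (uword k = 0; k < K1; ++k) U(k, a) = th * Wp[k * D + d];
      }
      // pbar = U' p
      for (uword c = 0; c < np; ++c) {
        double s = 0.0;
        const double* Uc = U.colptr(c);
        for (uword k = 0; k < K1; ++k) s += Uc[k] * p(k);
        pbar(c) = s;
      }
      uword y = (uword)Y(n, i);
      for (uword c = 0; c < np; ++c) grad(c) += U(y, c) - pbar(c);
      // hess += sum_k p_k u_k u_k' - pbar pbar'
      for (uword c = 0; c < np; ++c) {
        const double* Uc = U.colptr(c);
        for (uword c2 = c; c2 < np; ++c2) {
          const double* Uc2 = U.colptr(c2);
          double s = 0.0;
          for (uword k = 0; k < K1; ++k) s += p(k) * Uc[k] * Uc2[k];
          s -= pbar(c) * pbar(c2);
          hess(c, c2) += s;
          if (c2 != c) hess(c2, c) += s;
        }
      }
    }
    out[i] = Rcpp::List::create(
      Rcpp::Named("grad") = grad, Rcpp::Named("hess") = hess,
      Rcpp::Named("adims") = adims + 1, Rcpp::Named("gcats") = gcats + 1);
  }
  return out;
}

// Newton MAP scoring with step halving; returns modes, log posterior
// (log p(Y|theta) + log N(theta; 0, Sigma)), log|−H| at the mode (for the
// Laplace approximation) and convergence flags.
// [[Rcpp::export]]
Rcpp::List cpp_map_scores(const arma::imat& Y, const arma::cube& W,
                          const arma::mat& alpha, const arma::mat& gamma,
                          const arma::mat& Sigma, const double tol,
                          const int maxit) {
  uword N = Y.n_rows, I = Y.n_cols, D = Sigma.n_cols, K1 = gamma.n_cols;
  mat SigmaInv = inv_sympd(Sigma);
  double ldS, sgn;
  log_det(ldS, sgn, Sigma);
  const double cst = -0.5 * (double)D * std::log(2.0 * datum::pi) - 0.5 * ldS;

  std::vector<mat> A(I);
  for (uword i = 0; i < I; ++i) A[i] = eff_weights(W, alpha, i);

  mat Th(N, D, fill::zeros);
  vec logpost(N), logdet(N);
  ivec conv(N, fill::ones);

  for (uword n = 0; n < N; ++n) {
    vec th(D, fill::zeros);
    auto objective = [&](const vec& t) {
      double o = cst - 0.5 * as_scalar(t.t() * SigmaInv * t);
      for (uword i = 0; i < I; ++i) {
        rowvec l = (A[i] * t).t() + gamma.row(i);
        o += l((uword)Y(n, i)) - log_sum_exp(l);
      }
      return o;
    };
    double obj = objective(th);
    mat H(D, D);
    bool ok = false;
    for (int it = 0; it < maxit; ++it) {
      vec g = -SigmaInv * th;
      H = -SigmaInv;
      for (uword i = 0; i < I; ++i) {
        vec l = A[i] * th + gamma.row(i).t();
        vec p = exp(l - l.max());
        p /= accu(p);
        g += A[i].row((uword)Y(n, i)).t() - A[i].t() * p;
        mat AP = A[i].each_col() % p;
        H -= A[i].t() * AP - (A[i].t() * p) * (p.t() * A[i]);
      }
      vec step = solve(-H, g);
      double nobj = 0.0;
      double sc = 1.0;
      int h = 0;
      for (; h < 30; ++h) {
        nobj = objective(th + sc * step);
        if (nobj >= obj - 1e-12) break;
        sc *= 0.5;
      }
      if (h == 30) { conv(n) = 0; break; }
      th += sc * step;
      double delta = std::abs(nobj - obj);
      obj = nobj;
      if (max(abs(sc * step)) < tol || delta < 1e-12) { ok = true; break; }
    }
    if (!ok && conv(n) == 1) conv(n) = 0;
    // refresh Hessian at the mode for the Laplace determinant
    H = -SigmaInv;
    for (uword i = 0; i < I; ++i) {
      vec l = A[i] * th + gamma.row(i).t();
      vec p = exp(l - l.max());
      p /= accu(p);
      mat AP = A[i].each_col() % p;
      H -= A[i].t() * AP - (A[i].t() * p) * (p.t() * A[i]);
    }
    double ld, s2;
    log_det(ld, s2, -H);
    Th.row(n) = th.t();
    logpost(n) = obj;
    logdet(n) = ld;
  }
  return Rcpp::List::create(
    Rcpp::Named("theta") = Th, Rcpp::Named("logpost") = logpost,
    Rcpp::Named("logdet_negH") = logdet, Rcpp::Named("converged") = conv);
}

// Draw responses by inverse CDF on the category probabilities.
// [[Rcpp::export]]
arma::imat cpp_sample_responses(const arma::cube& W, const arma::mat& alpha,
                                const arma::mat& gamma,
                                const arma::mat& Theta) {
  uword N = Theta.n_rows, I = alpha.n_rows, K1 = gamma.n_cols;
  imat Y(N, I);
  for (uword i = 0; i < I; ++i) {
    mat L = item_logits(W, alpha, gamma, Theta, i);
    for (uword n = 0; n < N; ++n) {
      rowvec p = exp(L.row(n) - L.row(n).max());
      p /= accu(p);
      double u = unif_rand(), cum = 0.0;
      uword k = K1 - 1;
      for (uword m = 0; m < K1; ++m) {
        cum += p(m);
        if (u <= cum) { k = m; break; }
      }
      Y(n, i) = (int)k;
    }
  }
  return Y;
}

// Importance-sampled marginal log-likelihood with a per-person
// N(MAP mode, (−H)^{-1}) proposal.
// [[Rcpp::export]]
arma::vec cpp_importance_ll(const arma::imat& Y, const arma::cube& W,
                            const arma::mat& alpha, const arma::mat& gamma,
                            const arma::mat& Sigma, const arma::mat& Mode,
                            const int ndraws) {
  uword N = Y.n_rows, I = Y.n_cols, D = Sigma.n_cols;
  mat SigmaInv = inv_sympd(Sigma);
  double ldS, sgn;
  log_det(ldS, sgn, Sigma);
  const double cst = -0.5 * (double)D * std::log(2.0 * datum::pi);

  std::vector<mat> A(I);
  for (uword i = 0; i < I; ++i) A[i] = eff_weights(W, alpha, i);

  vec out(N);
  for (uword n = 0; n < N; ++n) {
    vec mode = Mode.row(n).t();
    mat H = -SigmaInv;
    for (uword i = 0; i < I; ++i) {
      vec l = A[i] * mode + gamma.row(i).t();
      vec p = exp(l - l.max());
      p /= accu(p);
      mat AP = A[i].each_col() % p;
      H -= A[i].t() * AP - (A[i].t() * p) * (p.t() * A[i]);
    }
    mat Prec = -H;                      // proposal precision
    mat Lch = chol(inv_sympd(Prec), "lower");
    double ldP, s2;
    log_det(ldP, s2, Prec);
    vec lw(ndraws);
    for (int m = 0; m < ndraws; ++m) {
      vec z(D);
      for (uword d = 0; d < D; ++d) z(d) = norm_rand();
      vec t = mode + Lch * z;
      double ll = cst - 0.5 * ldS - 0.5 * as_scalar(t.t() * SigmaInv * t);
      for (uword i = 0; i < I; ++i) {
        rowvec l = (A[i] * t).t() + gamma.row(i);
        ll += l((uword)Y(n, i)) - log_sum_exp(l);
      }
      // proposal log density
      double lq = cst + 0.5 * ldP - 0.5 * as_scalar(z.t() * z);
      lw(m) = ll - lq;
    }
    double mx = lw.max();
    out(n) = mx + std::log(accu(exp(lw - mx))) - std::log((double)ndraws);
  }
  return out;
}
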