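// Numerical core for the binomial admixture model: log-likelihood, analytic
// block derivatives, and safeguarded sequential-quadratic-programming updates
// of the ancestry matrix Q and the allele-frequency matrix F.
//
// Conventions shared with the R layer:
//   * genotype counts n_ij in {0,1,2}, NA_INTEGER = missing/masked;
//   * Q is I x K row-stochastic, F is K x J with entries in [EPS_F, 1-EPS_F];
//   * p_ij = sum_k q_ik f_kj is clamped to [P_LO, 1-P_LO] before logs;
//   * the Q update receives the genotype matrix TRANSPOSED (J x I) so that a
//     row subproblem reads a contiguous column.
//
// Per-row / per-column subproblems are independent; when OpenMP is available
// they run in parallel with disjoint writes and all reductions are performed
// serially in index order afterwards, so results are identical for any number
// of threads.

#include <RcppArmadillo.h>
#ifdef _OPENMP
#include <omp.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double P_LO = 1e-10;
static const double EPS_F = 1e-6;

inline double clamp_p(double p) {
  if (p < P_LO) return P_LO;
  if (p > 1.0 - P_LO) return 1.0 - P_LO;
  return p;
}

// log-likelihood contribution of one individual; genotypes transposed (J x I)
static double row_ll(const Rcpp::IntegerMatrix& nT, const mat& F,
                     const double* q, int i) {
  const int J = nT.nrow();
  const int K = F.n_rows;
  double s = 0.0;
  for (int j = 0; j < J; ++j) {
    const int nij = nT(j, i);
    if (nij == NA_INTEGER) continue;
    double p = 0.0;
    for (int k = 0; k < K; ++k) p += q[k] * F.at(k, j);
    p = clamp_p(p);
    s += nij * std::log(p) + (2 - nij) * std::log1p(-p);
  }
  return s;
}

// log-likelihood contribution of one marker
static double col_ll(const Rcpp::IntegerMatrix& n, const mat& Q,
                     const double* f, int j) {
  const int I = n.nrow();
  const int K = Q.n_cols;
  double s = 0.0;
  for (int i = 0; i < I; ++i) {
    const int nij = n(i, j);
    if (nij == NA_INTEGER) continue;
    double p = 0.0;
    for (int k = 0; k < K; ++k) p += Q.at(i, k) * f[k];
    p = clamp_p(p);
    s += nij * std::log(p) + (2 - nij) * std::log1p(-p);
  }
  return s;
}

// approximate-l0 penalty of one Q row: lam * sum_k ln(1 + q_k/gam) / ln(1 + 1/gam)
inline double row_penalty(const double* q, int K, double lam, double gam) {
  if (lam <= 0.0) return 0.0;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::log1p(q[k] / gam);
  return lam * s / std::log1p(1.0 / gam);
}

// ---------------------------------------------------------------------------
// Small dense concave QP:  maximize g'(x-x0) + 0.5 (x-x0)' H (x-x0)
// subject to lo <= x <= hi and (optionally) sum(x) = sum(x0).
// A = -H must be positive definite (caller adds a ridge). Primal active-set.
// Returns the solution; sets ok=false on a linear-algebra failure.
// ---------------------------------------------------------------------------
static vec qp_solve(const mat& A, const vec& g, const vec& x0,
                    const vec& lo, const vec& hi, bool sumcon, bool& ok) {
  const int K = (int)x0.n_elem;
  ok = true;
  vec x = x0;
  for (int k = 0; k < K; ++k) {
    if (x[k] < lo[k]) x[k] = lo[k];
    if (x[k] > hi[k]) x[k] = hi[k];
  }
  // working set: 0 free, -1 at lower bound, +1 at upper bound
  ivec w(K, fill::zeros);
  for (int k = 0; k < K; ++k) {
    if (x[k] <= lo[k] + 1e-14) w[k] = -1;
    else if (x[k] >= hi[k] - 1e-14) w[k] = 1;
  }
  const int maxit = 10 * K + 20;
  for (int iter = 0; iter < maxit; ++iter) {
    // gradient of the (minimized) negated model at x
    vec gr = A * (x - x0) - g;
    std::vector<int> fr;
    fr.reserve(K);
    for (int k = 0; k < K; ++k) if (w[k] == 0) fr.push_back(k);
    const int nf = (int)fr.size();
    vec p(K, fill::zeros);
    double nu = 0.0;
    if (nf > 0) {
      const int dim = nf + (sumcon ? 1 : 0);
      mat KKT(dim, dim, fill::zeros);
      vec rhs(dim, fill::zeros);
      for (int a = 0; a < nf; ++a) {
        for (int b = 0; b < nf; ++b) KKT(a, b) = A.at(fr[a], fr[b]);
        rhs[a] = -gr[fr[a]];
        if (sumcon) { KKT(a, nf) = 1.0; KKT(nf, a) = 1.0; }
      }
      vec sol;
      if (!solve(sol, KKT, rhs, solve_opts::no_approx)) { ok = false; return x0; }
      for (int a = 0; a < nf; ++a) p[fr[a]] = sol[a];
      if (sumcon) nu = sol[nf];
    } else if (sumcon) {
      // degenerate: everything active; pick the multiplier that best balances
      nu = -mean(gr);
    }
    if (norm(p, "inf") < 1e-12) {
      // KKT multiplier check on active bounds; release the worst violator
      int worst = -1;
      double worstval = -1e-9;
      for (int k = 0; k < K; ++k) {
        if (w[k] == 0) continue;
        const double lambda_k = (w[k] == -1) ? (gr[k] + nu) : -(gr[k] + nu);
        if (lambda_k < worstval) { worstval = lambda_k; worst = k; }
      }
      if (worst < 0) return x;
      w[worst] = 0;
      continue;
    }
    // ratio test against the bounds of the free variables
    double alpha = 1.0;
    int blocker = -1, bdir = 0;
    for (int a = 0; a < nf; ++a) {
      const int k = fr[a];
      if (p[k] < -1e-16) {
        const double am = (lo[k] - x[k]) / p[k];
        if (am < alpha) { alpha = am; blocker = k; bdir = -1; }
      } else if (p[k] > 1e-16) {
        const double am = (hi[k] - x[k]) / p[k];
        if (am < alpha) { alpha = am; blocker = k; bdir = 1; }
      }
    }
    if (alpha < 0.0) alpha = 0.0;
    x += alpha * p;
    if (blocker >= 0 && alpha < 1.0) {
      w[blocker] = bdir;
      x[blocker] = (bdir == -1) ? lo[blocker] : hi[blocker];
    }
  }
  return x;
}

// ---------------------------------------------------------------------------
// Exported routines
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_loglik(Rcpp::IntegerMatrix n, arma::mat Q, arma::mat F) {
  const int J = n.ncol();
  double s = 0.0;
  for (int j = 0; j < J; ++j) s += col_ll(n, Q, F.colptr(j), j);
  return s;
}

// [[Rcpp::export]]
Rcpp::List cpp_q_derivs(Rcpp::IntegerMatrix nT, arma::mat Q, arma::mat F) {
  const int I = Q.n_rows, K = Q.n_cols, J = nT.nrow();
  mat grads(I, K, fill::zeros);
  cube hessians(K, K, I, fill::zeros);
  for (int i = 0; i < I; ++i) {
    vec g(K, fill::zeros);
    mat h(K, K, fill::zeros);
    for (int j = 0; j < J; ++j) {
      const int nij = nT(j, i);
      if (nij == NA_INTEGER) continue;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += Q.at(i, k) * F.at(k, j);
      p = clamp_p(p);
      const double a = nij / p - (2 - nij) / (1.0 - p);
      const double wgt = nij / (p * p) + (2 - nij) / ((1.0 - p) * (1.0 - p));
      for (int k = 0; k < K; ++k) {
        const double fk = F.at(k, j);
        g[k] += a * fk;
        for (int l = 0; l <= k; ++l) h.at(k, l) += wgt * fk * F.at(l, j);
      }
    }
    h = symmatl(h);
    grads.row(i) = g.t();
    hessians.slice(i) = -h;
  }
  return Rcpp::List::create(Rcpp::Named("gradients") = grads,
                            Rcpp::Named("hessians") = hessians);
}

// [[Rcpp::export]]
Rcpp::List cpp_f_derivs(Rcpp::IntegerMatrix n, arma::mat Q, arma::mat F) {
  const int I = Q.n_rows, K = Q.n_cols, J = n.ncol();
  mat grads(K, J, fill::zeros);
  cube hessians(K, K, J, fill::zeros);
  for (int j = 0; j < J; ++j) {
    vec g(K, fill::zeros);
    mat h(K, K, fill::zeros);
    for (int i = 0; i < I; ++i) {
      const int nij = n(i, j);
      if (nij == NA_INTEGER) continue;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += Q.at(i, k) * F.at(k, j);
      p = clamp_p(p);
      const double a = nij / p - (2 - nij) / (1.0 - p);
      const double wgt = nij / (p * p) + (2 - nij) / ((1.0 - p) * (1.0 - p));
      for (int k = 0; k < K; ++k) {
        const double qk = Q.at(i, k);
        g[k] += a * qk;
        for (int l = 0; l <= k; ++l) h.at(k, l) += wgt * qk * Q.at(i, l);
      }
    }
    h = symmatl(h);
    grads.col(j) = g;
    hessians.slice(j) = -h;
  }
  return Rcpp::List::create(Rcpp::Named("gradients") = grads,
                            Rcpp::Named("hessians") = hessians);
}

// One SQP pass over all Q rows. nT is J x I (transposed genotypes).
// fixed rows are returned untouched. lam/gam: approximate-l0 penalty via a
// local linear approximation inside the QP; the acceptance check uses the
// exact penalized row objective with step halving toward the current point.
// [[Rcpp::export]]
Rcpp::List cpp_update_Q(Rcpp::IntegerMatrix nT, arma::mat Q, arma::mat F,
                        Rcpp::LogicalVector fixed, double lam, double gam,
                        int threads) {
  const int I = Q.n_rows, K = Q.n_cols, J = nT.nrow();
  mat Qout = Q;
  vec rowll(I, fill::zeros);
  ivec failed(I, fill::zeros);
  const double lnorm = (lam > 0.0) ? std::log1p(1.0 / gam) : 1.0;
#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(threads > 0 ? threads : 1)
#endif
  for (int i = 0; i < I; ++i) {
    if (fixed[i]) {
      vec qi = Q.row(i).t();
      rowll[i] = row_ll(nT, F, qi.memptr(), i);
      continue;
    }
    vec q = Q.row(i).t();
    vec g(K, fill::zeros);
    mat Apos(K, K, fill::zeros);
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      const int nij = nT(j, i);
      if (nij == NA_INTEGER) continue;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += q[k] * F.at(k, j);
      p = clamp_p(p);
      ll += nij * std::log(p) + (2 - nij) * std::log1p(-p);
      const double a = nij / p - (2 - nij) / (1.0 - p);
      const double wgt = nij / (p * p) + (2 - nij) / ((1.0 - p) * (1.0 - p));
      for (int k = 0; k < K; ++k) {
        const double fk = F.at(k, j);
        g[k] += a * fk;
        for (int l = 0; l <= k; ++l) Apos.at(k, l) += wgt * fk * F.at(l, j);
      }
    }
    Apos = symmatl(Apos);
    double obj_old = ll - row_penalty(q.memptr(), K, lam, gam);
    if (lam > 0.0) {
      for (int k = 0; k < K; ++k) g[k] -= lam / ((q[k] + gam) * lnorm);
    }
    // ridge keeps the QP strictly concave
    Apos.diag() += 1e-9 * (1.0 + Apos.diag().max());
    vec lo(K, fill::zeros), hi(K, fill::ones);
    bool ok = true;
    vec qnew = qp_solve(Apos, g, q, lo, hi, true, ok);
    if (!ok) { failed[i] = 1; rowll[i] = ll; continue; }
    // snap QP dust to exact zero and renormalize
    for (int k = 0; k < K; ++k) if (qnew[k] < 1e-10) qnew[k] = 0.0;
    const double s = accu(qnew);
    if (s > 0.0) qnew /= s; else qnew = q;
    // safeguarded acceptance: step-halving toward the current point
    vec step = qnew - q;
    vec best = q;
    double bestobj = obj_old, bestll = ll;
    double scale = 1.0;
    for (int t = 0; t <= 10; ++t, scale *= 0.5) {
      vec cand = q + scale * step;
      const double cll = row_ll(nT, F, cand.memptr(), i);
      const double cobj = cll - row_penalty(cand.memptr(), K, lam, gam);
      if (cobj > bestobj) { best = cand; bestobj = cobj; bestll = cll; break; }
    }
    Qout.row(i) = best.t();
    rowll[i] = bestll;
  }
  double total = 0.0;
  for (int i = 0; i < I; ++i) total += rowll[i];
  return Rcpp::List::create(Rcpp::Named("Q") = Qout,
                            Rcpp::Named("loglik") = total,
                            Rcpp::Named("n_failed") = (int)accu(failed));
}

// One SQP pass over all F columns (box constraints [EPS_F, 1-EPS_F]).
// [[Rcpp::export]]
Rcpp::List cpp_update_F(Rcpp::IntegerMatrix n, arma::mat Q, arma::mat F,
                        int threads) {
  const int I = Q.n_rows, K = Q.n_cols, J = F.n_cols;
  mat Fout = F;
  vec colll(J, fill::zeros);
  ivec failed(J, fill::zeros);
#ifdef _OPENMP
#pragma omp parallel for schedule(static) num_threads(threads > 0 ? threads : 1)
#endif
  for (int j = 0; j < J; ++j) {
    vec f = F.col(j);
    vec g(K, fill::zeros);
    mat Apos(K, K, fill::zeros);
    double ll = 0.0;
    for (int i = 0; i < I; ++i) {
      const int nij = n(i, j);
      if (nij == NA_INTEGER) continue;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += Q.at(i, k) * f[k];
      p = clamp_p(p);
      ll += nij * std::log(p) + (2 - nij) * std::log1p(-p);
      const double a = nij / p - (2 - nij) / (1.0 - p);
      const double wgt = nij / (p * p) + (2 - nij) / ((1.0 - p) * (1.0 - p));
      for (int k = 0; k < K; ++k) {
        const double qk = Q.at(i, k);
        g[k] += a * qk;
        for (int l = 0; l <= k; ++l) Apos.at(k, l) += wgt * qk * Q.at(i, l);
      }
    }
    Apos = symmatl(Apos);
    Apos.diag() += 1e-9 * (1.0 + Apos.diag().max());
    vec lo(K, fill::value(EPS_F)), hi(K, fill::value(1.0 - EPS_F));
    bool ok = true;
    vec fnew = qp_solve(Apos, g, f, lo, hi, false, ok);
    if (!ok) { failed[j] = 1; colll[j] = ll; continue; }
    vec step = fnew - f;
    vec best = f;
    double bestll = ll;
    double scale = 1.0;
    for (int t = 0; t <= 10; ++t, scale *= 0.5) {
      vec cand = f + scale * step;
      const double cll = col_ll(n, Q, cand.memptr(), j);
      if (cll > bestll) { best = cand; bestll = cll; break; }
    }
    Fout.col(j) = best;
    colll[j] = bestll;
  }
  double total = 0.0;
  for (int j = 0; j < J; ++j) total += colll[j];
  return Rcpp::List::create(Rcpp::Named("F") = Fout,
                            Rcpp::Named("loglik") = total,
                            Rcpp::Named("n_failed") = (int)accu(failed));
}
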