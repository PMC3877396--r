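// Core numerical routines for the multiple-kernel-learning classifier:
//  - SMO solver for the soft-margin SVM dual with a precomputed kernel
//  - alternating simplex-weight optimization over per-ROI kernels
//  - recursive kernel elimination ranking
//  - the inner leave-one-out evaluation loop over (C, gamma, ROI count)
// All solvers operate on small dense kernels (n = cohort size), so the
// emphasis is on low per-call overhead rather than sparse tricks.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct SvmSolution {
  arma::vec alpha;
  double rho;       // decision f(x) = sum alpha_i y_i K(x_i, x) - rho
  double obj;       // 0.5 a'Qa - e'a   (minimized)
  double W;         // dual value  e'a - 0.5 a'Qa  (maximized)
  int iter;
};

// Maximal-violating-pair SMO on min 0.5 a'Qa - e'a, 0 <= a <= C, y'a = 0,
// with Q_ij = y_i y_j K_ij.
SvmSolution smo_solve(const arma::mat& K, const arma::ivec& y, double C,
                      double tol, int max_iter,
                      const arma::vec* warm = nullptr) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n);
  if (warm != nullptr && (int)warm->n_elem == n) {
    // warm start: same feasible set, G recomputed for the current kernel
    alpha = arma::clamp(*warm, 0.0, C);
    arma::vec ay = alpha % arma::conv_to<arma::vec>::from(y);
    arma::vec Kay = K * ay;
    for (int t = 0; t < n; ++t) G[t] = y[t] * Kay[t] - 1.0;
  } else {
    G.fill(-1.0);  // G = Qa - e at a = 0
  }
  int it = 0;
  for (; it < max_iter; ++it) {
    // first-order selection of i, second-order selection of j
    double gmax = -std::numeric_limits<double>::infinity();
    double gmin = std::numeric_limits<double>::infinity();
    int i = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      const bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < tol) break;
    int j = -1;
    double best = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (!lo) continue;
      const double diff = gmax + y[t] * G[t];  // violation of pair (i, t)
      if (diff <= 0) continue;
      double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (a <= 1e-12) a = 1e-12;
      const double score = diff * diff / a;
      if (score > best) { best = score; j = t; }
    }
    if (j < 0) break;

    // pair curvature; equals Q_ii + Q_jj +/- 2Q_ij for both label cases
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 1e-12) quad = 1e-12;

    const double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    const double d_ai = alpha[i] - old_ai, d_aj = alpha[j] - old_aj;
    if (d_ai == 0 && d_aj == 0) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * d_ai + y[j] * K(t, j) * d_aj);
  }
  // rho (bias) from the KKT conditions
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == 1) lb = std::max(lb, yG); else ub = std::min(ub, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == -1) lb = std::max(lb, yG); else ub = std::min(ub, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  SvmSolution s;
  s.alpha = alpha;
  s.rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
  s.obj = 0.5 * (arma::dot(alpha, G) - arma::accu(alpha));
  s.W = -s.obj;
  s.iter = it;
  return s;
}

void combine_kernels(const std::vector<const arma::mat*>& Ks,
                     const arma::vec& d, arma::mat& K) {
  K.zeros(Ks[0]->n_rows, Ks[0]->n_cols);
  for (size_t m = 0; m < Ks.size(); ++m)
    if (d[m] > 0) K += d[m] * (*Ks[m]);
}

struct MklFit {
  arma::vec d;
  arma::vec alpha;
  double rho;
  arma::vec S;            // per-kernel margin contributions (sum = ||w||^2)
  std::vector<double> obj_path;
  bool converged;
  int n_svm_calls = 0;
};

// per-kernel contribution S_m = d_m^2 * (a y)' K_m (a y); sum_m S_m = ||w||^2
// for the combined kernel sum_m d_m K_m with w in the concatenated
// sqrt(d_m)-scaled feature space.  The weight update d_m <- d_m sqrt(S_m)
// (renormalized) concentrates weight on kernels carrying margin norm; a
// damped step guards monotonicity of the fixed-d dual value.
arma::vec margin_contributions(const std::vector<const arma::mat*>& Ks,
                               const arma::vec& d, const arma::vec& ay) {
  // restrict the quadratic form to the support set (ay != 0)
  arma::uvec sv = arma::find(arma::abs(ay) > 0);
  arma::vec ays = ay.elem(sv);
  arma::vec S(Ks.size());
  for (size_t m = 0; m < Ks.size(); ++m)
    S[m] = d[m] * arma::as_scalar(ays.t() * Ks[m]->submat(sv, sv) * ays);
  return S;
}

MklFit mkl_fit_core(const std::vector<const arma::mat*>& Ks,
                    const arma::ivec& y, double C,
                    double tol_d, int max_outer,
                    double svm_tol, int svm_max_iter,
                    const arma::vec* warm = nullptr) {
  const size_t M = Ks.size();
  const int n = y.n_elem;
  arma::vec d(M, arma::fill::value(1.0 / M));
  MklFit fit;
  fit.converged = false;

  arma::mat K;
  combine_kernels(Ks, d, K);
  SvmSolution sol = smo_solve(K, y, C, svm_tol, svm_max_iter, warm);
  ++fit.n_svm_calls;
  fit.obj_path.push_back(sol.W);

  if (M == 1) {
    fit.d = d; fit.alpha = sol.alpha; fit.rho = sol.rho;
    arma::vec ay = sol.alpha % arma::conv_to<arma::vec>::from(y);
    fit.S = margin_contributions(Ks, d, ay);
    fit.converged = true;
    return fit;
  }

  for (int it = 0; it < max_outer; ++it) {
    arma::vec ay = sol.alpha % arma::conv_to<arma::vec>::from(y);
    arma::vec S = margin_contributions(Ks, d, ay);
    if (arma::accu(S) <= 0) { fit.converged = true; break; }
    arma::vec d_prop = d % arma::sqrt(S);
    const double tot = arma::accu(d_prop);
    if (tot <= 0) { fit.converged = true; break; }
    d_prop /= tot;
    if (arma::abs(d_prop - d).max() < tol_d) { fit.converged = true; break; }

    // damped monotone step on the fixed-d dual value W(d) (minimized over d)
    const double W_tol = 1e-8 * (1.0 + std::abs(fit.obj_path.back()));
    bool accepted = false;
    SvmSolution sol_new;
    arma::vec d_new;
    for (int h = 0; h < 8; ++h) {
      d_new = (h == 0) ? d_prop : 0.5 * (d + d_new);
      combine_kernels(Ks, d_new, K);
      sol_new = smo_solve(K, y, C, svm_tol, svm_max_iter, &sol.alpha);
      ++fit.n_svm_calls;
      if (sol_new.W <= fit.obj_path.back() + W_tol) { accepted = true; break; }
    }
    if (!accepted) { fit.converged = true; break; }
    const double step = arma::abs(d_new - d).max();
    d = d_new;
    sol = sol_new;
    fit.obj_path.push_back(sol.W);
    if (step < tol_d) { fit.converged = true; break; }
  }
  fit.d = d;
  fit.alpha = sol.alpha;
  fit.rho = sol.rho;
  arma::vec ay = sol.alpha % arma::conv_to<arma::vec>::from(y);
  fit.S = margin_contributions(Ks, d, ay);
  return fit;
}

std::vector<const arma::mat*> as_ptrs(const std::vector<arma::mat>& v) {
  std::vector<const arma::mat*> p(v.size());
  for (size_t i = 0; i < v.size(); ++i) p[i] = &v[i];
  return p;
}

std::vector<arma::mat> list_to_mats(const List& Ks) {
  std::vector<arma::mat> v;
  v.reserve(Ks.size());
  for (int m = 0; m < Ks.size(); ++m)
    v.push_back(as<arma::mat>(Ks[m]));
  return v;
}

// ranking by recursive elimination: repeatedly drop the kernel with the
// smallest margin contribution (ties: higher index eliminated first)
arma::uvec rck_core(const std::vector<const arma::mat*>& Ks,
                    const arma::ivec& y, double C,
                    double tol_d, int max_outer,
                    double svm_tol, int svm_max_iter,
                    arma::vec& elim_scores) {
  const size_t M = Ks.size();
  std::vector<arma::uword> active(M);
  for (size_t m = 0; m < M; ++m) active[m] = m;
  std::vector<arma::uword> eliminated;
  elim_scores.set_size(M);
  arma::uword pos = 0;
  arma::vec warm;
  while (active.size() > 1) {
    std::vector<const arma::mat*> sub;
    for (arma::uword m : active) sub.push_back(Ks[m]);
    MklFit fit = mkl_fit_core(sub, y, C, tol_d, max_outer, svm_tol, svm_max_iter,
                              warm.n_elem ? &warm : nullptr);
    warm = fit.alpha;
    // victim: smallest S; ties -> higher original index first
    size_t victim = 0;
    for (size_t m = 1; m < active.size(); ++m) {
      if (fit.S[m] < fit.S[victim] - 1e-15 ||
          (std::abs(fit.S[m] - fit.S[victim]) <= 1e-15 &&
           active[m] > active[victim]))
        victim = m;
    }
    eliminated.push_back(active[victim]);
    elim_scores[pos++] = fit.S[victim];
    active.erase(active.begin() + victim);
  }
  arma::uvec ranking(M);
  ranking[0] = active[0];
  for (size_t r = 0; r < eliminated.size(); ++r)
    ranking[r + 1] = eliminated[eliminated.size() - 1 - r];
  return ranking;
}

}  // namespace

// [[Rcpp::export(name = ".smo_svm")]]
List smo_svm_cpp(const arma::mat& K, const arma::ivec& y, double C,
                 double tol = 1e-8, int max_iter = 200000) {
  SvmSolution s = smo_solve(K, y, C, tol, max_iter);
  return List::create(_["alpha"] = s.alpha, _["b"] = -s.rho,
                      _["objective"] = s.W, _["iterations"] = s.iter);
}

// [[Rcpp::export(name = ".mkl_fit")]]
List mkl_fit_cpp(const List& Ks, const arma::ivec& y, double C,
                 double tol_d = 1e-4, int max_outer = 100,
                 double svm_tol = 1e-8, int svm_max_iter = 200000) {
  std::vector<arma::mat> mats = list_to_mats(Ks);
  MklFit fit = mkl_fit_core(as_ptrs(mats), y, C, tol_d, max_outer,
                            svm_tol, svm_max_iter);
  return List::create(_["weights"] = fit.d, _["alpha"] = fit.alpha,
                      _["b"] = -fit.rho, _["S"] = fit.S,
                      _["objective_path"] = fit.obj_path,
                      _["converged"] = fit.converged,
                      _["n_svm_calls"] = fit.n_svm_calls);
}

// [[Rcpp::export(name = ".rck_rank")]]
List rck_rank_cpp(const List& Ks, const arma::ivec& y, double C,
                  double tol_d = 1e-4, int max_outer = 100,
                  double svm_tol = 1e-8, int svm_max_iter = 200000) {
  std::vector<arma::mat> mats = list_to_mats(Ks);
  arma::vec elim_scores;
  arma::uvec ranking = rck_core(as_ptrs(mats), y, C, tol_d, max_outer,
                                svm_tol, svm_max_iter, elim_scores);
  return List::create(_["ranking"] = ranking + 1,  // 1-based
                      _["elimination_scores"] = elim_scores);
}

// Inner leave-one-out evaluation.  kernels_by_gamma: list (over gamma) of
// lists of M kernel matrices over the n training subjects.  For every inner
// fold, (C, gamma) pair and ROI count c (top-c kernels along `ranking`,
// 1-based), fit the MKL SVM on n-1 subjects and predict the held-out one.
// Returns accuracy array (nC x nGamma x M).
// [[Rcpp::export(name = ".inner_loo")]]
arma::cube inner_loo_cpp(const List& kernels_by_gamma, const arma::ivec& y,
                         const arma::vec& C_grid, const arma::uvec& ranking,
                         double tol_d = 1e-4, int max_outer = 100,
                         double svm_tol = 1e-6, int svm_max_iter = 100000) {
  const int n = y.n_elem;
  const int nG = kernels_by_gamma.size();
  const int nC = C_grid.n_elem;
  const int M = ranking.n_elem;
  std::vector<std::vector<arma::mat>> Kg(nG);
  for (int g = 0; g < nG; ++g) Kg[g] = list_to_mats(kernels_by_gamma[g]);

  arma::cube correct(nC, nG, M, arma::fill::zeros);
  arma::uvec rank0 = ranking - 1;

  for (int j = 0; j < n; ++j) {
    arma::uvec train(n - 1);
    int p = 0;
    for (int t = 0; t < n; ++t) if (t != j) train[p++] = t;
    arma::ivec y_tr(n - 1);
    for (int t = 0; t < n - 1; ++t) y_tr[t] = y[train[t]];
    for (int g = 0; g < nG; ++g) {
      // pre-subset the ranked kernels once per (fold, gamma)
      std::vector<arma::mat> sub(M);
      std::vector<arma::vec> ktest(M);
      for (int m = 0; m < M; ++m) {
        const arma::mat& Kfull = Kg[g][rank0[m]];
        sub[m] = Kfull.submat(train, train);
        arma::vec col(n - 1);
        for (int t = 0; t < n - 1; ++t) col[t] = Kfull(train[t], j);
        ktest[m] = col;
      }
      for (int ci = 0; ci < nC; ++ci) {
        arma::vec warm;
        for (int c = 1; c <= M; ++c) {
          std::vector<const arma::mat*> use(c);
          for (int m = 0; m < c; ++m) use[m] = &sub[m];
          MklFit fit = mkl_fit_core(use, y_tr, C_grid[ci], tol_d, max_outer,
                                    svm_tol, svm_max_iter,
                                    warm.n_elem ? &warm : nullptr);
          warm = fit.alpha;
          arma::vec kx(n - 1, arma::fill::zeros);
          for (int m = 0; m < c; ++m)
            if (fit.d[m] > 0) kx += fit.d[m] * ktest[m];
          double f = -fit.rho;
          for (int t = 0; t < n - 1; ++t)
            f += fit.alpha[t] * y_tr[t] * kx[t];
          const int pred = f >= 0 ? 1 : -1;
          if (pred == y[j]) correct(ci, g, c - 1) += 1.0;
        }
      }
    }
  }
  return correct / n;
}

// Fit on the training block (all but the last subject) at each ROI count
// along a fixed ranking and return the decision value for the held-out
// subject (last index).  Used for outer-fold peak-region prediction and the
// permutation null.
// [[Rcpp::export(name = ".predict_counts")]]
List predict_counts_cpp(const List& Ks, const arma::ivec& y_train,
                        const arma::uvec& ranking, double C,
                        double tol_d = 1e-4, int max_outer = 100,
                        double svm_tol = 1e-6, int svm_max_iter = 100000) {
  std::vector<arma::mat> mats = list_to_mats(Ks);
  const int n = mats[0].n_rows;       // n_train + 1
  const int n_tr = n - 1;
  const int M = ranking.n_elem;
  arma::uvec train(n_tr);
  for (int t = 0; t < n_tr; ++t) train[t] = t;
  arma::uvec rank0 = ranking - 1;

  std::vector<arma::mat> sub(M);
  std::vector<arma::vec> ktest(M);
  for (int m = 0; m < M; ++m) {
    sub[m] = mats[rank0[m]].submat(train, train);
    ktest[m] = mats[rank0[m]].submat(0, n - 1, n_tr - 1, n - 1);
  }
  arma::vec dec(M);
  arma::vec warm;
  for (int c = 1; c <= M; ++c) {
    std::vector<const arma::mat*> use(c);
    for (int m = 0; m < c; ++m) use[m] = &sub[m];
    MklFit fit = mkl_fit_core(use, y_train, C, tol_d, max_outer,
                              svm_tol, svm_max_iter,
                              warm.n_elem ? &warm : nullptr);
    warm = fit.alpha;
    arma::vec kx(n_tr, arma::fill::zeros);
    for (int m = 0; m < c; ++m)
      if (fit.d[m] > 0) kx += fit.d[m] * ktest[m];
    double f = -fit.rho;
    for (int t = 0; t < n_tr; ++t) f += fit.alpha[t] * y_train[t] * kx[t];
    dec[c - 1] = f;
  }
  return List::create(_["decision"] = dec);
}
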