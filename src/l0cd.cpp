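// Best-subset (L0-penalized) least squares by cyclic coordinate descent with
// hard-thresholding updates, followed by local combinatorial search over
// single-coordinate support moves (add, delete, swap), each candidate support
// evaluated by its exact OLS refit.
// Objective: 0.5 * ||y - X beta||^2 + gamma * ||beta||_0.
// Columns of X are assumed centered/standardized by the caller; the update
// threshold uses the actual column norms, so any consistent scaling is exact.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double objective(const vec &r, const vec &beta, double gamma) {
  return 0.5 * dot(r, r) + gamma * static_cast<double>(accu(beta != 0));
}

// One full cyclic sweep; returns max absolute coefficient change.
static double cd_sweep(const mat &X, const vec &s, double gamma, vec &beta,
                       vec &r) {
  const uword p = X.n_cols;
  double max_change = 0.0;
  for (uword j = 0; j < p; ++j) {
    if (s[j] <= 0.0) continue;
    const double old = beta[j];
    // partial-residual correlation: z is the one-dimensional OLS value
    double z = dot(X.col(j), r);
    if (old != 0.0) z += s[j] * old;
    z /= s[j];
    // keeping j is worth it iff 0.5 * z^2 * s_j > gamma
    const double newval = (z * z * s[j] > 2.0 * gamma) ? z : 0.0;
    if (newval != old) {
      r += X.col(j) * (old - newval);
      beta[j] = newval;
      const double ch = std::abs(newval - old);
      if (ch > max_change) max_change = ch;
    }
  }
  return max_change;
}

// 0.5 * RSS of the OLS refit on `supp`, via the precomputed Gram system;
// returns false if the system is singular. `coefs` gets the refit values.
static bool refit_half_rss(const mat &G, const vec &Xy, double yy,
                           const uvec &supp, double &half_rss, vec &coefs) {
  if (supp.n_elem == 0) {
    half_rss = 0.5 * yy;
    coefs.reset();
    return true;
  }
  const mat Gs = G.submat(supp, supp);
  const vec bs = Xy.elem(supp);
  if (!solve(coefs, Gs, bs, solve_opts::no_approx)) return false;
  half_rss = 0.5 * (yy - dot(bs, coefs));
  if (half_rss < 0.0) half_rss = 0.0;  // numerical guard
  return true;
}

// [[Rcpp::export(name = ".l0_cd_swap")]]
Rcpp::List l0_cd_swap(const arma::mat &X, const arma::vec &y,
                      double gamma, arma::vec beta0,
                      int max_sweeps = 200, double tol = 1e-10,
                      int swap_rounds = 100, bool do_search = true) {
  const uword p = X.n_cols;
  vec s(p);
  for (uword j = 0; j < p; ++j) s[j] = dot(X.col(j), X.col(j));

  vec beta = beta0;
  vec r = y - X * beta;
  std::vector<double> trace;
  trace.push_back(objective(r, beta, gamma));

  for (int it = 0; it < max_sweeps; ++it) {
    const double ch = cd_sweep(X, s, gamma, beta, r);
    trace.push_back(objective(r, beta, gamma));
    if (ch < tol) break;
  }

  if (!do_search) {
    return Rcpp::List::create(
        Rcpp::Named("beta") = beta,
        Rcpp::Named("objective") = objective(r, beta, gamma),
        Rcpp::Named("trace") = trace);
  }

  // Local combinatorial search on the support: candidate supports differing
  // by one add, one delete, or one swap, each scored by exact OLS refit.
  const mat G = X.t() * X;
  const vec Xy = X.t() * y;
  const double yy = dot(y, y);

  std::vector<uword> support;
  for (uword j = 0; j < p; ++j) {
    if (beta[j] != 0.0) support.push_back(j);
  }
  double cur;
  vec cur_coefs;
  {
    uvec supp(support);
    double hr;
    if (refit_half_rss(G, Xy, yy, supp, hr, cur_coefs)) {
      cur = hr + gamma * supp.n_elem;
    } else {
      cur = objective(r, beta, gamma);
    }
  }

  // The combinatorial search is worthwhile for sparse fixed points; very
  // dense solutions (reached only at negligible penalties along a path)
  // keep the coordinate-descent answer.
  const size_t search_cap = 20;
  for (int round = 0; support.size() <= search_cap && round < swap_rounds;
       ++round) {
    double best = cur;
    std::vector<uword> best_support;
    vec best_coefs;
    std::vector<bool> in_supp(p, false);
    for (uword j : support) in_supp[j] = true;

    auto consider = [&](std::vector<uword> cand) {
      std::sort(cand.begin(), cand.end());
      uvec supp(cand);
      double hr;
      vec coefs;
      if (!refit_half_rss(G, Xy, yy, supp, hr, coefs)) return;
      const double obj = hr + gamma * supp.n_elem;
      if (obj < best - 1e-10) {
        best = obj;
        best_support = cand;
        best_coefs = coefs;
      }
    };

    for (uword k = 0; k < p; ++k) {  // additions
      if (in_supp[k] || s[k] <= 0.0) continue;
      std::vector<uword> cand(support);
      cand.push_back(k);
      consider(cand);
    }
    for (size_t a = 0; a < support.size(); ++a) {  // deletions
      std::vector<uword> cand;
      for (size_t b = 0; b < support.size(); ++b) {
        if (b != a) cand.push_back(support[b]);
      }
      consider(cand);
    }
    for (size_t a = 0; a < support.size(); ++a) {  // swaps
      for (uword k = 0; k < p; ++k) {
        if (in_supp[k] || s[k] <= 0.0) continue;
        std::vector<uword> cand;
        for (size_t b = 0; b < support.size(); ++b) {
          if (b != a) cand.push_back(support[b]);
        }
        cand.push_back(k);
        consider(cand);
      }
    }
    // pair deletions: two coordinates can be jointly redundant while each
    // single deletion increases the refit RSS by more than gamma
    for (size_t a = 0; a + 1 < support.size(); ++a) {
      for (size_t b = a + 1; b < support.size(); ++b) {
        std::vector<uword> base;
        for (size_t c = 0; c < support.size(); ++c) {
          if (c != a && c != b) base.push_back(support[c]);
        }
        consider(base);
        // remove-two-add-one: a pair can be replaced by a single coordinate
        // even when neither the pair deletion nor any single swap improves
        if (support.size() <= 15) {
          for (uword k = 0; k < p; ++k) {
            if (in_supp[k] || s[k] <= 0.0) continue;
            std::vector<uword> cand(base);
            cand.push_back(k);
            consider(cand);
          }
        }
      }
    }

    if (best >= cur - 1e-12) break;
    support = best_support;
    std::sort(support.begin(), support.end());
    cur = best;
    // keep coefs aligned with the sorted support
    uvec supp(support);
    double hr;
    refit_half_rss(G, Xy, yy, supp, hr, cur_coefs);
    trace.push_back(cur);
  }

  // Final coefficients: OLS refit on the locally optimal support (stationary
  // for coordinate descent at this fixed point); falls back to the CD
  // solution if the refit system is singular.
  const vec cd_beta = beta;
  const double cd_obj = objective(r, beta, gamma);
  beta.zeros();
  {
    uvec supp(support);
    double hr;
    vec coefs;
    if (refit_half_rss(G, Xy, yy, supp, hr, coefs) &&
        hr + gamma * supp.n_elem <= cd_obj + 1e-12) {
      for (uword i = 0; i < supp.n_elem; ++i) beta[supp[i]] = coefs[i];
      cur = hr + gamma * supp.n_elem;
    } else {
      beta = cd_beta;
      cur = cd_obj;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("objective") = cur,
      Rcpp::Named("trace") = trace);
}
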