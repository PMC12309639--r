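#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Simulated-annealing minimum-set solver over single-unit flips.
//
// Objective (minimized):
//   sum(cost_i x_i) + blm * boundary(x)
//   + sum_det  spf_j * max(0, T_j - held_j)
//   + sum_prob spf_j * max(0, T_j + z_{P_j} * sigma_j(x) - mu_j(x))
// The probabilistic term is the certainty-equivalent shortfall under the
// independent-Bernoulli normal approximation (mu_j = sum a_ij p_i,
// sigma_j^2 = sum a_ij^2 p_i (1-p_i)): it is zero exactly when
// P(held >= T_j) >= P_j, carries a linear gradient in expected held amount,
// and collapses to the deterministic shortfall when all p_i = 1.
//
// Uses R's RNG: deterministic under set.seed() in the caller.

namespace {

struct ProblemData {
  int n, m;
  const double *cost;
  const double *amounts;  // n x m, column-major
  const double *target;
  const double *spf;
  const int *probabilistic;
  const double *certainty;
  std::vector<double> z_cert;  // qnorm(certainty) per feature
  const double *p;
  const double *perim;
  // adjacency in CSR form
  std::vector<int> adj_off, adj_idx;
  std::vector<double> adj_len;
  double blm;
};

struct State {
  std::vector<int> x;
  std::vector<double> held, mu, var;
  double cost_sum, boundary;
};

double feature_penalty(const ProblemData &pd, const State &s) {
  double pen = 0.0;
  for (int j = 0; j < pd.m; ++j) {
    if (pd.probabilistic[j]) {
      double sd = std::sqrt(std::max(0.0, s.var[j]));
      double short_p = pd.target[j] + pd.z_cert[j] * sd - s.mu[j];
      if (short_p > 0) pen += pd.spf[j] * short_p;
    } else {
      double short_d = pd.target[j] - s.held[j];
      if (short_d > 0) pen += pd.spf[j] * short_d;
    }
  }
  return pen;
}

double total_objective(const ProblemData &pd, const State &s) {
  return s.cost_sum + pd.blm * s.boundary + feature_penalty(pd, s);
}

// apply flip of unit i, updating running state
void apply_flip(const ProblemData &pd, State &s, int i) {
  double sgn = s.x[i] ? -1.0 : 1.0;
  s.x[i] = 1 - s.x[i];
  s.cost_sum += sgn * pd.cost[i];
  double shared = 0.0;
  for (int k = pd.adj_off[i]; k < pd.adj_off[i + 1]; ++k)
    if (s.x[pd.adj_idx[k]]) shared += pd.adj_len[k];
  s.boundary += sgn * (pd.perim[i] - 2.0 * shared);
  for (int j = 0; j < pd.m; ++j) {
    double a = pd.amounts[static_cast<size_t>(j) * pd.n + i];
    if (a == 0.0) continue;
    s.held[j] += sgn * a;
    if (pd.probabilistic[j]) {
      double pi = pd.p[i];
      s.mu[j] += sgn * a * pi;
      s.var[j] += sgn * a * a * pi * (1.0 - pi);
      if (s.var[j] < 0) s.var[j] = 0;  // guard fp drift
    }
  }
}

double flip_delta(const ProblemData &pd, State &s, int i) {
  double before = total_objective(pd, s);
  apply_flip(pd, s, i);
  double after = total_objective(pd, s);
  apply_flip(pd, s, i);  // revert
  return after - before;
}

}  // namespace

// [[Rcpp::export]]
List anneal_cpp(NumericVector cost, NumericMatrix amounts, NumericVector target,
                NumericVector spf, IntegerVector probabilistic,
                NumericVector certainty, NumericVector p, NumericVector perim,
                IntegerVector adj_i, IntegerVector adj_j, NumericVector adj_len,
                double blm, int n_iter, double t0, double cooling,
                IntegerVector x_init, bool final_improve) {
  const int n = cost.size(), m = target.size();
  if (amounts.nrow() != n || amounts.ncol() != m)
    stop("amounts must be n x m");

  ProblemData pd;
  pd.n = n; pd.m = m;
  pd.cost = REAL(cost); pd.amounts = REAL(amounts); pd.target = REAL(target);
  pd.spf = REAL(spf); pd.probabilistic = INTEGER(probabilistic);
  pd.certainty = REAL(certainty); pd.p = REAL(p); pd.perim = REAL(perim);
  pd.blm = blm;
  pd.z_cert.assign(m, 0.0);
  for (int j = 0; j < m; ++j)
    if (pd.probabilistic[j])
      pd.z_cert[j] = R::qnorm(pd.certainty[j], 0.0, 1.0, 1, 0);

  // symmetric CSR adjacency from an undirected edge list (1-based input)
  std::vector<int> deg(n, 0);
  const int ne = adj_i.size();
  for (int e = 0; e < ne; ++e) {
    int a = adj_i[e] - 1, b = adj_j[e] - 1;
    if (a < 0 || a >= n || b < 0 || b >= n) stop("adjacency index out of range");
    ++deg[a]; ++deg[b];
  }
  pd.adj_off.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) pd.adj_off[i + 1] = pd.adj_off[i] + deg[i];
  pd.adj_idx.assign(pd.adj_off[n], 0);
  pd.adj_len.assign(pd.adj_off[n], 0.0);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < ne; ++e) {
    int a = adj_i[e] - 1, b = adj_j[e] - 1;
    double L = adj_len[e];
    pd.adj_idx[pd.adj_off[a] + fill[a]] = b;
    pd.adj_len[pd.adj_off[a] + fill[a]++] = L;
    pd.adj_idx[pd.adj_off[b] + fill[b]] = a;
    pd.adj_len[pd.adj_off[b] + fill[b]++] = L;
  }

  // initial state
  State s;
  s.x.assign(n, 0);
  s.held.assign(m, 0.0); s.mu.assign(m, 0.0); s.var.assign(m, 0.0);
  s.cost_sum = 0.0; s.boundary = 0.0;
  for (int i = 0; i < n; ++i)
    if (x_init[i]) apply_flip(pd, s, i);

  // automatic initial temperature: 90th percentile of |delta| over probe flips
  double temp = t0;
  if (temp <= 0) {
    const int n_probe = 1000;
    std::vector<double> mags(n_probe);
    for (int k = 0; k < n_probe; ++k) {
      int i = static_cast<int>(unif_rand() * n);
      if (i >= n) i = n - 1;
      mags[k] = std::fabs(flip_delta(pd, s, i));
    }
    std::sort(mags.begin(), mags.end());
    temp = mags[static_cast<int>(0.9 * (n_probe - 1))];
    if (temp <= 0) temp = 1.0;
  }

  double cur = total_objective(pd, s);
  for (int it = 0; it < n_iter; ++it) {
    int i = static_cast<int>(unif_rand() * n);
    if (i >= n) i = n - 1;
    double d = flip_delta(pd, s, i);
    bool accept = d <= 0;
    if (!accept && temp > 0)
      accept = unif_rand() < std::exp(-d / temp);
    if (accept) {
      apply_flip(pd, s, i);
      cur += d;
    }
    temp *= cooling;
  }

  if (final_improve) {
    bool improved = true;
    while (improved) {
      improved = false;
      for (int i = 0; i < n; ++i) {
        double d = flip_delta(pd, s, i);
        if (d < -1e-12) {
          apply_flip(pd, s, i);
          improved = true;
        }
      }
    }
  }

  // recompute breakdown from scratch (no accumulated fp drift)
  State fresh;
  fresh.x = s.x;
  fresh.held.assign(m, 0.0); fresh.mu.assign(m, 0.0); fresh.var.assign(m, 0.0);
  fresh.cost_sum = 0.0; fresh.boundary = 0.0;
  std::vector<int> xs = s.x;
  std::fill(fresh.x.begin(), fresh.x.end(), 0);
  for (int i = 0; i < n; ++i)
    if (xs[i]) apply_flip(pd, fresh, i);

  NumericVector held(m), probv(m);
  double pen_det = 0.0, pen_prob = 0.0;
  for (int j = 0; j < m; ++j) {
    held[j] = fresh.held[j];
    if (pd.probabilistic[j]) {
      double sd = std::sqrt(std::max(0.0, fresh.var[j]));
      probv[j] = sd > 0
        ? 1.0 - R::pnorm((pd.target[j] - fresh.mu[j]) / sd, 0.0, 1.0, 1, 0)
        : (fresh.mu[j] >= pd.target[j] ? 1.0 : 0.0);
      double sp = pd.target[j] + pd.z_cert[j] * sd - fresh.mu[j];
      if (sp > 0) pen_prob += pd.spf[j] * sp;
    } else {
      probv[j] = NA_REAL;
      double sd2 = pd.target[j] - fresh.held[j];
      if (sd2 > 0) pen_det += pd.spf[j] * sd2;
    }
  }
  double tot = fresh.cost_sum + pd.blm * fresh.boundary + pen_det + pen_prob;

  return List::create(
    _["x"] = IntegerVector(xs.begin(), xs.end()),
    _["total"] = tot,
    _["cost"] = fresh.cost_sum,
    _["boundary"] = fresh.boundary,
    _["penalty_deterministic"] = pen_det,
    _["penalty_probabilistic"] = pen_prob,
    _["held"] = held,
    _["prob_target_met"] = probv);
}
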