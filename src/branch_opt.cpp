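// Pruning-likelihood kernel: postorder partials, edge-factorized site
// likelihoods and golden-section branch-length sweeps.  Mirrors the R
// reference implementation (see likelihood.R); both are cross-checked in the
// test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Engine {
  int ntip, nnode, nstates, ncat, npat;
  arma::imat E;                 // edges (parent, child), 0-based node ids
  std::vector<std::vector<int>> kids;   // node -> child edge indices
  arma::vec el;
  arma::mat left, right;        // eigen factors of the rate matrix
  arma::vec evals, freqs, cat_rates, cat_weights, pw;  // pw = pattern weights
  double pinv;
  arma::vec inv_lik;            // pinv * exp(invariant pattern loglik), or empty
  // D partials and log scalers, indexed [node][cat]
  std::vector<std::vector<arma::mat>> D;
  std::vector<std::vector<arma::rowvec>> Ds;

  arma::mat P(double t, double rate) const {
    arma::mat M = left * arma::diagmat(arma::exp(evals * (t * rate))) * right;
    M.transform([](double x) { return x < 0 ? 0.0 : x; });
    return M;
  }

  void update_D(int u) {
    const std::vector<int>& er = kids[u];
    int v1 = E(er[0], 1), v2 = E(er[1], 1);
    for (int k = 0; k < ncat; ++k) {
      arma::mat M = (P(el[er[0]], cat_rates[k]) * D[v1][k]) %
                    (P(el[er[1]], cat_rates[k]) * D[v2][k]);
      arma::rowvec sc = arma::max(M, 0);
      sc.transform([](double x) { return x <= 0 ? 1.0 : x; });
      M.each_row() /= sc;
      D[u][k] = M;
      Ds[u][k] = Ds[v1][k] + Ds[v2][k] + arma::log(sc);
    }
  }

  // site log-likelihood totals for the edge-factorized form at edge with
  // child partial D[v], complement partial U
  double edge_loglik(double t, int v, const std::vector<arma::mat>& U,
                     const std::vector<arma::rowvec>& Us) const {
    arma::mat parts(ncat, npat);
    for (int k = 0; k < ncat; ++k) {
      arma::rowvec s = arma::sum(U[k] % (P(t, cat_rates[k]) * D[v][k]), 0);
      s.transform([](double x) { return x <= 0 ? 1e-300 : x; });
      parts.row(k) = arma::log(s) + Us[k] + Ds[v][k] +
                     std::log(cat_weights[k]);
    }
    arma::rowvec M = arma::max(parts, 0);
    arma::rowvec ll(npat);
    for (int j = 0; j < npat; ++j) {
      double acc = 0;
      for (int k = 0; k < ncat; ++k) acc += std::exp(parts(k, j) - M[j]);
      double site = M[j] + std::log(acc);
      if (pinv > 0) site = std::log(std::exp(site) + inv_lik[j]);
      ll[j] = site;
    }
    return arma::dot(ll, pw.t());
  }

  // Brent's localmin on -edge_loglik over [lo, hi]; keeps the old length
  // unless the optimum improves on it
  double golden(int erow, const std::vector<arma::mat>& U,
                const std::vector<arma::rowvec>& Us,
                double lo, double hi) {
    int v = E(erow, 1);
    auto f = [&](double t) { return -edge_loglik(t, v, U, Us); };
    const double c = 0.3819660112501051, eps = 1e-8;
    double a = lo, b = hi;
    double x = std::min(std::max(el[erow], lo), hi);
    double w = x, vv = x, fx = f(x), fw = fx, fv = fx;
    double d = 0, e = 0;
    double f0 = fx;  // value at the current branch length
    for (int iter = 0; iter < 60; ++iter) {
      double m = 0.5 * (a + b);
      double tol1 = eps * std::abs(x) + 1e-8, tol2 = 2 * tol1;
      if (std::abs(x - m) <= tol2 - 0.5 * (b - a)) break;
      double p = 0, q = 0, r = 0;
      bool use_gold = true;
      if (std::abs(e) > tol1) {
        r = (x - w) * (fx - fv);
        q = (x - vv) * (fx - fw);
        p = (x - vv) * q - (x - w) * r;
        q = 2 * (q - r);
        if (q > 0) p = -p; else q = -q;
        if (std::abs(p) < std::abs(0.5 * q * e) && p > q * (a - x) &&
            p < q * (b - x)) {
          e = d; d = p / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
          use_gold = false;
        }
      }
      if (use_gold) { e = (x < m) ? b - x : a - x; d = c * e; }
      double u = (std::abs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
      double fu = f(u);
      if (fu <= fx) {
        if (u < x) b = x; else a = x;
        vv = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu <= fw || w == x) { vv = w; fv = fw; w = u; fw = fu; }
        else if (fu <= fv || vv == x || vv == w) { vv = u; fv = fu; }
      }
    }
    if (fx < f0) el[erow] = x;
    return 0;
  }

  static void scale_U(std::vector<arma::mat>& U, std::vector<arma::rowvec>& Us) {
    for (size_t k = 0; k < U.size(); ++k) {
      arma::rowvec sc = arma::max(U[k], 0);
      sc.transform([](double x) { return x <= 0 ? 1.0 : x; });
      U[k].each_row() /= sc;
      Us[k] += arma::log(sc);
    }
  }

  void descend(int erow, std::vector<arma::mat> U, std::vector<arma::rowvec> Us,
               double lo, double hi) {
    golden(erow, U, Us, lo, hi);
    int v = E(erow, 1);
    if (v < ntip) return;
    const std::vector<int>& er = kids[v];
    std::vector<arma::mat> base(ncat);
    for (int k = 0; k < ncat; ++k)
      base[k] = P(el[erow], cat_rates[k]).t() * U[k];
    for (int j = 0; j < 2; ++j) {
      int other = er[j == 0 ? 1 : 0];
      int ov = E(other, 1);
      std::vector<arma::mat> Uc(ncat);
      std::vector<arma::rowvec> Ucs(ncat);
      for (int k = 0; k < ncat; ++k) {
        Uc[k] = base[k] % (P(el[other], cat_rates[k]) * D[ov][k]);
        Ucs[k] = Us[k] + Ds[ov][k];
      }
      scale_U(Uc, Ucs);
      descend(er[j], Uc, Ucs, lo, hi);
    }
    update_D(v);
  }

  double total_loglik() {
    int root = ntip;
    arma::mat parts(ncat, npat);
    for (int k = 0; k < ncat; ++k) {
      arma::rowvec s = freqs.t() * D[root][k];
      s.transform([](double x) { return x <= 0 ? 1e-300 : x; });
      parts.row(k) = arma::log(s) + Ds[root][k] + std::log(cat_weights[k]);
    }
    double tot = 0;
    for (int j = 0; j < npat; ++j) {
      double M = parts.col(j).max();
      double acc = 0;
      for (int k = 0; k < ncat; ++k) acc += std::exp(parts(k, j) - M);
      double site = M + std::log(acc);
      if (pinv > 0) site = std::log(std::exp(site) + inv_lik[j]);
      tot += site * pw[j];
    }
    return tot;
  }

  arma::rowvec pattern_loglik() {
    int root = ntip;
    arma::mat parts(ncat, npat);
    for (int k = 0; k < ncat; ++k) {
      arma::rowvec s = freqs.t() * D[root][k];
      s.transform([](double x) { return x <= 0 ? 1e-300 : x; });
      parts.row(k) = arma::log(s) + Ds[root][k] + std::log(cat_weights[k]);
    }
    arma::rowvec out(npat);
    for (int j = 0; j < npat; ++j) {
      double M = parts.col(j).max();
      double acc = 0;
      for (int k = 0; k < ncat; ++k) acc += std::exp(parts(k, j) - M);
      double site = M + std::log(acc);
      if (pinv > 0) site = std::log(std::exp(site) + inv_lik[j]);
      out[j] = site;
    }
    return out;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_optimize_branches")]]
List cpp_optimize_branches(IntegerMatrix edge, int ntip, List tip_partials,
                           NumericVector pat_weights, NumericMatrix left,
                           NumericVector evals, NumericMatrix right,
                           NumericVector freqs, NumericVector cat_rates,
                           NumericVector cat_weights, double pinv,
                           NumericVector inv_lik, NumericVector edge_length,
                           double min_bl, double max_bl, double tol,
                           int max_cycles, bool optimize) {
  Engine eng;
  eng.ntip = ntip;
  eng.nnode = ntip + ntip - 1;  // rooted binary
  eng.E = arma::imat(edge.nrow(), 2);
  for (int i = 0; i < edge.nrow(); ++i) {
    eng.E(i, 0) = edge(i, 0) - 1;
    eng.E(i, 1) = edge(i, 1) - 1;
  }
  eng.kids.assign(eng.nnode, {});
  for (int i = 0; i < edge.nrow(); ++i) eng.kids[eng.E(i, 0)].push_back(i);
  eng.el = as<arma::vec>(edge_length);
  eng.left = as<arma::mat>(left);
  eng.right = as<arma::mat>(right);
  eng.evals = as<arma::vec>(evals);
  eng.freqs = as<arma::vec>(freqs);
  eng.cat_rates = as<arma::vec>(cat_rates);
  eng.cat_weights = as<arma::vec>(cat_weights);
  eng.pw = as<arma::vec>(pat_weights);
  eng.pinv = pinv;
  eng.nstates = eng.left.n_rows;
  eng.ncat = eng.cat_rates.n_elem;
  eng.npat = eng.pw.n_elem;
  if (pinv > 0) eng.inv_lik = as<arma::vec>(inv_lik);

  eng.D.assign(eng.nnode, std::vector<arma::mat>(eng.ncat));
  eng.Ds.assign(eng.nnode, std::vector<arma::rowvec>(eng.ncat));
  for (int i = 0; i < ntip; ++i) {
    arma::mat tp = as<arma::mat>(tip_partials[i]);
    for (int k = 0; k < eng.ncat; ++k) {
      eng.D[i][k] = tp;
      eng.Ds[i][k] = arma::rowvec(eng.npat, arma::fill::zeros);
    }
  }

  // postorder fill: process parents in order of their last child edge
  std::vector<std::pair<int,int>> ord;  // (last edge idx, node)
  for (int u = ntip; u < eng.nnode; ++u)
    ord.push_back({std::max(eng.kids[u][0], eng.kids[u][1]), u});
  std::sort(ord.begin(), ord.end());
  for (auto& p : ord) eng.update_D(p.second);

  double cur = eng.total_loglik();
  std::vector<double> trace;
  bool converged = !optimize;
  int cycles = 0;
  if (optimize) {
    int root = ntip;
    for (int cyc = 0; cyc < max_cycles; ++cyc) {
      const std::vector<int>& er = eng.kids[root];
      for (int j = 0; j < 2; ++j) {
        int other = er[j == 0 ? 1 : 0];
        int ov = eng.E(other, 1);
        std::vector<arma::mat> Uc(eng.ncat);
        std::vector<arma::rowvec> Ucs(eng.ncat);
        for (int k = 0; k < eng.ncat; ++k) {
          Uc[k] = (eng.P(eng.el[other], eng.cat_rates[k]) * eng.D[ov][k]);
          Uc[k].each_col() %= eng.freqs;
          Ucs[k] = eng.Ds[ov][k];
        }
        Engine::scale_U(Uc, Ucs);
        eng.descend(er[j], Uc, Ucs, min_bl, max_bl);
      }
      // refresh root partial with the new lengths
      eng.update_D(root);
      double now = eng.total_loglik();
      trace.push_back(now);
      ++cycles;
      if (now - cur < tol && cyc > 0) { converged = true; cur = std::max(cur, now); break; }
      cur = std::max(cur, now);
    }
  }

  arma::rowvec pat_ll = eng.pattern_loglik();
  return List::create(_["edge_length"] = wrap(arma::conv_to<std::vector<double>>::from(eng.el)),
                      _["loglik"] = cur,
                      _["pattern_loglik"] = wrap(arma::conv_to<std::vector<double>>::from(pat_ll)),
                      _["trace"] = wrap(trace),
                      _["cycles"] = cycles,
                      _["converged"] = converged);
}
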