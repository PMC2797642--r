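// Felsenstein pruning for amino-acid data with a discrete-gamma (+I)
// rate mixture, plus coordinate-ascent branch-length optimization.
//
// Conventions:
//  * nodes are 0-based here; tips are 0..ntip-1; edge matrix comes from
//    ape's postorder reordering (children listed before their parents);
//  * the rate matrix enters through its symmetric eigendecomposition
//    Q = U diag(lambda) Uinv, so P(t) = U diag(exp(lambda t)) Uinv;
//  * per-site likelihood =
//      pinv * invterm_s + (1 - pinv) * (1/k) * sum_c L(site | rate r_c);
//  * partial-likelihood columns are rescaled per node, with log scalers
//    accumulated, to keep 60+ taxon likelihoods inside double range.
//
// Branch optimization does one exact Gauss-Seidel sweep per iteration:
// a post-order pass computes "up" partials (data below each node), then a
// pre-order descent maintains "above" partials A incrementally, so each
// edge is optimized against the current state of all other edges.  Up
// partials below an edge never depend on edges above it, and A is rebuilt
// on the way down from already-updated lengths, so the one-dimensional
// Brent step can never decrease the joint likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Peeler {
  int ntip, nnode, nedge, ncat, nsite, root;
  const Rcpp::IntegerMatrix edge;   // nedge x 2: parent, child (1-based)
  vec el;
  mat U, Uinv;
  vec lambda, pi, rates;
  double pinv;
  vec invterm;
  mat tippart;                      // 20 x (ntip * nsite), indicator partials
  std::vector<cube> up;             // internal nodes: 20 x nsite x ncat
  std::vector<mat> upscale;         // ncat x nsite log scalers
  std::vector<std::vector<int>> child_edges;  // per node, edge indices
  std::vector<int> parent_of;       // node -> edge index to its parent

  Peeler(const Rcpp::IntegerMatrix& edge_, int ntip_, const vec& el_,
         const Rcpp::IntegerMatrix& tipstate, const mat& U_,
         const mat& Uinv_, const vec& lambda_, const vec& pi_,
         const vec& rates_, double pinv_, const vec& invterm_)
      : edge(edge_), el(el_), U(U_), Uinv(Uinv_), lambda(lambda_),
        pi(pi_), rates(rates_), pinv(pinv_), invterm(invterm_) {
    ntip = ntip_;
    nedge = edge.nrow();
    ncat = rates.n_elem;
    nsite = tipstate.ncol();
    nnode = nedge + 1;
    root = edge(nedge - 1, 0) - 1;
    child_edges.assign(nnode, {});
    parent_of.assign(nnode, -1);
    for (int e = 0; e < nedge; ++e) {
      child_edges[edge(e, 0) - 1].push_back(e);
      parent_of[edge(e, 1) - 1] = e;
    }
    tippart.set_size(20, (size_t)ntip * nsite);
    tippart.zeros();
    for (int i = 0; i < ntip; ++i)
      for (int s = 0; s < nsite; ++s) {
        int st = tipstate(i, s);
        if (st < 0)
          tippart.col((size_t)i * nsite + s).ones();
        else
          tippart((uword)st, (size_t)i * nsite + s) = 1.0;
      }
    up.assign(nnode, cube());
    upscale.assign(nnode, mat());
  }

  mat pmat(double t, int cat) const {
    vec ev = exp(lambda * (rates(cat) * t));
    mat P = Uinv;
    P.each_col() %= ev;
    P = U * P;
    // eigen round-off can leave tiny negative probabilities
    P.transform([](double v) { return v < 0 ? 0.0 : v; });
    return P;
  }

  // up partial of node n for category cat (tips are category-free)
  mat tip_slice(int n) const {
    return tippart.cols((size_t)n * nsite, (size_t)(n + 1) * nsite - 1);
  }
  const mat up_slice(int n, int cat) const {
    return n < ntip ? tip_slice(n) : mat(up[n].slice(cat));
  }
  rowvec up_scale(int n, int cat) const {
    return n < ntip ? rowvec(nsite, fill::zeros) : rowvec(upscale[n].row(cat));
  }

  static void rescale(mat& M, rowvec& logs) {
    rowvec mx = max(M, 0);
    mx.transform([](double v) { return v > 0 ? v : 1.0; });
    M.each_row() /= mx;
    logs += log(mx);
  }

  void up_pass() {
    for (int n = ntip; n < nnode; ++n) {
      up[n].set_size(20, nsite, ncat);
      up[n].ones();
      upscale[n].set_size(ncat, nsite);
      upscale[n].zeros();
    }
    std::vector<int> remaining(nnode);
    for (int n = 0; n < nnode; ++n) remaining[n] = (int)child_edges[n].size();
    for (int e = 0; e < nedge; ++e) {
      int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
      for (int cat = 0; cat < ncat; ++cat) {
        up[p].slice(cat) %= pmat(el(e), cat) * up_slice(c, cat);
        upscale[p].row(cat) += up_scale(c, cat);
      }
      if (--remaining[p] == 0) {  // all children folded in: rescale now,
        for (int cat = 0; cat < ncat; ++cat) {  // before p's parent edge
          mat M = up[p].slice(cat);
          rowvec sc = upscale[p].row(cat);
          rescale(M, sc);
          up[p].slice(cat) = M;
          upscale[p].row(cat) = sc;
        }
      }
    }
  }

  // mix per-category conditional log-likelihoods with the invariant class
  vec mix_sites(const mat& catll) const {
    vec out(nsite);
    double lw = std::log((1.0 - pinv) / ncat);
    for (int s = 0; s < nsite; ++s) {
      double mx = -datum::inf;
      for (int cat = 0; cat < ncat; ++cat)
        mx = std::max(mx, catll(cat, s) + lw);
      double liv = (pinv > 0 && invterm(s) > 0)
                       ? std::log(pinv * invterm(s)) : -datum::inf;
      mx = std::max(mx, liv);
      double acc = 0.0;
      for (int cat = 0; cat < ncat; ++cat)
        acc += std::exp(catll(cat, s) + lw - mx);
      if (std::isfinite(liv)) acc += std::exp(liv - mx);
      out(s) = mx + std::log(acc);
    }
    return out;
  }

  vec site_loglik_from_up() const {
    mat catll(ncat, nsite);
    for (int cat = 0; cat < ncat; ++cat) {
      rowvec l = pi.t() * up[root].slice(cat);
      catll.row(cat) = log(l) + upscale[root].row(cat);
    }
    return mix_sites(catll);
  }

  // log-likelihood of the whole tree seen from one edge: Xpi holds the
  // pi-weighted partial for everything on the parent side, upc the child
  // side; scale carries both sides' accumulated log scalers
  double edge_loglik(double t, const std::vector<mat>& Xpi,
                     const std::vector<rowvec>& scale,
                     const std::vector<mat>& upc) const {
    mat catll(ncat, nsite);
    for (int cat = 0; cat < ncat; ++cat) {
      mat W = pmat(t, cat) * upc[cat];
      rowvec l = sum(Xpi[cat] % W, 0);
      catll.row(cat) = log(l) + scale[cat];
    }
    return accu(mix_sites(catll));
  }

  // bounded Brent maximization of edge_loglik over t
  double brent_edge(double lo, double hi, double start,
                    const std::vector<mat>& X,
                    const std::vector<rowvec>& Xscale, int child,
                    double tol_t) const {
    std::vector<mat> Xpi(ncat), upc(ncat);
    std::vector<rowvec> scale(ncat);
    for (int cat = 0; cat < ncat; ++cat) {
      Xpi[cat] = X[cat].each_col() % pi;
      upc[cat] = up_slice(child, cat);
      scale[cat] = Xscale[cat] + up_scale(child, cat);
    }
    auto f = [&](double t) { return -edge_loglik(t, Xpi, scale, upc); };
    const double gold = 0.3819660112501051;
    double a = lo, b = hi;
    double x = std::min(std::max(start, lo), hi);
    double w = x, v = x, fx = f(x), fw = fx, fv = fx;
    double d = 0.0, e = 0.0;
    for (int iter = 0; iter < 40; ++iter) {
      double m = 0.5 * (a + b);
      double tol1 = tol_t * std::fabs(x) + 1e-9, tol2 = 2 * tol1;
      if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
      double p = 0, q = 0, r = 0;
      bool parab = false;
      if (std::fabs(e) > tol1) {
        r = (x - w) * (fx - fv);
        q = (x - v) * (fx - fw);
        p = (x - v) * q - (x - w) * r;
        q = 2 * (q - r);
        if (q > 0) p = -p; else q = -q;
        if (std::fabs(p) < std::fabs(0.5 * q * e) && p > q * (a - x) &&
            p < q * (b - x)) {
          e = d; d = p / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
          parab = true;
        }
      }
      if (!parab) {
        e = (x < m) ? b - x : a - x;
        d = gold * e;
      }
      double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
      double fu = f(u);
      if (fu <= fx) {
        if (u < x) b = x; else a = x;
        v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
        else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
      }
    }
    return x;
  }

  // one pre-order Gauss-Seidel sweep over all branch lengths; after the
  // first sweep each edge only needs local refinement, so the Brent
  // bracket shrinks to a window around the current value (the incumbent
  // is always evaluated first, so the sweep stays monotone even if the
  // true optimum were outside the window)
  void optimize_sweep(double min_el, double max_el, double tol_t,
                      bool local_bracket) {
    std::vector<mat> A(ncat, mat(20, nsite, fill::ones));
    std::vector<rowvec> Asc(ncat, rowvec(nsite, fill::zeros));
    struct Frame { int node; std::vector<mat> A; std::vector<rowvec> Asc; };
    std::vector<Frame> stack;
    stack.push_back({root, A, Asc});
    while (!stack.empty()) {
      Frame fr = std::move(stack.back());
      stack.pop_back();
      int u = fr.node;
      const auto& ces = child_edges[u];
      int m = (int)ces.size();
      // Z_j = P_j up_cj per category, with the child's scalers
      std::vector<std::vector<mat>> Z(m, std::vector<mat>(ncat));
      for (int j = 0; j < m; ++j) {
        int e = ces[j], c = edge(e, 1) - 1;
        for (int cat = 0; cat < ncat; ++cat)
          Z[j][cat] = pmat(el(e), cat) * up_slice(c, cat);
      }
      for (int j = 0; j < m; ++j) {
        int e = ces[j], c = edge(e, 1) - 1;
        // X = A * prod of siblings' Z (leave-one-out), rescaled
        std::vector<mat> X(ncat);
        std::vector<rowvec> Xsc(ncat);
        for (int cat = 0; cat < ncat; ++cat) {
          mat M = fr.A[cat];
          rowvec sc = fr.Asc[cat];
          for (int i = 0; i < m; ++i)
            if (i != j) {
              M %= Z[i][cat];
              sc += up_scale(edge(ces[i], 1) - 1, cat);
            }
          rescale(M, sc);
          X[cat] = std::move(M);
          Xsc[cat] = std::move(sc);
        }
        double lo = min_el, hi = max_el;
        if (local_bracket) {
          lo = std::max(min_el, el(e) / 4.0);
          hi = std::min(max_el, el(e) * 4.0 + 1e-6);
        }
        el(e) = brent_edge(lo, hi, el(e), X, Xsc, c, tol_t);
        // refresh this edge's Z so later siblings see the new length
        for (int cat = 0; cat < ncat; ++cat)
          Z[j][cat] = pmat(el(e), cat) * up_slice(c, cat);
        if (c >= ntip) {
          // descend with A_child = P(t_new)^T applied via reversibility
          std::vector<mat> Ac(ncat);
          std::vector<rowvec> Acs(ncat);
          for (int cat = 0; cat < ncat; ++cat) {
            mat M = pmat(el(e), cat).t() * X[cat];
            rowvec sc = Xsc[cat];
            rescale(M, sc);
            Ac[cat] = std::move(M);
            Acs[cat] = std::move(sc);
          }
          stack.push_back({c, std::move(Ac), std::move(Acs)});
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_peel(Rcpp::IntegerMatrix edge, int ntip, arma::vec el,
                    Rcpp::IntegerMatrix tipstate, arma::mat U,
                    arma::mat Uinv, arma::vec lambda, arma::vec pi,
                    arma::vec rates, double pinv, arma::vec invterm,
                    bool opt_branches, double tol, int max_sweeps,
                    double min_el, double max_el) {
  Peeler pl(edge, ntip, el, tipstate, U, Uinv, lambda, pi, rates, pinv,
            invterm);
  pl.up_pass();
  vec sitell = pl.site_loglik_from_up();
  double ll = accu(sitell);
  int sweeps = 0;
  if (opt_branches) {
    for (; sweeps < max_sweeps; ++sweeps) {
      // per-edge precision follows the requested convergence tolerance:
      // coarse overall tolerances do not need fine per-edge bracketing
      double tol_t = std::max(1e-8, std::min(1e-3, tol));
      pl.optimize_sweep(min_el, max_el, tol_t, sweeps > 0);
      pl.up_pass();
      vec s2 = pl.site_loglik_from_up();
      double ll2 = accu(s2);
      if (!std::isfinite(ll2))
        Rcpp::stop("numerical failure during branch optimization");
      sitell = s2;
      double gain = ll2 - ll;
      ll = ll2;
      if (gain < tol) { ++sweeps; break; }
    }
  }
  if (!sitell.is_finite())
    Rcpp::stop("numerical failure: non-finite site log-likelihood");
  return Rcpp::List::create(
      Rcpp::Named("sitell") = sitell, Rcpp::Named("loglik") = ll,
      Rcpp::Named("el") = pl.el, Rcpp::Named("sweeps") = sweeps);
}
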