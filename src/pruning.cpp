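// Felsenstein pruning over codon site patterns, with per-site-class
// log-likelihoods and analytic branch-length gradients.
//
// Conventions:
//  - nodes are 0-based; tips are 0..ntip-1; edges are given in postorder
//    (every node's subtree edges appear before the edge above that node).
//  - transition probabilities come from the symmetric eigendecomposition a
//    reversible Q affords: P(t) = C1 diag(exp(lam t)) C2.
//  - per-pattern column rescaling guards against underflow; scales are
//    tracked in log space.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct Eig {
  arma::mat C1, C2;
  arma::vec lam;
};

static std::vector<Eig> unpack_eigs(List eig_list) {
  std::vector<Eig> out;
  out.reserve(eig_list.size());
  for (int i = 0; i < eig_list.size(); ++i) {
    List e = eig_list[i];
    Eig eg;
    eg.C1 = as<arma::mat>(e["C1"]);
    eg.C2 = as<arma::mat>(e["C2"]);
    eg.lam = as<arma::vec>(e["lam"]);
    out.push_back(eg);
  }
  return out;
}

static arma::mat make_P(const Eig& e, double t) {
  arma::mat P = e.C1 * arma::diagmat(arma::exp(e.lam * t)) * e.C2;
  P.for_each([](arma::mat::elem_type& x) { if (x < 0) x = 0; });
  return P;
}

static arma::mat make_dP(const Eig& e, double t) {
  return e.C1 * arma::diagmat(e.lam % arma::exp(e.lam * t)) * e.C2;
}

// tipstate: ntip x npat (0-based codon states, -1 = missing)
// parent, child: 0-based node ids per edge, postorder
// edge_eig: n_edge x n_class, 1-based index into eig_list
// pi: shared stationary distribution (root prior)
// class_weights: length n_class (used only when want_grad)
// [[Rcpp::export]]
List cpp_pruning(IntegerMatrix tipstate, IntegerVector parent,
                 IntegerVector child, int n_node, int root,
                 NumericVector bl, List eig_list, IntegerMatrix edge_eig,
                 NumericVector pi, bool want_grad,
                 NumericVector class_weights) {
  const int ntip = tipstate.nrow();
  const int npat = tipstate.ncol();
  const int n_edge = parent.size();
  const int n_class = edge_eig.ncol();
  const int ns = pi.size();

  std::vector<Eig> eigs = unpack_eigs(eig_list);
  arma::vec piv = as<arma::vec>(pi);

  arma::mat sitelik(npat, n_class);            // log f_{h,c}
  arma::mat grad(n_edge, 1, arma::fill::zeros);
  // per-class per-edge df/f ratios, needed to combine with responsibilities
  std::vector<arma::mat> ratios;               // each n_edge x npat
  if (want_grad) ratios.resize(n_class);

  // children edge indices per node (for sibling products in the up pass)
  std::vector<std::vector<int>> child_edges(n_node);
  for (int e = 0; e < n_edge; ++e) child_edges[parent[e]].push_back(e);

  for (int c = 0; c < n_class; ++c) {
    // transition matrices, cached per distinct eigen index on each edge
    std::vector<arma::mat> P(n_edge);
    for (int e = 0; e < n_edge; ++e) P[e] = make_P(eigs[edge_eig(e, c) - 1], bl[e]);

    // down pass -------------------------------------------------------
    std::vector<arma::mat> D(n_node), M(n_edge);
    std::vector<arma::rowvec> logD(n_node);
    std::vector<arma::rowvec> logM(n_edge), cm(n_edge);
    for (int v = ntip; v < n_node; ++v) {
      D[v] = arma::mat(ns, npat, arma::fill::ones);
      logD[v] = arma::rowvec(npat, arma::fill::zeros);
    }
    for (int e = 0; e < n_edge; ++e) {
      const int par = parent[e], chi = child[e];
      arma::mat Mraw(ns, npat);
      arma::rowvec base(npat, arma::fill::zeros);
      if (chi < ntip) {
        for (int h = 0; h < npat; ++h) {
          const int s = tipstate(chi, h);
          if (s < 0) Mraw.col(h).ones();
          else Mraw.col(h) = P[e].col(s);
        }
      } else {
        Mraw = P[e] * D[chi];
        base = logD[chi];
      }
      arma::rowvec cmax = arma::max(Mraw, 0);
      cmax.for_each([](double& x) { if (x <= 0) x = 1.0; });
      Mraw.each_row() /= cmax;
      M[e] = std::move(Mraw);
      cm[e] = cmax;
      logM[e] = base + arma::log(cmax);
      D[par] %= M[e];
      logD[par] += logM[e];
    }
    arma::rowvec froot = piv.t() * D[root];
    for (int h = 0; h < npat; ++h) {
      sitelik(h, c) = (froot(h) > 0)
        ? std::log(froot(h)) + logD[root](h)
        : -arma::datum::inf;
    }

    if (!want_grad) continue;

    // up pass ---------------------------------------------------------
    // V[e] = outside partial at parent(e) excluding edge e's subtree:
    // U[par] (x) product of sibling-edge M's.  f_h = sum_s V[e](s,h) M[e](s,h).
    std::vector<arma::mat> U(n_node), V(n_edge);
    U[root] = arma::repmat(piv, 1, npat);
    for (int e = n_edge - 1; e >= 0; --e) {
      const int par = parent[e], chi = child[e];
      arma::mat sib = U[par];
      for (int e2 : child_edges[par]) {
        if (e2 != e) sib %= M[e2];
      }
      V[e] = std::move(sib);
      if (chi >= ntip) {
        arma::mat Uraw = P[e].t() * V[e];
        arma::rowvec umax = arma::max(Uraw, 0);
        umax.for_each([](double& x) { if (x <= 0) x = 1.0; });
        Uraw.each_row() /= umax;
        U[chi] = std::move(Uraw);
      }
    }

    // per-edge derivative ratios (df_h/dt_e) / f_h ---------------------
    arma::mat ratio(n_edge, npat, arma::fill::zeros);
    for (int e = 0; e < n_edge; ++e) {
      const int chi = child[e];
      arma::mat dP = make_dP(eigs[edge_eig(e, c) - 1], bl[e]);
      arma::mat dM(ns, npat);
      if (chi < ntip) {
        for (int h = 0; h < npat; ++h) {
          const int s = tipstate(chi, h);
          if (s < 0) dM.col(h).zeros();  // rows of P sum to 1 for all t
          else dM.col(h) = dP.col(s);
        }
      } else {
        dM = dP * D[chi];
      }
      dM.each_row() /= cm[e];
      arma::rowvec fe = arma::sum(V[e] % M[e], 0);
      arma::rowvec dfe = arma::sum(V[e] % dM, 0);
      for (int h = 0; h < npat; ++h) {
        ratio(e, h) = (fe(h) > 0) ? dfe(h) / fe(h) : 0.0;
      }
    }
    ratios[c] = std::move(ratio);
  }

  List out = List::create(Named("sitelik") = wrap(sitelik));
  if (want_grad) {
    // responsibilities r_{h,c} = w_c f_{hc} / sum_c w_c f_{hc}
    arma::vec w = as<arma::vec>(class_weights);
    arma::mat logwf = sitelik;
    for (int c = 0; c < n_class; ++c) {
      logwf.col(c) += (w(c) > 0 ? std::log(w(c)) : -arma::datum::inf);
    }
    arma::vec m = arma::max(logwf, 1);
    arma::mat r = arma::exp(logwf.each_col() - m);
    arma::vec denom = arma::sum(r, 1);
    r.each_col() /= denom;
    // d lnL / d t_e per pattern; caller contracts with pattern weights
    arma::mat gp(n_edge, npat, arma::fill::zeros);
    for (int c = 0; c < n_class; ++c) gp += ratios[c].each_row() % r.col(c).t();
    out["grad_per_pattern"] = wrap(gp);
  }
  return out;
}

// Row-stochastic transition matrix for testing/simulation from R-side eigen.
// [[Rcpp::export]]
arma::mat cpp_make_P(List eig, double t) {
  List e = eig;
  Eig eg;
  eg.C1 = as<arma::mat>(e["C1"]);
  eg.C2 = as<arma::mat>(e["C2"]);
  eg.lam = as<arma::vec>(e["lam"]);
  return make_P(eg, t);
}
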