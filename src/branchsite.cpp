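// Branch-site codon likelihood engine: GY94 rate matrices, spectral
// transition probabilities and Felsenstein pruning over the 61 sense-codon
// states, evaluated for the four Model A site classes. The foreground
// classes (2a, 2b) differ from their background classes (0, 1) only on the
// foreground edge, so their likelihoods are obtained by recomputing just
// the path from the foreground edge to the root of the stored background
// pass.
//
// Indices arriving from R are 0-based; pattern entries are codon state
// indices 0..60 with -1 marking a gap (missing data, partial vector of
// ones). Edges must be supplied in postorder (children before parents).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct SpectralQ {
  arma::mat A;   // D^{-1} U      (D = diag(sqrt(pi)))
  arma::mat B;   // U' D
  arma::vec ev;  // eigenvalues of the symmetrised generator
};

arma::mat build_q(const arma::uvec& ii, const arma::uvec& jj,
                  const arma::uvec& ts, const arma::uvec& ns,
                  const arma::vec& pi, double kappa, double omega,
                  double rate_scale) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword k = 0; k < ii.n_elem; ++k) {
    double r = pi[jj[k]];
    if (ts[k]) r *= kappa;
    if (ns[k]) r *= omega;
    Q(ii[k], jj[k]) = r;
  }
  Q.diag() = -arma::sum(Q, 1);
  Q /= rate_scale;  // shared mixture scale supplied by the caller
  return Q;
}

SpectralQ spectral(const arma::mat& Q, const arma::vec& pi) {
  arma::vec d = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= d;
  S.each_row() /= d.t();
  S = 0.5 * (S + S.t());
  SpectralQ out;
  arma::mat U;
  if (!arma::eig_sym(out.ev, U, S)) {
    stop("eigendecomposition of codon rate matrix failed");
  }
  out.A = U;
  out.A.each_col() /= d;
  out.B = U.t();
  out.B.each_row() %= d.t();
  return out;
}

arma::mat pmat(const SpectralQ& e, double t) {
  arma::mat B = e.B;
  B.each_col() %= arma::exp(e.ev * t);
  arma::mat P = e.A * B;
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

// per-column rescaling against underflow; accumulates log scale
void rescale(arma::mat& contrib, arma::rowvec& logscale) {
  arma::rowvec mx = arma::max(contrib, 0);
  for (arma::uword s = 0; s < contrib.n_cols; ++s) {
    if (mx[s] > 0 && mx[s] < 1e-6) {
      contrib.col(s) /= mx[s];
      logscale[s] += std::log(mx[s]);
    }
  }
}

arma::mat tip_contrib(const arma::mat& P, const IntegerMatrix& patt, int tip) {
  arma::mat contrib(P.n_rows, patt.ncol());
  for (int s = 0; s < patt.ncol(); ++s) {
    int st = patt(tip, s);
    if (st < 0) contrib.col(s).ones();
    else contrib.col(s) = P.col(st);
  }
  return contrib;
}

// One full pruning pass. Stores the (rescaled) per-edge contribution
// matrices and their log-scale rows so that a single-edge perturbation can
// be re-propagated along the root path without redoing the whole tree.
struct Pass {
  std::vector<arma::mat> contrib;
  std::vector<arma::rowvec> scale;
  arma::rowvec loglik;
};

Pass full_pass(const std::vector<const arma::mat*>& P,
               const IntegerMatrix& patt,
               const arma::ivec& parent, const arma::ivec& child,
               int root, int ntips, int nnodes, const arma::vec& pi) {
  const int npat = patt.ncol();
  const arma::uword n = pi.n_elem;
  const arma::uword nedge = child.n_elem;
  Pass pass;
  pass.contrib.resize(nedge);
  pass.scale.assign(nedge, arma::rowvec(npat, arma::fill::zeros));
  std::vector<arma::mat> part(nnodes);
  std::vector<bool> seen(nnodes, false);
  for (arma::uword e = 0; e < nedge; ++e) {
    const int ch = child[e];
    arma::mat contrib = (ch < ntips) ? tip_contrib(*P[e], patt, ch)
                                     : (*P[e]) * part[ch];
    rescale(contrib, pass.scale[e]);
    const int pa = parent[e];
    if (!seen[pa]) { part[pa] = contrib; seen[pa] = true; }
    else part[pa] %= contrib;
    pass.contrib[e] = std::move(contrib);
  }
  arma::rowvec site = pi.t() * part[root];
  pass.loglik = arma::log(site);
  for (arma::uword e = 0; e < nedge; ++e) pass.loglik += pass.scale[e];
  return pass;
}

// Recompute a stored pass with the foreground edge's transition matrix
// replaced, touching only the edges on the path foreground -> root.
arma::rowvec fg_repass(const Pass& base,
                       const std::vector<const arma::mat*>& P,
                       const arma::mat& Pfg, int fg_edge,
                       const IntegerMatrix& patt,
                       const arma::ivec& parent, const arma::ivec& child,
                       const std::vector<int>& incoming,
                       const std::vector<std::vector<int> >& child_edges,
                       int root, int ntips, const arma::vec& pi) {
  const int npat = patt.ncol();
  int cur = fg_edge;
  arma::mat cur_contrib = (child[fg_edge] < ntips)
      ? tip_contrib(Pfg, patt, child[fg_edge])
      : arma::mat();  // foreground is a terminal branch in this model
  arma::rowvec cur_scale(npat, arma::fill::zeros);
  rescale(cur_contrib, cur_scale);
  arma::rowvec delta = cur_scale - base.scale[fg_edge];
  for (;;) {
    const int u = parent[cur];
    arma::mat part;
    bool first = true;
    for (int e : child_edges[u]) {
      const arma::mat& c = (e == cur) ? cur_contrib : base.contrib[e];
      if (first) { part = c; first = false; }
      else part %= c;
    }
    if (u == root) {
      arma::rowvec site = pi.t() * part;
      arma::rowvec total = arma::log(site) + delta;
      for (arma::uword e = 0; e < child.n_elem; ++e) total += base.scale[e];
      return total;
    }
    const int e_up = incoming[u];
    cur_contrib = (*P[e_up]) * part;
    arma::rowvec sc(npat, arma::fill::zeros);
    rescale(cur_contrib, sc);
    delta += sc - base.scale[e_up];
    cur = e_up;
  }
}

}  // namespace

// Log site likelihoods for the four Model A site classes.
//
// Rows of the returned matrix: class 0 (omega0 everywhere), class 1 (omega 1
// everywhere), class 2a (background omega0, foreground omega2), class 2b
// (background 1, foreground omega2). fg_edge is the 0-based index of the
// foreground edge among the supplied (postordered) edges; it must be a
// terminal edge.
// [[Rcpp::export]]
NumericMatrix cpp_class_site_loglik(IntegerMatrix patt,
                                    IntegerVector edge_parent,
                                    IntegerVector edge_child,
                                    NumericVector edge_len,
                                    int fg_edge, int root, int ntips,
                                    int nnodes, NumericVector pi_,
                                    double kappa, double omega0,
                                    double omega2, double rate_scale,
                                    IntegerVector ii, IntegerVector jj,
                                    IntegerVector ts, IntegerVector ns) {
  const arma::vec pi(pi_.begin(), pi_.size());
  const arma::uvec uii = as<arma::uvec>(ii);
  const arma::uvec ujj = as<arma::uvec>(jj);
  const arma::uvec uts = as<arma::uvec>(ts);
  const arma::uvec uns = as<arma::uvec>(ns);
  const arma::ivec parent = as<arma::ivec>(edge_parent);
  const arma::ivec child = as<arma::ivec>(edge_child);
  const int nedge = edge_len.size();
  if (fg_edge < 0 || fg_edge >= nedge || child[fg_edge] >= ntips) {
    stop("foreground edge must be a terminal branch");
  }

  SpectralQ e0 = spectral(build_q(uii, ujj, uts, uns, pi, kappa, omega0, rate_scale), pi);
  SpectralQ e1 = spectral(build_q(uii, ujj, uts, uns, pi, kappa, 1.0, rate_scale), pi);
  SpectralQ e2 = spectral(build_q(uii, ujj, uts, uns, pi, kappa, omega2, rate_scale), pi);

  std::vector<arma::mat> P0(nedge), P1(nedge);
  for (int e = 0; e < nedge; ++e) {
    P0[e] = pmat(e0, edge_len[e]);
    P1[e] = pmat(e1, edge_len[e]);
  }
  arma::mat Pfg2 = pmat(e2, edge_len[fg_edge]);

  std::vector<const arma::mat*> s0(nedge), s1(nedge);
  for (int e = 0; e < nedge; ++e) { s0[e] = &P0[e]; s1[e] = &P1[e]; }

  std::vector<int> incoming(nnodes, -1);
  std::vector<std::vector<int> > child_edges(nnodes);
  for (int e = 0; e < nedge; ++e) {
    incoming[child[e]] = e;
    child_edges[parent[e]].push_back(e);
  }

  Pass pass0 = full_pass(s0, patt, parent, child, root, ntips, nnodes, pi);
  Pass pass1 = full_pass(s1, patt, parent, child, root, ntips, nnodes, pi);
  arma::rowvec l2a = fg_repass(pass0, s0, Pfg2, fg_edge, patt, parent, child,
                               incoming, child_edges, root, ntips, pi);
  arma::rowvec l2b = fg_repass(pass1, s1, Pfg2, fg_edge, patt, parent, child,
                               incoming, child_edges, root, ntips, pi);

  const int npat = patt.ncol();
  NumericMatrix out(4, npat);
  for (int s = 0; s < npat; ++s) {
    out(0, s) = pass0.loglik[s];
    out(1, s) = pass1.loglik[s];
    out(2, s) = l2a[s];
    out(3, s) = l2b[s];
  }
  return out;
}
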