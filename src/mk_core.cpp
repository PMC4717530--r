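// Core numerics for the Mk (k-state continuous-time Markov) machinery:
// transition matrices, Felsenstein pruning with ambiguous tips, marginal
// ancestral states, and the Metropolis-Hastings sampler over transition
// rates with an exponential hyperprior. Kept in C++ because the recovery
// experiments evaluate the pruning likelihood ~1e5-1e6 times on trees
// with hundreds of tips.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Eigen-based exp(Q t) with Pade fallback for defective Q.
struct QExp {
  arma::cx_mat V, Vinv;
  arma::cx_vec lam;
  arma::mat Q;
  bool use_eigen;

  explicit QExp(const arma::mat& Qin) : Q(Qin) {
    arma::cx_vec eigval;
    arma::cx_mat eigvec;
    use_eigen = arma::eig_gen(eigval, eigvec, Qin);
    if (use_eigen) {
      arma::cx_mat inv;
      use_eigen = arma::inv(inv, eigvec);
      if (use_eigen && arma::rcond(eigvec) > 1e-10) {
        V = eigvec; Vinv = inv; lam = eigval;
      } else {
        use_eigen = false;
      }
    }
  }

  arma::mat at(double t) const {
    arma::mat P;
    if (use_eigen) {
      arma::cx_mat M = V * arma::diagmat(arma::exp(lam * t)) * Vinv;
      P = arma::real(M);
    } else {
      P = arma::expmat(Q * t);
    }
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return P;
  }
};

// Pruning log-likelihood. Edges must be in postorder (children before
// parents); edge indices are 1-based node numbers as in ape.
double pruning_loglik(const arma::imat& edge, const arma::vec& elen,
                      int ntip, const arma::mat& tip_partials,
                      const QExp& qe, const arma::vec& pi) {
  const int k = pi.n_elem;
  const int nnode = edge.max();
  arma::mat part(nnode, k, arma::fill::ones);
  part.rows(0, ntip - 1) = tip_partials;
  double logscale = 0.0;
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    arma::mat P = qe.at(elen(e));
    arma::rowvec child = part.row(c);
    double mx = child.max();
    if (mx <= 0.0) return -arma::datum::inf;
    child /= mx;
    logscale += std::log(mx);
    part.row(p) %= (P * child.t()).t();
  }
  const int root = edge(edge.n_rows - 1, 0) - 1;
  double L = arma::dot(pi, part.row(root).t());
  if (!(L > 0.0)) return -arma::datum::inf;
  return std::log(L) + logscale;
}

arma::mat build_q(const arma::vec& rates) {
  // rates order: qAB qAC qBA qBC qCA qCB
  arma::mat Q(3, 3, arma::fill::zeros);
  Q(0, 1) = rates(0); Q(0, 2) = rates(1);
  Q(1, 0) = rates(2); Q(1, 2) = rates(3);
  Q(2, 0) = rates(4); Q(2, 1) = rates(5);
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat& Q, double t) {
  QExp qe(Q);
  return qe.at(t);
}

// [[Rcpp::export]]
double cpp_pruning_loglik(const arma::imat& edge, const arma::vec& elen,
                          int ntip, const arma::mat& tip_partials,
                          const arma::mat& Q, const arma::vec& pi) {
  QExp qe(Q);
  return pruning_loglik(edge, elen, ntip, tip_partials, qe, pi);
}

// Marginal state probabilities for every node (tips included) by the
// standard two-pass algorithm: down (subtree-conditional) partials, then
// a root-to-tip pass carrying the complementary partials.
// [[Rcpp::export]]
arma::mat cpp_marginals(const arma::imat& edge, const arma::vec& elen,
                        int ntip, const arma::mat& tip_partials,
                        const arma::mat& Q, const arma::vec& pi) {
  QExp qe(Q);
  const int k = pi.n_elem;
  const int nnode = edge.max();
  const int nedge = edge.n_rows;
  arma::mat down(nnode, k, arma::fill::ones);
  down.rows(0, ntip - 1) = tip_partials;
  arma::cube P(k, k, nedge);
  // contrib(e, s) = sum_{s'} P_e(s, s') down_child(s'), child partial
  // scaled to max 1 (per-node constants cancel in the normalization)
  arma::mat contrib(nedge, k);
  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    P.slice(e) = qe.at(elen(e));
    arma::rowvec child = down.row(c);
    double mx = child.max();
    if (mx > 0.0) child /= mx;
    contrib.row(e) = (P.slice(e) * child.t()).t();
    down.row(p) %= contrib.row(e);
    double pm = down.row(p).max();
    if (pm > 0.0 && pm < 1e-200) down.row(p) /= pm;
  }
  const int root = edge(nedge - 1, 0) - 1;
  arma::mat out(nnode, k, arma::fill::zeros);
  out.row(root) = pi.t();
  // preorder: reverse postorder visits parents before children
  for (int e = nedge - 1; e >= 0; --e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    // leave-one-out product over p's other child edges
    arma::rowvec loo = out.row(p);
    for (int f = 0; f < nedge; ++f) {
      if (f != e && edge(f, 0) - 1 == p) loo %= contrib.row(f);
    }
    out.row(c) = (P.slice(e).t() * loo.t()).t();
    double mx = out.row(c).max();
    if (mx > 0.0) out.row(c) /= mx;
  }
  arma::mat marg = out % down;
  for (int v = 0; v < nnode; ++v) {
    double s = arma::accu(marg.row(v));
    if (s > 0.0) marg.row(v) /= s;
  }
  return marg;
}

// Metropolis-Hastings sampler. Per iteration one move is chosen uniformly:
// (i) window perturbation of one random free rate (negative proposals
// rejected), (ii) window update of the exponential-hyperprior mean mu on
// (0, hyper_max], (iii) uniform redraw of the tree index. Rates carry an
// Exponential(mean mu) prior; mu is Uniform(0, hyper_max].
// [[Rcpp::export]]
List cpp_mcmc(const List& trees, const List& tip_partials_list,
              const LogicalVector& free_mask, double n_gen, double burnin,
              double thin_d, double ratedev, double hyper_max,
              double mu_window, const arma::vec& init_rates,
              double init_mu, int init_tree, const arma::vec& pi) {
  const int ntrees = trees.size();
  std::vector<arma::imat> edges(ntrees);
  std::vector<arma::vec> elens(ntrees);
  std::vector<arma::mat> tips(ntrees);
  std::vector<int> ntips(ntrees);
  for (int i = 0; i < ntrees; ++i) {
    List tr = trees[i];
    edges[i] = as<arma::imat>(tr["edge"]);
    elens[i] = as<arma::vec>(tr["edge_length"]);
    ntips[i] = as<int>(tr["ntip"]);
    tips[i] = as<arma::mat>(tip_partials_list[i]);
  }
  std::vector<int> free_idx;
  for (int j = 0; j < free_mask.size(); ++j) {
    if (free_mask[j]) free_idx.push_back(j);
  }
  const int nfree = free_idx.size();
  if (nfree == 0) stop("at least one rate must be unconstrained");

  arma::vec rates = init_rates;
  double mu = init_mu;
  int tree = init_tree;  // 0-based
  auto loglik = [&](const arma::vec& r, int ti) {
    QExp qe(build_q(r));
    return pruning_loglik(edges[ti], elens[ti], ntips[ti], tips[ti], qe, pi);
  };
  double cur_ll = loglik(rates, tree);
  double sum_rates = 0.0;
  for (int j = 0; j < nfree; ++j) sum_rates += rates(free_idx[j]);

  const long long gens = (long long)n_gen;
  const long long burn = (long long)burnin;
  const long long thin = (long long)thin_d;
  const long n_samples = (long)((gens - burn) / thin);
  arma::mat samples(std::max(n_samples, 0L), 10);
  long srow = 0;
  arma::vec prop(3, arma::fill::zeros), acc(3, arma::fill::zeros);

  for (long long it = 1; it <= gens; ++it) {
    const int move = (int)(unif_rand() * 3.0);
    if (move == 0) {
      const int j = free_idx[(int)(unif_rand() * nfree)];
      prop(0) += 1.0;
      const double r_new = rates(j) + (unif_rand() - 0.5) * ratedev;
      if (r_new >= 0.0) {
        arma::vec cand = rates;
        cand(j) = r_new;
        const double ll = loglik(cand, tree);
        const double log_alpha = ll - cur_ll - (r_new - rates(j)) / mu;
        if (std::log(unif_rand()) < log_alpha) {
          sum_rates += r_new - rates(j);
          rates = cand; cur_ll = ll; acc(0) += 1.0;
        }
      }
    } else if (move == 1) {
      prop(1) += 1.0;
      const double mu_new = mu + (unif_rand() - 0.5) * 2.0 * mu_window;
      if (mu_new > 0.0 && mu_new <= hyper_max) {
        const double log_alpha = nfree * std::log(mu / mu_new) -
          sum_rates * (1.0 / mu_new - 1.0 / mu);
        if (std::log(unif_rand()) < log_alpha) {
          mu = mu_new; acc(1) += 1.0;
        }
      }
    } else {
      prop(2) += 1.0;
      const int t_new = (int)(unif_rand() * ntrees);
      if (t_new == tree) {
        acc(2) += 1.0;
      } else {
        const double ll = loglik(rates, t_new);
        if (std::log(unif_rand()) < ll - cur_ll) {
          tree = t_new; cur_ll = ll; acc(2) += 1.0;
        }
      }
    }
    if (it > burn && (it - burn) % thin == 0 && srow < n_samples) {
      samples(srow, 0) = it;
      for (int j = 0; j < 6; ++j) samples(srow, 1 + j) = rates(j);
      samples(srow, 7) = mu;
      samples(srow, 8) = tree + 1;
      samples(srow, 9) = cur_ll;
      ++srow;
    }
  }
  arma::vec acc_rate(3);
  for (int m = 0; m < 3; ++m) {
    acc_rate(m) = prop(m) > 0 ? acc(m) / prop(m) : NA_REAL;
  }
  arma::mat kept = srow > 0 ? samples.rows(0, srow - 1)
                            : arma::mat(0, 10);
  return List::create(_["samples"] = kept,
                      _["acceptance"] = acc_rate,
                      _["final_loglik"] = cur_ll);
}
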