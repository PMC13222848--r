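#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Matrix exponential of Q*t for a CTMC generator (dense; state spaces here
// are small, <= ~60 states, so Pade/scaling-squaring via Armadillo is fine).
// [[Rcpp::export]]
arma::mat expm_ctmc_cpp(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// P(t) factory by uniformization: with Omega = max(-diag(Q)) and
// R = I + Q/Omega,
//   P(t) = sum_n Poisson(n; Omega t) R^n.
// Every term is non-negative, so unlike eigendecomposition or Pade there is
// no cancellation and even entries of order 1e-14 (many-jump paths) keep
// good relative accuracy. Powers of R are grown once and shared across all
// branch lengths of a tree, which is what makes per-branch propagators
// cheap. Falls back to expmat when exp(-Omega t) would underflow.
struct PropagatorFactory {
  const arma::mat& Q;
  double omega;
  std::vector<arma::mat> powers;  // powers[n] = R^n

  explicit PropagatorFactory(const arma::mat& Q_) : Q(Q_) {
    omega = -Q.diag().min();
    powers.push_back(arma::eye(Q.n_rows, Q.n_cols));
    if (omega > 0.0) {
      powers.push_back(arma::eye(Q.n_rows, Q.n_cols) + Q / omega);
    }
  }

  const arma::mat& power(unsigned int n) {
    while (powers.size() <= n) {
      powers.push_back(powers.back() * powers[1]);
    }
    return powers[n];
  }

  arma::mat operator()(double t) {
    const double lambda = omega * t;
    if (lambda <= 0.0) return powers[0];
    if (lambda > 700.0) return arma::expmat(Q * t);  // exp(-lambda) underflows
    arma::mat P(Q.n_rows, Q.n_cols, arma::fill::zeros);
    double w = std::exp(-lambda);  // Poisson(0; lambda)
    unsigned int n = 0;
    for (;;) {
      P += w * power(n);
      ++n;
      w *= lambda / n;
      // past the mode, stop once the term weight is negligible even
      // relative to the tiniest transition probabilities of interest
      if (n > lambda && w < 1e-30) break;
      if (n > 100000) break;  // defensive; unreachable for lambda <= 700
    }
    return P;
  }
};

// Felsenstein pruning over a postorder edge list.
//
// edge: 2-column matrix (parent, child), 1-based ape node numbering, rows in
//   postorder (every edge below a child precedes the edge above it).
// tip_state: 1-based state index per tip (tips are nodes 1..n_tip).
// Returns per-node conditional (subtree) likelihood vectors, scaled per edge
// to avoid underflow, the accumulated log scaling factor, and optionally the
// per-edge transition-probability matrices (needed for stochastic mapping).
// [[Rcpp::export]]
List ctmc_pruning_cpp(const IntegerMatrix& edge, const NumericVector& edge_len,
                      const IntegerVector& tip_state, int n_tip, int n_node,
                      const arma::mat& Q, bool keep_P) {
  const int S = Q.n_rows;
  const int n_edge = edge.nrow();
  PropagatorFactory make_P(Q);
  arma::mat partial(n_node, S);
  partial.zeros();
  // tips: unit vector on the observed state; internals: multiplicative identity
  for (int i = 0; i < n_tip; ++i) {
    partial(i, tip_state[i] - 1) = 1.0;
  }
  for (int i = n_tip; i < n_node; ++i) partial.row(i).ones();

  std::map<double, arma::mat> P_cache;
  List P_out(keep_P ? n_edge : 0);
  double log_scale = 0.0;
  bool impossible = false;

  for (int e = 0; e < n_edge && !impossible; ++e) {
    const int parent = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    const double len = edge_len[e];
    std::map<double, arma::mat>::iterator it = P_cache.find(len);
    if (it == P_cache.end()) {
      it = P_cache.insert(std::make_pair(len, make_P(len))).first;
    }
    const arma::mat& P = it->second;
    if (keep_P) P_out[e] = wrap(P);
    arma::rowvec contrib = partial.row(child) * P.t();  // contrib_i = sum_j P(i,j) L_child(j)
    const double s = arma::accu(contrib);
    if (!(s > 0.0) || !std::isfinite(s)) {
      impossible = true;
      break;
    }
    contrib /= s;
    log_scale += std::log(s);
    partial.row(parent) %= contrib;
  }

  return List::create(
    _["partial"] = wrap(partial),
    _["log_scale"] = log_scale,
    _["impossible"] = impossible,
    _["P"] = keep_P ? SEXP(P_out) : R_NilValue);
}
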