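// Core numerical kernels: dense matrix exponential and Felsenstein pruning
// over PoMo state spaces. Matrices are small (4 + 6(N-1) states, <= ~120
// at N = 20), so dense scaling-and-squaring is the right tool.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat expm_cpp(const arma::mat& M) {
  return arma::expmat(M);
}

// Pruning log-likelihood on a rooted tree with ape-style node numbering
// (tips 1..ntip, root ntip+1, internals above). `edge` is the 2-column
// edge matrix in postorder, `elen` the matching branch lengths.
// `tipcond` holds one (nstate x npattern) conditional matrix per tip, in
// tip-number order. Columns are rescaled by their sum at every internal
// node to avoid underflow; the log scalers are accumulated per pattern.
// [[Rcpp::export]]
double pruning_loglik_cpp(const arma::mat& Q,
                          const arma::imat& edge,
                          const arma::vec& elen,
                          const List& tipcond,
                          const arma::vec& root_freq,
                          const arma::vec& weights,
                          const int n_node) {
  const int ntip = tipcond.size();
  const arma::mat tip0 = as<arma::mat>(tipcond[0]);
  const int k = tip0.n_rows;
  const int np = tip0.n_cols;

  std::vector<arma::mat> partial(n_node + 1);
  std::vector<bool> seen(n_node + 1, false);
  arma::rowvec logscale(np, arma::fill::zeros);

  const int nedge = edge.n_rows;
  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0);
    const int child  = edge(e, 1);
    arma::mat down;  // (k x np) conditionals moved up the branch
    if (child <= ntip) {
      down = arma::expmat(Q * elen(e)) *
             as<arma::mat>(tipcond[child - 1]);
    } else {
      down = arma::expmat(Q * elen(e)) * partial[child];
    }
    if (!seen[parent]) {
      partial[parent] = down;
      seen[parent] = true;
    } else {
      partial[parent] %= down;
      // rescale after each product to keep columns O(1)
      arma::rowvec cs = arma::sum(partial[parent], 0);
      cs.elem(arma::find(cs <= 0)).fill(1.0);
      partial[parent].each_row() /= cs;
      logscale += arma::log(cs);
    }
  }

  const int root = ntip + 1;
  arma::rowvec site = root_freq.t() * partial[root];
  double ll = 0.0;
  for (int p = 0; p < np; ++p) {
    double s = site(p);
    if (s <= 0.0) return -std::numeric_limits<double>::infinity();
    ll += weights(p) * (std::log(s) + logscale(p));
  }
  return ll;
}

// Build the PoMo generator directly from raw parameter vectors (same
// state ordering as the R builder: mono A,C,G,T then pairs AC, AG, AT,
// CG, CT, GT with n = 1..N-1 counting the first allele). mu holds the 12
// mutation rates in order (AC,AG,AT,CG,CT,GT, CA,GA,TA,GC,TC,TG).
static arma::mat build_q_arma(const int N, const arma::vec& mu,
                              const arma::vec& phi, const arma::vec& beta,
                              const arma::ivec& B, const bool balance) {
  const int k = 4 + 6 * (N - 1);
  static const int FIRST[6]  = {0, 0, 0, 1, 1, 2};
  static const int SECOND[6] = {1, 2, 3, 2, 3, 3};
  arma::mat Q(k, k, arma::fill::zeros);
  for (int p = 0; p < 6; ++p) {
    const int f = FIRST[p], s = SECOND[p];
    const int base = 4 + p * (N - 1);           // index of poly(p, n=1)
    const int idxN1 = base + (N - 2);           // poly(p, N-1)
    Q(f, idxN1) += mu(p);                        // mono first -> N-1
    Q(s, base) += mu(6 + p);                     // mono second -> 1
    const double be = balance ? beta(p) : 1.0;
    const int Bp = balance ? B(p) : 0;
    for (int n = 1; n <= N - 1; ++n) {
      const double drift = double(n) * (N - n) / N;
      const int i = base + (n - 1);
      // up-move n -> n+1 gains the first allele
      double eup = 0.0, edn = 0.0;
      if (balance) {
        eup = (std::abs(n - Bp) - std::abs(n + 1 - Bp) + 1) / 2.0;
        edn = (std::abs(n - Bp) - std::abs(n - 1 - Bp) + 1) / 2.0;
      }
      const int j_up = (n + 1 == N) ? f : base + n;
      const int j_dn = (n - 1 == 0) ? s : base + (n - 2);
      Q(i, j_up) += drift * phi(f) * std::pow(be, eup);
      Q(i, j_dn) += drift * phi(s) * std::pow(be, edn);
    }
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// [[Rcpp::export]]
arma::mat build_q_cpp(const int N, const arma::vec& mu, const arma::vec& phi,
                      const arma::vec& beta, const arma::ivec& B,
                      const bool balance) {
  return build_q_arma(N, mu, phi, beta, B, balance);
}

// One-shot likelihood evaluation for the sampler hot loop: generator,
// stationary root frequencies (least-squares null space), pruning.
// root_mode: 0 = stationary, 1 = uniform. Returns -Inf on any numerical
// failure so the caller can simply reject the proposal.
// [[Rcpp::export]]
double pomo_state_loglik_cpp(const int N, const arma::vec& mu,
                             const arma::vec& phi, const arma::vec& beta,
                             const arma::ivec& B, const bool balance,
                             const arma::imat& edge, const arma::vec& elen,
                             const List& tipcond, const arma::vec& weights,
                             const int n_node, const int root_mode) {
  const double NEGINF = -std::numeric_limits<double>::infinity();
  arma::mat Q = build_q_arma(N, mu, phi, beta, B, balance);
  const int k = Q.n_rows;
  arma::vec root(k);
  if (root_mode == 1) {
    root.fill(1.0 / k);
  } else {
    arma::mat A(k + 1, k);
    A.rows(0, k - 1) = Q.t();
    A.row(k).fill(1.0);
    arma::vec b(k + 1, arma::fill::zeros);
    b(k) = 1.0;
    bool ok = arma::solve(root, A, b, arma::solve_opts::no_approx);
    if (!ok || !root.is_finite()) return NEGINF;
    root.clamp(0.0, arma::datum::inf);
    const double tot = arma::accu(root);
    if (tot <= 0) return NEGINF;
    root /= tot;
  }
  return pruning_loglik_cpp(Q, edge, elen, tipcond, root, weights, n_node);
}
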