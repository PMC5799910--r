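#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Shared workhorse for MNTD / betaMNTD null models.
//
// Conventions:
//  D    K x K patristic distance matrix (taxa in fixed "slot" order)
//  W    N x K weight matrix; row s gives each taxon's weight in sample s
//       (relative abundance, or 1/richness for presence-absence); zero
//       means absent. Rows sum to 1 over present taxa.
//  perm length-K 0-based permutation: slot i takes the tree position
//       perm[i]. The observed statistic uses the identity permutation.
//
// betaMNTD(a,b) = 0.5 * [ sum_{i in a} w_ai min_{j in b} D(p_i,p_j)
//                       + sum_{j in b} w_bj min_{i in a} D(p_i,p_j) ]
// Minima may hit j == i (shared taxon -> distance 0), the standard
// between-community convention. Within-sample MNTD excludes self.

// For one permutation, fill M (N x K): M(s, i) = min over taxa j present
// in sample s of D(perm[i], perm[j]).
static void min_dist_to_samples(const arma::mat& D,
                                const std::vector< std::vector<arma::uword> >& present,
                                const arma::uvec& perm,
                                arma::mat& M) {
  const arma::uword N = present.size();
  const arma::uword K = D.n_rows;
  arma::vec msite(K);
  for (arma::uword s = 0; s < N; ++s) {
    const std::vector<arma::uword>& ps = present[s];
    // msite(u) = min over present j of D(u, perm[j]) for every tree position u
    msite.fill(arma::datum::inf);
    for (arma::uword jj = 0; jj < ps.size(); ++jj) {
      const double* col = D.colptr(perm[ps[jj]]);
      for (arma::uword u = 0; u < K; ++u) {
        if (col[u] < msite[u]) msite[u] = col[u];
      }
    }
    for (arma::uword i = 0; i < K; ++i) M(s, i) = msite[perm[i]];
  }
}

static std::vector< std::vector<arma::uword> > presence_lists(const arma::mat& W) {
  std::vector< std::vector<arma::uword> > present(W.n_rows);
  for (arma::uword s = 0; s < W.n_rows; ++s)
    for (arma::uword i = 0; i < W.n_cols; ++i)
      if (W(s, i) > 0.0) present[s].push_back(i);
  return present;
}

static arma::mat beta_mntd_from_M(const arma::mat& W, const arma::mat& M) {
  arma::mat C = W * M.t();       // C(a,b) = sum_i w_ai * M(b,i)
  return 0.5 * (C + C.t());
}

// [[Rcpp::export(name = ".cpp_beta_mntd")]]
arma::mat cpp_beta_mntd(const arma::mat& D, const arma::mat& W) {
  std::vector< std::vector<arma::uword> > present = presence_lists(W);
  arma::uvec perm = arma::regspace<arma::uvec>(0, D.n_rows - 1);
  arma::mat M(W.n_rows, W.n_cols);
  min_dist_to_samples(D, present, perm, M);
  return beta_mntd_from_M(W, M);
}

// Null distribution of betaMNTD for all pairs under shared taxa-shuffle
// replicates. P is n_null x K, 0-based. Returns per-pair null mean and
// (n-1 denominator) sd via Welford accumulation.
// [[Rcpp::export(name = ".cpp_beta_mntd_null")]]
List cpp_beta_mntd_null(const arma::mat& D, const arma::mat& W,
                        const arma::umat& P) {
  const arma::uword N = W.n_rows;
  const arma::uword R = P.n_rows;
  std::vector< std::vector<arma::uword> > present = presence_lists(W);
  arma::mat M(N, W.n_cols);
  arma::mat mean(N, N, arma::fill::zeros), m2(N, N, arma::fill::zeros);
  for (arma::uword r = 0; r < R; ++r) {
    arma::uvec perm = P.row(r).t();
    min_dist_to_samples(D, present, perm, M);
    arma::mat B = beta_mntd_from_M(W, M);
    arma::mat delta = B - mean;
    mean += delta / double(r + 1);
    m2 += delta % (B - mean);
  }
  arma::mat sd = arma::sqrt(m2 / double(R - 1));
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Within-sample MNTD for every sample under one permutation: nearest
// neighbour among the *other* present taxa of the same sample.
static void mntd_samples(const arma::mat& D, const arma::mat& W,
                         const std::vector< std::vector<arma::uword> >& present,
                         const arma::uvec& perm, arma::vec& out) {
  const arma::uword N = W.n_rows;
  for (arma::uword s = 0; s < N; ++s) {
    const std::vector<arma::uword>& ps = present[s];
    double acc = 0.0;
    for (arma::uword a = 0; a < ps.size(); ++a) {
      double mn = arma::datum::inf;
      const arma::uword ua = perm[ps[a]];
      for (arma::uword b = 0; b < ps.size(); ++b) {
        if (a == b) continue;
        const double d = D(ua, perm[ps[b]]);
        if (d < mn) mn = d;
      }
      acc += W(s, ps[a]) * mn;
    }
    out[s] = acc;
  }
}

// [[Rcpp::export(name = ".cpp_mntd")]]
arma::vec cpp_mntd(const arma::mat& D, const arma::mat& W) {
  std::vector< std::vector<arma::uword> > present = presence_lists(W);
  arma::uvec perm = arma::regspace<arma::uvec>(0, D.n_rows - 1);
  arma::vec out(W.n_rows);
  mntd_samples(D, W, present, perm, out);
  return out;
}

// Per-sample null mean/sd of MNTD plus the count of null values <= observed
// (for the permutation quantile p).
// [[Rcpp::export(name = ".cpp_mntd_null")]]
List cpp_mntd_null(const arma::mat& D, const arma::mat& W, const arma::umat& P) {
  const arma::uword N = W.n_rows;
  const arma::uword R = P.n_rows;
  std::vector< std::vector<arma::uword> > present = presence_lists(W);
  arma::uvec perm = arma::regspace<arma::uvec>(0, D.n_rows - 1);
  arma::vec obs(N);
  mntd_samples(D, W, present, perm, obs);
  arma::vec mean(N, arma::fill::zeros), m2(N, arma::fill::zeros);
  arma::vec cnt_le(N, arma::fill::zeros), cur(N);
  for (arma::uword r = 0; r < R; ++r) {
    arma::uvec pr = P.row(r).t();
    mntd_samples(D, W, present, pr, cur);
    arma::vec delta = cur - mean;
    mean += delta / double(r + 1);
    m2 += delta % (cur - mean);
    cnt_le += arma::conv_to<arma::vec>::from(cur <= obs);
  }
  arma::vec sd = arma::sqrt(m2 / double(R - 1));
  return List::create(_["obs"] = obs, _["mean"] = mean, _["sd"] = sd,
                      _["count_le"] = cnt_le);
}
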