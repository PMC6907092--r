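// Branch-and-bound search for the feature subset maximizing the Mahalanobis
// class-separability criterion J(S) = d_S' * Sigma_S^{-1} * d_S, where d is
// the class-mean difference and Sigma the pooled within-class covariance.
// J is monotone non-increasing under feature deletion, so any node whose
// criterion does not exceed the incumbent can be pruned together with its
// whole subtree while preserving global optimality.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

static long long g_nodes;

static double crit(const arma::mat& S, const arma::vec& d,
                   const std::vector<int>& idx) {
  arma::uvec u(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) u[i] = idx[i];
  arma::mat Ss = S.submat(u, u);
  arma::vec ds = d.elem(u);
  arma::vec x;
  if (!arma::solve(x, Ss, ds, arma::solve_opts::no_approx)) {
    Rcpp::stop("Singular covariance submatrix in branch-and-bound; "
               "increase the ridge.");
  }
  ++g_nodes;
  return arma::dot(ds, x);
}

static std::vector<int> without(const std::vector<int>& cur, int f) {
  std::vector<int> out;
  out.reserve(cur.size() - 1);
  for (int v : cur) if (v != f) out.push_back(v);
  return out;
}

struct Best {
  double J = -1.0;
  std::vector<int> sel;
};

// cur: current feature set; avail: features still allowed to be removed in
// this subtree (a subset of cur, in a fixed order that guarantees each
// combination of removals is enumerated exactly once).
static void bb_rec(const arma::mat& S, const arma::vec& d, int target,
                   const std::vector<int>& cur,
                   const std::vector<int>& avail, Best& best) {
  int need = static_cast<int>(cur.size()) - target;
  if (need == 0) return;  // leaf handled by caller

  const int k = static_cast<int>(avail.size());
  std::vector<double> J(k);
  std::vector<int> ord(k);
  for (int i = 0; i < k; ++i) {
    J[i] = crit(S, d, without(cur, avail[i]));
    ord[i] = i;
  }
  // explore children in ascending criterion order: low-J children (largest
  // remaining subtrees) are pruned against the incumbent first
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return J[a] < J[b]; });

  // child i keeps only the later-ordered features removable; it must retain
  // at least need-1 of them
  for (int pos = 0; pos <= k - need; ++pos) {
    int i = ord[pos];
    if (J[i] <= best.J) continue;  // bound: no subset of this child can win
    std::vector<int> child = without(cur, avail[i]);
    if (need == 1) {
      best.J = J[i];
      best.sel = child;
      continue;
    }
    std::vector<int> child_avail;
    child_avail.reserve(k - pos - 1);
    for (int q = pos + 1; q < k; ++q) child_avail.push_back(avail[ord[q]]);
    bb_rec(S, d, target, child, child_avail, best);
  }
}

// [[Rcpp::export]]
Rcpp::List bb_search_cpp(const arma::mat& S, const arma::vec& d, int target) {
  const int p = S.n_rows;
  if (target < 1 || target > p) Rcpp::stop("target size out of range");
  g_nodes = 0;

  std::vector<int> full(p);
  for (int i = 0; i < p; ++i) full[i] = i;

  Best best;
  if (target == p) {
    best.J = crit(S, d, full);
    best.sel = full;
  } else {
    // greedy backward-elimination incumbent to tighten the bound early
    std::vector<int> cur = full;
    while (static_cast<int>(cur.size()) > target) {
      double bestJ = -1.0;
      int bestF = cur[0];
      for (int f : cur) {
        double Jf = crit(S, d, without(cur, f));
        if (Jf > bestJ) { bestJ = Jf; bestF = f; }
      }
      cur = without(cur, bestF);
    }
    best.J = crit(S, d, cur);
    best.sel = cur;

    bb_rec(S, d, target, full, full, best);
  }

  std::sort(best.sel.begin(), best.sel.end());
  Rcpp::IntegerVector sel(best.sel.begin(), best.sel.end());
  return Rcpp::List::create(
    Rcpp::Named("selected") = sel + 1,
    Rcpp::Named("criterion") = best.J,
    Rcpp::Named("nodes") = static_cast<double>(g_nodes)
  );
}
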