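// Generalized Louvain for an arbitrary symmetric quality matrix B.
// Objective: sum over all node pairs (i, j) in the same community of B(i, j)
// (diagonal included).  Two phases repeated until no improvement: greedy
// single-node moves over a randomly shuffled sweep order, then aggregation of
// B by summing community blocks.  Randomness comes from R's RNG so set.seed()
// in R makes runs reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One move phase on the current (possibly aggregated) matrix.  memb holds
// 0-based community labels in [0, n).  A move is accepted only if its gain
// exceeds tol; ties keep the current community.  As in the classical Louvain
// procedure, candidate targets are the currently non-empty communities: the
// move phase never creates new communities.
static bool move_phase(const arma::mat& B, arma::ivec& memb, double tol) {
  const int n = B.n_rows;
  arma::vec s(n);
  arma::ivec csize(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) csize[memb[i]]++;
  bool any_move = false;
  bool moved = true;
  int guard = 0;
  while (moved) {
    moved = false;
    IntegerVector ord = sample(n, n, false);  // R RNG, values 1..n
    for (int k = 0; k < n; ++k) {
      const int i = ord[k] - 1;
      const int cur = memb[i];
      s.zeros();
      for (int j = 0; j < n; ++j) s[memb[j]] += B(i, j);
      const double s_cur = s[cur] - B(i, i);  // links to own community, i excluded
      int best = cur;
      double best_gain = tol;
      for (int c = 0; c < n; ++c) {
        if (csize[c] == 0 || c == cur) continue;
        const double g = 2.0 * (s[c] - s_cur);
        if (g > best_gain) { best_gain = g; best = c; }
      }
      if (best != cur) {
        csize[cur]--; csize[best]++;
        memb[i] = best;
        moved = true;
        any_move = true;
      }
    }
    if (++guard > 4 * n + 100) break;  // defensive; gain > tol forbids cycles
  }
  return any_move;
}

static double objective_of(const arma::mat& B, const arma::ivec& memb) {
  double obj = 0.0;
  const int n = B.n_rows;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (memb[i] == memb[j]) obj += B(i, j);
  return obj;
}

// [[Rcpp::export(name = ".louvain_dense")]]
List louvain_dense(const arma::mat& B0, double tol) {
  const int n0 = B0.n_rows;
  arma::mat B = B0;
  arma::ivec full = arma::regspace<arma::ivec>(0, n0 - 1);
  double prev_obj = objective_of(B0, full);  // singleton baseline
  int levels = 0;
  for (;;) {
    const int n = B.n_rows;
    arma::ivec memb = arma::regspace<arma::ivec>(0, n - 1);
    const bool improved = move_phase(B, memb, tol);
    // relabel to 0..c-1 in order of first appearance
    arma::ivec map(n); map.fill(-1);
    int c = 0;
    for (int i = 0; i < n; ++i) {
      if (map[memb[i]] < 0) map[memb[i]] = c++;
      memb[i] = map[memb[i]];
    }
    for (int i = 0; i < n0; ++i) full[i] = memb[full[i]];
    levels++;
    const double obj = objective_of(B, memb);
    if (obj < prev_obj - 1e-9) stop("internal error: Louvain objective decreased");
    prev_obj = obj;
    if (!improved || c == n) break;
    // aggregate: B' = S' B S
    arma::mat Bagg(c, c, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Bagg(memb[i], memb[j]) += B(i, j);
    B = Bagg;
  }
  return List::create(_["membership"] = IntegerVector(full.begin(), full.end()),
                      _["objective"] = prev_obj,
                      _["levels"] = levels);
}
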