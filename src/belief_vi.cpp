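// Belief-state value iteration for the nest-restriction MDP.
//
// State: (S, B) with S the occupied-site count and B a point on the
// 3-model belief simplex grid.  Observations are pre-compressed into
// classes (see .compress_kernels): class c under pair p = (S, A) has
// per-model mass w_c (so P_B(c) = B . w_c and the posterior is
// B * w_c renormalized) and a model-independent conditional distribution
// over S_next stored as row qid_c of Qu.  The Bellman backup is
//   Q(S,A,B) = R(S,A,B) + delta * sum_c (B.w_c) * sum_k omega_k V(., g_k)
// where the inner sum interpolates the S_next-averaged value surface
// Vt = Qu * V at the posterior belief (Kuhn-triangulation barycentric
// weights).  Modified policy iteration: greedy sweeps with fixed-policy
// evaluation sweeps in between; starting from V = 0 with nonnegative
// rewards the iterates increase monotonically toward the fixed point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// index of lattice point (i, j) in the belief_grid ordering (0-based)
static inline int grid_index(int m, int i, int j) {
  return i * (m + 1) - (i * (i - 1)) / 2 + j;
}

// barycentric interpolation of row `row` of Vt at belief (b1, b2)
static inline double interp_value(const arma::mat& Vt, int row,
                                  double b1, double b2, int m) {
  double f1 = b1 * m, f2 = b2 * m;
  if (f1 < 0) f1 = 0;
  if (f2 < 0) f2 = 0;
  if (f1 > m) f1 = m;
  if (f2 > m - f1) f2 = m - f1;
  int i = (int)std::floor(f1);
  if (i > m - 1) i = m - 1;
  int j = (int)std::floor(f2);
  int jmax = m - 1 - i;
  if (jmax < 0) jmax = 0;
  if (j > jmax) j = jmax;
  double r1 = f1 - i, r2 = f2 - j;
  if (r1 + r2 <= 1.0) {
    return (1.0 - r1 - r2) * Vt(row, grid_index(m, i, j)) +
           r1 * Vt(row, grid_index(m, i + 1, j)) +
           r2 * Vt(row, grid_index(m, i, j + 1));
  }
  return (r1 + r2 - 1.0) * Vt(row, grid_index(m, i + 1, j + 1)) +
         (1.0 - r1) * Vt(row, grid_index(m, i, j + 1)) +
         (1.0 - r2) * Vt(row, grid_index(m, i + 1, j));
}

// expected continuation value of pair p at grid point j under belief B
static inline double continuation(int p, double B1, double B2, double B3,
                                  const IntegerVector& pair_start,
                                  const arma::mat& W,
                                  const IntegerVector& qid,
                                  const arma::mat& Vt, int m) {
  double acc = 0.0;
  for (int c = pair_start[p]; c < pair_start[p + 1]; ++c) {
    double w1 = B1 * W(c, 0), w2 = B2 * W(c, 1), w3 = B3 * W(c, 2);
    double pb = w1 + w2 + w3;
    if (pb <= 0) continue;
    acc += pb * interp_value(Vt, qid[c], w1 / pb, w2 / pb, m);
  }
  return acc;
}

// [[Rcpp::export]]
List belief_vi(IntegerVector pair_S, IntegerVector pair_A,
               IntegerVector pair_start, arma::mat class_w,
               IntegerVector class_qid, arma::mat Qu, arma::mat Rmat,
               arma::mat grid_pts, int grid_order, double discount,
               double tol, int max_iter, int eval_sweeps) {
  const int P = pair_S.size();
  const int N = pair_S[P - 1];
  const int nS = N + 1;
  const int ng = grid_pts.n_rows;
  const int m = grid_order;

  arma::mat V(nS, ng, arma::fill::zeros);
  arma::imat pol(nS, ng, arma::fill::zeros);

  // pairs grouped by S: pair index of (S, A) is S(S+1)/2 + A
  double delta = R_PosInf;
  int iter = 0;
  std::vector<double> deltas;
  while (iter < max_iter) {
    ++iter;
    arma::mat Vt = Qu * V;
    double d = 0.0;
    for (int j = 0; j < ng; ++j) {
      double B1 = grid_pts(j, 0), B2 = grid_pts(j, 1), B3 = grid_pts(j, 2);
      for (int S = 0; S <= N; ++S) {
        double best = -1.0;
        int best_a = 0;
        for (int A = 0; A <= S; ++A) {
          int p = (S * (S + 1)) / 2 + A;
          double q = Rmat(p, j) + discount *
            continuation(p, B1, B2, B3, pair_start, class_w, class_qid,
                         Vt, m);
          // strict improvement beyond a tiny relative slack keeps ties on
          // the least restrictive action
          if (q > best + 1e-9 * (1.0 + std::abs(best))) {
            best = q;
            best_a = A;
          }
        }
        double diff = std::abs(best - V(S, j));
        if (diff > d) d = diff;
        V(S, j) = best;
        pol(S, j) = best_a;
      }
    }
    delta = d;
    deltas.push_back(d);
    if (delta < tol) break;
    for (int e = 0; e < eval_sweeps; ++e) {
      arma::mat Vte = Qu * V;
      for (int j = 0; j < ng; ++j) {
        double B1 = grid_pts(j, 0), B2 = grid_pts(j, 1), B3 = grid_pts(j, 2);
        for (int S = 0; S <= N; ++S) {
          int A = pol(S, j);
          int p = (S * (S + 1)) / 2 + A;
          V(S, j) = Rmat(p, j) + discount *
            continuation(p, B1, B2, B3, pair_start, class_w, class_qid,
                         Vte, m);
        }
      }
    }
    if (iter % 10 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["value"] = V, _["policy"] = pol,
                      _["iterations"] = iter, _["residual"] = delta,
                      _["residual_trace"] = deltas);
}
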