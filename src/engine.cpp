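#include <Rcpp.h>
using namespace Rcpp;

// Draw a neighbour of node i from the CSR cumulative-weight table.
static inline int draw_neighbor(int i, const IntegerVector& ptr,
                                const IntegerVector& idx,
                                const NumericVector& cw) {
  double u = unif_rand();
  int lo = ptr[i], hi = ptr[i + 1];
  for (int k = lo; k < hi - 1; ++k)
    if (u <= cw[k]) return idx[k];
  return idx[hi - 1];
}

// Random-walk Monte Carlo oracle for the stationary public-goods field.
// Each particle is utilized w.p. 1/(1+d+lambda), decays w.p. d/(1+d+lambda),
// otherwise steps along an edge. Returns raw utilization counts per node.
// [[Rcpp::export]]
NumericVector rw_field_cpp(IntegerVector ptr, IntegerVector idx,
                           NumericVector cw, IntegerVector producers,
                           double lambda, double decay, int n_particles,
                           int n_nodes) {
  NumericVector counts(n_nodes);
  const double denom = 1.0 + decay + lambda;
  const double p_util = 1.0 / denom;
  const double p_gone = (1.0 + decay) / denom;  // utilized or decayed
  for (int p = 0; p < producers.size(); ++p) {
    for (int t = 0; t < n_particles; ++t) {
      int node = producers[p];
      for (;;) {
        double u = unif_rand();
        if (u < p_util) { counts[node] += 1.0; break; }
        if (u < p_gone) break;  // decayed / escaped
        node = draw_neighbor(node, ptr, idx, cw);
      }
    }
  }
  return counts;
}

// Death-Birth fixation trials for one mutant type.
//
// State: s[i] in {0,1}; psi maintained incrementally via columns of the
// influence matrix M (psi = M s). Each step: a uniformly random cell dies;
// neighbours compete for the vacancy with probability proportional to
// fecundity (1 + b*psi - c*s) times edge weight. A trial ends when the
// population is homogeneous; trials exceeding max_steps are counted
// separately, never silently dropped.
//
// Returns: [fixations, completed_trials, overran_trials, total_steps].
// [[Rcpp::export]]
NumericVector db_fixation_cpp(IntegerVector ptr, IntegerVector idx,
                              NumericVector w, NumericMatrix M,
                              NumericVector m_rowsum, double b, double c,
                              bool mutant_coop, int trials,
                              double max_steps) {
  const int n = M.nrow();
  std::vector<int> s(n);
  std::vector<double> psi(n), fw(64);
  double fixations = 0, completed = 0, overran = 0, total_steps = 0;

  for (int tr = 0; tr < trials; ++tr) {
    int start = (int)(unif_rand() * n);
    if (start == n) start = n - 1;
    int ncoop;
    if (mutant_coop) {
      std::fill(s.begin(), s.end(), 0);
      s[start] = 1;
      ncoop = 1;
      for (int i = 0; i < n; ++i) psi[i] = M(i, start);
    } else {
      std::fill(s.begin(), s.end(), 1);
      s[start] = 0;
      ncoop = n - 1;
      for (int i = 0; i < n; ++i) psi[i] = m_rowsum[i] - M(i, start);
    }
    double steps = 0;
    bool done = false;
    while (!done) {
      if (steps >= max_steps) { overran += 1; break; }
      steps += 1;
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      int lo = ptr[i], hi = ptr[i + 1], deg = hi - lo;
      if ((int)fw.size() < deg) fw.resize(deg);
      double tot = 0;
      for (int k = 0; k < deg; ++k) {
        int j = idx[lo + k];
        tot += w[lo + k] * (1.0 + b * psi[j] - c * s[j]);
        fw[k] = tot;
      }
      double u = unif_rand() * tot;
      int pick = deg - 1;
      for (int k = 0; k < deg - 1; ++k)
        if (u <= fw[k]) { pick = k; break; }
      int j = idx[lo + pick];
      if (s[j] != s[i]) {
        if (s[j] == 1) {
          s[i] = 1; ++ncoop;
          for (int q = 0; q < n; ++q) psi[q] += M(q, i);
        } else {
          s[i] = 0; --ncoop;
          for (int q = 0; q < n; ++q) psi[q] -= M(q, i);
        }
        if (ncoop == 0 || ncoop == n) {
          completed += 1;
          bool mutant_fixed = mutant_coop ? (ncoop == n) : (ncoop == 0);
          if (mutant_fixed) fixations += 1;
          done = true;
        }
      }
    }
    total_steps += steps;
  }
  return NumericVector::create(fixations, completed, overran, total_steps);
}
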