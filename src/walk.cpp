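#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo walkers. All randomness comes from R's RNG (unif_rand), so
// set.seed() in R governs reproducibility bit-for-bit.

static inline int rand_int(int n) {
  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Moran fixation probability, relative fitness r, population size N
static inline double moran_rho(double r, int N) {
  if (N == 1) return 1.0;
  double lr = std::log(r);
  if (std::fabs(lr) < 1e-12) return 1.0 / N;
  return std::expm1(-lr) / std::expm1(-N * lr);
}

// Evolutionary random walk in the full sequence space with m target centers.
// seqs: n x L matrix of start sequences (0-based letter codes); centers:
// m x L. Fitness depends only on the minimal Hamming distance to a center,
// through fit_by_d (length L+1). A proposal is accepted with min(1, N*rho);
// every proposal counts as one event. Discovery convention: if
// discovery_on_proposal, proposing a target sequence ends the walk even if
// the mutant would not have fixed.
// [[Rcpp::export]]
List walk_full_batch_cpp(IntegerMatrix starts, IntegerMatrix centers,
                         int A, int w, NumericVector fit_by_d, double N,
                         double budget, bool discovery_on_proposal) {
  const int n = starts.nrow(), L = starts.ncol(), m = centers.nrow();
  const int Npop = (int)N;
  LogicalVector hit(n);
  NumericVector steps(n);
  IntegerVector final_d(n);
  std::vector<int> seq(L), dist(m);

  for (int run = 0; run < n; ++run) {
    for (int j = 0; j < L; ++j) seq[j] = starts(run, j);
    int dmin = L + 1;
    for (int c = 0; c < m; ++c) {
      int d = 0;
      for (int j = 0; j < L; ++j) d += (seq[j] != centers(c, j));
      dist[c] = d;
      if (d < dmin) dmin = d;
    }
    double step = 0.0;
    bool ok = dmin <= w;
    while (!ok && step < budget) {
      step += 1.0;
      int pos = rand_int(L);
      int old = seq[pos];
      int nl = rand_int(A - 1);
      if (nl >= old) ++nl; // uniform over the A-1 other letters
      // proposed distances
      int dmin_new = L + 1;
      for (int c = 0; c < m; ++c) {
        int d = dist[c];
        int cl = centers(c, pos);
        if (old == cl) ++d;
        else if (nl == cl) --d;
        if (d < dmin_new) dmin_new = d;
      }
      if (discovery_on_proposal && dmin_new <= w) {
        // the proposed mutant is a target sequence: discovered
        for (int c = 0; c < m; ++c) {
          int cl = centers(c, pos);
          if (old == cl) ++dist[c];
          else if (nl == cl) --dist[c];
        }
        seq[pos] = nl;
        dmin = dmin_new;
        ok = true;
        break;
      }
      double fcur = fit_by_d[dmin], fnew = fit_by_d[dmin_new];
      double acc = 1.0;
      if (fnew != fcur) {
        acc = N * moran_rho(fnew / fcur, Npop);
        if (acc > 1.0) acc = 1.0;
      }
      if (acc >= 1.0 || unif_rand() < acc) {
        for (int c = 0; c < m; ++c) {
          int cl = centers(c, pos);
          if (old == cl) ++dist[c];
          else if (nl == cl) --dist[c];
        }
        seq[pos] = nl;
        dmin = dmin_new;
        if (dmin <= w) ok = true;
      }
    }
    hit[run] = ok;
    steps[run] = step;
    final_d[run] = dmin;
  }
  return List::create(_["hit"] = hit, _["steps"] = steps,
                      _["final_distance"] = final_d);
}

// Direct simulation of the projected birth-death chain. p_down/p_stay/p_up
// have length L+1 (states 0..L); states <= w absorb.
// [[Rcpp::export]]
List chain_sim_batch_cpp(NumericVector p_down, NumericVector p_stay,
                         NumericVector p_up, int w, IntegerVector start,
                         double budget, int n) {
  const int L = p_down.size() - 1;
  LogicalVector hit(n);
  NumericVector steps(n);
  IntegerVector final_k(n);
  for (int run = 0; run < n; ++run) {
    int k = start[start.size() == 1 ? 0 : run];
    double step = 0.0;
    bool ok = k <= w;
    while (!ok && step < budget) {
      step += 1.0;
      double u = unif_rand();
      if (u < p_down[k]) --k;
      else if (u >= p_down[k] + p_stay[k]) { if (k < L) ++k; }
      if (k <= w) ok = true;
    }
    hit[run] = ok;
    steps[run] = step;
    final_k[run] = k;
  }
  return List::create(_["hit"] = hit, _["steps"] = steps,
                      _["final_distance"] = final_k);
}
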