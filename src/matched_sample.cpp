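#include <Rcpp.h>
using namespace Rcpp;

// Distance of a running mean to the target interval (0 inside).
static inline double band_dist(double m, double lo, double hi) {
  if (m < lo) return lo - m;
  if (m > hi) return m - hi;
  return 0.0;
}

// Uniform draw of a position in [0, n).
static inline int draw_pos(int n) {
  int j = (int)(unif_rand() * n);
  if (j >= n) j = n - 1;
  return j;
}

// Staged dN-matched sampling without replacement.
//
// Draws `size` distinct indices from `dn` so that the sample mean dN ends
// inside [dn_inf, dn_sup]:
//  * the first `initial_free` slots are unconditional uniform draws;
//  * thereafter every `x_period`-th accepted member (counting after the
//    free draws) is unconditional;
//  * all other slots repeat candidate draws, accepting one only if the
//    resulting running mean is inside the interval or strictly closer to
//    it than the current running mean (progress rule), up to `max_tries`;
//  * if the final mean is outside the interval, the most deviant
//    unconditionally-drawn member is swapped for a constrained replacement
//    until the mean re-enters.
//
// Uses R's RNG (so set.seed() governs reproducibility). Returns 1-based
// indices plus a flag marking which members were unconditional draws.
// [[Rcpp::export]]
List sample_matched_cpp(NumericVector dn, int size, double dn_inf,
                        double dn_sup, int initial_free, int x_period,
                        int max_tries) {
  int n = dn.size();
  if (size > n) stop("sample size exceeds pool size");
  if (x_period < 1) stop("x_period must be >= 1");

  // avail holds pool positions not yet selected (swap-remove on pick)
  std::vector<int> avail(n);
  for (int i = 0; i < n; ++i) avail[i] = i;
  int n_avail = n;

  std::vector<int> sel;
  std::vector<bool> freed;  // was this member an unconditional draw?
  sel.reserve(size);
  freed.reserve(size);
  double sum = 0.0;

  auto take = [&](int pos, bool is_free) {
    int idx = avail[pos];
    avail[pos] = avail[--n_avail];
    sel.push_back(idx);
    freed.push_back(is_free);
    sum += dn[idx];
  };

  for (int k = 0; k < size; ++k) {
    bool unconditional = (k < initial_free) ||
      (((k - initial_free + 1) % x_period) == 0);
    if (unconditional) {
      take(draw_pos(n_avail), true);
      continue;
    }
    // with no prior members any candidate is progress
    double cur_d = (k == 0) ? R_PosInf
                            : band_dist(sum / k, dn_inf, dn_sup);
    bool accepted = false;
    for (int t = 0; t < max_tries; ++t) {
      int pos = draw_pos(n_avail);
      double cand_mean = (sum + dn[avail[pos]]) / (k + 1);
      double cand_d = band_dist(cand_mean, dn_inf, dn_sup);
      if (cand_d == 0.0 || cand_d < cur_d) {
        take(pos, false);
        accepted = true;
        break;
      }
    }
    if (!accepted)
      stop("matched sampling stalled at slot %d: no candidate improved the "
           "running mean toward [%g, %g] within %d tries",
           k + 1, dn_inf, dn_sup, max_tries);
  }

  // Final fix-up: swap out deviant unconditional members until the sample
  // mean re-enters the interval.
  int guard = 0;
  while (band_dist(sum / size, dn_inf, dn_sup) > 0.0) {
    if (++guard > size + max_tries)
      stop("matched sampling could not restore the sample mean into "
           "[%g, %g] (pool mean %g)", dn_inf, dn_sup,
           mean(NumericVector(dn)));
    double m = sum / size;
    bool too_high = m > dn_sup;
    // pool extremes bound what a swap can achieve
    double amax = R_NegInf, amin = R_PosInf;
    for (int i = 0; i < n_avail; ++i) {
      double v = dn[avail[i]];
      if (v > amax) amax = v;
      if (v < amin) amin = v;
    }
    // most deviant member, preferring unconditionally drawn ones, but a
    // free member is only eligible if replacing it can still improve the
    // mean (otherwise fall back to the globally most deviant member)
    int worst = -1;
    double worst_val = 0.0;
    for (int pass = 0; pass < 2 && worst < 0; ++pass) {
      for (int i = 0; i < size; ++i) {
        if (pass == 0 && !freed[i]) continue;
        double v = dn[sel[i]];
        if (worst < 0 || (too_high ? v > worst_val : v < worst_val)) {
          worst = i;
          worst_val = v;
        }
      }
      if (worst >= 0) {
        bool can_improve = too_high ? (amin < worst_val)
                                    : (amax > worst_val);
        if (!can_improve && pass == 0) worst = -1;  // retry over everyone
      }
    }
    if (worst < 0 ||
        (too_high ? !(amin < dn[sel[worst]]) : !(amax > dn[sel[worst]])))
      stop("matched sampling cannot reach [%g, %g]: pool exhausted "
           "(sample mean %g, pool extremes [%g, %g])",
           dn_inf, dn_sup, m, amin, amax);
    double base = sum - dn[sel[worst]];
    double cur_d = band_dist(sum / size, dn_inf, dn_sup);
    bool swapped = false;
    for (int t = 0; t < max_tries; ++t) {
      int pos = draw_pos(n_avail);
      double cand_mean = (base + dn[avail[pos]]) / size;
      double cand_d = band_dist(cand_mean, dn_inf, dn_sup);
      if (cand_d == 0.0 || cand_d < cur_d) {
        int removed = sel[worst];
        int idx = avail[pos];
        avail[pos] = removed;  // swapped-out member returns to the pool
        sel[worst] = idx;
        freed[worst] = false;
        sum = base + dn[idx];
        swapped = true;
        break;
      }
    }
    if (!swapped)
      stop("matched sampling fix-up exhausted %d tries for interval "
           "[%g, %g] (sample mean %g, pool range [%g, %g])",
           max_tries, dn_inf, dn_sup, sum / size, amin, amax);
  }

  IntegerVector out(size);
  LogicalVector fr(size);
  for (int i = 0; i < size; ++i) {
    out[i] = sel[i] + 1;
    fr[i] = freed[i];
  }
  return List::create(_["idx"] = out, _["free"] = fr);
}
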