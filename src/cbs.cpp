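// Circular binary segmentation kernel.
//
// A segment x[0..n) is circularized; every arc (i, j] (0 <= i < j <= n,
// excluding the full circle) splits it into the arc and its complement.
// The split statistic is the pooled two-sample t between the two groups;
// the best split maximizes |t| subject to minimum-width constraints.
//
// Key algebraic fact exploited below: with prefix sums S and Q of the
// values and their squares, the within-group sum of squares of a split is
//   ssw = Q[n] - sa^2/k - (S[n]-sa)^2/(n-k),
// a function of the arc sum sa and arc length k only (the arc's own sum of
// squares cancels).  For fixed k, |t| is monotone in |sa - k*S[n]/n|, so
// only the extreme sliding-window sums per arc length need a t evaluation:
// the scan is O(n^2) index updates but O(n) t evaluations.
//
// Significance is assessed by permutation: the observed max |t| is compared
// with the max |t| of shuffled copies.  Permutations stop early once the
// exceedance count makes p >= alpha certain, and each permutation scan
// stops at its first exceedance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct BestSplit {
  double t = 0.0;
  int i = -1;
  int j = -1;
};

inline double split_t(double sa, int k, double S, double Q, int n) {
  const int m = n - k;
  const double eps = 1e-12;
  const double ma = sa / k, mb = (S - sa) / m;
  const double ssw = Q - sa * sa / k - (S - sa) * (S - sa) / m;
  if (ssw <= eps)
    return (std::fabs(ma - mb) <= eps)
               ? 0.0
               : std::numeric_limits<double>::infinity();
  return std::fabs(ma - mb) /
         std::sqrt(ssw / (n - 2) * (1.0 / k + 1.0 / m));
}

// Max |t| over all admissible arcs of x.  min_w constrains the arc, its
// complement, and every non-empty linear piece the split would create.
// If stop_at > 0, return as soon as a t >= stop_at is seen (permutation
// scans only need exceedance, not the argmax).
BestSplit max_arc_t(const std::vector<double>& x, int min_w,
                    double stop_at = -1.0) {
  const int n = (int)x.size();
  BestSplit best;
  if (n < 2 * min_w) return best;
  std::vector<double> S(n + 1, 0.0);
  double Q = 0.0;
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    Q += x[k] * x[k];
  }
  const double Sn = S[n];
  for (int k = min_w; k <= n - min_w; ++k) {
    // admissible arc starts: i = 0, i in [min_w, n-k-min_w], i = n-k
    double sa_max = -std::numeric_limits<double>::infinity();
    double sa_min = std::numeric_limits<double>::infinity();
    int i_max = -1, i_min = -1;
    auto consider = [&](int i) {
      const double sa = S[i + k] - S[i];
      if (sa > sa_max) { sa_max = sa; i_max = i; }
      if (sa < sa_min) { sa_min = sa; i_min = i; }
    };
    consider(0);
    consider(n - k);
    const int hi = n - k - min_w;
    for (int i = min_w; i <= hi; ++i) consider(i);
    for (int side = 0; side < 2; ++side) {
      const double sa = side ? sa_min : sa_max;
      const int i = side ? i_min : i_max;
      const double t = split_t(sa, k, Sn, Q, n);
      if (t > best.t) {
        best.t = t;
        best.i = i;
        best.j = i + k;
        if (stop_at > 0 && t >= stop_at) return best;
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".cbs_best_split")]]
List cbs_best_split(NumericVector x, int min_width) {
  std::vector<double> v(x.begin(), x.end());
  BestSplit b = max_arc_t(v, min_width);
  return List::create(_["t"] = b.t, _["i"] = b.i, _["j"] = b.j);
}

// Permutation p-value for an observed max |t|.  Uses R's RNG so results
// are reproducible under set.seed().
//
// Shuffling leaves the total sum S and total sum of squares Q unchanged,
// and ssw = ssw0 - u^2 * c with ssw0 = Q - S^2/n, u = sa - k*S/n and
// c = 1/k + 1/(n-k).  Hence t >= obs_t is equivalent to |u| >= u_crit(k)
// with u_crit(k)^2 = obs_t^2 * ssw0 / (c * (n - 2 + obs_t^2)), which is
// precomputed once: each permutation scan is a cheap window-sum compare
// that stops at its first exceedance.  Early termination: once the
// exceedance count reaches ceil(alpha * (nperm + 1)), p >= alpha is
// certain and the split can be rejected without further shuffles.
// [[Rcpp::export(name = ".cbs_perm_pvalue")]]
double cbs_perm_pvalue(NumericVector x, double obs_t, int nperm,
                       double alpha, int min_width) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  const int stop_count = (int)std::ceil(alpha * (nperm + 1));
  int exceed = 0;
  int done = 0;

  double Sn = 0.0, Q = 0.0;
  for (int k = 0; k < n; ++k) {
    Sn += v[k];
    Q += v[k] * v[k];
  }
  const double ssw0 = Q - Sn * Sn / n;
  std::vector<double> ucrit(n + 1, 0.0);
  for (int k = min_width; k <= n - min_width; ++k) {
    const double c = 1.0 / k + 1.0 / (n - k);
    double u2;
    if (std::isinf(obs_t)) {
      u2 = ssw0 / c;  // t = inf <=> ssw = 0
    } else {
      u2 = obs_t * obs_t * ssw0 / (c * (n - 2 + obs_t * obs_t));
    }
    // shave an epsilon so t == obs_t counts as an exceedance
    ucrit[k] = std::sqrt(std::max(u2, 0.0)) * (1.0 - 1e-12);
  }

  std::vector<double> S(n + 1, 0.0);
  RNGScope scope;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int k = n - 1; k > 0; --k) {
      int r = (int)(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(v[k], v[r]);
    }
    for (int k = 0; k < n; ++k) S[k + 1] = S[k] + v[k];
    bool hit = false;
    for (int k = min_width; k <= n - min_width && !hit; ++k) {
      const double mu = k * Sn / n;
      const double uc = ucrit[k];
      auto check = [&](int i) {
        return std::fabs(S[i + k] - S[i] - mu) >= uc;
      };
      if (check(0) || check(n - k)) {
        hit = true;
        break;
      }
      const int hi = n - k - min_width;
      for (int i = min_width; i <= hi; ++i) {
        if (check(i)) {
          hit = true;
          break;
        }
      }
    }
    ++done;
    if (hit) {
      ++exceed;
      if (exceed >= stop_count) break;
    }
  }
  // conservative add-one estimator
  return (1.0 + exceed) / (1.0 + (exceed >= stop_count ? done : nperm));
}
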