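#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mann-Whitney U statistic for x vs sorted y:
// U = #{(i,j): x_i > y_j} + 0.5 * #{(i,j): x_i == y_j}
static double u_stat_sorted(const std::vector<double>& x,
                            const std::vector<double>& ysort) {
  double U = 0.0;
  for (double xi : x) {
    std::vector<double>::const_iterator lo =
      std::lower_bound(ysort.begin(), ysort.end(), xi);
    std::vector<double>::const_iterator hi =
      std::upper_bound(ysort.begin(), ysort.end(), xi);
    U += (double)(lo - ysort.begin()) + 0.5 * (double)(hi - lo);
  }
  return U;
}

// sum over tie groups of (t^3 - t) for the pooled sample (both inputs sorted)
static double tie_term_merged(const std::vector<double>& a,
                              const std::vector<double>& b) {
  double term = 0.0;
  size_t i = 0, j = 0;
  bool have = false;
  double cur = 0.0;
  double run = 0.0;
  while (i < a.size() || j < b.size()) {
    double v;
    if (j >= b.size() || (i < a.size() && a[i] <= b[j])) v = a[i++];
    else v = b[j++];
    if (have && v == cur) {
      run += 1.0;
    } else {
      if (have) term += run * run * run - run;
      cur = v; run = 1.0; have = true;
    }
  }
  if (have) term += run * run * run - run;
  return term;
}

// two-sided p via normal approximation with tie correction and
// continuity correction (matches wilcox.test(correct = TRUE) conventions)
static double p_normal(double U, double n1, double n2, double tie_term) {
  double n = n1 + n2;
  double mu = n1 * n2 / 2.0;
  double sig2 = (n1 * n2 / 12.0) * ((n + 1.0) - tie_term / (n * (n - 1.0)));
  if (sig2 <= 0.0) return 1.0;
  double z = std::fabs(U - mu) - 0.5;
  if (z < 0.0) z = 0.0;
  z /= std::sqrt(sig2);
  double p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
  return p > 1.0 ? 1.0 : p;
}

// exact two-sided p: P(|U - n1*n2/2| >= |U_obs - n1*n2/2|) over all
// C(n1+n2, n1) assignments of the pooled values to the first sample
static double p_exact(const std::vector<double>& x,
                      const std::vector<double>& y, double Uobs) {
  int n1 = (int)x.size(), n2 = (int)y.size(), n = n1 + n2;
  std::vector<double> pool;
  pool.reserve(n);
  pool.insert(pool.end(), x.begin(), x.end());
  pool.insert(pool.end(), y.begin(), y.end());
  double mu = (double)n1 * (double)n2 / 2.0;
  double dev = std::fabs(Uobs - mu) - 1e-9;
  std::vector<int> idx(n1);
  for (int i = 0; i < n1; ++i) idx[i] = i;
  double hits = 0.0, total = 0.0;
  std::vector<char> in(n);
  for (;;) {
    std::fill(in.begin(), in.end(), 0);
    for (int i = 0; i < n1; ++i) in[idx[i]] = 1;
    double U = 0.0;
    for (int a = 0; a < n; ++a) {
      if (!in[a]) continue;
      for (int b = 0; b < n; ++b) {
        if (in[b]) continue;
        if (pool[a] > pool[b]) U += 1.0;
        else if (pool[a] == pool[b]) U += 0.5;
      }
    }
    total += 1.0;
    if (std::fabs(U - mu) >= dev) hits += 1.0;
    // next lexicographic combination
    int k = n1 - 1;
    while (k >= 0 && idx[k] == n - n1 + k) --k;
    if (k < 0) break;
    ++idx[k];
    for (int i = k + 1; i < n1; ++i) idx[i] = idx[i - 1] + 1;
  }
  return hits / total;
}

// Monte-Carlo permutation p for a small sample vs a large one.
// Uses the identity U(S vs complement) = sum_{i in S} g_i - m(m-1)/2 where
// g_i = #{pool < v_i} + 0.5 * (#{pool == v_i} - 1), so each draw costs O(m^2)
// after a single O(n) pass. Sampling uses Floyd's algorithm on R's RNG.
// `Uobs` must be the U statistic of the smaller sample vs the larger.
static double p_mc(const std::vector<double>& small_sorted,
                   const std::vector<double>& large_sorted,
                   double Uobs, int B) {
  int m = (int)small_sorted.size();
  int n = m + (int)large_sorted.size();
  // merged sorted pool
  std::vector<double> pool(n);
  std::merge(small_sorted.begin(), small_sorted.end(),
             large_sorted.begin(), large_sorted.end(), pool.begin());
  std::vector<double> g(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && pool[j] == pool[i]) ++j; // tie run [i, j)
    double gv = (double)i + 0.5 * (double)(j - i - 1);
    for (int k = i; k < j; ++k) g[k] = gv;
    i = j;
  }
  double mu = (double)m * (double)(n - m) / 2.0;
  double half = (double)m * (m - 1) / 2.0;
  double dev = std::fabs(Uobs - mu) - 1e-9;
  int idx[64];
  double hits = 0.0;
  for (int b = 0; b < B; ++b) {
    // Floyd's sampling of m distinct indices in [0, n)
    int cnt = 0;
    for (int t = n - m; t < n; ++t) {
      int r = (int)(unif_rand() * (t + 1));
      if (r > t) r = t;
      bool dup = false;
      for (int k = 0; k < cnt; ++k) if (idx[k] == r) { dup = true; break; }
      idx[cnt++] = dup ? t : r;
    }
    double s = 0.0;
    for (int k = 0; k < cnt; ++k) s += g[idx[k]];
    double U = s - half;
    if (std::fabs(U - mu) >= dev) hits += 1.0;
  }
  return (1.0 + hits) / (double)(B + 1);
}

// route to exact enumeration (both samples small), Monte-Carlo permutation
// (one sample small) or tie-corrected normal approximation (both large);
// x and y must be sorted
static double mwu_p_sorted(const std::vector<double>& x,
                           const std::vector<double>& y,
                           int exact_max, int n_mc,
                           double* Uout, int* method) {
  double U = u_stat_sorted(x, y);
  if (Uout) *Uout = U;
  int n1 = (int)x.size(), n2 = (int)y.size();
  if (n1 <= exact_max && n2 <= exact_max) {
    if (method) *method = 0;
    return p_exact(x, y, U);
  }
  if (n1 <= exact_max || n2 <= exact_max) {
    if (method) *method = 1;
    if (n1 <= n2) return p_mc(x, y, U, n_mc);
    // symmetric: |U(y,x) - mu| == |U(x,y) - mu|
    return p_mc(y, x, (double)n1 * n2 - U, n_mc);
  }
  if (method) *method = 2;
  return p_normal(U, (double)n1, (double)n2, tie_term_merged(x, y));
}

// [[Rcpp::export]]
List mwu_cpp(NumericVector x, NumericVector y, int exact_max, int n_mc) {
  std::vector<double> xv = as<std::vector<double> >(x);
  std::vector<double> yv = as<std::vector<double> >(y);
  std::sort(xv.begin(), xv.end());
  std::sort(yv.begin(), yv.end());
  double U = NA_REAL;
  int method = -1;
  double p = mwu_p_sorted(xv, yv, exact_max, n_mc, &U, &method);
  const char* mnames[] = {"exact", "mc_permutation", "normal"};
  return List::create(_["statistic"] = U, _["p_value"] = p,
                      _["method"] = std::string(mnames[method]));
}

static void pair_intervals(const std::vector<double>& notes,
                           std::vector<double>& out) {
  out.clear();
  size_t N = notes.size();
  for (size_t i = 0; i + 1 < N; ++i)
    for (size_t j = i + 1; j < N; ++j)
      out.push_back(notes[j] - notes[i]);
}

// deviations |v - I| for sorted values v within [I - w, I + w], returned sorted
static void window_devs(const std::vector<double>& vsort, double I, double w,
                        std::vector<double>& out) {
  out.clear();
  std::vector<double>::const_iterator lo =
    std::lower_bound(vsort.begin(), vsort.end(), I - w);
  std::vector<double>::const_iterator hi =
    std::upper_bound(vsort.begin(), vsort.end(), I + w);
  std::vector<double>::const_iterator mid =
    std::lower_bound(lo, hi, I);
  // left of I: deviations descend as v ascends -> walk backwards
  std::vector<double> left;
  for (std::vector<double>::const_iterator it = lo; it != mid; ++it)
    left.push_back(I - *it);
  std::reverse(left.begin(), left.end());
  std::vector<double> right;
  for (std::vector<double>::const_iterator it = mid; it != hi; ++it)
    right.push_back(*it - I);
  out.resize(left.size() + right.size());
  std::merge(left.begin(), left.end(), right.begin(), right.end(),
             out.begin());
  // snap to a 1e-6 cent grid: block sums of the same steps taken in a
  // different order must stay exact ties despite floating-point rounding
  for (size_t i = 0; i < out.size(); ++i)
    out[i] = std::round(out[i] * 1e6) / 1e6;
}

// U of sample x against itself (self pairs count once via the 0.5 rule)
static double u_self(const std::vector<double>& x) {
  return u_stat_sorted(x, x);
}

// Within-scale interval significance for one scale across many target
// intervals. Per repeat, n_shuffle step-shuffled arrangements of the scale
// are generated; per target, each arrangement's windowed deviations are
// scored with the Mann-Whitney AUC (normalized U) against the pooled
// deviations of the other arrangements. Under the null the original
// arrangement is exchangeable with its shuffles, so the two-sided p-value
// is the permutation rank of the original's AUC extremity |AUC - 0.5|
// among the shuffles'. p-values are averaged over repeats.
// Uses R's RNG (seed with set.seed before calling).
// [[Rcpp::export]]
List sweep_scale_cpp(NumericVector notes, NumericVector targets,
                     double window, int n_shuffle, int n_repeat) {
  int nt = targets.size();
  std::vector<double> nv = as<std::vector<double> >(notes);
  int N = (int)nv.size();
  std::vector<double> steps(N - 1);
  for (int i = 0; i < N - 1; ++i) steps[i] = nv[i + 1] - nv[i];

  // arrangement 0 is the original, rebuilt from its steps through the same
  // cumulative-sum arithmetic as the shuffles so that arrangements sharing
  // block sums stay exact floating-point ties
  int K = n_shuffle + 1;
  std::vector<std::vector<double> > iv(K);
  {
    std::vector<double> notes0(N);
    notes0[0] = 0.0;
    for (int i = 0; i < N - 1; ++i) notes0[i + 1] = notes0[i] + steps[i];
    pair_intervals(notes0, iv[0]);
    std::sort(iv[0].begin(), iv[0].end());
  }

  NumericVector mean_p(nt, NA_REAL), dev_orig(nt, NA_REAL),
    dev_shuf(nt, NA_REAL);
  LogicalVector tested(nt, false);
  IntegerVector n_valid(nt, 0);

  std::vector<double> psum(nt, 0.0), ssum(nt, 0.0), scount(nt, 0.0);
  std::vector<int> valid(nt, 0);
  std::vector<double> sh(steps), notes2(N);
  std::vector<std::vector<double> > dv(K);
  std::vector<double> pool;

  for (int r = 0; r < n_repeat; ++r) {
    for (int a = 1; a < K; ++a) {
      // Fisher-Yates using R RNG
      for (int i = (int)sh.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(sh[i], sh[j]);
      }
      notes2[0] = 0.0;
      for (int i = 0; i < N - 1; ++i) notes2[i + 1] = notes2[i] + sh[i];
      pair_intervals(notes2, iv[a]);
      std::sort(iv[a].begin(), iv[a].end());
    }
    for (int t = 0; t < nt; ++t) {
      double I = targets[t];
      window_devs(iv[0], I, window, dv[0]);
      if (dv[0].empty()) continue;
      size_t M = dv[0].size();
      for (int a = 1; a < K; ++a) {
        window_devs(iv[a], I, window, dv[a]);
        M += dv[a].size();
        for (double d : dv[a]) { ssum[t] += d; scount[t] += 1.0; }
      }
      if (M == dv[0].size()) { // no shuffle produced an in-window interval
        psum[t] += 1.0;
        ++valid[t];
        continue;
      }
      // the p reported per repeat estimates the original's extremity
      // quantile among shuffled arrangements (mid-p convention: ties split
      // at half weight, keeping the converged mean over repeats unbiased in
      // this heavily discrete setting); a degenerate permutation
      // distribution (every arrangement equally extreme) reports p = 1
      pool.clear();
      pool.reserve(M);
      for (int a = 0; a < K; ++a)
        pool.insert(pool.end(), dv[a].begin(), dv[a].end());
      std::sort(pool.begin(), pool.end());
      // AUC of each non-empty arrangement vs the pooled others
      int n_ref = 0;
      double hits = 0.0, ties = 0.0, e0 = 0.0;
      {
        double U = u_stat_sorted(dv[0], pool) - u_self(dv[0]);
        size_t m = dv[0].size();
        e0 = std::fabs(U / ((double)m * (double)(M - m)) - 0.5);
      }
      for (int a = 1; a < K; ++a) {
        size_t m = dv[a].size();
        if (m == 0 || m == M) continue;
        double U = u_stat_sorted(dv[a], pool) - u_self(dv[a]);
        double e = std::fabs(U / ((double)m * (double)(M - m)) - 0.5);
        ++n_ref;
        if (e >= e0 + 1e-12) hits += 1.0;
        else if (e >= e0 - 1e-12) ties += 1.0;
      }
      double p;
      if (n_ref == 0 || ties >= (double)n_ref) p = 1.0; // degenerate
      else p = (hits + 0.5 * ties) / (double)n_ref;
      psum[t] += p;
      ++valid[t];
    }
  }
  std::vector<double> dx;
  for (int t = 0; t < nt; ++t) {
    window_devs(iv[0], targets[t], window, dx);
    if (dx.empty() || valid[t] == 0) continue;
    tested[t] = true;
    n_valid[t] = valid[t];
    double sx = 0.0;
    for (double d : dx) sx += d;
    dev_orig[t] = sx / dx.size();
    mean_p[t] = psum[t] / valid[t];
    dev_shuf[t] = scount[t] > 0 ? ssum[t] / scount[t] : NA_REAL;
  }
  return List::create(_["mean_p"] = mean_p, _["tested"] = tested,
                      _["mean_dev_orig"] = dev_orig,
                      _["mean_dev_shuffled"] = dev_shuf,
                      _["n_valid_repeats"] = n_valid);
}
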