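#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive enumeration of grid scales: ordered tuples of n_steps steps,
// each an integer in [lo_u, hi_u] grid units, summing to span_u units.
// Single pass accumulates (i) the count, (ii) how many tuples have mean
// absolute internal-note deviation from the equidistant reference at most
// dev_threshold cents, and (iii) per-internal-note histograms of note
// positions (one row per grid position 0..span_u).
// [[Rcpp::export]]
List grid_stats_cpp(int n_steps, int lo_u, int hi_u, int span_u,
                    double resolution, double dev_threshold) {
  int ni = n_steps - 1; // internal notes
  std::vector<double> ref(ni);
  for (int k = 0; k < ni; ++k)
    ref[k] = (double)(k + 1) * span_u * resolution / n_steps;

  NumericMatrix hist(span_u + 1, ni > 0 ? ni : 1);
  double total = 0.0, within = 0.0;

  // min/max achievable sums for the remaining steps
  std::vector<int> step_u(n_steps), note_u(n_steps);
  std::vector<double> acc(n_steps + 1, 0.0);
  // iterative depth-first enumeration
  int depth = 0;
  std::vector<int> cur(n_steps, 0);
  std::vector<int> rem(n_steps + 1, 0);
  rem[0] = span_u;
  std::vector<int> nu(n_steps + 1, 0);
  while (depth >= 0) {
    if (depth == n_steps - 1) {
      int s = rem[depth];
      if (s >= lo_u && s <= hi_u) {
        total += 1.0;
        if (ni > 0 && acc[depth] / ni <= dev_threshold + 1e-9)
          within += 1.0;
        // one completed tuple: count each of its internal notes
        for (int k = 1; k <= ni; ++k) hist(nu[k], k - 1) += 1.0;
      }
      --depth;
      continue;
    }
    int remaining_steps = n_steps - 1 - depth; // after choosing this one
    int smin = rem[depth] - hi_u * remaining_steps;
    if (smin < lo_u) smin = lo_u;
    int smax = rem[depth] - lo_u * remaining_steps;
    if (smax > hi_u) smax = hi_u;
    if (cur[depth] == 0) cur[depth] = smin; else ++cur[depth];
    if (cur[depth] > smax) { cur[depth] = 0; --depth; continue; }
    int s = cur[depth];
    rem[depth + 1] = rem[depth] - s;
    nu[depth + 1] = nu[depth] + s;
    // note after this step is internal note index `depth` (0-based)
    double note_cents = (double)nu[depth + 1] * resolution;
    acc[depth + 1] = acc[depth] + std::fabs(note_cents - ref[depth]);
    ++depth;
  }
  return List::create(_["count"] = total, _["n_within"] = within,
                      _["note_hist"] = hist);
}

// Materialize all step tuples (in grid units) for small enumerations.
// [[Rcpp::export]]
IntegerMatrix grid_enumerate_cpp(int n_steps, int lo_u, int hi_u, int span_u,
                                 double max_rows) {
  std::vector<std::vector<int> > rows;
  std::vector<int> cur(n_steps, 0);
  std::vector<int> rem(n_steps + 1, 0);
  rem[0] = span_u;
  int depth = 0;
  while (depth >= 0) {
    if (depth == n_steps - 1) {
      int s = rem[depth];
      if (s >= lo_u && s <= hi_u) {
        if ((double)rows.size() >= max_rows)
          stop("enumeration exceeds max_rows; use grid_scale_stats() instead");
        std::vector<int> row(cur.begin(), cur.begin() + n_steps - 1);
        row.push_back(s);
        rows.push_back(row);
      }
      --depth;
      continue;
    }
    int remaining_steps = n_steps - 1 - depth;
    int smin = rem[depth] - hi_u * remaining_steps;
    if (smin < lo_u) smin = lo_u;
    int smax = rem[depth] - lo_u * remaining_steps;
    if (smax > hi_u) smax = hi_u;
    if (cur[depth] == 0) cur[depth] = smin; else ++cur[depth];
    if (cur[depth] > smax) { cur[depth] = 0; --depth; continue; }
    rem[depth + 1] = rem[depth] - cur[depth];
    ++depth;
  }
  IntegerMatrix out((int)rows.size(), n_steps);
  for (int i = 0; i < (int)rows.size(); ++i)
    for (int j = 0; j < n_steps; ++j) out(i, j) = rows[i][j];
  return out;
}
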