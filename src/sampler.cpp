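#include <Rcpp.h>
using namespace Rcpp;

// Inverse-transform sampling of photon events and accumulation onto the
// pixel grid. Uses R's RNG (two uniforms per event: radius first, then
// angle) so that set.seed() in R governs the stream and the pure-R engine
// can reproduce it draw for draw.
//
// The quantile lookup is the inverse of the piecewise-linear CDF: binary
// search for the first node with cdf >= u, then linear interpolation -- the
// same arithmetic, in the same order, as radial_quantile() in R.

// [[Rcpp::export]]
List cpp_sample_accumulate(double n_events, NumericVector r_grid,
                           NumericVector cdf, double beam_fast,
                           double beam_slow, double pixel_size, int n_fast,
                           int n_slow, int module_fast, int gap_fast,
                           int module_slow, int gap_slow) {
  IntegerMatrix counts(n_fast, n_slow);
  const int m = cdf.size();
  const int period_f = module_fast + gap_fast;
  const int period_s = module_slow + gap_slow;
  const double *cp = &cdf[0];
  const double *rp = &r_grid[0];
  int *mp = counts.begin();
  double recorded = 0.0;

  // coarse jump table: start[k] = first node with cdf >= k/K, so the exact
  // bisection below only scans a short range (result identical to a full
  // binary search)
  const int K = 16384;
  std::vector<int> start(K + 1);
  {
    int idx = 0;
    for (int k = 0; k <= K; k++) {
      const double u = (double)k / K;
      while (idx < m - 1 && cp[idx] < u) idx++;
      start[k] = idx;
    }
  }

  for (double k = 0.0; k < n_events; k += 1.0) {
    const double u = unif_rand();
    // first index with cdf[idx] >= u
    int cell = (int)(u * K);
    if (cell > K - 1) cell = K - 1;
    int lo = start[cell], hi = start[cell + 1];
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (cp[mid] < u) lo = mid + 1; else hi = mid;
    }
    double r;
    if (lo == 0) {
      r = rp[0];
    } else {
      const double c0 = cp[lo - 1], c1 = cp[lo];
      r = rp[lo - 1] + (u - c0) * (rp[lo] - rp[lo - 1]) / (c1 - c0);
    }
    const double phi = -M_PI + 2.0 * M_PI * unif_rand();
    const double x = beam_fast + (r / pixel_size) * cos(phi);
    const double y = beam_slow + (r / pixel_size) * sin(phi);
    const double fx = floor(x + 0.5), fy = floor(y + 0.5);
    if (fx < 0 || fx >= n_fast || fy < 0 || fy >= n_slow) continue;
    const int i = (int)fx, j = (int)fy;
    if (gap_fast > 0 && (i % period_f) >= module_fast) continue;
    if (gap_slow > 0 && (j % period_s) >= module_slow) continue;
    mp[(size_t)j * n_fast + i] += 1;
    recorded += 1.0;
  }
  return List::create(_["counts"] = counts, _["n_recorded"] = recorded);
}

// Per-bin sums and live-pixel counts for radial averaging: each pixel is
// assigned to the nearest-integer pixel distance from the beam.

// [[Rcpp::export]]
List cpp_radial_accumulate(IntegerMatrix counts, LogicalMatrix excluded,
                           bool use_mask, double beam_fast, double beam_slow,
                           int n_bins) {
  const int nf = counts.nrow(), ns = counts.ncol();
  NumericVector sum(n_bins);
  IntegerVector npix(n_bins);
  for (int j = 0; j < ns; j++) {
    const double dy2 = (j - beam_slow) * (j - beam_slow);
    for (int i = 0; i < nf; i++) {
      if (use_mask && excluded(i, j)) continue;
      const double d = sqrt((i - beam_fast) * (i - beam_fast) + dy2);
      const int b = (int)floor(d + 0.5);
      if (b < 0 || b >= n_bins) continue;
      sum[b] += counts(i, j);
      npix[b] += 1;
    }
  }
  return List::create(_["sum"] = sum, _["npix"] = npix);
}
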