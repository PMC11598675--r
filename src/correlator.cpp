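// Multi-tau intensity autocorrelation from photon time tags.
//
// Photons are held as integer picosecond timestamps. Each level bins the
// stream at base_bin * 2^level by integer division; level 0 evaluates lags
// 1..m (in bin units), deeper levels lags m/2+1..m. Pair counting uses a
// two-pointer sweep over occupied bins, so the cost is O(levels * m * N)
// for N photons regardless of the bin width. The symmetric normalization
// divides the pair count by the window-restricted mean rates at both ends
// of the lag, which suppresses finite-window bias.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".multitau_cpp")]]
List multitau_cpp(NumericVector times_ps, double t_start_ps, double t_end_ps,
                  double base_bin_ps, int m, int octaves) {
  const int64_t t0 = (int64_t)llround(t_start_ps);
  const int64_t t1 = (int64_t)llround(t_end_ps);
  const int64_t w0 = (int64_t)llround(base_bin_ps);
  if (w0 < 1) stop("base bin must be >= 1 ps");
  if (m < 2 || m % 2 != 0) stop("m must be even and >= 2");
  const int n = times_ps.size();

  std::vector<int64_t> ts;
  ts.reserve(n);
  for (int i = 0; i < n; ++i) {
    int64_t t = (int64_t)llround(times_ps[i]);
    if (t >= t0 && t < t1) ts.push_back(t - t0);
  }
  if (!std::is_sorted(ts.begin(), ts.end()))
    std::sort(ts.begin(), ts.end());

  std::vector<double> lag_out, g2_out;
  std::vector<int64_t> occ;     // occupied bin indices
  std::vector<double> cnt;      // counts per occupied bin
  std::vector<double> pref;     // prefix sums of cnt

  for (int lev = 0; lev < octaves; ++lev) {
    const int64_t w = w0 << lev;
    const int64_t B = (t1 - t0) / w;   // number of complete bins
    if (B < 2) break;

    occ.clear(); cnt.clear();
    for (size_t i = 0; i < ts.size(); ++i) {
      int64_t b = ts[i] / w;
      if (b >= B) continue;
      if (!occ.empty() && occ.back() == b) cnt.back() += 1.0;
      else { occ.push_back(b); cnt.push_back(1.0); }
    }
    const size_t no = occ.size();
    pref.assign(no + 1, 0.0);
    for (size_t i = 0; i < no; ++i) pref[i + 1] = pref[i] + cnt[i];

    const int j_lo = (lev == 0) ? 1 : m / 2 + 1;
    for (int j = j_lo; j <= m; ++j) {
      if ((int64_t)j >= B) break;
      // pair count G = sum_b n(b) n(b+j), b <= B-1-j
      double G = 0.0;
      size_t k = 0;
      for (size_t i = 0; i < no; ++i) {
        if (occ[i] > B - 1 - (int64_t)j) break;
        int64_t target = occ[i] + j;
        while (k < no && occ[k] < target) ++k;
        if (k >= no) break;
        if (occ[k] == target) G += cnt[i] * cnt[k];
      }
      // M_L: photons in bins [0, B-1-j]; M_R: photons in bins [j, B-1]
      int64_t bl = B - (int64_t)j;   // first excluded bin on the left sum
      size_t il = std::lower_bound(occ.begin(), occ.end(), bl) - occ.begin();
      double ML = pref[il];
      size_t ir = std::lower_bound(occ.begin(), occ.end(), (int64_t)j) -
                  occ.begin();
      double MR = pref[no] - pref[ir];
      double g2 = NA_REAL;
      if (ML > 0.0 && MR > 0.0)
        g2 = G * (double)(B - j) / (ML * MR);
      lag_out.push_back((double)j * (double)w);
      g2_out.push_back(g2);
    }
  }
  return List::create(_["lag_ps"] = wrap(lag_out), _["g2"] = wrap(g2_out),
                      _["n_photons"] = (double)ts.size());
}
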