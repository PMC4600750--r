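#include <Rcpp.h>
using namespace Rcpp;

// Hartigan's dip statistic: the sup-norm distance from the empirical CDF to
// the closest unimodal (convex-then-concave) CDF.
//
// Computed by the classic iterative narrowing scheme.  On the current
// candidate modal interval, the greatest convex minorant (GCM) of the lower
// ECDF corners and the least concave majorant (LCM) of the upper corners
// are fitted; the largest vertical gap between the two curves locates the
// next, narrower modal candidate, and the ECDF's deviations from the fitted
// curves outside it are banked (a convex function within a half-band d of
// the ECDF on a region exists iff 2d is at least the deviation of the upper
// corners from the GCM there, the optimal fit being the shifted minorant;
// mirrored for the concave side).  The dip is half the largest banked
// requirement once the modal gap no longer exceeds it.
//
// Inputs are the unique sorted values with their tie counts.

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector t_in, IntegerVector cnt_in, int n) {
  const int J = t_in.size();
  if (J == 1) return 0.0;
  std::vector<double> t(t_in.begin(), t_in.end());
  std::vector<double> lo(J), up(J);
  {
    int c = 0;
    for (int k = 0; k < J; ++k) {
      lo[k] = (double)c / n;
      c += cnt_in[k];
      up[k] = (double)c / n;
    }
  }

  int low = 0, high = J - 1;
  double D = 0.0;
  std::vector<int> gcm, lcm;          // touch-point indices
  std::vector<double> gval(J), lval(J);  // curve values at every knot

  for (int iter = 0; iter < 2 * J + 5; ++iter) {
    // ---- GCM of (t, lo) on [low, high] ---------------------------------
    gcm.clear();
    for (int k = low; k <= high; ++k) {
      while ((int)gcm.size() >= 2) {
        int b = gcm[(int)gcm.size() - 1], a = gcm[(int)gcm.size() - 2];
        if ((lo[b] - lo[a]) * (t[k] - t[b]) - (lo[k] - lo[b]) * (t[b] - t[a]) > 0)
          gcm.pop_back();
        else break;
      }
      gcm.push_back(k);
    }
    // ---- LCM of (t, up) on [low, high] ---------------------------------
    lcm.clear();
    for (int k = low; k <= high; ++k) {
      while ((int)lcm.size() >= 2) {
        int b = lcm[(int)lcm.size() - 1], a = lcm[(int)lcm.size() - 2];
        if ((up[b] - up[a]) * (t[k] - t[b]) - (up[k] - up[b]) * (t[b] - t[a]) < 0)
          lcm.pop_back();
        else break;
      }
      lcm.push_back(k);
    }
    // curve values at the knots of [low, high]
    {
      int s = 0;
      for (int k = low; k <= high; ++k) {
        while (s < (int)gcm.size() - 1 && gcm[s + 1] <= k) ++s;
        if (gcm[s] == k) gval[k] = lo[k];
        else {
          int a = gcm[s], b = gcm[s + 1];
          gval[k] = lo[a] + (lo[b] - lo[a]) * (t[k] - t[a]) / (t[b] - t[a]);
        }
      }
      s = 0;
      for (int k = low; k <= high; ++k) {
        while (s < (int)lcm.size() - 1 && lcm[s + 1] <= k) ++s;
        if (lcm[s] == k) lval[k] = up[k];
        else {
          int a = lcm[s], b = lcm[s + 1];
          lval[k] = up[a] + (up[b] - up[a]) * (t[k] - t[a]) / (t[b] - t[a]);
        }
      }
    }

    // ---- largest gap between the curves, with its modal candidate ------
    double d = -1.0;
    int new_low = low, new_high = high;
    {
      // gaps at GCM touch points: modal candidate [touch, right LCM touch]
      int s = 0;
      for (int gi = 0; gi < (int)gcm.size(); ++gi) {
        int k = gcm[gi];
        double dx = lval[k] - lo[k];
        if (dx > d) {
          while (s < (int)lcm.size() - 1 && lcm[s + 1] < k) ++s;
          int rt = (lcm[s] >= k) ? lcm[s]
                                 : (s + 1 < (int)lcm.size() ? lcm[s + 1] : high);
          d = dx;
          new_low = k;
          new_high = rt;
        }
      }
      // gaps at LCM touch points: modal candidate [left GCM touch, touch]
      s = (int)gcm.size() - 1;
      for (int li = (int)lcm.size() - 1; li >= 0; --li) {
        int k = lcm[li];
        double dx = up[k] - gval[k];
        if (dx > d) {
          while (s > 0 && gcm[s - 1] > k) --s;
          int lt = (gcm[s] <= k) ? gcm[s] : (s > 0 ? gcm[s - 1] : low);
          d = dx;
          new_low = lt;
          new_high = k;
        }
      }
    }

    if (d <= D) break;

    // ---- bank the deviations outside the new modal interval ------------
    // The boundary knots themselves are deferred: they are re-measured
    // against the refitted minorant/majorant of the next, narrower
    // interval, and absorbed entirely by the CDF's jump when the mode
    // lands exactly on them.
    double dl = 0.0, du = 0.0;
    for (int k = low; k < new_low; ++k) {
      double dev = up[k] - gval[k];
      if (dev > dl) dl = dev;
    }
    for (int k = new_high + 1; k <= high; ++k) {
      double dev = lval[k] - lo[k];
      if (dev > du) du = dev;
    }
    double bank = std::max(dl, du);
    if (bank > D) D = bank;

    if (new_low == new_high) break;  // mode at a knot: its mass jumps
    if (new_low == low && new_high == high) {
      // modal interval cannot shrink further: its gap must be absorbed
      if (d > D) D = d;
      break;
    }
    low = new_low;
    high = new_high;
  }
  return D / 2.0;
}
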