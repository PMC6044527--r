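#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Appearance-adaptive shape-prior window search: for each test voxel,
// search a window centered at its mapped database-lattice location across
// all aligned training volumes for voxels within the intensity tolerance;
// grow the window by 2 per axis (up to max_window) until a match exists.
// The prior is the kidney fraction among matches; if the largest window
// still has no intensity match, label occurrences in that window are used
// ignoring intensity.

// [[Rcpp::export]]
NumericVector adapt_prior_cpp(IntegerVector test, IntegerVector tdims,
                              IntegerMatrix mapped, List train_vols,
                              List train_maps, IntegerVector ddims,
                              IntegerVector window0, IntegerVector max_window,
                              int tol) {
  const int nx = ddims[0], ny = ddims[1], nz = ddims[2];
  const R_xlen_t n = (R_xlen_t)tdims[0] * tdims[1] * tdims[2];
  const int ns = train_vols.size();
  std::vector<const int*> vols(ns), maps(ns);
  for (int s = 0; s < ns; ++s) {
    vols[s] = INTEGER(train_vols[s]);
    maps[s] = INTEGER(train_maps[s]);
  }
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    const int g = test[v];
    const int cx = mapped((int)v, 0), cy = mapped((int)v, 1),
              cz = mapped((int)v, 2);
    int wx = window0[0], wy = window0[1], wz = window0[2];
    double prob = 0.5;
    for (;;) {
      const int hx = wx / 2, hy = wy / 2, hz = wz / 2;
      long match = 0, kid = 0, lab_n = 0, lab_kid = 0;
      for (int dz = -hz; dz <= hz; ++dz) {
        const int pz = cz + dz;
        if (pz < 0 || pz >= nz) continue;
        for (int dy = -hy; dy <= hy; ++dy) {
          const int py = cy + dy;
          if (py < 0 || py >= ny) continue;
          const R_xlen_t rowbase = (R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx;
          for (int dx = -hx; dx <= hx; ++dx) {
            const int px = cx + dx;
            if (px < 0 || px >= nx) continue;
            const R_xlen_t idx = rowbase + px;
            for (int s = 0; s < ns; ++s) {
              const int lab = maps[s][idx];
              ++lab_n;
              lab_kid += lab;
              if (std::abs(vols[s][idx] - g) <= tol) {
                ++match;
                kid += lab;
              }
            }
          }
        }
      }
      if (match > 0) {
        prob = (double)kid / (double)match;
        break;
      }
      const bool at_max = wx >= max_window[0] && wy >= max_window[1] &&
                          wz >= max_window[2];
      if (at_max) {
        // fallback: relative label occurrence ignoring intensity
        if (lab_n > 0) prob = (double)lab_kid / (double)lab_n;
        break;
      }
      if (wx < max_window[0]) wx += 2;
      if (wy < max_window[1]) wy += 2;
      if (wz < max_window[2]) wz += 2;
    }
    out[v] = prob;
  }
  return out;
}
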