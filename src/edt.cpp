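#include <Rcpp.h>
#include "dt.h"
using namespace Rcpp;

// Exact squared Euclidean distance transform with anisotropic spacing;
// seeds have distance 0.

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector seed, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> grid(n);
  for (size_t i = 0; i < n; ++i)
    grid[i] = seed[i] ? 0.0 : kidneyseg::DT_INF;
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  kidneyseg::edt3(grid, nx, ny, nz, sp);
  return NumericVector(grid.begin(), grid.end());
}
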