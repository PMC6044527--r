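#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential single-site Gibbs sampler for the binary 4th-order MGRF.
// Families are passed as offset matrices plus per-class potential vectors:
// pairs (V_eq, V_ne), triples (V_eq3, V_eq2), quadruples
// (V_eq4, V_eq3, V_eq2). Uses R's RNG so set.seed() fixes the draw.

struct Fam {
  int nu;                       // clique order
  std::vector<int> ox, oy, oz;  // member offsets
  std::vector<double> pot;      // per-equality-class potentials
};

static inline double clique_pot(const Fam& fam, int ssum) {
  if (fam.nu == 2)
    return (ssum != 1) ? fam.pot[0] : fam.pot[1];
  if (fam.nu == 3)
    return (ssum == 0 || ssum == 3) ? fam.pot[0] : fam.pot[1];
  if (ssum == 0 || ssum == 4) return fam.pot[0];
  if (ssum == 2) return fam.pot[2];
  return fam.pot[1];
}

// [[Rcpp::export]]
IntegerVector gibbs_sample_cpp(List families, List potentials,
                               IntegerVector init, IntegerVector dims,
                               int n_sweeps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Fam> fams;
  for (int i = 0; i < families.size(); ++i) {
    List fl = families[i];
    IntegerMatrix off = fl["offsets"];
    Fam f;
    f.nu = as<int>(fl["order"]);
    for (int r = 0; r < off.nrow(); ++r) {
      f.ox.push_back(off(r, 0));
      f.oy.push_back(off(r, 1));
      f.oz.push_back(off(r, 2));
    }
    NumericVector pv = potentials[i];
    f.pot.assign(pv.begin(), pv.end());
    fams.push_back(f);
  }
  std::vector<int> m(init.begin(), init.end());
  RNGScope scope;
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double e0 = 0.0, e1 = 0.0;
          for (size_t fi = 0; fi < fams.size(); ++fi) {
            const Fam& f = fams[fi];
            const int nu = f.nu;
            for (int role = 0; role < nu; ++role) {
              // anchor the clique so that member `role` sits at (x,y,z)
              int ax = x - f.ox[role], ay = y - f.oy[role],
                  az = z - f.oz[role];
              bool ok = true;
              int osum = 0;
              for (int j = 0; j < nu && ok; ++j) {
                if (j == role) continue;
                int px = ax + f.ox[j], py = ay + f.oy[j], pz = az + f.oz[j];
                if (px < 0 || px >= nx || py < 0 || py >= ny ||
                    pz < 0 || pz >= nz) { ok = false; break; }
                osum += m[(size_t)pz * nx * ny + (size_t)py * nx + px];
              }
              if (!ok) continue;
              e0 += clique_pot(f, osum);
              e1 += clique_pot(f, osum + 1);
            }
          }
          double p1 = 1.0 / (1.0 + std::exp(e0 - e1));
          m[(size_t)z * nx * ny + (size_t)y * nx + x] =
            (R::runif(0.0, 1.0) < p1) ? 1 : 0;
        }
  }
  return IntegerVector(m.begin(), m.end());
}
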