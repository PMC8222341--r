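#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// The O(I^2) repulsion sweep dominates the runtime of the whole morphology
// module; allow the compiler to vectorize it aggressively.  Associativity
// relaxation only reorders the force accumulation (a sum of ~10^3 terms of
// comparable magnitude), it does not change the algorithm.
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "fast-math", "unroll-loops")
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// Attraction-repulsion spherical parameterization.
//
// Starting from an initial one-to-one map of mesh nodes onto the unit sphere,
// each iteration applies (i) an attraction step that pulls every node toward
// its mesh neighbours, with a cubic term that acts at long range and a
// constant-magnitude term that acts at short range, (ii) a global pairwise
// repulsion step that inflates the map so nodes cannot collapse onto each
// other, and (iii) re-projection onto the unit sphere.  Iterations stop when
// the largest node displacement falls below `tol` or after `max_iters`.
//
// `literal_alpha` re-uses the pre-attraction positions in the repulsion step
// (the displacement subscript as printed); the default recomputes them from
// the post-attraction positions so the repulsion counteracts the attraction
// just applied.
//
// [[Rcpp::export]]
List ar_run_cpp(NumericMatrix coords, List nbrs, double ca1, double ca2,
                double cr, double tol, int max_iters, bool literal_alpha) {
  const int I = coords.nrow();
  std::vector<double> x(I), y(I), z(I);
  for (int i = 0; i < I; ++i) {
    x[i] = coords(i, 0);
    y[i] = coords(i, 1);
    z[i] = coords(i, 2);
  }
  // flatten neighbour index lists (1-based from R)
  std::vector<int> nb_start(I + 1, 0);
  std::vector<int> nb_idx;
  for (int i = 0; i < I; ++i) {
    IntegerVector ji = nbrs[i];
    nb_start[i + 1] = nb_start[i] + ji.size();
    for (int k = 0; k < ji.size(); ++k) nb_idx.push_back(ji[k] - 1);
  }

  std::vector<double> xp(I), yp(I), zp(I), rx(I), ry(I), rz(I);
  bool converged = false;
  int iter = 0;
  double maxdisp = R_PosInf;
  const double rep_scale = cr / (2.0 * I);

  for (iter = 0; iter < max_iters; ++iter) {
    // attraction: neighbours only, from current accepted positions
    for (int i = 0; i < I; ++i) {
      double ax = 0.0, ay = 0.0, az = 0.0;
      for (int k = nb_start[i]; k < nb_start[i + 1]; ++k) {
        const int j = nb_idx[k];
        const double dx = x[j] - x[i];
        const double dy = y[j] - y[i];
        const double dz = z[j] - z[i];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= 0.0) stop("duplicate node");
        const double d = std::sqrt(d2);
        const double w = d2 + ca2 / d;  // d_ji * d^2 + ca2 * d_ji / d
        ax += dx * w;
        ay += dy * w;
        az += dz * w;
      }
      xp[i] = x[i] + ca1 * ax;
      yp[i] = y[i] + ca1 * ay;
      zp[i] = z[i] + ca1 * az;
    }

    // repulsion: all pairs, symmetric accumulation
    const std::vector<double>& bx = literal_alpha ? x : xp;
    const std::vector<double>& by = literal_alpha ? y : yp;
    const std::vector<double>& bz = literal_alpha ? z : zp;
    const double* RESTRICT px = bx.data();
    const double* RESTRICT py = by.data();
    const double* RESTRICT pz = bz.data();
    bool dup = false;
    for (int i = 0; i < I; ++i) {
      const double xi = px[i], yi = py[i], zi = pz[i];
      double ax = 0.0, ay = 0.0, az = 0.0;
      int zeros = 0;  // the i == j term itself contributes a guarded zero
      for (int j = 0; j < I; ++j) {
        const double dx = xi - px[j];
        const double dy = yi - py[j];
        const double dz = zi - pz[j];
        const double d2 = dx * dx + dy * dy + dz * dz;
        const double inv = (d2 > 0.0) ? 1.0 / d2 : 0.0;
        zeros += (d2 <= 0.0);
        ax += dx * inv;
        ay += dy * inv;
        az += dz * inv;
      }
      if (zeros > 1) dup = true;
      rx[i] = ax; ry[i] = ay; rz[i] = az;
    }
    if (dup) stop("duplicate node");

    // inflate, re-project onto the unit sphere, measure displacement
    maxdisp = 0.0;
    for (int i = 0; i < I; ++i) {
      double nx = xp[i] + rep_scale * rx[i];
      double ny = yp[i] + rep_scale * ry[i];
      double nz = zp[i] + rep_scale * rz[i];
      const double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
      if (nrm <= 0.0) stop("duplicate node");
      nx /= nrm; ny /= nrm; nz /= nrm;
      const double dx = nx - x[i], dy = ny - y[i], dz = nz - z[i];
      const double disp = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (disp > maxdisp) maxdisp = disp;
      x[i] = nx; y[i] = ny; z[i] = nz;
    }
    if (maxdisp <= tol) {
      converged = true;
      ++iter;
      break;
    }
  }

  NumericMatrix out(I, 3);
  for (int i = 0; i < I; ++i) {
    out(i, 0) = x[i];
    out(i, 1) = y[i];
    out(i, 2) = z[i];
  }
  return List::create(_["coords"] = out, _["iterations"] = iter,
                      _["converged"] = converged, _["last_disp"] = maxdisp);
}
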