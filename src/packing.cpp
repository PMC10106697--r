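// Hard-sphere packing inside a spherical boundary by stepwise compression.
//
// Spheres of diameter d start dilute inside a ball; pairwise overlaps are
// relaxed by symmetric displacement with a small decaying random jitter
// (drawn from R's RNG so results are reproducible under set.seed), and the
// confining radius is shrunk geometrically until the target center radius
// is reached. A uniform cell grid keeps the neighbour search near O(n).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  double cell, origin;
  int dim;
  std::vector<std::vector<int>> bins;

  Grid(double radius, double cellSize) : cell(cellSize) {
    dim = std::max(1, (int)std::ceil(2.0 * radius / cell));
    origin = -radius;
    bins.assign((size_t)dim * dim * dim, {});
  }
  int index(double x, double y, double z) const {
    int i = std::min(dim - 1, std::max(0, (int)((x - origin) / cell)));
    int j = std::min(dim - 1, std::max(0, (int)((y - origin) / cell)));
    int k = std::min(dim - 1, std::max(0, (int)((z - origin) / cell)));
    return (i * dim + j) * dim + k;
  }
  void insert(int id, double x, double y, double z) {
    bins[index(x, y, z)].push_back(id);
  }
  void clear() {
    for (auto &b : bins) b.clear();   // keeps capacity, no reallocation
  }
};

// One relaxation pass; returns true when no overlap remains.
bool relax(NumericMatrix X, double d, double rcur, int maxIter, double tol) {
  const int n = X.nrow();
  const double dtol = d - tol;
  const double d2 = dtol * dtol;
  std::vector<double> dx(n), dy(n), dz(n);
  Grid g(rcur + d, d);

  for (int it = 0; it < maxIter; ++it) {
    bool outside = false;
    for (int i = 0; i < n; ++i) {
      double rr = std::sqrt(X(i, 0) * X(i, 0) + X(i, 1) * X(i, 1) + X(i, 2) * X(i, 2));
      if (rr > rcur + 1e-12) { outside = true; break; }
    }

    g.clear();
    for (int i = 0; i < n; ++i) g.insert(i, X(i, 0), X(i, 1), X(i, 2));

    bool any = false;
    double worst = 0.0;
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);

    for (int i = 0; i < n; ++i) {
      int ci = std::min(g.dim - 1, std::max(0, (int)((X(i, 0) - g.origin) / g.cell)));
      int cj = std::min(g.dim - 1, std::max(0, (int)((X(i, 1) - g.origin) / g.cell)));
      int ck = std::min(g.dim - 1, std::max(0, (int)((X(i, 2) - g.origin) / g.cell)));
      for (int a = std::max(0, ci - 1); a <= std::min(g.dim - 1, ci + 1); ++a)
        for (int b = std::max(0, cj - 1); b <= std::min(g.dim - 1, cj + 1); ++b)
          for (int c = std::max(0, ck - 1); c <= std::min(g.dim - 1, ck + 1); ++c)
            for (int j : g.bins[(size_t)(a * g.dim + b) * g.dim + c]) {
              if (j <= i) continue;
              double vx = X(j, 0) - X(i, 0);
              double vy = X(j, 1) - X(i, 1);
              double vz = X(j, 2) - X(i, 2);
              double r2 = vx * vx + vy * vy + vz * vz;
              if (r2 >= d2) continue;
              any = true;
              double r = std::sqrt(r2), push;
              if (d - r > worst) worst = d - r;
              if (r < 1e-12) { vx = 1; vy = 0; vz = 0; r = 1; push = 0.5 * d; }
              else push = 1.9 * (d - r) / r;
              double hx = 0.5 * vx * push, hy = 0.5 * vy * push, hz = 0.5 * vz * push;
              dx[i] -= hx; dy[i] -= hy; dz[i] -= hz;
              dx[j] += hx; dy[j] += hy; dz[j] += hz;
            }
    }
    if (!any && !outside) return true;

    // self-scaling jitter: strong enough to unjam, vanishing as overlaps
    // resolve, so a quiet (converged) pass is reached quickly
    double amp = any ? std::min(0.02 * d, 0.5 * worst) : 0.0;
    for (int i = 0; i < n; ++i) {
      X(i, 0) += dx[i] + amp * (R::unif_rand() - 0.5);
      X(i, 1) += dy[i] + amp * (R::unif_rand() - 0.5);
      X(i, 2) += dz[i] + amp * (R::unif_rand() - 0.5);
      double rr = std::sqrt(X(i, 0) * X(i, 0) + X(i, 1) * X(i, 1) + X(i, 2) * X(i, 2));
      if (rr > rcur) {
        double s = rcur / rr;
        X(i, 0) *= s; X(i, 1) *= s; X(i, 2) *= s;
      }
    }
  }
  return false;
}

} // namespace

// Compress toward target center radius rc; when the packing jams first,
// return the configuration at the last radius that relaxed cleanly.
// [[Rcpp::export(name = ".pack_relax")]]
List pack_relax(NumericMatrix Xinit, double d, double rc,
                double shrink = 0.98, int relaxIter = 700,
                double tol = 1e-9) {
  NumericMatrix X = clone(Xinit);
  const int n = X.nrow();

  double rcur = rc;
  for (int i = 0; i < n; ++i) {
    double rr = std::sqrt(X(i, 0) * X(i, 0) + X(i, 1) * X(i, 1) + X(i, 2) * X(i, 2));
    if (rr > rcur) rcur = rr;
  }

  NumericMatrix best;
  double rbest = -1.0;
  bool reached = false;
  while (true) {
    bool ok = relax(X, d, rcur, relaxIter, tol);
    if (ok) {
      best = clone(X);
      rbest = rcur;
      if (rcur <= rc + 1e-12) { reached = true; break; }
      rcur = std::max(rc, rcur * shrink);
    } else break;
  }
  if (rbest < 0)
    return List::create(_["X"] = R_NilValue, _["ok"] = false,
                        _["rachieved"] = NA_REAL, _["reached"] = false);
  return List::create(_["X"] = best, _["ok"] = true,
                      _["rachieved"] = rbest, _["reached"] = reached);
}
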