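#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Lattice coordinates run 1..gx, 1..gy. The allowed region is the wall
// band: points whose distance to the nearest boundary is below the margin.
static inline bool inBand(int x, int y, int gx, int gy, int margin) {
  if (x < 1 || x > gx || y < 1 || y > gy) return false;
  int d = std::min(std::min(x - 1, gx - x), std::min(y - 1, gy - y));
  return d < margin;
}

static inline void moveAgent(int &x, int &y, int gx, int gy, int margin,
                             int stepMin, int stepMax) {
  // uniform direction, uniform integer step length; proposals leaving the
  // band are re-drawn (up to 100 attempts, then the agent stays in place)
  for (int attempt = 0; attempt < 100; ++attempt) {
    double ang = unif_rand() * 2.0 * M_PI;
    int len = stepMin + (int)std::floor(unif_rand() * (stepMax - stepMin + 1));
    if (len > stepMax) len = stepMax; // guard unif_rand() == 1
    int nx = x + (int)std::lround(len * std::cos(ang));
    int ny = y + (int)std::lround(len * std::sin(ang));
    if (inBand(nx, ny, gx, gy, margin)) { x = nx; y = ny; return; }
  }
}

// [[Rcpp::export(name = ".simulatePairCpp")]]
List simulatePairCpp(int gx, int gy, int margin, int stepMin, int stepMax,
                     int n, double thresh, double pStay) {
  IntegerMatrix A(n, 2), B(n, 2);
  int ax, ay, bx, by;
  // independent uniform starts over the allowed band (rejection)
  do {
    ax = 1 + (int)std::floor(unif_rand() * gx);
    ay = 1 + (int)std::floor(unif_rand() * gy);
  } while (!inBand(ax, ay, gx, gy, margin));
  do {
    bx = 1 + (int)std::floor(unif_rand() * gx);
    by = 1 + (int)std::floor(unif_rand() * gy);
  } while (!inBand(bx, by, gx, gy, margin));
  A(0, 0) = ax; A(0, 1) = ay; B(0, 0) = bx; B(0, 1) = by;
  for (int t = 1; t < n; ++t) {
    double dx = ax - bx, dy = ay - by;
    double d = std::sqrt(dx * dx + dy * dy);
    bool stay = false;
    if (d < thresh && pStay > 0.0) stay = unif_rand() < pStay;
    if (!stay) {
      moveAgent(ax, ay, gx, gy, margin, stepMin, stepMax);
      moveAgent(bx, by, gx, gy, margin, stepMin, stepMax);
    }
    A(t, 0) = ax; A(t, 1) = ay; B(t, 0) = bx; B(t, 1) = by;
  }
  return List::create(_["A"] = A, _["B"] = B);
}
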