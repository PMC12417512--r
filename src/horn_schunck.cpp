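#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dense Horn-Schunck optical flow on the basket pixel lattice.
//
// Layout: a frame is a G x G image stored with the spline axis fastest
// (index i, periodic) and the electrode axis slowest (index j, clamped /
// replicated at the ends).  `frames` holds nf frames contiguously.
//
// Scheme (also implemented by the slow reference oracle in the tests):
//   * each frame pair is jointly standardized (subtract the joint mean,
//     divide by the joint population SD) so the flow is invariant to
//     affine intensity changes applied to both frames;
//   * spatial derivatives: central differences of the pair average,
//     periodic on the spline axis, replicate-clamped on the electrode
//     axis; temporal derivative: two-frame difference;
//   * Jacobi iterations u = ubar - Ix (Ix ubar + Iy vbar + It) / (alpha^2
//     + Ix^2 + Iy^2) with the 4-neighbour average ubar (periodic /
//     replicate boundaries), starting from zero flow.

static inline int wrap(int i, int G) { return (i % G + G) % G; }
static inline int clampi(int i, int G) { return i < 0 ? 0 : (i >= G ? G - 1 : i); }

static void hs_pair(const double* a, const double* b, int G,
                    double alpha, int niter, double* u, double* v,
                    std::vector<double>& work) {
  const int n = G * G;
  double* A  = work.data();
  double* Ix = A + n;
  double* Iy = Ix + n;
  double* It = Iy + n;
  double* un = It + n;
  double* vn = un + n;

  // joint standardization of the pair
  double mean = 0.0;
  for (int k = 0; k < n; ++k) mean += a[k] + b[k];
  mean /= (2.0 * n);
  double var = 0.0;
  for (int k = 0; k < n; ++k) {
    var += (a[k] - mean) * (a[k] - mean) + (b[k] - mean) * (b[k] - mean);
  }
  var /= (2.0 * n);
  double sd = std::sqrt(var);
  std::fill(u, u + n, 0.0);
  std::fill(v, v + n, 0.0);
  if (sd < 1e-12) return;  // constant scene: zero flow

  std::vector<double> as(n), bs(n);
  for (int k = 0; k < n; ++k) {
    as[k] = (a[k] - mean) / sd;
    bs[k] = (b[k] - mean) / sd;
    A[k] = 0.5 * (as[k] + bs[k]);
    It[k] = bs[k] - as[k];
  }
  for (int j = 0; j < G; ++j) {
    for (int i = 0; i < G; ++i) {
      int k = i + j * G;
      Ix[k] = 0.5 * (A[wrap(i + 1, G) + j * G] - A[wrap(i - 1, G) + j * G]);
      Iy[k] = 0.5 * (A[i + clampi(j + 1, G) * G] - A[i + clampi(j - 1, G) * G]);
    }
  }
  const double a2 = alpha * alpha;
  for (int it = 0; it < niter; ++it) {
    for (int j = 0; j < G; ++j) {
      int jm = clampi(j - 1, G) * G, jp = clampi(j + 1, G) * G, j0 = j * G;
      for (int i = 0; i < G; ++i) {
        int im = wrap(i - 1, G), ip = wrap(i + 1, G);
        int k = i + j0;
        double ub = 0.25 * (u[im + j0] + u[ip + j0] + u[i + jm] + u[i + jp]);
        double vb = 0.25 * (v[im + j0] + v[ip + j0] + v[i + jm] + v[i + jp]);
        double num = Ix[k] * ub + Iy[k] * vb + It[k];
        double den = a2 + Ix[k] * Ix[k] + Iy[k] * Iy[k];
        un[k] = ub - Ix[k] * num / den;
        vn[k] = vb - Iy[k] * num / den;
      }
    }
    std::copy(un, un + n, u);
    std::copy(vn, vn + n, v);
  }
}

// [[Rcpp::export(name = ".hs_flow_cpp")]]
List hs_flow_cpp(NumericMatrix frames, int G, double alpha, int niter) {
  const int n = G * G;
  if (frames.nrow() != n) stop("frame mismatch: bad frame size");
  const int nf = frames.ncol();
  if (nf < 2) stop("too short: need at least 2 frames");
  if (alpha <= 0 || niter < 1) stop("bad flow parameters");
  NumericMatrix U(n, nf - 1), V(n, nf - 1);
  std::vector<double> work(6 * n);
  for (int f = 0; f + 1 < nf; ++f) {
    hs_pair(&frames(0, f), &frames(0, f + 1), G, alpha, niter,
            &U(0, f), &V(0, f), work);
  }
  return List::create(_["u"] = U, _["v"] = V);
}
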