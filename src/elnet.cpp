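#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net on a precomputed Gram
// matrix, with warm starts along a decreasing lambda path and glmnet-style
// active-set iteration: after each full sweep, inner sweeps run over the
// currently nonzero set until it converges, then one full sweep checks for
// newly activated predictors.
//
// Solves, per lambda:
//   min_c 1/2 c'Gc - b'c + lambda * sum_j pf_j * ((1-alpha)/2 c_j^2 + alpha |c_j|)
// with G = X'WX / W and b = X'Wy / W on the (optionally standardized,
// centered) scale prepared by the R wrapper. Predictors with G_jj <= 0
// (constant columns) keep coefficient exactly zero.
//
// When dev_stop is true the path is truncated (as in glmnet) once the
// deviance ratio saturates: R2 > 0.999 or its per-step gain < 1e-5 * R2.
// yvar is the weighted variance of the centered response on the same scale
// as b; the returned $nlam says how many lambdas were actually solved.
//
// [[Rcpp::export]]
List cd_enet_path(const NumericMatrix& G, const NumericVector& b,
                  const NumericVector& lambda, double alpha,
                  const NumericVector& pf, double tol, int maxit,
                  double yvar, bool dev_stop, const NumericVector& cinit) {
  const int p = G.ncol();
  const int K = lambda.size();
  NumericMatrix coef(p, K);
  NumericVector devRatio(K, NA_REAL);
  int nlam = 0;
  double prevDev = 0.0;
  std::vector<double> c(p, 0.0);
  std::vector<double> gc(p, 0.0);  // running G %*% c
  const double* Gp = G.begin();
  if (cinit.size() == p) {
    for (int j = 0; j < p; ++j) c[j] = cinit[j];
    for (int k = 0; k < p; ++k) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += Gp[k + (size_t)j * p] * c[j];
      gc[k] = s;
    }
  }

  for (int l = 0; l < K; ++l) {
    const double lam = lambda[l];

    auto update = [&](int j) -> double {
      const double gjj = Gp[j + (size_t)j * p];
      if (gjj <= 0.0) return 0.0;
      const double rj = b[j] - gc[j] + gjj * c[j];
      const double thr = lam * alpha * pf[j];
      const double denom = gjj + lam * (1.0 - alpha) * pf[j];
      double cj;
      if (rj > thr)       cj = (rj - thr) / denom;
      else if (rj < -thr) cj = (rj + thr) / denom;
      else                cj = 0.0;
      const double d = cj - c[j];
      if (d != 0.0) {
        const double* Gj = Gp + (size_t)j * p;
        for (int k = 0; k < p; ++k) gc[k] += Gj[k] * d;
        c[j] = cj;
      }
      return std::fabs(d);
    };

    for (int it = 0; it < maxit; ++it) {
      // full sweep over all predictors
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        const double ad = update(j);
        if (ad > dmax) dmax = ad;
      }
      if (dmax < tol) break;
      // inner sweeps restricted to the active set
      std::vector<int> active;
      active.reserve(p);
      for (int j = 0; j < p; ++j) if (c[j] != 0.0) active.push_back(j);
      for (int inner = 0; inner < maxit; ++inner) {
        double dact = 0.0;
        for (int j : active) {
          const double ad = update(j);
          if (ad > dact) dact = ad;
        }
        if (dact < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) coef(j, l) = c[j];
    nlam = l + 1;
    if (yvar > 0.0) {
      double bc = 0.0, cgc = 0.0;
      for (int j = 0; j < p; ++j) { bc += b[j] * c[j]; cgc += c[j] * gc[j]; }
      const double dev = (2.0 * bc - cgc) / yvar;
      devRatio[l] = dev;
      if (dev_stop && l > 0 &&
          (dev > 0.999 || dev - prevDev < 1e-5 * dev)) break;
      prevDev = dev;
    }
  }
  return List::create(_["coef"] = coef, _["nlam"] = nlam,
                      _["devRatio"] = devRatio);
}
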