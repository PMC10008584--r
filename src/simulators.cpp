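#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the 6-site cyclic Ising model with field h and
// nearest-neighbour coupling J (spins +/-1).  Conditional flip
// probabilities depend only on the neighbour spin sum in {-2, 0, 2}, so
// they are tabulated once.  Uses R's RNG stream.
// [[Rcpp::export(name = ".gibbsRings")]]
IntegerMatrix gibbs_rings(int n, double h, double J, int burnin) {
  IntegerMatrix out(n, 6);
  double ptab[3];
  for (int k = 0; k < 3; ++k) {
    double ns = -2.0 + 2.0 * k;
    ptab[k] = 1.0 / (1.0 + std::exp(-2.0 * (h + J * ns)));
  }
  int s[6];
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < 6; ++i) s[i] = (unif_rand() < 0.5) ? 1 : -1;
    for (int sweep = 0; sweep < burnin; ++sweep) {
      for (int i = 0; i < 6; ++i) {
        int ns = s[(i + 5) % 6] + s[(i + 1) % 6];
        s[i] = (unif_rand() < ptab[(ns + 2) / 2]) ? 1 : -1;
      }
    }
    for (int i = 0; i < 6; ++i) out(r, i) = (s[i] + 1) / 2;
  }
  return out;
}

// Overdamped Langevin dynamics of non-interacting ions in a reflective
// cylinder of radius poreRadius, periodic along z over boxZ.  The electric
// drift (qE/kT, 1/Angstrom) acts only where |z| <= poreHalf; optional
// Gaussian potential wells (depth in kT) add local axial drift.  Frames
// are stored every `stride` steps, starting with the initial state.
// [[Rcpp::export(name = ".langevinRun")]]
List langevin_run(double D, double qEkT, double dt, int nSteps, int stride,
                  double poreRadius, double poreHalf, double boxZ,
                  NumericVector wellDepth, NumericVector wellZ,
                  NumericVector wellW,
                  NumericVector x0, NumericVector y0, NumericVector z0) {
  int nIons = x0.size();
  int nSave = nSteps / stride + 1;
  NumericMatrix X(nSave, nIons), Y(nSave, nIons), Z(nSave, nIons);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> z(z0.begin(), z0.end());
  double sigma = std::sqrt(2.0 * D * dt);
  double drift = D * qEkT * dt;
  int nWells = wellDepth.size();
  double halfZ = boxZ / 2.0;

  for (int i = 0; i < nIons; ++i) {
    X(0, i) = x[i]; Y(0, i) = y[i]; Z(0, i) = z[i];
  }
  int row = 1;
  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < nIons; ++i) {
      double zw = z[i];
      double dz = sigma * norm_rand();
      if (std::fabs(zw) <= poreHalf) dz += drift;
      for (int w = 0; w < nWells; ++w) {
        double u = zw - wellZ[w];
        double w2 = wellW[w] * wellW[w];
        // U/kT = -depth * exp(-u^2/(2 w^2)); drift = -D dU/dz dt / kT
        dz += D * dt * (-wellDepth[w] * u / w2) *
          std::exp(-u * u / (2.0 * w2));
      }
      zw += dz;
      // periodic wrap into [-boxZ/2, boxZ/2)
      zw -= boxZ * std::floor((zw + halfZ) / boxZ);
      z[i] = zw;
      double nx = x[i] + sigma * norm_rand();
      double ny = y[i] + sigma * norm_rand();
      double r = std::sqrt(nx * nx + ny * ny);
      if (r > poreRadius && r > 0) {
        double rr = 2.0 * poreRadius - r;   // reflective wall
        if (rr < 0) rr = 0;
        nx *= rr / r;
        ny *= rr / r;
      }
      x[i] = nx; y[i] = ny;
    }
    if (step % stride == 0) {
      for (int i = 0; i < nIons; ++i) {
        X(row, i) = x[i]; Y(row, i) = y[i]; Z(row, i) = z[i];
      }
      ++row;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["z"] = Z);
}
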