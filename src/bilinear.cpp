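#include <Rcpp.h>
using namespace Rcpp;

// Stochastic integration of the bilinear neural state equation
//   dz/dt = (A + u_face B_face + u_int B_int) z + C [u_face, u_int]' + extra
// using Heun's predictor-corrector for the drift (second-order accurate for
// the deterministic part; inputs are held constant within a step) plus an
// Euler-Maruyama additive-noise increment.
// z: n_regions state vector; inputs sampled on the dt grid (length n_steps).
// extra is an optional additive drive (n_regions x n_steps), used by the
// cohort simulator for the instructed-regulation input; pass a 0 x 0 matrix
// to disable. Noise uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
NumericMatrix integrate_bilinear_cpp(NumericMatrix A, NumericMatrix Bf,
                                     NumericMatrix Bi, NumericMatrix C,
                                     NumericVector u_face, NumericVector u_int,
                                     NumericMatrix extra, double dt,
                                     NumericVector z0, double noise_sd,
                                     double bound) {
  const int n = A.nrow();
  const int T = u_face.size();
  const bool has_extra = extra.nrow() == n && extra.ncol() == T;
  NumericMatrix Z(n, T);
  double *zp = REAL(Z);
  const double *ap = REAL(A), *bfp = REAL(Bf), *bip = REAL(Bi);
  const double *cp = REAL(C), *ufp = REAL(u_face), *uip = REAL(u_int);
  const double *exp_ = has_extra ? REAL(extra) : nullptr;
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> dz1(n), dz2(n), zpred(n), M(n * n);
  const double sqdt = std::sqrt(dt);
  bool diverged = false;
  double uf_prev = NA_REAL, ui_prev = NA_REAL;
  // drift at state s under the coupling M and inputs cached outside
  auto drift = [&](const std::vector<double> &s, std::vector<double> &out,
                   double uf, double ui, const double *ecol) {
    for (int i = 0; i < n; ++i) out[i] = cp[i] * uf + cp[n + i] * ui;
    for (int j = 0; j < n; ++j) {
      const double sj = s[j];
      const double *mcol = &M[j * n];
      for (int i = 0; i < n; ++i) out[i] += mcol[i] * sj;
    }
    if (ecol) for (int i = 0; i < n; ++i) out[i] += ecol[i];
  };
  for (int t = 0; t < T; ++t) {
    const double uf = ufp[t], ui = uip[t];
    if (uf != uf_prev || ui != ui_prev) {  // effective coupling at (uf, ui)
      for (int k = 0; k < n * n; ++k) M[k] = ap[k] + uf * bfp[k] + ui * bip[k];
      uf_prev = uf; ui_prev = ui;
    }
    const double *ecol = has_extra ? exp_ + (size_t)t * n : nullptr;
    drift(z, dz1, uf, ui, ecol);
    for (int i = 0; i < n; ++i) zpred[i] = z[i] + dt * dz1[i];
    drift(zpred, dz2, uf, ui, ecol);
    double *zcol = zp + (size_t)t * n;
    for (int i = 0; i < n; ++i) {
      z[i] += 0.5 * dt * (dz1[i] + dz2[i]);
      if (noise_sd > 0.0) z[i] += noise_sd * sqdt * ::norm_rand();
      zcol[i] = z[i];
      if (std::fabs(z[i]) > bound) diverged = true;
    }
    if (diverged) break;
  }
  if (diverged) stop("neural trajectory diverged (|z| exceeded bound); unstable parameters");
  return Z;
}

// BOLD prediction at volume times: causal discrete convolution of the
// dt-sampled neural trajectory with the dt-sampled HRF kernel, evaluated
// only at every `stride`-th grid point (stride = TR/dt). Row = region.
// vol_offset gives the dt index (1-based) of the first volume's sample.
// [[Rcpp::export]]
NumericMatrix bold_at_volumes_cpp(NumericMatrix Z, NumericVector hrf,
                                  int stride, int vol_offset, double dt,
                                  int n_vol) {
  const int n = Z.nrow();
  const int T = Z.ncol();
  const int L = hrf.size();
  NumericMatrix Y(n, n_vol);
  const double *zp = REAL(Z), *hp = REAL(hrf);
  double *yp = REAL(Y);
  std::vector<double> acc(n);
  for (int v = 0; v < n_vol; ++v) {
    const int t = vol_offset - 1 + v * stride;  /* 0-based grid index */
    if (t >= T) stop("volume index beyond trajectory length");
    std::fill(acc.begin(), acc.end(), 0.0);
    const int kmax = std::min(L, t + 1);
    for (int k = 0; k < kmax; ++k) {
      const double h = hp[k];
      const double *zcol = zp + (size_t)(t - k) * n;
      for (int i = 0; i < n; ++i) acc[i] += h * zcol[i];
    }
    double *ycol = yp + (size_t)v * n;
    for (int i = 0; i < n; ++i) ycol[i] = acc[i] * dt;
  }
  return Y;
}
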