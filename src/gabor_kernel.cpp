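#include <Rcpp.h>
using namespace Rcpp;

// Project an image patch onto a bank of Gabor receptive fields whose
// coordinates are affinely warped over the regular patch grid, and
// optionally accumulate the weighted filter-gradient sums needed for the
// Jacobian of the warped place token with respect to the six affine
// parameters.
//
// The patch grid is the (2*half+1)^2 square of integer offsets in
// column-major order (x = column offset, y = row offset).  Warped filter
// coordinates are w = B (v - t) with B the inverse linear part.  Because w
// is affine in the grid indices, the Gabor carrier phase is linear and the
// log-envelope quadratic along each column, so both are advanced by
// incremental recurrences instead of per-point transcendental calls.
//
// fv      image values at the grid points (column-major, length side^2)
// side    2*half+1
// B       inverse linear part, length 4: (b11, b12, b21, b22)
// tx, ty  translation
// kx, ky  wave vector of each filter (length n)
// sigma   Gaussian envelope sd of each filter; filters sharing an sd must
//         be contiguous (the envelope is cached per sd block)
// dc      DC-correction constant subtracted inside the envelope
// phase   0 for cosine (even) filters, pi/2 for sine (odd)
// scale   per-filter normalisation constant
//
// Filter model: F(w) = scale * exp(-|w|^2 / (2 sigma^2)) * (cos(k.w - phase) - dc)
//
// Returns s_i = sum_v fv * F_i(w) and, when derivs is true, the six sums
//   P = sum fv Fx wx, Q = sum fv Fx wy, R = sum fv Fy wx, S = sum fv Fy wy,
//   T = sum fv Fx,    U = sum fv Fy
// where (Fx, Fy) is the spatial gradient of F.
// [[Rcpp::export(name = ".gabor_project_cpp")]]
List gabor_project_cpp(NumericVector fv, int side, NumericVector B,
                       double tx, double ty,
                       NumericVector kx, NumericVector ky, NumericVector sigma,
                       NumericVector dc, NumericVector phase,
                       NumericVector scale, bool derivs) {
  const int n = kx.size();
  const int half = (side - 1) / 2;
  const int N = side * side;
  if (fv.size() != N) stop("fv length does not match grid side");
  const double b11 = B[0], b12 = B[1], b21 = B[2], b22 = B[3];
  NumericVector s(n), P(n), Q(n), R(n), S(n), T(n), U(n);

  // per-sd-block cache: envelope, warped coordinates, envelope-weighted image
  std::vector<double> gv(N), cwx(N), cwy(N);
  // warped coordinates are filter-independent; fill once
  for (int j = 0, v = 0; j < side; ++j) {
    const double gx = j - half - tx;
    double wx = b11 * gx + b12 * (-half - ty);
    double wy = b21 * gx + b22 * (-half - ty);
    for (int i = 0; i < side; ++i, ++v) {
      cwx[v] = wx; cwy[v] = wy;
      wx += b12; wy += b22;
    }
  }
  const double dd1 = b12 * b12 + b22 * b22;  // |dw/drow|^2

  double cur_sigma = -1.0;
  for (int f = 0; f < n; ++f) {
    const double kxi = kx[f], kyi = ky[f], sg = sigma[f], dci = dc[f],
                 phi = phase[f], sc = scale[f];
    const double invs2 = 1.0 / (sg * sg);
    if (sg != cur_sigma) {
      cur_sigma = sg;
      // advance the log-envelope quadratically down each column;
      // exponentiate only inside the effective support (log > -21)
      const double ddq = -dd1 * invs2;  // constant second difference
      for (int j = 0, v = 0; j < side; ++j) {
        const double wx0 = cwx[v], wy0 = cwy[v];
        double q = -0.5 * (wx0 * wx0 + wy0 * wy0) * invs2;
        double d = -(wx0 * b12 + wy0 * b22 + 0.5 * dd1) * invs2;
        for (int i = 0; i < side; ++i, ++v) {
          // support cutoff at ~3.6 sigma (envelope ~1.5e-3); -6.51 rather than -6.5
          // so no integer lattice point can sit exactly on the boundary
          gv[v] = (q > -6.51) ? std::exp(q) : 0.0;
          q += d;
          d += ddq;
        }
      }
    }
    // carrier phase advances linearly down each column
    const double dA = kxi * b12 + kyi * b22;
    const double cd = std::cos(dA), sd = std::sin(dA);
    double si = 0, Pi = 0, Qi = 0, Ri = 0, Si = 0, Ti = 0, Ui = 0;
    for (int j = 0, v = 0; j < side; ++j) {
      const double arg0 = kxi * cwx[v] + kyi * cwy[v] - phi;
      double c = std::cos(arg0), sn = std::sin(arg0);
      for (int i = 0; i < side; ++i, ++v) {
        const double g = gv[v];
        if (g > 1e-9) {
          const double fval = fv[v];
          const double cc = c - dci;
          si += fval * sc * g * cc;
          if (derivs) {
            const double wxv = cwx[v], wyv = cwy[v];
            const double Fx = sc * g * (-wxv * invs2 * cc - kxi * sn);
            const double Fy = sc * g * (-wyv * invs2 * cc - kyi * sn);
            const double fFx = fval * Fx, fFy = fval * Fy;
            Pi += fFx * wxv; Qi += fFx * wyv;
            Ri += fFy * wxv; Si += fFy * wyv;
            Ti += fFx;       Ui += fFy;
          }
        }
        const double cn = c * cd - sn * sd;
        sn = sn * cd + c * sd;
        c = cn;
      }
    }
    s[f] = si;
    if (derivs) { P[f] = Pi; Q[f] = Qi; R[f] = Ri; S[f] = Si; T[f] = Ti; U[f] = Ui; }
  }
  if (!derivs) return List::create(_["s"] = s);
  return List::create(_["s"] = s, _["P"] = P, _["Q"] = Q, _["R"] = R,
                      _["S"] = S, _["T"] = T, _["U"] = U);
}

// Bilinear sampling of a matrix at 0-based (x, y) coordinates, where x
// indexes columns and y indexes rows.  Out-of-range coordinates either
// clamp to the border or return `fill`.
// [[Rcpp::export(name = ".bilinear_sample_cpp")]]
NumericVector bilinear_sample_cpp(NumericMatrix img, NumericVector x,
                                  NumericVector y, double fill, bool clamp) {
  const int nr = img.nrow(), nc = img.ncol(), N = x.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    double xi = x[i], yi = y[i];
    if (clamp) {
      if (xi < 0) xi = 0; else if (xi > nc - 1) xi = nc - 1;
      if (yi < 0) yi = 0; else if (yi > nr - 1) yi = nr - 1;
    } else if (xi < 0 || xi > nc - 1 || yi < 0 || yi > nr - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    if (x0 > nc - 2) x0 = nc - 2;
    if (y0 > nr - 2) y0 = nr - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    const double ax = xi - x0, ay = yi - y0;
    const double v00 = img(y0, x0), v01 = img(y0, x0 + 1);
    const double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
    out[i] = (1 - ay) * ((1 - ax) * v00 + ax * v01) +
             ay * ((1 - ax) * v10 + ax * v11);
  }
  return out;
}

static inline double catmull_rom(double t) {
  t = std::fabs(t);
  if (t < 1.0) return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0) return ((-0.5 * t + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}

// Bicubic (Catmull-Rom) sampling; same conventions as bilinear_sample_cpp.
// [[Rcpp::export(name = ".bicubic_sample_cpp")]]
NumericVector bicubic_sample_cpp(NumericMatrix img, NumericVector x,
                                 NumericVector y, double fill, bool clamp) {
  const int nr = img.nrow(), nc = img.ncol(), N = x.size();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    double xi = x[i], yi = y[i];
    if (clamp) {
      if (xi < 0) xi = 0; else if (xi > nc - 1) xi = nc - 1;
      if (yi < 0) yi = 0; else if (yi > nr - 1) yi = nr - 1;
    } else if (xi < 0 || xi > nc - 1 || yi < 0 || yi > nr - 1) {
      out[i] = fill;
      continue;
    }
    const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    const double fx = xi - x0, fy = yi - y0;
    double acc = 0.0, wsum = 0.0;
    for (int dy = -1; dy <= 2; ++dy) {
      int yy = y0 + dy;
      if (yy < 0) yy = 0; else if (yy > nr - 1) yy = nr - 1;
      const double wy = catmull_rom(dy - fy);
      for (int dx = -1; dx <= 2; ++dx) {
        int xx = x0 + dx;
        if (xx < 0) xx = 0; else if (xx > nc - 1) xx = nc - 1;
        const double w = wy * catmull_rom(dx - fx);
        acc += w * img(yy, xx);
        wsum += w;
      }
    }
    out[i] = acc / wsum;
  }
  return out;
}
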