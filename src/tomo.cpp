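#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Ray-driven parallel-beam projector.
// img: N x M matrix, row index = x, col index = y, pixel centres at
//      ((i - (N-1)/2) * dx, (j - (M-1)/2) * dx), dx in micrometres.
// theta: view angles in radians; u: detector coordinates in micrometres.
// step: sampling step along each ray (micrometres).
// Returns line integrals (dimensionless for f in 1/um) of shape
// n_theta x n_u.
// [[Rcpp::export]]
arma::mat cpp_forward_project(const arma::mat& img, double dx,
                              const arma::vec& theta, const arma::vec& u,
                              double step) {
  const int N = img.n_rows, M = img.n_cols;
  const double hx = 0.5 * (N - 1), hy = 0.5 * (M - 1);
  const int na = theta.n_elem, nu = u.n_elem;
  // half-length of the sampled segment: covers the image diagonal
  const double extent = 0.5 * std::sqrt((double)N * N + (double)M * M) * dx
                        + 2.0 * step;
  const int nt = (int)std::ceil(2.0 * extent / step);
  arma::mat out(na, nu, arma::fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(theta[a]), s = std::sin(theta[a]);
    for (int m = 0; m < nu; ++m) {
      const double uu = u[m];
      double acc = 0.0;
      for (int k = 0; k <= nt; ++k) {
        const double t = -extent + k * step;
        const double x = uu * c - t * s;
        const double y = uu * s + t * c;
        const double fx = x / dx + hx, fy = y / dx + hy;
        const int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
        if (ix < -1 || ix > N - 1 || iy < -1 || iy > M - 1) continue;
        const double wx = fx - ix, wy = fy - iy;
        double v = 0.0;
        if (ix >= 0     && iy >= 0)     v += (1 - wx) * (1 - wy) * img(ix, iy);
        if (ix + 1 < N  && iy >= 0)     v += wx * (1 - wy) * img(ix + 1, iy);
        if (ix >= 0     && iy + 1 < M)  v += (1 - wx) * wy * img(ix, iy + 1);
        if (ix + 1 < N  && iy + 1 < M)  v += wx * wy * img(ix + 1, iy + 1);
        acc += v;
      }
      out(a, m) = acc * step;
    }
  }
  return out;
}

// Backprojection of filtered detector rows onto a square grid.
// q: n_theta x n_u filtered sinogram, detector coordinate of column m is
//    (m - (n_u-1)/2) * du (micrometres). dpix: output pixel pitch (um).
// Accumulates linear interpolation of q at u = x cos(theta) + y sin(theta),
// scaled by dtheta (radians).
// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& q, const arma::vec& theta,
                          double du, int nout, double dpix, double dtheta) {
  const int na = q.n_rows, nu = q.n_cols;
  const double uc = 0.5 * (nu - 1), half = 0.5 * (nout - 1);
  arma::mat img(nout, nout, arma::fill::zeros);
  for (int a = 0; a < na; ++a) {
    const double c = std::cos(theta[a]), s = std::sin(theta[a]);
    for (int iy = 0; iy < nout; ++iy) {
      const double y = (iy - half) * dpix;
      for (int ix = 0; ix < nout; ++ix) {
        const double x = (ix - half) * dpix;
        const double fm = (x * c + y * s) / du + uc;
        const int m = (int)std::floor(fm);
        if (m < 0 || m >= nu - 1) continue;
        const double w = fm - m;
        img(ix, iy) += (1 - w) * q(a, m) + w * q(a, m + 1);
      }
    }
  }
  return img * dtheta;
}

// One Gauss-Seidel sweep of the PWLS quadratic, raster order.
// p: current estimate (modified in place semantics via return), phat: noisy
// data, v: per-pixel variance estimates, wsrc: field the neighbour weights
// are computed from (frozen during the sweep).
// Update: p_i <- (phat_i / v_i + 2 beta sum_j w_ij p_j) /
//                (1 / v_i + 2 beta sum_j w_ij)
// [[Rcpp::export]]
arma::mat cpp_pwls_sweep(const arma::mat& p_in, const arma::mat& phat,
                         const arma::mat& v, const arma::mat& wsrc,
                         double beta, double sigma) {
  const int n = p_in.n_rows, m = p_in.n_cols;
  arma::mat p = p_in;
  const double s2 = sigma * sigma;
  // pairwise weights from wsrc: wr(i,j) pairs (i,j)-(i+1,j), wc pairs
  // (i,j)-(i,j+1)
  arma::mat wr(n > 1 ? n - 1 : 0, m), wc(n, m > 1 ? m - 1 : 0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i + 1 < n; ++i) {
      double d = wsrc(i, j) - wsrc(i + 1, j);
      wr(i, j) = std::exp(-(d * d) / s2);
    }
  for (int j = 0; j + 1 < m; ++j)
    for (int i = 0; i < n; ++i) {
      double d = wsrc(i, j) - wsrc(i, j + 1);
      wc(i, j) = std::exp(-(d * d) / s2);
    }
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double num = phat(i, j) / v(i, j);
      double den = 1.0 / v(i, j);
      if (i > 0)     { double w = wr(i - 1, j); num += 2 * beta * w * p(i - 1, j); den += 2 * beta * w; }
      if (i + 1 < n) { double w = wr(i, j);     num += 2 * beta * w * p(i + 1, j); den += 2 * beta * w; }
      if (j > 0)     { double w = wc(i, j - 1); num += 2 * beta * w * p(i, j - 1); den += 2 * beta * w; }
      if (j + 1 < m) { double w = wc(i, j);     num += 2 * beta * w * p(i, j + 1); den += 2 * beta * w; }
      p(i, j) = num / den;
    }
  }
  return p;
}

// Bilinear rotation of an image about its centre (used for consistency
// checks of the discrete projector; 90-degree corpus augmentation uses exact
// permutations instead).
// [[Rcpp::export]]
arma::mat cpp_rotate_image(const arma::mat& img, double angle) {
  const int N = img.n_rows, M = img.n_cols;
  const double hx = 0.5 * (N - 1), hy = 0.5 * (M - 1);
  const double c = std::cos(angle), s = std::sin(angle);
  arma::mat out(N, M, arma::fill::zeros);
  for (int j = 0; j < M; ++j) {
    for (int i = 0; i < N; ++i) {
      // inverse map: source = R(-angle) * target
      const double x = i - hx, y = j - hy;
      const double fx = c * x + s * y + hx;
      const double fy = -s * x + c * y + hy;
      const int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
      if (ix < -1 || ix > N - 1 || iy < -1 || iy > M - 1) continue;
      const double wx = fx - ix, wy = fy - iy;
      double v = 0.0;
      if (ix >= 0    && iy >= 0)    v += (1 - wx) * (1 - wy) * img(ix, iy);
      if (ix + 1 < N && iy >= 0)    v += wx * (1 - wy) * img(ix + 1, iy);
      if (ix >= 0    && iy + 1 < M) v += (1 - wx) * wy * img(ix, iy + 1);
      if (ix + 1 < N && iy + 1 < M) v += wx * wy * img(ix + 1, iy + 1);
      out(i, j) = v;
    }
  }
  return out;
}
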