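#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped-Langevin well-tempered metadynamics in a 2-D CV space.
//
// The history-dependent bias is accumulated on a uniform grid (value plus
// analytic gradient), with bilinear interpolation supplying the per-step
// bias force; Gaussian heights at deposition use the exact kernel sum, so
// the well-tempered damping rule is honoured independently of the grid.

struct Grid {
  double min1, max1, min2, max2, d1, d2;
  int n1, n2;
  std::vector<double> v, gx, gy;

  Grid(double mn1, double mx1, int nn1, double mn2, double mx2, int nn2)
      : min1(mn1), max1(mx1), min2(mn2), max2(mx2), n1(nn1), n2(nn2) {
    d1 = (max1 - min1) / (n1 - 1);
    d2 = (max2 - min2) / (n2 - 1);
    v.assign((size_t)n1 * n2, 0.0);
    gx.assign((size_t)n1 * n2, 0.0);
    gy.assign((size_t)n1 * n2, 0.0);
  }

  inline size_t idx(int i, int j) const { return (size_t)j * n1 + i; }

  // add one Gaussian kernel over a +/- 5 sigma window
  void add_kernel(double c1, double c2, double h, double s1, double s2) {
    int i0 = std::max(0, (int)std::floor((c1 - 5.0 * s1 - min1) / d1));
    int i1 = std::min(n1 - 1, (int)std::ceil((c1 + 5.0 * s1 - min1) / d1));
    int j0 = std::max(0, (int)std::floor((c2 - 5.0 * s2 - min2) / d2));
    int j1 = std::min(n2 - 1, (int)std::ceil((c2 + 5.0 * s2 - min2) / d2));
    for (int j = j0; j <= j1; ++j) {
      double y = min2 + j * d2 - c2;
      double ey = std::exp(-y * y / (2.0 * s2 * s2));
      for (int i = i0; i <= i1; ++i) {
        double x = min1 + i * d1 - c1;
        double g = h * std::exp(-x * x / (2.0 * s1 * s1)) * ey;
        size_t k = idx(i, j);
        v[k] += g;
        gx[k] += -x / (s1 * s1) * g;
        gy[k] += -y / (s2 * s2) * g;
      }
    }
  }

  // bilinear interpolation of (v, gx, gy); zero outside the grid
  void interp(double x, double y, double &vv, double &fx, double &fy) const {
    vv = fx = fy = 0.0;
    if (x < min1 || x > max1 || y < min2 || y > max2) return;
    int i = std::min(n1 - 2, (int)std::floor((x - min1) / d1));
    int j = std::min(n2 - 2, (int)std::floor((y - min2) / d2));
    double tx = (x - (min1 + i * d1)) / d1;
    double ty = (y - (min2 + j * d2)) / d2;
    double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty);
    double w01 = (1 - tx) * ty, w11 = tx * ty;
    size_t k00 = idx(i, j), k10 = idx(i + 1, j);
    size_t k01 = idx(i, j + 1), k11 = idx(i + 1, j + 1);
    vv = w00 * v[k00] + w10 * v[k10] + w01 * v[k01] + w11 * v[k11];
    fx = w00 * gx[k00] + w10 * gx[k10] + w01 * gx[k01] + w11 * gx[k11];
    fy = w00 * gy[k00] + w10 * gy[k10] + w01 * gy[k01] + w11 * gy[k11];
  }
};

static inline void pot_grad(int form, const NumericVector &p, double x,
                            double y, double &u, double &gx, double &gy) {
  if (form == 0) {  // quartic double well: p = (barrier, a, k2)
    double B = p[0], a = p[1], k2 = p[2];
    double q = (x / a) * (x / a) - 1.0;
    u = B * q * q + 0.5 * k2 * y * y;
    gx = 4.0 * B * x * q / (a * a);
    gy = k2 * y;
  } else if (form == 1) {  // harmonic: p = (k1, k2)
    u = 0.5 * p[0] * x * x + 0.5 * p[1] * y * y;
    gx = p[0] * x;
    gy = p[1] * y;
  } else {  // free diffusion
    u = gx = gy = 0.0;
  }
}

// [[Rcpp::export]]
List metad_run_cpp(int form, NumericVector pot_params, double w0,
                   double gamma, int pace, NumericVector sigma, double kT,
                   double friction, double dt, int n_steps,
                   NumericVector s0, NumericVector grid1, NumericVector grid2,
                   int stride, bool use_wall, NumericVector wall,
                   double sanity_bound, bool bias_on) {
  Grid grid(grid1[0], grid1[1], (int)grid1[2], grid2[0], grid2[1],
            (int)grid2[2]);
  double x = s0[0], y = s0[1];
  double s1 = sigma[0], s2 = sigma[1];
  double pref = dt / friction;
  double noise = std::sqrt(2.0 * kT * dt / friction);

  int n_rec = n_steps / stride + 1;
  NumericVector rec_t(n_rec), rec_x(n_rec), rec_y(n_rec), rec_v(n_rec);
  std::vector<double> dep_t, dep_x, dep_y, dep_h;
  int n_dep_max = bias_on ? (n_steps / pace + 1) : 0;
  dep_t.reserve(n_dep_max);
  dep_x.reserve(n_dep_max);
  dep_y.reserve(n_dep_max);
  dep_h.reserve(n_dep_max);

  RNGScope scope;
  int irec = 0;
  double vb, fbx, fby, u, gx, gy;
  grid.interp(x, y, vb, fbx, fby);
  rec_t[0] = 0.0; rec_x[0] = x; rec_y[0] = y; rec_v[0] = vb;
  irec = 1;

  for (int step = 1; step <= n_steps; ++step) {
    pot_grad(form, pot_params, x, y, u, gx, gy);
    grid.interp(x, y, vb, fbx, fby);
    double fx = -gx - fbx, fy = -gy - fby;
    if (use_wall) {  // half-harmonic walls on CV1 at wall[0] (lower), wall[1] (upper)
      if (x < wall[0]) fx += -wall[2] * (x - wall[0]);
      if (x > wall[1]) fx += -wall[2] * (x - wall[1]);
    }
    x += pref * fx + noise * R::norm_rand();
    y += pref * fy + noise * R::norm_rand();
    if (std::fabs(x) > sanity_bound || std::fabs(y) > sanity_bound ||
        !std::isfinite(x) || !std::isfinite(y)) {
      stop("metadynamics trajectory diverged at step %d (|s| > %.1f); "
           "check timestep/friction", step, sanity_bound);
    }
    if (bias_on && step % pace == 0) {
      // exact kernel-sum bias at the deposition point
      double vexact = 0.0;
      for (size_t k = 0; k < dep_t.size(); ++k) {
        double ddx = (x - dep_x[k]) / s1;
        double ddy = (y - dep_y[k]) / s2;
        vexact += dep_h[k] * std::exp(-0.5 * (ddx * ddx + ddy * ddy));
      }
      double h = w0 * std::exp(-vexact / ((gamma - 1.0) * kT));
      dep_t.push_back(step * dt);
      dep_x.push_back(x);
      dep_y.push_back(y);
      dep_h.push_back(h);
      grid.add_kernel(x, y, h, s1, s2);
    }
    if (step % stride == 0) {
      grid.interp(x, y, vb, fbx, fby);
      rec_t[irec] = step * dt;
      rec_x[irec] = x;
      rec_y[irec] = y;
      rec_v[irec] = vb;
      ++irec;
    }
  }

  return List::create(
      _["time"] = rec_t, _["cv1"] = rec_x, _["cv2"] = rec_y,
      _["v_bias"] = rec_v,
      _["dep_time"] = NumericVector(dep_t.begin(), dep_t.end()),
      _["dep_cv1"] = NumericVector(dep_x.begin(), dep_x.end()),
      _["dep_cv2"] = NumericVector(dep_y.begin(), dep_y.end()),
      _["dep_height"] = NumericVector(dep_h.begin(), dep_h.end()));
}

// Exact kernel-sum bias on a set of points (used by FES estimators).
// [[Rcpp::export]]
NumericVector bias_sum_cpp(NumericVector px, NumericVector py,
                           NumericVector kx, NumericVector ky,
                           NumericVector kh, NumericVector ks1,
                           NumericVector ks2) {
  int np = px.size(), nk = kx.size();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double acc = 0.0;
    for (int k = 0; k < nk; ++k) {
      double dx = (px[i] - kx[k]) / ks1[k];
      double dy = (py[i] - ky[k]) / ks2[k];
      acc += kh[k] * std::exp(-0.5 * (dx * dx + dy * dy));
    }
    out[i] = acc;
  }
  return out;
}
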