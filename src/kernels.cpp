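#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sinc(double x) {
  return (std::fabs(x) < 1e-12) ? 1.0 : std::sin(x) / x;
}

// Separable far-field directivity of a square element for a unit direction
// (dx, dy, dz)/r from the element; alam = element_size / wavelength.
// obliq = 0 (rigid baffle) adds nothing; obliq = 1 multiplies by cos(theta).
static inline double directivity(double dx, double dy, double dz, double r,
                                 double alam, int obliq) {
  double d = sinc(M_PI * alam * dx / r) * sinc(M_PI * alam * dy / r);
  if (obliq) d *= dz / r;
  return d;
}

// Voxel-wise maximum over dynamic-focusing sweep events.
//
// For each voxel x (range r), each event steers the array along the unit
// direction u(az, el) = (cos az, cos el, sqrt(1 - cos^2 az - cos^2 el)) with
// focal delays tracking range (focus at p = r * u). The narrowband field value
// at the focal-zone passage time is |sum_i a_i g(d_i) exp(i w d_i)| with
// d_i = (|x - e_i| - |p - e_i|)/c, a_i = directivity_i / r_i and g the
// Gaussian pulse envelope. Events farther than `window` radians from the
// voxel direction in either steering angle are pruned (their value cannot
// exceed the in-window maximum for a sweep step below the beamwidth); the
// nearest event per axis is always retained.
// [[Rcpp::export]]
NumericVector cpp_sweep_max(NumericMatrix vox, NumericMatrix elem,
                            NumericVector az, NumericVector el,
                            double c0, double omega, double sigma_t,
                            double alam, int obliq, double window) {
  const int nv = vox.nrow(), ne = elem.nrow();
  const int na = az.size(), nl = el.size();
  NumericVector out(nv);
  std::vector<double> tau(ne), amp(ne), ex(ne), ey(ne);
  for (int e = 0; e < ne; ++e) { ex[e] = elem(e, 0); ey[e] = elem(e, 1); }
  const double inv2s2 = 1.0 / (2.0 * sigma_t * sigma_t);

  for (int v = 0; v < nv; ++v) {
    const double px = vox(v, 0), py = vox(v, 1), pz = vox(v, 2);
    const double r = std::sqrt(px * px + py * py + pz * pz);
    for (int e = 0; e < ne; ++e) {
      const double dx = px - ex[e], dy = py - ey[e];
      const double ri = std::sqrt(dx * dx + dy * dy + pz * pz);
      tau[e] = ri / c0;
      amp[e] = directivity(dx, dy, pz, ri, alam, obliq) / ri;
    }
    const double av = std::acos(std::max(-1.0, std::min(1.0, px / r)));
    const double lv = std::acos(std::max(-1.0, std::min(1.0, py / r)));

    // candidate index ranges (always at least the nearest event per axis)
    int a_lo = 0, a_hi = na - 1, l_lo = 0, l_hi = nl - 1;
    if (R_finite(window)) {
      a_lo = std::lower_bound(az.begin(), az.end(), av - window) - az.begin();
      a_hi = (std::upper_bound(az.begin(), az.end(), av + window) - az.begin()) - 1;
      l_lo = std::lower_bound(el.begin(), el.end(), lv - window) - el.begin();
      l_hi = (std::upper_bound(el.begin(), el.end(), lv + window) - el.begin()) - 1;
      if (a_hi < a_lo) {  // window missed the grid: take nearest
        int k = std::lower_bound(az.begin(), az.end(), av) - az.begin();
        if (k >= na) k = na - 1;
        if (k > 0 && av - az[k - 1] < az[k] - av) k = k - 1;
        a_lo = a_hi = k;
      }
      if (l_hi < l_lo) {
        int k = std::lower_bound(el.begin(), el.end(), lv) - el.begin();
        if (k >= nl) k = nl - 1;
        if (k > 0 && lv - el[k - 1] < el[k] - lv) k = k - 1;
        l_lo = l_hi = k;
      }
    }

    double best = 0.0;
    for (int ia = a_lo; ia <= a_hi; ++ia) {
      const double ux = std::cos(az[ia]);
      for (int il = l_lo; il <= l_hi; ++il) {
        const double uy = std::cos(el[il]);
        const double s2 = ux * ux + uy * uy;
        if (s2 >= 1.0) continue;  // steering direction outside the hemisphere
        const double uz = std::sqrt(1.0 - s2);
        const double fx = r * ux, fy = r * uy, fz = r * uz;
        double re = 0.0, im = 0.0;
        for (int e = 0; e < ne; ++e) {
          const double dxf = fx - ex[e], dyf = fy - ey[e];
          const double rf = std::sqrt(dxf * dxf + dyf * dyf + fz * fz);
          const double d = tau[e] - rf / c0;
          const double g = amp[e] * std::exp(-d * d * inv2s2);
          const double ph = omega * d;
          re += g * std::cos(ph);
          im += g * std::sin(ph);
        }
        const double val = std::sqrt(re * re + im * im);
        if (val > best) best = val;
      }
    }
    out[v] = best;
  }
  return out;
}

// Splat retarded point-source contributions into per-element impulse trains.
// src: source positions (m), amp: p0 * voxel_volume / (4*pi) per source,
// elem: element positions (z = 0 plane). Each contribution amp/r * D is
// linearly distributed between the two samples bracketing delay r/c.
// Sources closer than r_min to an element are skipped and counted.
// [[Rcpp::export]]
List cpp_splat(NumericMatrix src, NumericVector amp, NumericMatrix elem,
               double c0, double fs, double t0, int nt,
               double alam, int obliq, double r_min) {
  const int ns = src.nrow(), ne = elem.nrow();
  NumericMatrix tr(ne, nt);
  int skipped = 0;
  for (int e = 0; e < ne; ++e) {
    const double ex = elem(e, 0), ey = elem(e, 1);
    for (int s = 0; s < ns; ++s) {
      const double dx = src(s, 0) - ex, dy = src(s, 1) - ey, dz = src(s, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < r_min) { ++skipped; continue; }
      const double a = amp[s] * directivity(dx, dy, dz, r, alam, obliq) / r;
      const double pos = (r / c0 - t0) * fs;
      const int i0 = (int)std::floor(pos);
      if (i0 < 0 || i0 >= nt - 1) continue;
      const double f = pos - i0;
      tr(e, i0) += a * (1.0 - f);
      tr(e, i0 + 1) += a * f;
    }
  }
  return List::create(_["traces"] = tr, _["skipped"] = skipped);
}

// Delay-and-sum on analytic (complex) channel data. For each voxel, sums the
// complex trace of every element sampled at t = r/c with linear inter-sample
// interpolation; returns the magnitude (envelope of the coherent sum).
// Voxels requiring a delay outside the trace support are zeroed and counted.
// [[Rcpp::export]]
List cpp_das(NumericMatrix tr_re, NumericMatrix tr_im, NumericMatrix elem,
             NumericMatrix vox, double c0, double fs, double t0) {
  const int ne = tr_re.nrow(), nt = tr_re.ncol(), nv = vox.nrow();
  NumericVector out(nv);
  int zeroed = 0;
  for (int v = 0; v < nv; ++v) {
    const double px = vox(v, 0), py = vox(v, 1), pz = vox(v, 2);
    double re = 0.0, im = 0.0;
    bool ok = true;
    for (int e = 0; e < ne; ++e) {
      const double dx = px - elem(e, 0), dy = py - elem(e, 1),
                   dz = pz - elem(e, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double pos = (r / c0 - t0) * fs;
      const int i0 = (int)std::floor(pos);
      if (i0 < 0 || i0 >= nt - 1) { ok = false; break; }
      const double f = pos - i0;
      re += tr_re(e, i0) * (1.0 - f) + tr_re(e, i0 + 1) * f;
      im += tr_im(e, i0) * (1.0 - f) + tr_im(e, i0 + 1) * f;
    }
    if (!ok) { ++zeroed; out[v] = 0.0; continue; }
    out[v] = std::sqrt(re * re + im * im);
  }
  return List::create(_["amplitude"] = out, _["zeroed"] = zeroed);
}

static inline double trilinear(const NumericVector &a, int nx, int ny, int nz,
                               double x, double y, double z, bool &ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  double v = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        const double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                         (dk ? fz : 1 - fz);
        v += w * a[(i0 + di) + nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
      }
  return v;
}

// Global gamma index. disp: candidate displacements (m), one per row, sorted
// by increasing norm, first row (0,0,0); dd_abs: absolute dose-difference
// criterion (same units as ref); dta: distance-to-agreement (m). The
// evaluated volume is interpolated trilinearly at x + displacement; candidates
// falling outside the evaluated volume are skipped. Early exit once the pure
// distance term exceeds the current best gamma^2.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector eval,
                        IntegerVector dim, NumericVector spacing,
                        NumericMatrix disp, double dd_abs, double dta) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const int nd = disp.nrow(), nv = ref.size();
  std::vector<double> dist2(nd);
  for (int d = 0; d < nd; ++d) {
    const double rx = disp(d, 0), ry = disp(d, 1), rz = disp(d, 2);
    dist2[d] = (rx * rx + ry * ry + rz * rz) / (dta * dta);
  }
  NumericVector out(nv);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t v = i + nx * (j + (size_t)ny * k);
        double best = R_PosInf;
        for (int d = 0; d < nd; ++d) {
          if (dist2[d] >= best) break;  // sorted: no better candidate left
          bool ok;
          const double ev = trilinear(eval, nx, ny, nz,
                                      i + disp(d, 0) / dx,
                                      j + disp(d, 1) / dy,
                                      k + disp(d, 2) / dz, ok);
          if (!ok) continue;
          const double dd = (ref[v] - ev) / dd_abs;
          const double g2 = dd * dd + dist2[d];
          if (g2 < best) best = g2;
        }
        out[v] = std::sqrt(best);
      }
  return out;
}
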