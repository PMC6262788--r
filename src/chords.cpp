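#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive in-mask chord search on a pixelated xz cell mask.
//
// Candidate endpoints are boundary pixels (4-neighbour touches background
// or the image edge). A chord is admissible when every pixel cell touched
// by the closed segment between the two pixel centres belongs to the mask
// (conservative supercover: grazing a cell corner counts as touching) and
// when its undirected angle from the z-axis, measured in physical um with
// anisotropic pixel spacing, lies within `halfwidth_deg` of `center_deg`
// (wrapped modulo 180). Returns the longest admissible chord; ties are
// broken by smaller |angle - center|, then by lexicographically smaller
// (x1, z1, x2, z2) with endpoints in canonical order.

static const double EPS_T = 1e-12;
static const double EPS_DEG = 1e-7;

// closed segment vs closed unit pixel cell centred at (bx, bz)
static bool seg_box(double x1, double z1, double x2, double z2,
                    double bx, double bz) {
  double t0 = 0.0, t1 = 1.0;
  double dx = x2 - x1, dz = z2 - z1;
  double p[4] = {-dx, dx, -dz, dz};
  double q[4] = {x1 - (bx - 0.5), (bx + 0.5) - x1,
                 z1 - (bz - 0.5), (bz + 0.5) - z1};
  for (int i = 0; i < 4; i++) {
    if (p[i] == 0.0) {
      if (q[i] < 0.0) return false;
    } else {
      double t = q[i] / p[i];
      if (p[i] < 0.0) { if (t > t0) t0 = t; }
      else            { if (t < t1) t1 = t; }
    }
  }
  return t0 <= t1 + EPS_T;
}

// is the segment between pixel centres (0-based) fully inside the mask?
static bool seg_inside(const LogicalMatrix &mask, int x1, int z1,
                       int x2, int z2) {
  int xmin = std::min(x1, x2), xmax = std::max(x1, x2);
  int zmin = std::min(z1, z2), zmax = std::max(z1, z2);
  for (int px = xmin; px <= xmax; px++)
    for (int pz = zmin; pz <= zmax; pz++) {
      if (mask(px, pz)) continue;
      if (seg_box((double)x1, (double)z1, (double)x2, (double)z2,
                  (double)px, (double)pz))
        return false;
    }
  return true;
}

// undirected angle from the z-axis in degrees, range (-90, 90]
static double chord_angle(double dxu, double dzu) {
  if (dzu < 0.0 || (dzu == 0.0 && dxu < 0.0)) { dxu = -dxu; dzu = -dzu; }
  return std::atan2(dxu, dzu) * 180.0 / M_PI;
}

// wrapped angular difference on the 180-degree circle of undirected lines
static double ang_diff(double a, double b) {
  double d = a - b + 90.0;
  d -= 180.0 * std::floor(d / 180.0);   // now in [0, 180)
  return d - 90.0;
}

// [[Rcpp::export(name = ".chord_best_cpp")]]
List chord_best_cpp(LogicalMatrix mask, double sx, double sz,
                    double center_deg, double halfwidth_deg) {
  int nx = mask.nrow(), nz = mask.ncol();
  std::vector<int> bx, bz;
  for (int i = 0; i < nx; i++)
    for (int j = 0; j < nz; j++) {
      if (!mask(i, j)) continue;
      bool edge = (i == 0 || i == nx - 1 || j == 0 || j == nz - 1);
      if (!edge) {
        if (!mask(i - 1, j) || !mask(i + 1, j) ||
            !mask(i, j - 1) || !mask(i, j + 1)) edge = true;
      }
      if (edge) { bx.push_back(i); bz.push_back(j); }
    }
  int nb = (int)bx.size();
  bool found = false;
  double best_len = -1.0, best_dev = 1e9, best_ang = 0.0;
  int e1x = -1, e1z = -1, e2x = -1, e2z = -1;

  for (int a = 0; a < nb; a++) {
    for (int b = a; b < nb; b++) {
      int x1 = bx[a], z1 = bz[a], x2 = bx[b], z2 = bz[b];
      // canonical endpoint order
      if (x2 < x1 || (x2 == x1 && z2 < z1)) {
        std::swap(x1, x2); std::swap(z1, z2);
      }
      double dxu = (x2 - x1) * sx, dzu = (z2 - z1) * sz;
      double ang = chord_angle(dxu, dzu);
      double dev = std::fabs(ang_diff(ang, center_deg));
      if (dev > halfwidth_deg + EPS_DEG) continue;
      double len = std::sqrt(dxu * dxu + dzu * dzu);
      if (found) {
        if (len < best_len) continue;
        if (len == best_len) {
          bool better = false;
          if (dev < best_dev) better = true;
          else if (dev == best_dev) {
            int cur[4] = {x1, z1, x2, z2};
            int old_[4] = {e1x, e1z, e2x, e2z};
            for (int k = 0; k < 4; k++) {
              if (cur[k] < old_[k]) { better = true; break; }
              if (cur[k] > old_[k]) break;
            }
          }
          if (!better) continue;
        }
      }
      if (!seg_inside(mask, x1, z1, x2, z2)) continue;
      found = true;
      best_len = len; best_dev = dev; best_ang = ang;
      e1x = x1; e1z = z1; e2x = x2; e2z = z2;
    }
  }
  return List::create(_["found"] = found,
                      _["length_um"] = best_len,
                      _["angle_deg"] = best_ang,
                      _["x1"] = e1x + 1, _["z1"] = e1z + 1,
                      _["x2"] = e2x + 1, _["z2"] = e2z + 1);
}
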