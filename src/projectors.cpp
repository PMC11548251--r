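// Ray-driven (Joseph) projectors for 2D parallel- and fan-beam geometries.
//
// Conventions (shared with the R layer):
//   * angles in radians here (degrees at the R surface), counterclockwise,
//     0 along +x;
//   * image indexed row-major with pixel centers, physical origin at the
//     grid center; row 0 is the +y edge;
//   * lengths in mm, attenuation in 1/mm, so line integrals are unitless.
//
// back_project() is the literal transpose of forward_project(): same ray
// loops, gather replaced by scatter, so <Fu, y> == <u, F^T y> to rounding.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Geometry {
  bool fan;
  int n_rows, n_cols, n_det;
  double px, ds;      // pixel size, detector bin spacing (mm)
  double sid, sdd;    // source-isocenter / source-detector distances (fan)
  NumericVector angles; // radians
};

static Geometry parse_geom(const List &g) {
  Geometry geom;
  std::string bt = as<std::string>(g["beam_type"]);
  geom.fan = (bt == "fan");
  geom.n_rows = as<int>(g["n_rows"]);
  geom.n_cols = as<int>(g["n_cols"]);
  geom.n_det  = as<int>(g["n_det"]);
  geom.px = as<double>(g["pixel_size"]);
  geom.ds = as<double>(g["det_spacing"]);
  geom.sid = geom.fan ? as<double>(g["source_to_isocenter"]) : 0.0;
  geom.sdd = geom.fan ? as<double>(g["source_to_detector"]) : 0.0;
  geom.angles = as<NumericVector>(g["angles_rad"]);
  return geom;
}

// Ray for view a, detector bin k: origin (ox,oy) + t * (dx,dy), |(dx,dy)| = 1.
static inline void ray_setup(const Geometry &g, double ca, double sa, int k,
                             double &ox, double &oy, double &dx, double &dy) {
  double s = (k - (g.n_det - 1) / 2.0) * g.ds;
  if (!g.fan) {
    dx = ca; dy = sa;
    ox = -s * sa; oy = s * ca;
  } else {
    double sx = -g.sid * ca, sy = -g.sid * sa;           // source
    double cx = (g.sdd - g.sid) * ca, cy = (g.sdd - g.sid) * sa; // det center
    double ex = cx - s * sa, ey = cy + s * ca;           // det bin position
    double vx = ex - sx, vy = ey - sy;
    double n = std::sqrt(vx * vx + vy * vy);
    dx = vx / n; dy = vy / n;
    ox = sx; oy = sy;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix &img, const List &geom_list) {
  Geometry g = parse_geom(geom_list);
  const int n_ang = g.angles.size();
  NumericMatrix sino(n_ang, g.n_det);
  const double cr = (g.n_rows - 1) / 2.0, cc = (g.n_cols - 1) / 2.0;

  for (int a = 0; a < n_ang; ++a) {
    const double ca = std::cos(g.angles[a]), sa = std::sin(g.angles[a]);
    for (int k = 0; k < g.n_det; ++k) {
      double ox, oy, dx, dy;
      ray_setup(g, ca, sa, k, ox, oy, dx, dy);
      double acc = 0.0;
      if (std::fabs(dx) >= std::fabs(dy)) {
        const double w = g.px / std::fabs(dx);
        for (int j = 0; j < g.n_cols; ++j) {
          double x = (j - cc) * g.px;
          double t = (x - ox) / dx;
          double y = oy + t * dy;
          double rf = cr - y / g.px;
          int i0 = (int)std::floor(rf);
          double fr = rf - i0;
          if (i0 >= 0 && i0 < g.n_rows)         acc += (1.0 - fr) * img(i0, j);
          if (i0 + 1 >= 0 && i0 + 1 < g.n_rows) acc += fr * img(i0 + 1, j);
        }
        sino(a, k) = acc * w;
      } else {
        const double w = g.px / std::fabs(dy);
        for (int i = 0; i < g.n_rows; ++i) {
          double y = (cr - i) * g.px;
          double t = (y - oy) / dy;
          double x = ox + t * dx;
          double cf = x / g.px + cc;
          int j0 = (int)std::floor(cf);
          double fr = cf - j0;
          if (j0 >= 0 && j0 < g.n_cols)         acc += (1.0 - fr) * img(i, j0);
          if (j0 + 1 >= 0 && j0 + 1 < g.n_cols) acc += fr * img(i, j0 + 1);
        }
        sino(a, k) = acc * w;
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix &sino, const List &geom_list) {
  Geometry g = parse_geom(geom_list);
  const int n_ang = g.angles.size();
  NumericMatrix img(g.n_rows, g.n_cols);
  const double cr = (g.n_rows - 1) / 2.0, cc = (g.n_cols - 1) / 2.0;

  for (int a = 0; a < n_ang; ++a) {
    const double ca = std::cos(g.angles[a]), sa = std::sin(g.angles[a]);
    for (int k = 0; k < g.n_det; ++k) {
      const double val = sino(a, k);
      if (val == 0.0) continue;
      double ox, oy, dx, dy;
      ray_setup(g, ca, sa, k, ox, oy, dx, dy);
      if (std::fabs(dx) >= std::fabs(dy)) {
        const double v = val * g.px / std::fabs(dx);
        for (int j = 0; j < g.n_cols; ++j) {
          double x = (j - cc) * g.px;
          double t = (x - ox) / dx;
          double y = oy + t * dy;
          double rf = cr - y / g.px;
          int i0 = (int)std::floor(rf);
          double fr = rf - i0;
          if (i0 >= 0 && i0 < g.n_rows)         img(i0, j) += (1.0 - fr) * v;
          if (i0 + 1 >= 0 && i0 + 1 < g.n_rows) img(i0 + 1, j) += fr * v;
        }
      } else {
        const double v = val * g.px / std::fabs(dy);
        for (int i = 0; i < g.n_rows; ++i) {
          double y = (cr - i) * g.px;
          double t = (y - oy) / dy;
          double x = ox + t * dx;
          double cf = x / g.px + cc;
          int j0 = (int)std::floor(cf);
          double fr = cf - j0;
          if (j0 >= 0 && j0 < g.n_cols)         img(i, j0) += (1.0 - fr) * v;
          if (j0 + 1 >= 0 && j0 + 1 < g.n_cols) img(i, j0 + 1) += fr * v;
        }
      }
    }
  }
  return img;
}

// Pixel-driven backprojection used by filtered backprojection. `weights`
// carries the per-view angular weight (radians, already halved for full-turn
// redundancy). For fan beams the classic flat-detector distance weighting
// (sid/t)^2 is applied and the detector coordinate is found by similar
// triangles through the source.
// [[Rcpp::export]]
NumericMatrix cpp_fbp_backproject(const NumericMatrix &filt, const List &geom_list,
                                  const NumericVector &weights) {
  Geometry g = parse_geom(geom_list);
  const int n_ang = g.angles.size();
  NumericMatrix img(g.n_rows, g.n_cols);
  const double cr = (g.n_rows - 1) / 2.0, cc = (g.n_cols - 1) / 2.0;
  const double kc = (g.n_det - 1) / 2.0;

  for (int a = 0; a < n_ang; ++a) {
    const double ca = std::cos(g.angles[a]), sa = std::sin(g.angles[a]);
    const double wa = weights[a];
    for (int i = 0; i < g.n_rows; ++i) {
      const double y = (cr - i) * g.px;
      for (int j = 0; j < g.n_cols; ++j) {
        const double x = (j - cc) * g.px;
        double kf, wpix = wa;
        if (!g.fan) {
          double s = -x * sa + y * ca;
          kf = s / g.ds + kc;
        } else {
          double qx = x + g.sid * ca, qy = y + g.sid * sa; // pixel - source
          double t = qx * ca + qy * sa;                    // along central ray
          if (t <= 0) continue;
          double p = -qx * sa + qy * ca;
          double s = p * g.sdd / t;
          kf = s / g.ds + kc;
          double u = t / g.sid;
          wpix = wa / (u * u);
        }
        int k0 = (int)std::floor(kf);
        double fr = kf - k0;
        double v = 0.0;
        if (k0 >= 0 && k0 < g.n_det)         v += (1.0 - fr) * filt(a, k0);
        if (k0 + 1 >= 0 && k0 + 1 < g.n_det) v += fr * filt(a, k0 + 1);
        img(i, j) += wpix * v;
      }
    }
  }
  return img;
}
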