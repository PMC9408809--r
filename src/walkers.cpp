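// Monte-Carlo random-walk diffusion in a periodic cube populated with
// impermeable cylinders (synthetic myocytes). Cylinders are replicated
// across the periodic faces and binned into a uniform 3D grid so that
// point-membership tests touch only nearby cylinders. All randomness
// comes from R's RNG, so set.seed() on the R side makes runs
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cyl {
  double p1x, p1y, p1z;   // first axis endpoint
  double dx, dy, dz;      // axis vector (p2 - p1)
  double len2;            // |axis|^2
  double r, r2;           // radius, radius^2
};

struct CylGrid {
  double edge;
  int nc;                 // cells per dimension
  double cell;            // cell size
  std::vector<Cyl> cyls;  // replicated cylinders
  std::vector<std::vector<int> > bins;

  CylGrid(const NumericMatrix& M, double edge_, int nc_)
      : edge(edge_), nc(nc_), cell(edge_ / nc_), bins((size_t)nc_ * nc_ * nc_) {
    const int n = M.nrow();
    const double shifts[3] = {-edge, 0.0, edge};
    for (int i = 0; i < n; ++i) {
      double p1[3] = {M(i, 0), M(i, 1), M(i, 2)};
      double p2[3] = {M(i, 3), M(i, 4), M(i, 5)};
      double r = M(i, 6);
      for (int sx = 0; sx < 3; ++sx)
        for (int sy = 0; sy < 3; ++sy)
          for (int sz = 0; sz < 3; ++sz) {
            double o[3] = {shifts[sx], shifts[sy], shifts[sz]};
            double lo[3], hi[3];
            bool inter = true;
            for (int a = 0; a < 3; ++a) {
              double q1 = p1[a] + o[a], q2 = p2[a] + o[a];
              lo[a] = std::min(q1, q2) - r;
              hi[a] = std::max(q1, q2) + r;
              if (hi[a] < 0.0 || lo[a] > edge) { inter = false; break; }
            }
            if (!inter) continue;
            Cyl c;
            c.p1x = p1[0] + o[0]; c.p1y = p1[1] + o[1]; c.p1z = p1[2] + o[2];
            c.dx = p2[0] - p1[0]; c.dy = p2[1] - p1[1]; c.dz = p2[2] - p1[2];
            c.len2 = c.dx * c.dx + c.dy * c.dy + c.dz * c.dz;
            c.r = r; c.r2 = r * r;
            int id = (int)cyls.size();
            cyls.push_back(c);
            int i0[3], i1[3];
            for (int a = 0; a < 3; ++a) {
              i0[a] = std::max(0, (int)std::floor(lo[a] / cell));
              i1[a] = std::min(nc - 1, (int)std::floor(hi[a] / cell));
            }
            for (int ix = i0[0]; ix <= i1[0]; ++ix)
              for (int iy = i0[1]; iy <= i1[1]; ++iy)
                for (int iz = i0[2]; iz <= i1[2]; ++iz)
                  bins[(size_t)(ix * nc + iy) * nc + iz].push_back(id);
          }
    }
  }

  inline double wrap(double x) const {
    double w = std::fmod(x, edge);
    return (w < 0.0) ? w + edge : w;
  }

  // squared distance from point to cylinder axis segment
  inline double dist2(const Cyl& c, double x, double y, double z) const {
    double vx = x - c.p1x, vy = y - c.p1y, vz = z - c.p1z;
    double t = (c.len2 > 0.0)
                   ? (vx * c.dx + vy * c.dy + vz * c.dz) / c.len2
                   : 0.0;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double ex = vx - t * c.dx, ey = vy - t * c.dy, ez = vz - t * c.dz;
    return ex * ex + ey * ey + ez * ez;
  }

  bool inside(double x, double y, double z) const {
    if (cyls.empty()) return false;
    double wx = wrap(x), wy = wrap(y), wz = wrap(z);
    int ix = std::min(nc - 1, (int)(wx / cell));
    int iy = std::min(nc - 1, (int)(wy / cell));
    int iz = std::min(nc - 1, (int)(wz / cell));
    const std::vector<int>& b = bins[(size_t)(ix * nc + iy) * nc + iz];
    for (size_t k = 0; k < b.size(); ++k) {
      const Cyl& c = cyls[b[k]];
      if (dist2(c, wx, wy, wz) <= c.r2) return true;
    }
    return false;
  }

  // index of one cylinder containing the point, or -1
  int which_inside(double x, double y, double z) const {
    if (cyls.empty()) return -1;
    double wx = wrap(x), wy = wrap(y), wz = wrap(z);
    int ix = std::min(nc - 1, (int)(wx / cell));
    int iy = std::min(nc - 1, (int)(wy / cell));
    int iz = std::min(nc - 1, (int)(wz / cell));
    const std::vector<int>& b = bins[(size_t)(ix * nc + iy) * nc + iz];
    for (size_t k = 0; k < b.size(); ++k)
      if (dist2(cyls[b[k]], wx, wy, wz) <= cyls[b[k]].r2) return b[k];
    return -1;
  }
};

int grid_cells(const NumericMatrix& cyl, double edge) {
  double rmax = 0.0;
  for (int i = 0; i < cyl.nrow(); ++i) rmax = std::max(rmax, cyl(i, 6));
  if (rmax <= 0.0) return 1;
  int nc = (int)std::floor(edge / (2.5 * rmax));
  if (nc < 1) nc = 1;
  if (nc > 32) nc = 32;
  return nc;
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix pts, NumericMatrix cyl,
                                double edge) {
  LogicalVector out(pts.nrow());
  if (cyl.nrow() == 0) {
    std::fill(out.begin(), out.end(), false);
    return out;
  }
  CylGrid g(cyl, edge, grid_cells(cyl, edge));
  for (int i = 0; i < pts.nrow(); ++i)
    out[i] = g.inside(pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Random-walk simulation. Walkers are seeded uniformly in the requested
// compartment (intracellular = true seeds inside cylinders), take
// Gaussian (or fixed-length) steps, and steps that would cross a
// membrane are rejected and redrawn (or specularly bounced when
// reflect = true). Positions accumulate unwrapped; the periodic
// structure is honored through wrapped membership tests.
// [[Rcpp::export]]
List cpp_walk(NumericMatrix cyl, double edge, int n_walkers, int n_steps,
              double sigma_step, bool fixed_step, double step_len,
              bool intracellular, bool reflect, int max_redraw) {
  CylGrid* g = NULL;
  if (cyl.nrow() > 0) g = new CylGrid(cyl, edge, grid_cells(cyl, edge));
  NumericMatrix disp(n_walkers, 3);
  NumericMatrix start(n_walkers, 3);
  long long rejected = 0;

  std::vector<double> px(n_walkers), py(n_walkers), pz(n_walkers);
  for (int i = 0; i < n_walkers; ++i) {
    bool placed = false;
    for (int tries = 0; tries < 100000; ++tries) {
      double x = unif_rand() * edge;
      double y = unif_rand() * edge;
      double z = unif_rand() * edge;
      bool in = g ? g->inside(x, y, z) : false;
      if (in == intracellular) {
        px[i] = x; py[i] = y; pz[i] = z;
        start(i, 0) = x; start(i, 1) = y; start(i, 2) = z;
        placed = true;
        break;
      }
    }
    if (!placed) {
      if (g) delete g;
      stop("walker initialization failure: compartment volume too small");
    }
  }

  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < n_walkers; ++i) {
      double dx, dy, dz;
      bool accepted = false;
      for (int att = 0; att <= max_redraw; ++att) {
        dx = norm_rand(); dy = norm_rand(); dz = norm_rand();
        if (fixed_step) {
          double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (nrm < 1e-300) continue;
          dx *= step_len / nrm; dy *= step_len / nrm; dz *= step_len / nrm;
        } else {
          dx *= sigma_step; dy *= sigma_step; dz *= sigma_step;
        }
        double cx = px[i] + dx, cy = py[i] + dy, cz = pz[i] + dz;
        bool in = g ? g->inside(cx, cy, cz) : false;
        if (in == intracellular) {
          px[i] = cx; py[i] = cy; pz[i] = cz;
          accepted = true;
          break;
        }
        if (reflect && g) {
          // single-scatter specular bounce off the violated membrane
          double wx = g->wrap(cx), wy = g->wrap(cy), wz = g->wrap(cz);
          int id = g->which_inside(cx, cy, cz);
          if (id >= 0) {
            const Cyl& c = g->cyls[id];
            double vx = wx - c.p1x, vy = wy - c.p1y, vz = wz - c.p1z;
            double t = (c.len2 > 0.0)
                           ? (vx * c.dx + vy * c.dy + vz * c.dz) / c.len2
                           : 0.0;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
            double ax = c.p1x + t * c.dx, ay = c.p1y + t * c.dy,
                   az = c.p1z + t * c.dz;
            double nx = wx - ax, ny = wy - ay, nz = wz - az;
            double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
            if (nn > 1e-300) {
              nx /= nn; ny /= nn; nz /= nn;
              double pen = c.r - nn;  // penetration depth
              double rx = cx + 2.0 * pen * nx, ry = cy + 2.0 * pen * ny,
                     rz = cz + 2.0 * pen * nz;
              bool in2 = g->inside(rx, ry, rz);
              if (in2 == intracellular) {
                px[i] = rx; py[i] = ry; pz[i] = rz;
                accepted = true;
                break;
              }
            }
          }
        }
        ++rejected;
      }
      // if never accepted the walker stays put this step
      (void)accepted;
    }
  }

  for (int i = 0; i < n_walkers; ++i) {
    disp(i, 0) = px[i] - start(i, 0);
    disp(i, 1) = py[i] - start(i, 1);
    disp(i, 2) = pz[i] - start(i, 2);
  }
  NumericMatrix fin(n_walkers, 3);
  for (int i = 0; i < n_walkers; ++i) {
    fin(i, 0) = px[i]; fin(i, 1) = py[i]; fin(i, 2) = pz[i];
  }
  if (g) delete g;
  return List::create(_["displacements"] = disp, _["start"] = start,
                      _["final"] = fin,
                      _["rejected_steps"] = (double)rejected);
}
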