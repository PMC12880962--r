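#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Voxel grids are R arrays in column-major order: idx = x + nx*(y + ny*z),
// 0-based here. World position of a voxel center = origin + (idx + 0.5)*spacing.

namespace {

struct Dims {
  int nx, ny, nz;
  inline long long idx(int x, int y, int z) const {
    return (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// 26-neighbourhood offsets with their chamfer class (1 face, 2 edge, 3 corner)
struct Offs {
  int dx[26], dy[26], dz[26], cls[26];
  Offs() {
    int k = 0;
    for (int dz_ = -1; dz_ <= 1; ++dz_)
      for (int dy_ = -1; dy_ <= 1; ++dy_)
        for (int dx_ = -1; dx_ <= 1; ++dx_) {
          if (dx_ == 0 && dy_ == 0 && dz_ == 0) continue;
          dx[k] = dx_; dy[k] = dy_; dz[k] = dz_;
          cls[k] = std::abs(dx_) + std::abs(dy_) + std::abs(dz_);
          ++k;
        }
  }
};
static const Offs OFFS;

// ---- simple point test, (26, 6) connectivity pair -------------------------
// nb[27]: 3x3x3 neighbourhood foreground flags, centre at index 13
// (i = (dx+1) + 3*(dy+1) + 9*(dz+1)).

inline int nb27(int dx, int dy, int dz) { return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); }

// number of 26-connected components of foreground within N26 (centre excluded)
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int k = 0; k < 26; ++k) {
        int qx = cx + OFFS.dx[k], qy = cy + OFFS.dy[k], qz = cz + OFFS.dz[k];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1) continue;
        int q = nb27(qx, qy, qz);
        if (q == 13 || !nb[q] || seen[q]) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components within N18 that touch a face
// neighbour of the centre (i.e. are 6-adjacent to the centre)
static int bg_components6(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  static const int fdx[6] = {1, -1, 0, 0, 0, 0};
  static const int fdy[6] = {0, 0, 1, -1, 0, 0};
  static const int fdz[6] = {0, 0, 0, 0, 1, -1};
  for (int f = 0; f < 6; ++f) {
    int s = nb27(fdx[f], fdy[f], fdz[f]);
    if (nb[s] || seen[s]) continue;            // must be background, unvisited
    ++ncomp;
    std::vector<int> stack(1, s);
    seen[s] = true;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      for (int f2 = 0; f2 < 6; ++f2) {
        int qx = cx + fdx[f2], qy = cy + fdy[f2], qz = cz + fdz[f2];
        if (qx < -1 || qx > 1 || qy < -1 || qy > 1 || qz < -1 || qz > 1) continue;
        if (std::abs(qx) + std::abs(qy) + std::abs(qz) > 2) continue; // stay in N18
        int q = nb27(qx, qy, qz);
        if (q == 13 || nb[q] || seen[q]) continue;
        seen[q] = true;
        stack.push_back(q);
      }
    }
  }
  return ncomp;
}

inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static void fill_nb(const std::vector<uint8_t>& fg, const Dims& d,
                    int x, int y, int z, bool nb[27]) {
  for (int dz_ = -1; dz_ <= 1; ++dz_)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        int qx = x + dx_, qy = y + dy_, qz = z + dz_;
        nb[nb27(dx_, dy_, dz_)] =
          d.inside(qx, qy, qz) ? (fg[d.idx(qx, qy, qz)] != 0) : false;
      }
}

static int count_fg_neighbours26(const std::vector<uint8_t>& fg, const Dims& d,
                                 int x, int y, int z) {
  int n = 0;
  for (int k = 0; k < 26; ++k) {
    int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
    if (d.inside(qx, qy, qz) && fg[d.idx(qx, qy, qz)]) ++n;
  }
  return n;
}

} // namespace

// ---- chamfer distance map -------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_chamfer(LogicalVector mask, IntegerVector dims,
                          NumericVector weights) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  double w[4] = {0.0, weights[0], weights[1], weights[2]};
  const double BIG = 1e30;
  std::vector<double> dist(n);
  for (long long i = 0; i < n; ++i) dist[i] = mask[i] ? BIG : 0.0;

  // forward pass: neighbours preceding in raster order
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        long long i = d.idx(x, y, z);
        if (dist[i] == 0.0) continue;
        double best = dist[i];
        for (int k = 0; k < 26; ++k) {
          int dz_ = OFFS.dz[k], dy_ = OFFS.dy[k], dx_ = OFFS.dx[k];
          if (dz_ > 0 || (dz_ == 0 && (dy_ > 0 || (dy_ == 0 && dx_ > 0)))) continue;
          int qx = x + dx_, qy = y + dy_, qz = z + dz_;
          double nd = d.inside(qx, qy, qz) ? dist[d.idx(qx, qy, qz)] : 0.0;
          double cand = nd + w[OFFS.cls[k]];
          if (cand < best) best = cand;
        }
        dist[i] = best;
      }
  // backward pass
  for (int z = d.nz - 1; z >= 0; --z)
    for (int y = d.ny - 1; y >= 0; --y)
      for (int x = d.nx - 1; x >= 0; --x) {
        long long i = d.idx(x, y, z);
        if (dist[i] == 0.0) continue;
        double best = dist[i];
        for (int k = 0; k < 26; ++k) {
          int dz_ = OFFS.dz[k], dy_ = OFFS.dy[k], dx_ = OFFS.dx[k];
          if (dz_ < 0 || (dz_ == 0 && (dy_ < 0 || (dy_ == 0 && dx_ < 0)))) continue;
          int qx = x + dx_, qy = y + dy_, qz = z + dz_;
          double nd = d.inside(qx, qy, qz) ? dist[d.idx(qx, qy, qz)] : 0.0;
          double cand = nd + w[OFFS.cls[k]];
          if (cand < best) best = cand;
        }
        dist[i] = best;
      }

  NumericVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = dist[i];
  out.attr("dim") = dims;
  return out;
}

// ---- distance-ordered homotopic thinning ----------------------------------

// Erode foreground voxels in increasing distance order; a voxel may go only
// if it is a (26,6) simple point and not a line end (<= 1 foreground
// neighbour). Ties broken by voxel index for determinism. Terminal branches
// shorter than min_end_length voxels are pruned afterwards (spur removal).

// [[Rcpp::export]]
LogicalVector cpp_thin(NumericVector distmap, IntegerVector dims,
                       int min_end_length) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  std::vector<uint8_t> fg(n);
  for (long long i = 0; i < n; ++i) fg[i] = distmap[i] > 0 ? 1 : 0;

  // Strict tie-breaking: add a tiny deterministic index-hash perturbation
  // (< one chamfer unit) so distance plateaus become strictly ordered.
  // Anchors are then strict local maxima of the perturbed map: isolated
  // voxels scattered along the medial ridge. They stop free tube ends from
  // being eaten axially, and — being strict maxima — can never be mutually
  // adjacent, so no 2-voxel-thick anchored structure survives.
  std::vector<double> pert(n, 0.0);
  double minpos = 0.0;                // the face step cost on any real mask
  for (long long i = 0; i < n; ++i)
    if (fg[i] && (minpos == 0.0 || distmap[i] < minpos)) minpos = distmap[i];
  // Plateau centrality: voxels surrounded by more >=-distance neighbours sit
  // nearer the middle of their plateau; eroding plateau rims first keeps
  // line ends centred (e.g. on a tube's axis at its end caps).
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        long long i = d.idx(x, y, z);
        if (!fg[i]) continue;
        int ge = 0;
        for (int k = 0; k < 26; ++k) {
          int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
          double nd = d.inside(qx, qy, qz) ? distmap[d.idx(qx, qy, qz)] : 0.0;
          if (nd >= distmap[i]) ++ge;
        }
        uint32_t h = (uint32_t)(i + 1) * 2654435761u;
        h ^= h >> 16;
        pert[i] = distmap[i] + 0.6 * (double)ge / 26.0 +
          0.05 * (double)(h & 0xffffu) / 65535.0;
      }
  std::vector<uint8_t> anchor(n, 0);
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        long long i = d.idx(x, y, z);
        // only strictly interior voxels may anchor: boundary-layer plateaus
        // (e.g. the rim of a tube's end cap) are not medial
        if (!fg[i] || distmap[i] <= minpos) continue;
        bool mx = true;
        for (int k = 0; k < 26 && mx; ++k) {
          int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
          double nd = d.inside(qx, qy, qz) ? pert[d.idx(qx, qy, qz)] : 0.0;
          if (nd > pert[i]) mx = false;
        }
        if (mx) anchor[i] = 1;
      }

  typedef std::pair<double, long long> Q; // (distance, index), min-heap
  bool nb[27];
  // pass 1: distance-ordered erosion, ridge anchors and line ends protected
  {
    std::priority_queue<Q, std::vector<Q>, std::greater<Q> > pq;
    for (long long i = 0; i < n; ++i) if (fg[i] && !anchor[i]) pq.push(Q(pert[i], i));
    while (!pq.empty()) {
      long long i = pq.top().second;
      pq.pop();
      if (!fg[i] || anchor[i]) continue;
      int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
      int nn = count_fg_neighbours26(fg, d, x, y, z);
      if (nn <= 1) continue;                  // protected line end / isolated
      fill_nb(fg, d, x, y, z, nb);
      if (!is_simple(nb)) continue;
      fg[i] = 0;                              // remove; re-examine neighbours
      for (int k = 0; k < 26; ++k) {
        int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
        if (d.inside(qx, qy, qz)) {
          long long q = d.idx(qx, qy, qz);
          if (fg[q] && !anchor[q]) pq.push(Q(pert[q], q));
        }
      }
    }
  }
  // pass 2: synchronous directional cleanup. Anchor plateaus can be 2
  // voxels thick; six border-directed subiterations thin them to 1-wide
  // lines while free line ends retract at most ~1 voxel per cycle (an
  // asynchronous queue would eat thick free-ended columns axially).
  {
    static const int ddx[6] = {1, -1, 0, 0, 0, 0};
    static const int ddy[6] = {0, 0, 1, -1, 0, 0};
    static const int ddz[6] = {0, 0, 0, 0, 1, -1};
    bool changed = true;
    while (changed) {
      changed = false;
      for (int dir = 0; dir < 6; ++dir) {
        std::vector<std::pair<double, long long> > cand;
        for (long long i = 0; i < n; ++i) {
          if (!fg[i]) continue;
          int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
          int qx = x + ddx[dir], qy = y + ddy[dir], qz = z + ddz[dir];
          bool borderHere = !d.inside(qx, qy, qz) || !fg[d.idx(qx, qy, qz)];
          if (borderHere && !anchor[i]) cand.push_back(std::make_pair(pert[i], i));
        }
        std::sort(cand.begin(), cand.end());
        for (size_t c = 0; c < cand.size(); ++c) {
          long long i = cand[c].second;
          if (!fg[i]) continue;
          int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
          int nn = count_fg_neighbours26(fg, d, x, y, z);
          if (nn <= 1) continue;
          fill_nb(fg, d, x, y, z, nb);
          if (!is_simple(nb)) continue;
          fg[i] = 0;
          changed = true;
        }
      }
    }
  }

  // spur pruning: walk from each terminal through degree-2 voxels; if a
  // branch voxel (>= 3 neighbours) is met within < min_end_length steps the
  // walked spur is deleted. Pure lines (terminal to terminal) are kept.
  if (min_end_length > 1) {
    std::vector<long long> terms;
    for (long long i = 0; i < n; ++i) {
      if (!fg[i]) continue;
      int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
      if (count_fg_neighbours26(fg, d, x, y, z) == 1) terms.push_back(i);
    }
    for (size_t t = 0; t < terms.size(); ++t) {
      long long cur = terms[t];
      if (!fg[cur]) continue;
      std::vector<long long> walk;
      long long prev = -1;
      bool hit_branch = false;
      while ((int)walk.size() < min_end_length) {
        walk.push_back(cur);
        int x = (int)(cur % d.nx), y = (int)((cur / d.nx) % d.ny), z = (int)(cur / ((long long)d.nx * d.ny));
        long long nxt = -1;
        int nnb = 0;
        for (int k = 0; k < 26; ++k) {
          int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
          if (!d.inside(qx, qy, qz)) continue;
          long long q = d.idx(qx, qy, qz);
          if (fg[q] && q != cur) {
            ++nnb;
            if (q != prev) nxt = q;
          }
        }
        if (walk.size() > 1 && nnb >= 3) { hit_branch = true; walk.pop_back(); break; }
        if (nxt < 0) break;                   // dead end: pure line
        prev = cur;
        cur = nxt;
      }
      if (hit_branch && (int)walk.size() < min_end_length)
        for (size_t j = 0; j < walk.size(); ++j) fg[walk[j]] = 0;
    }
  }

  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- seeded region growing ------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_region_grow(NumericVector vol, IntegerVector dims,
                              IntegerMatrix seeds0, double low, double high,
                              int connectivity) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  std::vector<uint8_t> in(n, 0);
  std::vector<long long> stack;
  for (int s = 0; s < seeds0.nrow(); ++s) {
    long long i = d.idx(seeds0(s, 0), seeds0(s, 1), seeds0(s, 2));
    if (vol[i] >= low && vol[i] <= high && !in[i]) { in[i] = 1; stack.push_back(i); }
  }
  while (!stack.empty()) {
    long long i = stack.back(); stack.pop_back();
    int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
    for (int k = 0; k < 26; ++k) {
      if (connectivity == 6 && OFFS.cls[k] != 1) continue;
      int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
      if (!d.inside(qx, qy, qz)) continue;
      long long q = d.idx(qx, qy, qz);
      if (!in[q] && vol[q] >= low && vol[q] <= high) { in[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = in[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- connected-component labelling ----------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long long> stack;
  for (long long i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    lab[i0] = ++next;
    stack.assign(1, i0);
    while (!stack.empty()) {
      long long i = stack.back(); stack.pop_back();
      int x = (int)(i % d.nx), y = (int)((i / d.nx) % d.ny), z = (int)(i / ((long long)d.nx * d.ny));
      for (int k = 0; k < 26; ++k) {
        if (connectivity == 6 && OFFS.cls[k] != 1) continue;
        int qx = x + OFFS.dx[k], qy = y + OFFS.dy[k], qz = z + OFFS.dz[k];
        if (!d.inside(qx, qy, qz)) continue;
        long long q = d.idx(qx, qy, qz);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- capsule-union rasterization ------------------------------------------

// segs: list of numeric matrices, columns x, y, z, radius (world mm).
// A voxel is foreground iff its centre lies within the (linearly
// interpolated) radius of any polyline interval.

// [[Rcpp::export]]
LogicalVector cpp_rasterize(List segs, IntegerVector dims,
                            NumericVector spacing, NumericVector origin) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  std::vector<uint8_t> fg(n, 0);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];

  for (int s = 0; s < segs.size(); ++s) {
    NumericMatrix P = segs[s];
    for (int j = 0; j + 1 < P.nrow(); ++j) {
      double ax = P(j, 0), ay = P(j, 1), az = P(j, 2), ar = P(j, 3);
      double bx = P(j + 1, 0), by = P(j + 1, 1), bz = P(j + 1, 2), br = P(j + 1, 3);
      double rmax = std::max(ar, br);
      int x0 = (int)std::floor((std::min(ax, bx) - rmax - ox) / sx - 0.5);
      int x1 = (int)std::ceil((std::max(ax, bx) + rmax - ox) / sx - 0.5);
      int y0 = (int)std::floor((std::min(ay, by) - rmax - oy) / sy - 0.5);
      int y1 = (int)std::ceil((std::max(ay, by) + rmax - oy) / sy - 0.5);
      int z0 = (int)std::floor((std::min(az, bz) - rmax - oz) / sz - 0.5);
      int z1 = (int)std::ceil((std::max(az, bz) + rmax - oz) / sz - 0.5);
      x0 = std::max(x0, 0); y0 = std::max(y0, 0); z0 = std::max(z0, 0);
      x1 = std::min(x1, d.nx - 1); y1 = std::min(y1, d.ny - 1); z1 = std::min(z1, d.nz - 1);
      double ux = bx - ax, uy = by - ay, uz = bz - az;
      double L2 = ux * ux + uy * uy + uz * uz;
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y)
          for (int x = x0; x <= x1; ++x) {
            double px = ox + (x + 0.5) * sx - ax;
            double py = oy + (y + 0.5) * sy - ay;
            double pz = oz + (z + 0.5) * sz - az;
            double t = L2 > 0 ? (px * ux + py * uy + pz * uz) / L2 : 0.0;
            if (t < 0) t = 0; else if (t > 1) t = 1;
            double dx_ = px - t * ux, dy_ = py - t * uy, dz_ = pz - t * uz;
            double r = ar + t * (br - ar);
            if (dx_ * dx_ + dy_ * dy_ + dz_ * dz_ <= r * r)
              fg[d.idx(x, y, z)] = 1;
          }
    }
  }
  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- neighbour counts (skeleton voxels) -----------------------------------

// [[Rcpp::export]]
IntegerVector cpp_neighbour_count26(LogicalVector mask, IntegerVector dims) {
  Dims d{dims[0], dims[1], dims[2]};
  long long n = (long long)d.nx * d.ny * d.nz;
  std::vector<uint8_t> fg(n);
  for (long long i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;
  IntegerVector out(n);
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int x = 0; x < d.nx; ++x) {
        long long i = d.idx(x, y, z);
        out[i] = fg[i] ? count_fg_neighbours26(fg, d, x, y, z) : 0;
      }
  out.attr("dim") = dims;
  return out;
}
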