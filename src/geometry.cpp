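// Voxel geometry kernels: connected-component labelling, separable
// Gaussian smoothing, iso-surface extraction by marching tetrahedra
// (Kuhn 6-tetrahedra cell decomposition, translation-consistent so the
// mesh of a padded mask is closed), exposed voxel-face counting, and a
// stratified bootstrap for paired AUC differences.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// ---------------------------------------------------------------------
// Connected components (6- or 26-neighbourhood), labels 1..n, 0 = background.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  const int noff = (int)offs_i.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int next_label = 0;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int v = lin(i, j, k, nx, ny);
        if (!mask[v] || labels[v] != 0) continue;
        ++next_label;
        labels[v] = next_label;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
          for (int o = 0; o < noff; ++o) {
            int ni = ci + offs_i[o], nj = cj + offs_j[o], nk = ck + offs_k[o];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz)
              continue;
            int nb = lin(ni, nj, nk, nx, ny);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next_label;
              stack.push_back(nb);
            }
          }
        }
      }
  return labels;
}

// ---------------------------------------------------------------------
// Separable Gaussian smoothing; sigma per axis in voxel units.
// Boundary handling renormalizes by in-bounds kernel mass, so constant
// fields are preserved exactly.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out = clone(vol);

  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0.0) continue;
    int radius = (int)std::ceil(3.5 * s);
    if (radius < 1) radius = 1;
    std::vector<double> kern(2 * radius + 1);
    double ksum = 0.0;
    for (int t = -radius; t <= radius; ++t) {
      kern[t + radius] = std::exp(-0.5 * (double)t * t / (s * s));
      ksum += kern[t + radius];
    }
    for (double &w : kern) w /= ksum;

    NumericVector src = clone(out);
    const int stride = strides[axis];
    const int len = sizes[axis];
    // iterate over all lines along `axis`
    int o1 = (axis == 0) ? 1 : 0;          // other axes indices
    int o2 = (axis == 2) ? 1 : 2;
    const int n1 = sizes[o1], n2 = sizes[o2];
    const int s1 = strides[o1], s2 = strides[o2];
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        int base = a * s1 + b * s2;
        for (int p = 0; p < len; ++p) {
          double acc = 0.0, wsum = 0.0;
          int lo = std::max(0, p - radius), hi = std::min(len - 1, p + radius);
          for (int q = lo; q <= hi; ++q) {
            double w = kern[q - p + radius];
            acc += w * src[base + q * stride];
            wsum += w;
          }
          out[base + p * stride] = acc / wsum;
        }
      }
    if (n != nx * ny * nz) stop("internal size error"); // defensive
  }
  return out;
}

// ---------------------------------------------------------------------
// Marching tetrahedra at `level` on a scalar field.  Each grid cell is
// split into 6 tetrahedra around its main diagonal (Kuhn subdivision):
// tetrahedron p = {c, c+e[p0], c+e[p0]+e[p1], c+(1,1,1)} for each
// permutation (p0,p1,p2) of the axes.  Faces on shared cell boundaries
// coincide between neighbours, so surfaces of padded fields are closed.
// Vertices are deduplicated per grid edge; coordinates are spacing-scaled.
// [[Rcpp::export(name = ".march_tetra_cpp")]]
List march_tetra_cpp(NumericVector field, IntegerVector dim,
                     NumericVector spacing, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  static const int perms[6][3] = {
    {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::vector<double> vx, vy, vz;       // vertex coords (mm)
  std::vector<int> tri;                 // triangle vertex indices (0-based)
  std::unordered_map<uint64_t, int> edge_vertex;
  edge_vertex.reserve(1 << 16);

  // returns (deduplicated) vertex index of the crossing on grid edge (ga,gb)
  auto edge_point = [&](int ga, int gb) -> int {
    uint64_t a = (uint64_t)std::min(ga, gb), b = (uint64_t)std::max(ga, gb);
    uint64_t key = (a << 32) | b;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = field[ga], fb = field[gb];
    double t = (level - fa) / (fb - fa);
    int ai = ga % nx, aj = (ga / nx) % ny, ak = ga / (nx * ny);
    int bi = gb % nx, bj = (gb / nx) % ny, bk = gb / (nx * ny);
    double px = (ai + t * (bi - ai)) * sx;
    double py = (aj + t * (bj - aj)) * sy;
    double pz = (ak + t * (bk - ak)) * sz;
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_vertex[key] = id;
    return id;
  };

  int corner[8];  // global linear indices of current cell corners (bit: x|y<<1|z<<2)
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          corner[c] = lin(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1),
                          nx, ny);
          if (field[corner[c]] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int p = 0; p < 6; ++p) {
          int bits[4];
          bits[0] = 0;
          bits[1] = bits[0] | (1 << perms[p][0]);
          bits[2] = bits[1] | (1 << perms[p][1]);
          bits[3] = 7;
          int g[4];
          bool in[4];
          int n_in = 0;
          for (int t = 0; t < 4; ++t) {
            g[t] = corner[bits[t]];
            in[t] = field[g[t]] > level;
            if (in[t]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int t = 0; t < 4; ++t) (in[t] ? ins[ni++] : outs[no++]) = g[t];
          if (n_in == 1) {
            int a = edge_point(ins[0], outs[0]);
            int b = edge_point(ins[0], outs[1]);
            int c = edge_point(ins[0], outs[2]);
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          } else if (n_in == 3) {
            int a = edge_point(ins[0], outs[0]);
            int b = edge_point(ins[1], outs[0]);
            int c = edge_point(ins[2], outs[0]);
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          } else {  // 2 in, 2 out: quad AC-AD-BD-BC split into two triangles
            int pac = edge_point(ins[0], outs[0]);
            int pad = edge_point(ins[0], outs[1]);
            int pbc = edge_point(ins[1], outs[0]);
            int pbd = edge_point(ins[1], outs[1]);
            tri.push_back(pac); tri.push_back(pad); tri.push_back(pbd);
            tri.push_back(pac); tri.push_back(pbd); tri.push_back(pbc);
          }
        }
      }

  const int ntri = (int)tri.size() / 3;
  double area = 0.0;
  for (int t = 0; t < ntri; ++t) {
    int a = tri[3 * t], b = tri[3 * t + 1], c = tri[3 * t + 2];
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double cxp = uy * wz - uz * wy;
    double cyp = uz * wx - ux * wz;
    double czp = ux * wy - uy * wx;
    area += 0.5 * std::sqrt(cxp * cxp + cyp * cyp + czp * czp);
  }

  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = vx[v]; verts(v, 1) = vy[v]; verts(v, 2) = vz[v];
  }
  IntegerMatrix tris(ntri, 3);
  for (int t = 0; t < ntri; ++t) {
    tris(t, 0) = tri[3 * t] + 1;      // 1-based for R
    tris(t, 1) = tri[3 * t + 1] + 1;
    tris(t, 2) = tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris,
                      _["area"] = area);
}

// ---------------------------------------------------------------------
// Total area of voxel faces adjoining a false/outside voxel.
// [[Rcpp::export(name = ".voxel_face_area_cpp")]]
double voxel_face_area_cpp(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double fa_x = spacing[1] * spacing[2];  // face normal to x
  const double fa_y = spacing[0] * spacing[2];
  const double fa_z = spacing[0] * spacing[1];
  double area = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[lin(i, j, k, nx, ny)]) continue;
        if (i == 0 || !mask[lin(i - 1, j, k, nx, ny)]) area += fa_x;
        if (i == nx - 1 || !mask[lin(i + 1, j, k, nx, ny)]) area += fa_x;
        if (j == 0 || !mask[lin(i, j - 1, k, nx, ny)]) area += fa_y;
        if (j == ny - 1 || !mask[lin(i, j + 1, k, nx, ny)]) area += fa_y;
        if (k == 0 || !mask[lin(i, j, k - 1, nx, ny)]) area += fa_z;
        if (k == nz - 1 || !mask[lin(i, j, k + 1, nx, ny)]) area += fa_z;
      }
  return area;
}

// ---------------------------------------------------------------------
// Paired stratified bootstrap of the AUC difference between two score
// vectors over the same cases.  Uses R's RNG so set.seed() applies.
static double auc_pairs(const std::vector<double> &sp,
                        const std::vector<double> &sn) {
  double u = 0.0;
  for (double a : sp)
    for (double b : sn) {
      if (a > b) u += 1.0;
      else if (a == b) u += 0.5;
    }
  return u / ((double)sp.size() * (double)sn.size());
}

// [[Rcpp::export(name = ".boot_auc_diff_cpp")]]
NumericVector boot_auc_diff_cpp(NumericVector s1, NumericVector s2,
                                LogicalVector positive, int nboot) {
  std::vector<int> ipos, ineg;
  for (int i = 0; i < positive.size(); ++i)
    (positive[i] ? ipos : ineg).push_back(i);
  const int n1 = (int)ipos.size(), n0 = (int)ineg.size();
  if (n1 == 0 || n0 == 0) stop("both classes required");
  NumericVector out(nboot);
  std::vector<double> p1(n1), p2(n1), q1(n0), q2(n0);
  for (int b = 0; b < nboot; ++b) {
    for (int t = 0; t < n1; ++t) {
      int pick = ipos[(int)(unif_rand() * n1) % n1];
      p1[t] = s1[pick]; p2[t] = s2[pick];
    }
    for (int t = 0; t < n0; ++t) {
      int pick = ineg[(int)(unif_rand() * n0) % n0];
      q1[t] = s1[pick]; q2[t] = s2[pick];
    }
    out[b] = auc_pairs(p1, q1) - auc_pairs(p2, q2);
  }
  return out;
}
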