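// Interphase chromatin: fixed-step random walks confined to the nucleus
// sphere (radial reflection at the boundary) and rasterization of fiber
// segments onto the 20 nm voxel lattice (3D DDA).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {
inline void iso_dir(double& ux, double& uy, double& uz) {
  double c = 2.0 * unif_rand() - 1.0;
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double ph = 2.0 * M_PI * unif_rand();
  ux = s * std::cos(ph); uy = s * std::sin(ph); uz = c;
}
} // namespace

// [[Rcpp::export]]
List cpp_generate_chromatin(IntegerVector nseg, double RT, double step) {
  long long ntot = 0;
  for (int i = 0; i < nseg.size(); ++i) ntot += nseg[i] + 1;
  NumericVector X((R_xlen_t)ntot), Y((R_xlen_t)ntot), Z((R_xlen_t)ntot);
  IntegerVector F((R_xlen_t)ntot);
  R_xlen_t at = 0;
  for (int f = 0; f < nseg.size(); ++f) {
    double x, y, z;
    // uniform start point in the sphere
    do {
      x = (2.0 * unif_rand() - 1.0) * RT;
      y = (2.0 * unif_rand() - 1.0) * RT;
      z = (2.0 * unif_rand() - 1.0) * RT;
    } while (x * x + y * y + z * z > RT * RT);
    X[at] = x; Y[at] = y; Z[at] = z; F[at] = f + 1; ++at;
    for (int s = 0; s < nseg[f]; ++s) {
      double ux, uy, uz;
      iso_dir(ux, uy, uz);
      x += step * ux; y += step * uy; z += step * uz;
      double r = std::sqrt(x * x + y * y + z * z);
      if (r > RT) {                       // reflect radially about the shell
        double rr = (2.0 * RT - r) / r;
        x *= rr; y *= rr; z *= rr;
      }
      X[at] = x; Y[at] = y; Z[at] = z; F[at] = f + 1; ++at;
    }
  }
  return List::create(_["fiber"] = F, _["x"] = X, _["y"] = Y, _["z"] = Z);
}

namespace {
struct Ent { double key; int fib; int seg; };

// collect voxels crossed by segment p0 -> p1
void raster_segment(std::vector<Ent>& out, double x0, double y0, double z0,
                    double x1, double y1, double z1,
                    double RT, double vox, int N, int fib, int seg) {
  double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
  double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len < 1e-12) {
    int ix = std::min(N - 1, std::max(0, (int)std::floor((x0 + RT) / vox)));
    int iy = std::min(N - 1, std::max(0, (int)std::floor((y0 + RT) / vox)));
    int iz = std::min(N - 1, std::max(0, (int)std::floor((z0 + RT) / vox)));
    out.push_back(Ent{((double)ix * N + iy) * N + iz, fib, seg});
    return;
  }
  double ux = dx / len, uy = dy / len, uz = dz / len;
  double t = 0.0;
  int guard = (int)(len / vox) * 4 + 16;
  while (t < len && guard-- > 0) {
    double tn = len;
    const double pu[3] = {x0, y0, z0};
    const double uu[3] = {ux, uy, uz};
    for (int a = 0; a < 3; ++a) {
      double ua = uu[a];
      if (std::fabs(ua) < 1e-12) continue;
      double w = (pu[a] + t * ua + RT) / vox;
      double dt;
      if (ua > 0) {
        dt = ((std::floor(w) + 1.0) - w) * vox / ua;
      } else {
        double d = w - std::floor(w);
        if (d < 1e-9) d = 1.0;
        dt = d * vox / (-ua);
      }
      if (dt < 1e-12) dt = 1e-12;
      if (t + dt < tn) tn = t + dt;
    }
    double tm = 0.5 * (t + tn);
    int ix = std::min(N - 1, std::max(0,
              (int)std::floor((x0 + tm * ux + RT) / vox)));
    int iy = std::min(N - 1, std::max(0,
              (int)std::floor((y0 + tm * uy + RT) / vox)));
    int iz = std::min(N - 1, std::max(0,
              (int)std::floor((z0 + tm * uz + RT) / vox)));
    out.push_back(Ent{((double)ix * N + iy) * N + iz, fib, seg});
    t = tn;
  }
}

} // namespace

// Rows (ix, iy, iz, fiber, segment) for every voxel a segment passes through.
// [[Rcpp::export]]
List cpp_fiber_voxel_rows(NumericVector x, NumericVector y, NumericVector z,
                          IntegerVector fiber, double RT, double vox) {
  int N = (int)std::lround(2.0 * RT / vox);
  std::vector<Ent> ent;
  ent.reserve(x.size() * 2);
  int seg = 0, cur = -1;
  for (R_xlen_t i = 0; i + 1 < x.size(); ++i) {
    if (fiber[i] != fiber[i + 1]) continue;
    if (fiber[i] != cur) { cur = fiber[i]; seg = 0; }
    ++seg;
    raster_segment(ent, x[i], y[i], z[i], x[i + 1], y[i + 1], z[i + 1],
                   RT, vox, N, fiber[i], seg);
  }
  // drop duplicate (voxel, fiber, segment) rows from boundary grazing
  std::sort(ent.begin(), ent.end(), [](const Ent& a, const Ent& b) {
    if (a.key != b.key) return a.key < b.key;
    if (a.fib != b.fib) return a.fib < b.fib;
    return a.seg < b.seg;
  });
  ent.erase(std::unique(ent.begin(), ent.end(),
                        [](const Ent& a, const Ent& b) {
    return a.key == b.key && a.fib == b.fib && a.seg == b.seg;
  }), ent.end());
  R_xlen_t n = (R_xlen_t)ent.size();
  NumericVector key(n);
  IntegerVector fib(n), sg(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    key[i] = ent[i].key; fib[i] = ent[i].fib; sg[i] = ent[i].seg;
  }
  return List::create(_["key"] = key, _["fiber"] = fib, _["segment"] = sg,
                      _["n_axis"] = N);
}

// CSR occupancy index over unique voxel keys, for the fused simulation path.
// [[Rcpp::export]]
List cpp_occupancy_index(NumericVector key, IntegerVector fiber,
                         IntegerVector segment) {
  // key assumed sorted ascending (output of cpp_fiber_voxel_rows)
  R_xlen_t n = key.size();
  std::vector<double> uk;
  std::vector<int> off;
  uk.reserve(n / 2); off.reserve(n / 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (uk.empty() || uk.back() != key[i]) {
      uk.push_back(key[i]);
      off.push_back((int)i);
    }
  }
  off.push_back((int)n);
  return List::create(_["key"] = NumericVector(uk.begin(), uk.end()),
                      _["offset"] = IntegerVector(off.begin(), off.end()),
                      _["fiber"] = fiber, _["segment"] = segment);
}
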