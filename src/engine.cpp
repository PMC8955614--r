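// Monte Carlo engine: ion chords through a periodic box around a spherical
// nucleus, discrete core energy-deposition events, condensed-history delta
// electron transport, sparse 20 nm voxel scoring and Poisson DSB induction.
// Geometry is nucleus-centered, lengths in micrometers, energies in eV.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geom {
  double RT;   // nucleus radius (um)
  double L;    // PBC box side (um)
  double vox;  // voxel size (um)
  int N;       // voxels per axis over the sphere bounding cube
};

struct Params {
  double f_local;  // fraction of LET deposited as local core events
  double Tcut;     // delta spectrum low cutoff (eV)
  double w0;       // mean core event energy (eV)
  double q;        // energy fraction lost per transport step
  double a_um;     // range-energy coefficient: R(E) = a * E[keV]^p (um)
  double p_exp;
  double fc;       // fraction of electron energy loss in discrete clusters
  double c_lo;     // cluster energy spectrum bounds (eV)
  double c_hi;
};

// centered-box periodic wrap, valid for arbitrary offsets
inline double pwrap(double x, double L) {
  return x - L * std::floor(x / L + 0.5);
}

// Deposit sink. Fused mode accumulates sparse voxel deposits (in-sphere
// only) and per-track imparted energy; events mode records individual
// deposition events anywhere in the box.
struct Collector {
  const Geom* g;
  bool keep_rows;
  std::vector<double> key, e;                 // in-sphere voxel deposits
  std::vector<double> ex, ey, ez, ee;         // event rows
  std::vector<int> etrk, eorig;
  std::vector<double>* track_e;
  int trk;

  Collector(const Geom* gg, bool rows, std::vector<double>* te)
    : g(gg), keep_rows(rows), track_e(te), trk(-1) {}

  inline int vidx(double x) const {
    int i = (int)std::floor((x + g->RT) / g->vox);
    if (i < 0) i = 0;
    if (i >= g->N) i = g->N - 1;
    return i;
  }

  inline void point(double x, double y, double z, double en, int origin) {
    if (en <= 0.0) return;
    double r2 = x * x + y * y + z * z;
    if (r2 <= g->RT * g->RT) {
      double k = ((double)vidx(x) * g->N + vidx(y)) * g->N + vidx(z);
      key.push_back(k);
      e.push_back(en);
      if (track_e && trk >= 0) (*track_e)[trk] += en;
    }
    if (keep_rows) {
      ex.push_back(x); ey.push_back(y); ez.push_back(z); ee.push_back(en);
      etrk.push_back(trk); eorig.push_back(origin);
    }
  }
};

inline void iso_dir(double& ux, double& uy, double& uz) {
  double c = 2.0 * unif_rand() - 1.0;
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  double ph = 2.0 * M_PI * unif_rand();
  ux = s * std::cos(ph); uy = s * std::sin(ph); uz = c;
}

inline void wrap1(double& x, double L) {
  if (x >= 0.5 * L) x -= L;
  else if (x < -0.5 * L) x += L;
}

// Rasterize the sub-path [t0, t1] of the ray p + t*u onto the 20 nm lattice,
// depositing energy proportional to in-voxel path length (3D DDA).
void raster(Collector& C, double px, double py, double pz,
            double ux, double uy, double uz,
            double t0, double t1, double epl, int origin) {
  const double vox = C.g->vox, RT = C.g->RT;
  double t = t0;
  int guard = (int)((t1 - t0) / vox) * 4 + 16;
  while (t < t1 && guard-- > 0) {
    double tn = t1;
    const double pu[3] = {px, py, pz};
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
    double dl = tn - t;
    if (dl > 0) {
      double tm = t + 0.5 * dl;
      C.point(px + tm * ux, py + tm * uy, pz + tm * uz, epl * dl, origin);
    }
    t = tn;
  }
}

// Deposit `edep` uniformly along a path of length s from p in direction u,
// wrapping across box faces when pbc is on.  When sphere_only, only the
// sphere-clipped portions are rasterized (out-of-nucleus dose is discarded).
// Position is advanced in place; returns nothing.
void deposit_segment(Collector& C, double& x, double& y, double& z,
                     double ux, double uy, double uz,
                     double s, double edep, bool pbc, bool sphere_only,
                     int origin) {
  const double L = C.g->L, RT = C.g->RT;
  double epl = edep / s;
  double rem = s;
  int guard = (int)(s / L) * 8 + 64;
  while (rem > 1e-12 && guard-- > 0) {
    double leg = rem;
    if (pbc) {
      if (ux > 1e-12) leg = std::min(leg, (0.5 * L - x) / ux);
      else if (ux < -1e-12) leg = std::min(leg, (-0.5 * L - x) / ux);
      if (uy > 1e-12) leg = std::min(leg, (0.5 * L - y) / uy);
      else if (uy < -1e-12) leg = std::min(leg, (-0.5 * L - y) / uy);
      if (uz > 1e-12) leg = std::min(leg, (0.5 * L - z) / uz);
      else if (uz < -1e-12) leg = std::min(leg, (-0.5 * L - z) / uz);
      if (leg < 1e-12) leg = 1e-12;
    }
    if (sphere_only) {
      double b = x * ux + y * uy + z * uz;
      double c = x * x + y * y + z * z - RT * RT;
      double disc = b * b - c;
      if (disc > 0) {
        double sq = std::sqrt(disc);
        double ta = std::max(0.0, -b - sq), tb = std::min(leg, -b + sq);
        if (tb > ta) raster(C, x, y, z, ux, uy, uz, ta, tb, epl, origin);
      }
    } else {
      raster(C, x, y, z, ux, uy, uz, 0.0, leg, epl, origin);
    }
    x += leg * ux; y += leg * uy; z += leg * uz;
    rem -= leg;
    if (pbc) { wrap1(x, L); wrap1(y, L); wrap1(z, L); }
  }
}

// Condensed-history electron random walk: per step the electron loses a
// fixed fraction q of its energy, spread along the corresponding decrement
// of the residual range R(E) = a*E^p, then scatters isotropically.  The
// residual (< 2*Tcut) is deposited at the final position.  With prune on,
// electrons whose residual range cannot reach the nucleus are dropped.
void transport(Collector& C, double x, double y, double z,
               double ux, double uy, double uz, double E,
               const Params& P, bool pbc, bool prune, bool sphere_only) {
  const double RT = C.g->RT;
  int guard = 10000;
  while (E >= 2.0 * P.Tcut && guard-- > 0) {
    double R = P.a_um * std::pow(E / 1000.0, P.p_exp);
    if (prune) {
      double d = std::sqrt(x * x + y * y + z * z) - RT;
      if (d > R) return;
    }
    double Enew = E * (1.0 - P.q);
    double Rnew = P.a_um * std::pow(Enew / 1000.0, P.p_exp);
    double s = R - Rnew;
    if (s < 1e-9) s = 1e-9;
    double dE = E - Enew;
    // energy-loss straggling: part of the step's loss goes into discrete
    // cluster events (spur/blob analog, 1/T^2 spectrum); the remainder is
    // spread continuously along the step.  The split conserves dE exactly.
    double cont = dE;
    if (P.fc > 0.0 && P.c_lo > 0.0) {
      double chi = std::min(P.c_hi, 0.5 * E);
      if (chi > P.c_lo * 1.5) {
        double cnorm = 1.0 / (1.0 / P.c_lo - 1.0 / chi);
        double cmean = cnorm * std::log(chi / P.c_lo);
        int nc = (int)R::rpois(P.fc * dE / cmean);
        if (nc > 0) {
          std::vector<double> ce(nc), ct(nc);
          double csum = 0.0;
          for (int m = 0; m < nc; ++m) {
            double u = unif_rand();
            ce[m] = 1.0 / (1.0 / P.c_lo - u * (1.0 / P.c_lo - 1.0 / chi));
            ct[m] = unif_rand() * s;
            csum += ce[m];
          }
          double scale = 1.0;
          if (csum > dE) { scale = dE / csum; cont = 0.0; }
          else cont = dE - csum;
          const double Lb = C.g->L;
          for (int m = 0; m < nc; ++m) {
            double cx = x + ct[m] * ux, cy = y + ct[m] * uy,
                   cz = z + ct[m] * uz;
            if (pbc) { cx = pwrap(cx, Lb); cy = pwrap(cy, Lb);
                       cz = pwrap(cz, Lb); }
            C.point(cx, cy, cz, ce[m] * scale, 1);
          }
        }
      }
    }
    if (cont > 0.0)
      deposit_segment(C, x, y, z, ux, uy, uz, s, cont, pbc, sphere_only, 1);
    else {
      // still advance the electron along the step
      x += s * ux; y += s * uy; z += s * uz;
      if (pbc) { wrap1(x, C.g->L); wrap1(y, C.g->L); wrap1(z, C.g->L); }
    }
    E = Enew;
    iso_dir(ux, uy, uz);
  }
  C.point(x, y, z, E, 1);
}

// Inverse-CDF draw from dN/dT ~ 1/T^2 truncated to [Tcut, Tmax].
inline double draw_delta_T(double Tcut, double Tmax) {
  double u = unif_rand();
  return 1.0 / (1.0 / Tcut - u * (1.0 / Tcut - 1.0 / Tmax));
}

inline double mean_delta_T(double Tcut, double Tmax) {
  double C = 1.0 / (1.0 / Tcut - 1.0 / Tmax);
  return C * std::log(Tmax / Tcut);
}

struct Chord {
  double x, y, z;       // start point
  double ux, uy, uz;
  bool direct;
};

// Does the wrapped length-L chord pass through the nucleus?
bool chord_hits_sphere(const Geom& g, double x, double y, double z,
                       double ux, double uy, double uz, bool pbc) {
  double rem = g.L;
  int guard = 64;
  while (rem > 1e-12 && guard-- > 0) {
    double leg = rem;
    if (pbc) {
      if (ux > 1e-12) leg = std::min(leg, (0.5 * g.L - x) / ux);
      else if (ux < -1e-12) leg = std::min(leg, (-0.5 * g.L - x) / ux);
      if (uy > 1e-12) leg = std::min(leg, (0.5 * g.L - y) / uy);
      else if (uy < -1e-12) leg = std::min(leg, (-0.5 * g.L - y) / uy);
      if (uz > 1e-12) leg = std::min(leg, (0.5 * g.L - z) / uz);
      else if (uz < -1e-12) leg = std::min(leg, (-0.5 * g.L - z) / uz);
      if (leg < 1e-12) leg = 1e-12;
    }
    double b = x * ux + y * uy + z * uz;
    double c = x * x + y * y + z * z - g.RT * g.RT;
    double disc = b * b - c;
    if (disc > 0) {
      double sq = std::sqrt(disc);
      double ta = std::max(0.0, -b - sq), tb = std::min(leg, -b + sq);
      if (tb > ta) return true;
    }
    x += leg * ux; y += leg * uy; z += leg * uz;
    rem -= leg;
    if (pbc) { wrap1(x, g.L); wrap1(y, g.L); wrap1(z, g.L); }
  }
  return false;
}

// Simulate one full track: core events along the sphere-clipped chord plus
// delta electrons emitted along the whole chord.
void simulate_track(Collector& C, const Geom& g, const Params& P,
                    const Chord& ch, double LET_keV_um, double Tmax,
                    bool pbc, bool prune, bool sphere_only) {
  const double LET_eV = LET_keV_um * 1000.0;
  // walk wrapped legs once, storing start points and lengths
  double x = ch.x, y = ch.y, z = ch.z;
  double rem = g.L;
  std::vector<double> lx, ly, lz, ll;
  int guard = 64;
  while (rem > 1e-12 && guard-- > 0) {
    double leg = rem;
    if (pbc) {
      if (ch.ux > 1e-12) leg = std::min(leg, (0.5 * g.L - x) / ch.ux);
      else if (ch.ux < -1e-12) leg = std::min(leg, (-0.5 * g.L - x) / ch.ux);
      if (ch.uy > 1e-12) leg = std::min(leg, (0.5 * g.L - y) / ch.uy);
      else if (ch.uy < -1e-12) leg = std::min(leg, (-0.5 * g.L - y) / ch.uy);
      if (ch.uz > 1e-12) leg = std::min(leg, (0.5 * g.L - z) / ch.uz);
      else if (ch.uz < -1e-12) leg = std::min(leg, (-0.5 * g.L - z) / ch.uz);
      if (leg < 1e-12) leg = 1e-12;
    }
    lx.push_back(x); ly.push_back(y); lz.push_back(z); ll.push_back(leg);
    x += leg * ch.ux; y += leg * ch.uy; z += leg * ch.uz;
    rem -= leg;
    if (pbc) { wrap1(x, g.L); wrap1(y, g.L); wrap1(z, g.L); }
  }
  // core events: along the sphere-clipped chord in fused mode (out-of-
  // nucleus core dose can never be scored), along the whole chord otherwise
  if (ch.direct || !sphere_only) {
    for (size_t i = 0; i < ll.size(); ++i) {
      double ta = 0.0, tb = ll[i];
      if (sphere_only) {
        double b = lx[i] * ch.ux + ly[i] * ch.uy + lz[i] * ch.uz;
        double c = lx[i] * lx[i] + ly[i] * ly[i] + lz[i] * lz[i] -
                   g.RT * g.RT;
        double disc = b * b - c;
        if (disc <= 0) continue;
        double sq = std::sqrt(disc);
        ta = std::max(0.0, -b - sq); tb = std::min(ll[i], -b + sq);
        if (tb <= ta) continue;
      }
      double lam = P.f_local * LET_eV * (tb - ta) / P.w0;
      int n = (int)R::rpois(lam);
      for (int kk = 0; kk < n; ++kk) {
        double t = ta + unif_rand() * (tb - ta);
        double en = R::rexp(P.w0);
        C.point(lx[i] + t * ch.ux, ly[i] + t * ch.uy, lz[i] + t * ch.uz,
                en, 0);
      }
    }
  }
  // delta electrons along the whole chord
  double Tm = mean_delta_T(P.Tcut, Tmax);
  double lam_d = (1.0 - P.f_local) * LET_eV * g.L / Tm;
  int nd = (int)R::rpois(lam_d);
  for (int kk = 0; kk < nd; ++kk) {
    double s = unif_rand() * g.L;
    // locate emission point on the wrapped chord
    size_t i = 0;
    while (i + 1 < ll.size() && s > ll[i]) { s -= ll[i]; ++i; }
    double exq = lx[i] + s * ch.ux, eyq = ly[i] + s * ch.uy,
           ezq = lz[i] + s * ch.uz;
    double T = draw_delta_T(P.Tcut, Tmax);
    double ux, uy, uz;
    iso_dir(ux, uy, uz);
    transport(C, exq, eyq, ezq, ux, uy, uz, T, P, pbc, prune, sphere_only);
  }
}

} // namespace

//' @name microca-internal
//' @keywords internal
// [[Rcpp::export]]
List cpp_transport_electron(NumericVector origin, NumericVector direction,
                            double energy, double RT, double L, double vox,
                            double Tcut, double q, double a_um, double p_exp,
                            double fc, double c_lo, double c_hi,
                            bool pbc, bool prune) {
  Geom g{RT, L, vox, (int)std::lround(2.0 * RT / vox)};
  Params P{0.5, Tcut, 60.0, q, a_um, p_exp, fc, c_lo, c_hi};
  Collector C(&g, true, nullptr);
  double nu = std::sqrt(direction[0] * direction[0] +
                        direction[1] * direction[1] +
                        direction[2] * direction[2]);
  transport(C, origin[0], origin[1], origin[2],
            direction[0] / nu, direction[1] / nu, direction[2] / nu,
            energy, P, pbc, prune, false);
  return List::create(_["x"] = C.ex, _["y"] = C.ey, _["z"] = C.ez,
                      _["energy"] = C.ee);
}

// mode: 0 = all tracks, 1 = direct only, 2 = indirect only
// Occupancy arrays (sorted keys + CSR offsets into fiber/segment lists) may
// be zero-length, in which case no breaks are induced.
// [[Rcpp::export]]
List cpp_simulate_run(NumericVector bin_phi, NumericVector bin_LET,
                      NumericVector bin_Tmax,
                      double RT, double L, double vox,
                      double f_local, double Tcut, double w0, double q,
                      double a_um, double p_exp,
                      double fc, double c_lo, double c_hi,
                      int mode, bool axis_z, bool pbc, bool prune,
                      bool sphere_only, bool keep_events,
                      NumericVector occ_key, IntegerVector occ_off,
                      IntegerVector occ_fib, IntegerVector occ_seg,
                      double k_break, double e_thresh,
                      bool want_breaks, bool want_voxels) {
  Geom g{RT, L, vox, (int)std::lround(2.0 * RT / vox)};
  Params P{f_local, Tcut, w0, q, a_um, p_exp, fc, c_lo, c_hi};
  const int nb = bin_phi.size();
  double phi_tot = 0.0;
  std::vector<double> cum(nb);
  for (int i = 0; i < nb; ++i) { phi_tot += bin_phi[i]; cum[i] = phi_tot; }
  if (phi_tot <= 0.0) stop("empty spectrum: total fluence must be positive");

  std::vector<double> track_e;
  Collector C(&g, keep_events, &track_e);

  std::vector<int> track_cat, track_bin;

  // number of primary chords
  double lam;
  if (mode == 1 && axis_z) lam = phi_tot * M_PI * RT * RT;
  else if (mode == 2 && axis_z) lam = phi_tot * (L * L - M_PI * RT * RT);
  else lam = phi_tot * L * L;
  int nchord = (int)R::rpois(lam);

  for (int ic = 0; ic < nchord; ++ic) {
    // draw source bin
    int b = 0;
    if (nb > 1) {
      double u = unif_rand() * phi_tot;
      b = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (b >= nb) b = nb - 1;
    }
    Chord ch;
    if (axis_z) {
      ch.ux = 0.0; ch.uy = 0.0; ch.uz = 1.0;
      ch.z = -0.5 * L;
      if (mode == 1) {
        double r = RT * std::sqrt(unif_rand());
        double ph = 2.0 * M_PI * unif_rand();
        ch.x = r * std::cos(ph); ch.y = r * std::sin(ph);
        ch.direct = true;
      } else if (mode == 2) {
        do {
          ch.x = (unif_rand() - 0.5) * L;
          ch.y = (unif_rand() - 0.5) * L;
        } while (ch.x * ch.x + ch.y * ch.y <= RT * RT);
        ch.direct = false;
      } else {
        ch.x = (unif_rand() - 0.5) * L;
        ch.y = (unif_rand() - 0.5) * L;
        ch.direct = (ch.x * ch.x + ch.y * ch.y <= RT * RT);
      }
    } else {
      ch.x = (unif_rand() - 0.5) * L;
      ch.y = (unif_rand() - 0.5) * L;
      ch.z = (unif_rand() - 0.5) * L;
      iso_dir(ch.ux, ch.uy, ch.uz);
      ch.direct = chord_hits_sphere(g, ch.x, ch.y, ch.z,
                                    ch.ux, ch.uy, ch.uz, pbc);
      if (mode == 1 && !ch.direct) continue;
      if (mode == 2 && ch.direct) continue;
    }
    int trk = (int)track_cat.size();
    track_cat.push_back(ch.direct ? 0 : 1);
    track_bin.push_back(b + 1);
    track_e.push_back(0.0);
    C.trk = trk;
    simulate_track(C, g, P, ch, bin_LET[b], bin_Tmax[b], pbc, prune,
                   sphere_only);
  }

  // aggregate sparse voxel deposits (sorted by key: deterministic order)
  std::vector<int> ord(C.key.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int bb) {
    return C.key[a] < C.key[bb];
  });
  std::vector<double> vkey, ven;
  vkey.reserve(ord.size()); ven.reserve(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    double kk = C.key[ord[i]], en = C.e[ord[i]];
    if (!vkey.empty() && vkey.back() == kk) ven.back() += en;
    else { vkey.push_back(kk); ven.push_back(en); }
  }

  // DSB induction on voxels that hold both energy and chromatin
  std::vector<double> bx, by, bz, bkey;
  std::vector<int> bfib, bseg;
  std::vector<int> bcomplex;
  double elig = 0.0;
  const int nocc = occ_key.size();
  if (nocc > 0) {
    const double* ok = occ_key.begin();
    for (size_t i = 0; i < vkey.size(); ++i) {
      const double* it = std::lower_bound(ok, ok + nocc, vkey[i]);
      if (it == ok + nocc || *it != vkey[i]) continue;
      int j = (int)(it - ok);
      double E = ven[i];
      elig += E;
      if (want_breaks && k_break > 0.0) {
        int n = (int)R::rpois(k_break * E);
        if (n > 0) {
          int lo = occ_off[j], hi = occ_off[j + 1];
          long long ki = (long long)vkey[i];
          int iz = (int)(ki % g.N); ki /= g.N;
          int iy = (int)(ki % g.N); ki /= g.N;
          int ix = (int)ki;
          double cx = (ix + 0.5) * vox - RT;
          double cy = (iy + 0.5) * vox - RT;
          double cz = (iz + 0.5) * vox - RT;
          for (int m = 0; m < n; ++m) {
            int pick = lo + (int)(unif_rand() * (hi - lo));
            if (pick >= hi) pick = hi - 1;
            bkey.push_back(vkey[i]);
            bx.push_back(cx); by.push_back(cy); bz.push_back(cz);
            bfib.push_back(occ_fib[pick]); bseg.push_back(occ_seg[pick]);
            bcomplex.push_back(E > e_thresh ? 1 : 0);
          }
        }
      }
    }
  }

  double e_dir = 0.0, e_ind = 0.0;
  for (size_t i = 0; i < track_e.size(); ++i) {
    if (track_cat[i] == 0) e_dir += track_e[i]; else e_ind += track_e[i];
  }

  List out = List::create(
    _["track_cat"] = track_cat,
    _["track_eps"] = track_e,
    _["track_bin"] = track_bin,
    _["e_dir"] = e_dir, _["e_ind"] = e_ind,
    _["elig_energy"] = elig,
    _["breaks"] = List::create(
      _["key"] = bkey, _["x"] = bx, _["y"] = by, _["z"] = bz,
      _["fiber"] = bfib, _["segment"] = bseg, _["complex"] = bcomplex));
  if (want_voxels)
    out["voxels"] = List::create(_["key"] = vkey, _["energy"] = ven);
  if (keep_events)
    out["events"] = List::create(
      _["track"] = C.etrk, _["x"] = C.ex, _["y"] = C.ey, _["z"] = C.ez,
      _["energy"] = C.ee, _["origin"] = C.eorig);
  return out;
}
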