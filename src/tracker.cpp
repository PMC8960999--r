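// Probabilistic streamline propagation over a multi-fibre orientation field.
//
// Conventions shared with the R layer:
//  - voxel indices are 0-based; the affine maps integer voxel coordinates to
//    voxel centres, so the voxel containing a continuous world point is the
//    nearest integer under the inverse affine;
//  - fibre population selection: on the first step, sample proportionally to
//    the volume fractions; afterwards pick the population (above the fraction
//    floor) whose mean direction maximises |dot| with the previous direction;
//  - sampled directions perturb the mean by a Gaussian polar angle (the
//    population's dispersion, degrees) with uniform azimuth, then sign-align
//    with the previous direction;
//  - a step is accepted only if cos(previous, new) >= curvature threshold;
//  - all randomness comes from R's RNG, so set.seed() makes runs exact.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Field {
  const double *dirs, *frac, *disp;
  int nx, ny, nz, K;
  R_xlen_t nvox() const { return (R_xlen_t)nx * ny * nz; }
  R_xlen_t lin(int i, int j, int k) const {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  }
  bool inside(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
};

struct Xform {
  double inv[12];  // rows of the 3x4 inverse affine
  void voxelOf(const double p[3], double v[3]) const {
    for (int r = 0; r < 3; ++r)
      v[r] = inv[4 * r] * p[0] + inv[4 * r + 1] * p[1] + inv[4 * r + 2] * p[2] +
             inv[4 * r + 3];
  }
  bool containing(const double p[3], int ijk[3], const Field &f) const {
    double v[3];
    voxelOf(p, v);
    for (int r = 0; r < 3; ++r) ijk[r] = (int)std::lround(v[r]);
    return f.inside(ijk[0], ijk[1], ijk[2]);
  }
};

inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Perturb unit vector m by polar angle theta ~ N(0, sd) with uniform azimuth.
void perturb(const double m[3], double sd_rad, double out[3]) {
  if (sd_rad <= 0) { out[0] = m[0]; out[1] = m[1]; out[2] = m[2]; return; }
  double theta = norm_rand() * sd_rad;
  double phi = unif_rand() * 2.0 * M_PI;
  // orthonormal basis perpendicular to m
  double e[3] = {1, 0, 0};
  if (std::fabs(m[0]) > 0.9) { e[0] = 0; e[1] = 1; }
  double u1[3] = {m[1] * e[2] - m[2] * e[1], m[2] * e[0] - m[0] * e[2],
                  m[0] * e[1] - m[1] * e[0]};
  double n = std::sqrt(dot3(u1, u1));
  for (int c = 0; c < 3; ++c) u1[c] /= n;
  double u2[3] = {m[1] * u1[2] - m[2] * u1[1], m[2] * u1[0] - m[0] * u1[2],
                  m[0] * u1[1] - m[1] * u1[0]};
  double ct = std::cos(theta), st = std::sin(theta), cp = std::cos(phi),
         sp = std::sin(phi);
  for (int c = 0; c < 3; ++c)
    out[c] = ct * m[c] + st * (cp * u1[c] + sp * u2[c]);
}

// Draw an orientation at voxel (i,j,k). Returns false if no population has
// fraction >= floor. prev == nullptr marks the first step.
bool sampleOrientation(const Field &f, int i, int j, int k, const double *prev,
                       double fracFloor, double out[3]) {
  R_xlen_t v = f.lin(i, j, k), nvox = f.nvox();
  int chosen = -1;
  if (prev == nullptr) {
    double tot = 0;
    for (int q = 0; q < f.K; ++q) {
      double fr = f.frac[v + nvox * q];
      if (fr >= fracFloor && fr > 0) tot += fr;
    }
    if (tot <= 0) return false;
    double u = unif_rand() * tot, acc = 0;
    for (int q = 0; q < f.K; ++q) {
      double fr = f.frac[v + nvox * q];
      if (fr >= fracFloor && fr > 0) {
        acc += fr;
        if (u <= acc) { chosen = q; break; }
      }
    }
    if (chosen < 0) chosen = f.K - 1;
  } else {
    double best = -1;
    for (int q = 0; q < f.K; ++q) {
      double fr = f.frac[v + nvox * q];
      if (fr < fracFloor || fr <= 0) continue;
      double m[3] = {f.dirs[v + nvox * (0 + 3 * q)],
                     f.dirs[v + nvox * (1 + 3 * q)],
                     f.dirs[v + nvox * (2 + 3 * q)]};
      double a = std::fabs(dot3(m, prev));
      if (a > best) { best = a; chosen = q; }
    }
    if (chosen < 0) return false;
  }
  double m[3] = {f.dirs[v + nvox * (0 + 3 * chosen)],
                 f.dirs[v + nvox * (1 + 3 * chosen)],
                 f.dirs[v + nvox * (2 + 3 * chosen)]};
  double sd = f.disp[v + nvox * chosen] * M_PI / 180.0;
  perturb(m, sd, out);
  if (prev != nullptr && dot3(out, prev) < 0)
    for (int c = 0; c < 3; ++c) out[c] = -out[c];
  return true;
}

enum Status { ACCEPTED = 0, REJ_CURV = 1, REJ_EXCL = 2, REJ_WAY = 3,
              TERMINATED = 4 };
enum Stop { STOP_NONE = 0, STOP_GRID = 1, STOP_NOORIENT = 2, STOP_TERMMASK = 3,
            STOP_MAXSTEPS = 4 };

struct TrackState {
  std::vector<int> *stamp;      // per-voxel streamline stamp for dedup
  std::vector<R_xlen_t> *visited;
  int id;
  std::vector<const int *> way;
  std::vector<char> waySeen;
  const int *excl, *term;
  bool rejected;
  int rejStatus;
  bool sawTerm;
  NumericMatrix *points;        // optional point recording
  std::vector<double> pts;      // x,y,z triples in visit order

  // returns false if propagation must stop at this voxel
  bool visitVoxel(const Field &f, R_xlen_t v) {
    if (excl && excl[v]) { rejected = true; rejStatus = REJ_EXCL; return false; }
    if ((*stamp)[v] != id) { (*stamp)[v] = id; visited->push_back(v); }
    for (size_t w = 0; w < way.size(); ++w)
      if (way[w][v]) waySeen[w] = 1;
    if (term && term[v]) { sawTerm = true; return false; }
    return true;
  }
};

// Propagate one half-track from `p0` with initial direction `d0` (already
// sign-set). Appends recorded points (excluding the seed itself).
int runHalf(const Field &f, const Xform &x, TrackState &st, const double p0[3],
            const double d0[3], double stepSize, int maxSteps,
            double curvThresh, double fracFloor, bool record) {
  double p[3] = {p0[0], p0[1], p0[2]};
  double prev[3] = {d0[0], d0[1], d0[2]};
  for (int s = 0; s < maxSteps; ++s) {
    for (int c = 0; c < 3; ++c) p[c] += prev[c] * stepSize;
    int ijk[3];
    if (!x.containing(p, ijk, f)) return STOP_GRID;
    if (record) { st.pts.push_back(p[0]); st.pts.push_back(p[1]); st.pts.push_back(p[2]); }
    if (!st.visitVoxel(f, f.lin(ijk[0], ijk[1], ijk[2])))
      return st.rejected ? STOP_NONE : STOP_TERMMASK;
    double nd[3];
    if (!sampleOrientation(f, ijk[0], ijk[1], ijk[2], prev, fracFloor, nd))
      return STOP_NOORIENT;
    if (dot3(nd, prev) < curvThresh) {
      st.rejected = true;
      st.rejStatus = REJ_CURV;
      return STOP_NONE;
    }
    for (int c = 0; c < 3; ++c) prev[c] = nd[c];
  }
  return STOP_MAXSTEPS;
}

// Run one full bidirectional streamline. Returns the final status.
int runStreamline(const Field &f, const Xform &x, TrackState &st,
                  const double seed[3], double stepSize, int maxSteps,
                  double curvThresh, double fracFloor, bool record,
                  int stops[2]) {
  st.rejected = false;
  st.rejStatus = -1;
  st.sawTerm = false;
  std::fill(st.waySeen.begin(), st.waySeen.end(), 0);
  int ijk[3];
  stops[0] = stops[1] = STOP_NONE;
  if (!x.containing(seed, ijk, f)) return REJ_WAY;  // seed off-grid
  bool proceed = st.visitVoxel(f, f.lin(ijk[0], ijk[1], ijk[2]));
  if (st.rejected) return st.rejStatus;
  double d0[3];
  if (!proceed ||
      !sampleOrientation(f, ijk[0], ijk[1], ijk[2], nullptr, fracFloor, d0)) {
    // seed in the termination mask or no orientation: dead streamline,
    // waypoint logic decides the status
  } else {
    size_t mark = st.pts.size();
    stops[0] = runHalf(f, x, st, seed, d0, stepSize, maxSteps, curvThresh,
                       fracFloor, record);
    if (!st.rejected) {
      // reverse the first half so recorded points run end-to-end
      if (record && st.pts.size() > mark) {
        std::vector<double> tail(st.pts.begin() + mark, st.pts.end());
        st.pts.resize(mark);
        for (R_xlen_t q = (R_xlen_t)tail.size() / 3 - 1; q >= 0; --q) {
          st.pts.push_back(tail[3 * q]);
          st.pts.push_back(tail[3 * q + 1]);
          st.pts.push_back(tail[3 * q + 2]);
        }
      }
      if (record) { st.pts.push_back(seed[0]); st.pts.push_back(seed[1]); st.pts.push_back(seed[2]); }
      double dneg[3] = {-d0[0], -d0[1], -d0[2]};
      stops[1] = runHalf(f, x, st, seed, dneg, stepSize, maxSteps, curvThresh,
                         fracFloor, record);
    }
  }
  if (st.rejected) return st.rejStatus;
  for (size_t w = 0; w < st.way.size(); ++w)
    if (!st.waySeen[w]) return st.sawTerm ? TERMINATED : REJ_WAY;
  return ACCEPTED;
}

Field makeField(const NumericVector &dirs, const NumericVector &frac,
                const NumericVector &disp, const IntegerVector &dims, int K) {
  Field f;
  f.dirs = REAL(dirs);
  f.frac = REAL(frac);
  f.disp = REAL(disp);
  f.nx = dims[0];
  f.ny = dims[1];
  f.nz = dims[2];
  f.K = K;
  return f;
}

Xform makeXform(const NumericMatrix &invAffine) {
  Xform x;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) x.inv[4 * r + c] = invAffine(r, c);
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericVector dirs, NumericVector frac, NumericVector disp,
               IntegerVector dims, int K, IntegerMatrix seeds, List waypoints,
               Nullable<IntegerVector> exclusion,
               Nullable<IntegerVector> termination, NumericMatrix invAffine,
               NumericMatrix affine, int samplesPerVoxel, double curvThresh,
               double stepSize, int maxSteps, double fracFloor) {
  Field f = makeField(dirs, frac, disp, dims, K);
  Xform x = makeXform(invAffine);
  R_xlen_t nvox = f.nvox();

  std::vector<int> stamp(nvox, -1);
  std::vector<R_xlen_t> visited;
  TrackState st;
  st.stamp = &stamp;
  st.visited = &visited;
  for (R_xlen_t w = 0; w < waypoints.size(); ++w)
    st.way.push_back(INTEGER((SEXP)waypoints[w]));
  st.waySeen.assign(st.way.size(), 0);
  IntegerVector exclV, termV;
  st.excl = nullptr;
  st.term = nullptr;
  if (exclusion.isNotNull()) { exclV = exclusion.get(); st.excl = INTEGER(exclV); }
  if (termination.isNotNull()) { termV = termination.get(); st.term = INTEGER(termV); }

  NumericVector map(nvox, 0.0);
  double *mp = REAL(map);
  std::vector<double> statusCount(5, 0.0);
  int id = 0, stops[2];
  R_xlen_t total = (R_xlen_t)seeds.nrow() * samplesPerVoxel;

  for (int sv = 0; sv < seeds.nrow(); ++sv) {
    double vx[3] = {(double)seeds(sv, 0), (double)seeds(sv, 1),
                    (double)seeds(sv, 2)};
    double seedW[3];
    for (int r = 0; r < 3; ++r)
      seedW[r] = affine(r, 0) * vx[0] + affine(r, 1) * vx[1] +
                 affine(r, 2) * vx[2] + affine(r, 3);
    for (int rep = 0; rep < samplesPerVoxel; ++rep) {
      st.id = id;
      visited.clear();
      int status = runStreamline(f, x, st, seedW, stepSize, maxSteps,
                                 curvThresh, fracFloor, false, stops);
      statusCount[status] += 1;
      if (status == ACCEPTED)
        for (size_t q = 0; q < visited.size(); ++q) mp[visited[q]] += 1.0;
      ++id;
    }
    if (sv % 16 == 0) Rcpp::checkUserInterrupt();
  }
  if (total > 0)
    for (R_xlen_t q = 0; q < nvox; ++q) mp[q] /= (double)total;
  map.attr("dim") = dims;
  return List::create(
      _["map"] = map, _["total"] = (double)total,
      _["counts"] = NumericVector::create(
          _["accepted"] = statusCount[0], _["rejected_curvature"] = statusCount[1],
          _["rejected_exclusion"] = statusCount[2],
          _["rejected_waypoint"] = statusCount[3],
          _["terminated"] = statusCount[4]));
}

// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(NumericVector dirs, NumericVector frac, NumericVector disp,
                   IntegerVector dims, int K, NumericVector seedPoint,
                   List waypoints, Nullable<IntegerVector> exclusion,
                   Nullable<IntegerVector> termination,
                   NumericMatrix invAffine, double curvThresh, double stepSize,
                   int maxSteps, double fracFloor) {
  Field f = makeField(dirs, frac, disp, dims, K);
  Xform x = makeXform(invAffine);
  std::vector<int> stamp(f.nvox(), -1);
  std::vector<R_xlen_t> visited;
  TrackState st;
  st.stamp = &stamp;
  st.visited = &visited;
  for (R_xlen_t w = 0; w < waypoints.size(); ++w)
    st.way.push_back(INTEGER((SEXP)waypoints[w]));
  st.waySeen.assign(st.way.size(), 0);
  IntegerVector exclV, termV;
  st.excl = nullptr;
  st.term = nullptr;
  if (exclusion.isNotNull()) { exclV = exclusion.get(); st.excl = INTEGER(exclV); }
  if (termination.isNotNull()) { termV = termination.get(); st.term = INTEGER(termV); }
  st.id = 0;
  double seed[3] = {seedPoint[0], seedPoint[1], seedPoint[2]};
  int stops[2];
  int status = runStreamline(f, x, st, seed, stepSize, maxSteps, curvThresh,
                             fracFloor, true, stops);
  R_xlen_t np = (R_xlen_t)st.pts.size() / 3;
  NumericMatrix pts(np, 3);
  for (R_xlen_t q = 0; q < np; ++q)
    for (int c = 0; c < 3; ++c) pts(q, c) = st.pts[3 * q + c];
  const char *statusNames[5] = {"accepted", "rejected_curvature",
                                "rejected_exclusion", "rejected_waypoint",
                                "terminated"};
  const char *stopNames[5] = {"none", "grid_exit", "no_orientation",
                              "termination_mask", "max_steps"};
  return List::create(_["points"] = pts,
                      _["status"] = std::string(statusNames[status]),
                      _["stop_reasons"] = CharacterVector::create(
                          stopNames[stops[0]], stopNames[stops[1]]));
}

// [[Rcpp::export(name = ".sample_orientation_cpp")]]
NumericVector sample_orientation_cpp(NumericVector dirs, NumericVector frac,
                                     NumericVector disp, IntegerVector dims,
                                     int K, IntegerVector voxel,
                                     Nullable<NumericVector> prev,
                                     double fracFloor) {
  Field f = makeField(dirs, frac, disp, dims, K);
  double out[3];
  bool ok;
  if (prev.isNotNull()) {
    NumericVector pv = prev.get();
    double p[3] = {pv[0], pv[1], pv[2]};
    ok = sampleOrientation(f, voxel[0], voxel[1], voxel[2], p, fracFloor, out);
  } else {
    ok = sampleOrientation(f, voxel[0], voxel[1], voxel[2], nullptr, fracFloor,
                           out);
  }
  if (!ok) return NumericVector(0);
  return NumericVector::create(out[0], out[1], out[2]);
}
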