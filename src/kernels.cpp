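// Compiled kernels: trilinear grid interpolation, the Eq.-3/Eq.-11 style
// pair energy, the B22 lattice scan and the Brownian dynamics loop.
// Units throughout: A, ps, kcal/mol, elementary charge e.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double COULOMB_KCAL = 332.063713;  // e^2/(4 pi eps0) in kcal*A/mol

// ---------------------------------------------------------------------------
// grids

struct Grid {
  std::vector<double> v;
  double o[3];
  double h;
  double cutoff;
  int n[3];
  bool present;
  Grid() : h(0), cutoff(0), present(false) { o[0]=o[1]=o[2]=0; n[0]=n[1]=n[2]=0; }
};

static Grid grid_from_list(SEXP gsexp) {
  Grid g;
  if (Rf_isNull(gsexp)) return g;
  List gl(gsexp);
  NumericVector vals = gl["values"];
  IntegerVector dim = vals.attr("dim");
  g.n[0] = dim[0]; g.n[1] = dim[1]; g.n[2] = dim[2];
  g.v.assign(vals.begin(), vals.end());
  NumericVector o = gl["origin"];
  g.o[0] = o[0]; g.o[1] = o[1]; g.o[2] = o[2];
  g.h = as<double>(gl["spacing"]);
  g.cutoff = as<double>(gl["cutoff_radius"]);
  g.present = true;
  return g;
}

// node-centered trilinear interpolation; ok=false when outside the box
static inline double grid_tri(const Grid& g, double x, double y, double z, bool& ok) {
  double t[3] = { (x - g.o[0]) / g.h, (y - g.o[1]) / g.h, (z - g.o[2]) / g.h };
  int id[3]; double f[3];
  for (int a = 0; a < 3; ++a) {
    if (!(t[a] >= 0.0 && t[a] <= (double)(g.n[a] - 1))) { ok = false; return 0.0; }
    int i = (int)std::floor(t[a]);
    if (i > g.n[a] - 2) i = g.n[a] - 2;
    id[a] = i; f[a] = t[a] - i;
  }
  ok = true;
  const double* V = g.v.data();
  const size_t nx = g.n[0], ny = g.n[1];
  size_t base = id[0] + nx * (id[1] + ny * (size_t)id[2]);
  const double* p0 = V + base;
  const double* p1 = p0 + nx * ny;
  double c00 = p0[0] * (1 - f[0]) + p0[1] * f[0];
  double c10 = p0[nx] * (1 - f[0]) + p0[nx + 1] * f[0];
  double c01 = p1[0] * (1 - f[0]) + p1[1] * f[0];
  double c11 = p1[nx] * (1 - f[0]) + p1[nx + 1] * f[0];
  double c0 = c00 * (1 - f[1]) + c10 * f[1];
  double c1 = c01 * (1 - f[1]) + c11 * f[1];
  return c0 * (1 - f[2]) + c1 * f[2];
}

// [[Rcpp::export]]
NumericVector cpp_grid_value(List grid, NumericMatrix pts) {
  Grid g = grid_from_list(grid);
  int m = pts.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    bool ok;
    double val = grid_tri(g, pts(i, 0), pts(i, 1), pts(i, 2), ok);
    out[i] = ok ? val : NA_REAL;
  }
  return out;
}

// soft-core inverse-power grid: sum_a eps*(sigma_a/d)^n, capped
// [[Rcpp::export]]
NumericVector cpp_inverse_power_grid(NumericMatrix apos, NumericVector sigma,
                                     double eps, double expo,
                                     NumericVector origin, double spacing,
                                     IntegerVector shape, double cap) {
  int nx = shape[0], ny = shape[1], nz = shape[2];
  int na = apos.nrow();
  NumericVector out((size_t)nx * ny * nz);
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = origin[0] + i * spacing;
        double s = 0.0;
        for (int a = 0; a < na; ++a) {
          double dx = x - apos(a, 0), dy = y - apos(a, 1), dz = z - apos(a, 2);
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < 1e-9) { s = cap; break; }
          s += eps * std::pow(sigma[a] / d, expo);
          if (s >= cap) { s = cap; break; }
        }
        out[idx] = s > cap ? cap : s;
      }
    }
  }
  // note: filled x-fastest == R column-major order for dim c(nx,ny,nz)
  return out;
}

// ---------------------------------------------------------------------------
// species / pair energies

struct Species {
  std::vector<double> apos;   // 3*na, body frame (x,y,z per atom)
  std::vector<double> sasa;   // na
  std::vector<double> cpos;   // 3*nc effective charges
  std::vector<double> q, q2;  // nc
  Grid el, edes, npd, sc;
  double z, a_dh, extent;
  int na, nc;
};

static Species species_from_list(List sp) {
  Species s;
  NumericMatrix ap = sp["atom_pos"];
  s.na = ap.nrow();
  s.apos.resize(3 * s.na);
  for (int i = 0; i < s.na; ++i)
    for (int k = 0; k < 3; ++k) s.apos[3 * i + k] = ap(i, k);
  NumericVector sa = sp["sasa"];
  s.sasa.assign(sa.begin(), sa.end());
  NumericMatrix cp = sp["charge_pos"];
  s.nc = cp.nrow();
  s.cpos.resize(3 * s.nc);
  for (int i = 0; i < s.nc; ++i)
    for (int k = 0; k < 3; ++k) s.cpos[3 * i + k] = cp(i, k);
  NumericVector qq = sp["charge_q"];
  s.q.assign(qq.begin(), qq.end());
  s.q2.resize(s.nc);
  for (int i = 0; i < s.nc; ++i) s.q2[i] = s.q[i] * s.q[i];
  List gr = sp["grids"];
  s.el = grid_from_list(gr.containsElementNamed("electrostatic") ? gr["electrostatic"] : R_NilValue);
  s.edes = grid_from_list(gr.containsElementNamed("edesolv") ? gr["edesolv"] : R_NilValue);
  s.npd = grid_from_list(gr.containsElementNamed("npdesolv") ? gr["npdesolv"] : R_NilValue);
  s.sc = grid_from_list(gr.containsElementNamed("softcore") ? gr["softcore"] : R_NilValue);
  s.z = as<double>(sp["z"]);
  s.a_dh = as<double>(sp["a_dh"]);
  s.extent = 0.0;
  for (int i = 0; i < s.na; ++i) {
    double r2 = s.apos[3*i]*s.apos[3*i] + s.apos[3*i+1]*s.apos[3*i+1] + s.apos[3*i+2]*s.apos[3*i+2];
    if (r2 > s.extent) s.extent = r2;
  }
  for (int i = 0; i < s.nc; ++i) {
    double r2 = s.cpos[3*i]*s.cpos[3*i] + s.cpos[3*i+1]*s.cpos[3*i+1] + s.cpos[3*i+2]*s.cpos[3*i+2];
    if (r2 > s.extent) s.extent = r2;
  }
  s.extent = std::sqrt(s.extent);
  return s;
}

static inline void quat_to_rot(const double* q, double R[9]) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

static inline void rot_apply(const double R[9], const double* v, double* out) {
  out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
  out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
  out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

static inline void rot_applyT(const double R[9], const double* v, double* out) {
  out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2];
  out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2];
  out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2];
}

struct PairTerms {
  double el, dh, edes, npd, sc;
  double total() const { return el + dh + edes + npd + sc; }
};

// screened-Coulomb PMF; below contact a steep finite ramp stands in for the
// hard-overlap +Inf so finite-difference forces stay finite
static inline double dh_energy(double d, double zz, double a, double kappa, double epsr) {
  if (zz == 0.0) return 0.0;
  if (d < a) {
    double wc = COULOMB_KCAL * zz / (epsr * a * (1.0 + kappa * a));
    return wc + 1000.0 * (a - d);
  }
  return COULOMB_KCAL * zz * std::exp(-kappa * (d - a)) / (epsr * d * (1.0 + kappa * a));
}

// one-directional sum of field-of-A times sources-of-B; pts of B given by
// disp (center B - center A, lab) and rotations RA, RB
static double sum_on_grid(const Grid& gA, const double RA[9], const double RB[9],
                          const double* disp,
                          const std::vector<double>& srcpos,
                          const std::vector<double>& weight, int n) {
  double s = 0.0;
  double cut2 = gA.cutoff * gA.cutoff;
  for (int i = 0; i < n; ++i) {
    if (weight[i] == 0.0) continue;
    double lab[3], b[3], p[3];
    rot_apply(RB, &srcpos[3 * i], lab);
    p[0] = lab[0] + disp[0]; p[1] = lab[1] + disp[1]; p[2] = lab[2] + disp[2];
    double r2 = p[0] * p[0] + p[1] * p[1] + p[2] * p[2];
    if (r2 >= cut2) continue;  // isotropic per-source cutoff
    rot_applyT(RA, p, b);
    bool ok;
    double val = grid_tri(gA, b[0], b[1], b[2], ok);
    if (ok) s += weight[i] * val;
  }
  return s;
}

static PairTerms pair_terms(const Species& A, const Species& B,
                            const double RA[9], const double RB[9],
                            const double* disp, double kappa, double epsr,
                            bool use_dh, double dh_cutoff) {
  PairTerms t; t.el = t.dh = t.edes = t.npd = t.sc = 0.0;
  double d = std::sqrt(disp[0]*disp[0] + disp[1]*disp[1] + disp[2]*disp[2]);
  double ndisp[3] = { -disp[0], -disp[1], -disp[2] };
  double Rswitch = 0.0;
  if (A.el.present && B.el.present) Rswitch = std::min(A.el.cutoff, B.el.cutoff);
  if (d < Rswitch) {
    t.el = 0.5 * (sum_on_grid(A.el, RA, RB, disp, B.cpos, B.q, B.nc) +
                  sum_on_grid(B.el, RB, RA, ndisp, A.cpos, A.q, A.nc));
  } else if (use_dh && d <= dh_cutoff) {
    t.dh = dh_energy(d, A.z * B.z, A.a_dh + B.a_dh, kappa, epsr);
  }
  if (A.edes.present && d < A.edes.cutoff + B.extent)
    t.edes += sum_on_grid(A.edes, RA, RB, disp, B.cpos, B.q2, B.nc);
  if (B.edes.present && d < B.edes.cutoff + A.extent)
    t.edes += sum_on_grid(B.edes, RB, RA, ndisp, A.cpos, A.q2, A.nc);
  if (A.npd.present && d < A.npd.cutoff + B.extent)
    t.npd += sum_on_grid(A.npd, RA, RB, disp, B.apos, B.sasa, B.na);
  if (B.npd.present && d < B.npd.cutoff + A.extent)
    t.npd += sum_on_grid(B.npd, RB, RA, ndisp, A.apos, A.sasa, A.na);
  if (A.sc.present && d < A.sc.cutoff + B.extent) {
    std::vector<double> ones(B.na, 1.0);
    t.sc += sum_on_grid(A.sc, RA, RB, disp, B.apos, ones, B.na);
  }
  if (B.sc.present && d < B.sc.cutoff + A.extent) {
    std::vector<double> ones(A.na, 1.0);
    t.sc += sum_on_grid(B.sc, RB, RA, ndisp, A.apos, ones, A.na);
  }
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_pair_terms(List spA, List spB, NumericVector quatA, NumericVector quatB,
                             NumericVector disp, double kappa, double epsr,
                             bool use_dh, double dh_cutoff) {
  Species A = species_from_list(spA), B = species_from_list(spB);
  double RA[9], RB[9];
  quat_to_rot(quatA.begin(), RA);
  quat_to_rot(quatB.begin(), RB);
  double dv[3] = { disp[0], disp[1], disp[2] };
  PairTerms t = pair_terms(A, B, RA, RB, dv, kappa, epsr, use_dh, dh_cutoff);
  return NumericVector::create(_["electrostatic_grid"] = t.el, _["dh_tail"] = t.dh,
                               _["edesolv"] = t.edes, _["npdesolv"] = t.npd,
                               _["softcore"] = t.sc);
}

// energies at a set of displacement vertices, both solutes at identity
// orientation (the lattice protocol)
// [[Rcpp::export]]
NumericVector cpp_lattice_energies(List spA, List spB, NumericMatrix offsets,
                                   double kappa, double epsr,
                                   bool use_dh, double dh_cutoff) {
  Species A = species_from_list(spA), B = species_from_list(spB);
  double RI[9] = {1,0,0, 0,1,0, 0,0,1};
  int m = offsets.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double dv[3] = { offsets(i, 0), offsets(i, 1), offsets(i, 2) };
    PairTerms t = pair_terms(A, B, RI, RI, dv, kappa, epsr, use_dh, dh_cutoff);
    out[i] = t.total();
  }
  return out;
}

// ---------------------------------------------------------------------------
// hydrodynamic models (duplicated in R; engine uses these)

static inline double tokuyama_ratio(double phi) {
  if (phi <= 0) return 1.0;
  double b = std::sqrt(9.0 * phi / 8.0), c = 11.0 * phi / 16.0;
  double H = 2.0 * b * b / (1.0 - b) - c / (1.0 + 2.0 * c)
           - b * c * (2.0 + c) / ((1.0 + c) * (1.0 - b + c));
  return 1.0 / (1.0 + H);
}

static inline double cichocki_ratio(double phi) {
  if (phi <= 0) return 1.0;
  return 1.0 - 0.631 * phi - 0.726 * phi * phi;
}

// two-sphere lens (intersection) volume
static inline double lens_volume(double d, double r1, double r2) {
  if (d >= r1 + r2) return 0.0;
  double rmin = std::min(r1, r2);
  if (d <= std::fabs(r1 - r2)) return 4.0 * M_PI * rmin * rmin * rmin / 3.0;
  double s = r1 + r2 - d;
  return M_PI * s * s * (d * d + 2.0 * d * (r1 + r2) - 3.0 * (r1 - r2) * (r1 - r2)) / (12.0 * d);
}

// ---------------------------------------------------------------------------
// BD loop

static inline void quat_mul(const double* p, const double* q, double* out) {
  out[0] = p[0]*q[0] - p[1]*q[1] - p[2]*q[2] - p[3]*q[3];
  out[1] = p[0]*q[1] + p[1]*q[0] + p[2]*q[3] - p[3]*q[2];
  out[2] = p[0]*q[2] - p[1]*q[3] + p[2]*q[0] + p[3]*q[1];
  out[3] = p[0]*q[3] + p[1]*q[2] - p[2]*q[1] + p[3]*q[0];
}

static inline void quat_from_rotvec(const double* v, double* q) {
  double a = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  double h, c;
  if (a < 1e-8) { c = 1.0 - a * a / 8.0; h = 0.5 - a * a / 48.0; }
  else { c = std::cos(a / 2.0); h = std::sin(a / 2.0) / a; }
  q[0] = c; q[1] = h * v[0]; q[2] = h * v[1]; q[3] = h * v[2];
}

static inline void min_image(double* d, double side, bool periodic) {
  if (!periodic) return;
  for (int k = 0; k < 3; ++k) d[k] -= side * std::floor(d[k] / side + 0.5);
}

// [[Rcpp::export]]
List cpp_simulate(List speciesList, IntegerVector spIdx,
                  NumericMatrix pos0, NumericMatrix quat0,
                  double boxSide, bool periodic,
                  double kappa, double epsr, double kBT,
                  double dt, int nSteps, int recordStride,
                  bool useDH, double dhCutoff,
                  bool useHydro, double Rcut, bool selfPhi, int phiStride,
                  NumericVector D0t, NumericVector D0r,
                  NumericVector stokes, NumericVector volume,
                  double delta, double dtheta) {
  int nsp = speciesList.size();
  std::vector<Species> sp;
  sp.reserve(nsp);
  for (int i = 0; i < nsp; ++i) sp.push_back(species_from_list(speciesList[i]));

  const int N = pos0.nrow();
  std::vector<int> si(N);
  for (int i = 0; i < N; ++i) si[i] = spIdx[i] - 1;

  // per species-pair: switch radius and max reach of grid terms (+ FD margin)
  std::vector<double> reach(nsp * nsp), rswitch(nsp * nsp);
  for (int a = 0; a < nsp; ++a)
    for (int b = 0; b < nsp; ++b) {
      const Species &A = sp[a], &B = sp[b];
      double rs = (A.el.present && B.el.present) ? std::min(A.el.cutoff, B.el.cutoff) : 0.0;
      double r = rs;
      if (A.edes.present) r = std::max(r, A.edes.cutoff + B.extent);
      if (B.edes.present) r = std::max(r, B.edes.cutoff + A.extent);
      if (A.npd.present) r = std::max(r, A.npd.cutoff + B.extent);
      if (B.npd.present) r = std::max(r, B.npd.cutoff + A.extent);
      if (A.sc.present) r = std::max(r, A.sc.cutoff + B.extent);
      if (B.sc.present) r = std::max(r, B.sc.cutoff + A.extent);
      rswitch[a * nsp + b] = rs;
      reach[a * nsp + b] = r + 1.0;  // margin for FD displacements
    }

  std::vector<double> pos(3 * N), quat(4 * N);
  std::vector<int> img(3 * N, 0);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) pos[3 * i + k] = pos0(i, k);
    for (int k = 0; k < 4; ++k) quat[4 * i + k] = quat0(i, k);
  }

  int nFrames = nSteps / recordStride + 1;
  NumericVector outPos((size_t)N * 3 * nFrames), outQuat((size_t)N * 4 * nFrames);
  IntegerVector outImg((size_t)N * 3 * nFrames);
  NumericMatrix outE(nFrames, 6);
  NumericMatrix outPhi(nFrames, N);
  NumericVector outT(nFrames);

  std::vector<double> F(3 * N), Tq(3 * N), phi(N, 0.0), Dt(N), Dr(N);
  std::vector<double> rot(9 * N);
  for (int i = 0; i < N; ++i) { Dt[i] = D0t[i]; Dr[i] = D0r[i]; }

  RNGScope rngScope;
  int frame = 0;

  auto record = [&](int step) {
    outT[frame] = step * dt;
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 3; ++k) {
        outPos[(size_t)frame * 3 * N + k * N + i] = pos[3 * i + k];
        outImg[(size_t)frame * 3 * N + k * N + i] = img[3 * i + k];
      }
      for (int k = 0; k < 4; ++k)
        outQuat[(size_t)frame * 4 * N + k * N + i] = quat[4 * i + k];
      outPhi(frame, i) = phi[i];
    }
    // energy bookkeeping: instantaneous per-term sums over all pairs
    double E[5] = {0, 0, 0, 0, 0};
    for (int i = 0; i < N; ++i) quat_to_rot(&quat[4 * i], &rot[9 * i]);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double d[3] = { pos[3*j] - pos[3*i], pos[3*j+1] - pos[3*i+1], pos[3*j+2] - pos[3*i+2] };
        min_image(d, boxSide, periodic);
        double dd = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        double rmax = std::max(reach[si[i] * nsp + si[j]], useDH ? dhCutoff : 0.0);
        if (dd > rmax) continue;
        PairTerms t = pair_terms(sp[si[i]], sp[si[j]], &rot[9 * i], &rot[9 * j],
                                 d, kappa, epsr, useDH, dhCutoff);
        E[0] += t.el; E[1] += t.dh; E[2] += t.edes; E[3] += t.npd; E[4] += t.sc;
      }
    for (int k = 0; k < 5; ++k) outE(frame, k) = E[k];
    outE(frame, 5) = E[0] + E[1] + E[2] + E[3] + E[4];
    ++frame;
  };

  // initial phi
  auto update_phi = [&]() {
    double Vloc = 4.0 * M_PI * Rcut * Rcut * Rcut / 3.0;
    for (int i = 0; i < N; ++i) {
      double occ = selfPhi ? volume[i] : 0.0;
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double d[3] = { pos[3*j] - pos[3*i], pos[3*j+1] - pos[3*i+1], pos[3*j+2] - pos[3*i+2] };
        min_image(d, boxSide, periodic);
        double dd = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        if (dd >= Rcut + stokes[j]) continue;
        if (dd < Rcut - stokes[j]) occ += volume[j];
        else occ += lens_volume(dd, Rcut, stokes[j]);
      }
      double p = occ / Vloc;
      if (p < 0) p = 0;
      if (p > 0.6375) p = 0.6375;  // Tokuyama domain guard
      phi[i] = p;
      Dt[i] = D0t[i] * tokuyama_ratio(p);
      Dr[i] = D0r[i] * cichocki_ratio(p);
    }
  };

  if (useHydro) update_phi();
  record(0);

  for (int step = 1; step <= nSteps; ++step) {
    if (useHydro && ((step - 1) % phiStride == 0)) update_phi();
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(Tq.begin(), Tq.end(), 0.0);
    for (int i = 0; i < N; ++i) quat_to_rot(&quat[4 * i], &rot[9 * i]);

    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        int a = si[i], b = si[j];
        double d[3] = { pos[3*j] - pos[3*i], pos[3*j+1] - pos[3*i+1], pos[3*j+2] - pos[3*i+2] };
        min_image(d, boxSide, periodic);
        double dd = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
        double rch = reach[a * nsp + b];
        double rmax = std::max(rch, useDH ? dhCutoff : 0.0);
        if (dd > rmax) continue;
        if (dd >= rch) {
          // pure Debye-Hueckel regime: radial central difference, zero torque
          double zz = sp[a].z * sp[b].z;
          if (!useDH || zz == 0.0 || dd > dhCutoff) continue;
          double asum = sp[a].a_dh + sp[b].a_dh;
          double Ep = dh_energy(dd + delta, zz, asum, kappa, epsr);
          double Em = dh_energy(dd - delta, zz, asum, kappa, epsr);
          double f = -(Ep - Em) / (2.0 * delta);  // dE/dd, force on j along +d
          for (int k = 0; k < 3; ++k) {
            double fk = f * d[k] / dd;
            F[3 * j + k] += fk;
            F[3 * i + k] -= fk;
          }
          continue;
        }
        // full finite differences of the pair energy
        const Species &A = sp[a], &B = sp[b];
        for (int k = 0; k < 3; ++k) {
          double dp[3] = { d[0], d[1], d[2] }, dm[3] = { d[0], d[1], d[2] };
          dp[k] += delta; dm[k] -= delta;
          double Ep = pair_terms(A, B, &rot[9 * i], &rot[9 * j], dp, kappa, epsr, useDH, dhCutoff).total();
          double Em = pair_terms(A, B, &rot[9 * i], &rot[9 * j], dm, kappa, epsr, useDH, dhCutoff).total();
          double fk = -(Ep - Em) / (2.0 * delta);
          if (!std::isfinite(fk))
            stop("non-finite force between solutes %d and %d (d = %.3f A)", i + 1, j + 1, dd);
          F[3 * j + k] += fk;
          F[3 * i + k] -= fk;
        }
        for (int k = 0; k < 3; ++k) {
          double axis[3] = {0, 0, 0};
          // torque on i
          axis[k] = dtheta;
          double qp[4], qm[4], dq[4], Rp[9], Rm[9];
          quat_from_rotvec(axis, dq); quat_mul(dq, &quat[4 * i], qp);
          axis[k] = -dtheta;
          quat_from_rotvec(axis, dq); quat_mul(dq, &quat[4 * i], qm);
          quat_to_rot(qp, Rp); quat_to_rot(qm, Rm);
          double Ep = pair_terms(A, B, Rp, &rot[9 * j], d, kappa, epsr, useDH, dhCutoff).total();
          double Em = pair_terms(A, B, Rm, &rot[9 * j], d, kappa, epsr, useDH, dhCutoff).total();
          double tk = -(Ep - Em) / (2.0 * dtheta);
          if (!std::isfinite(tk))
            stop("non-finite torque on solute %d (pair %d-%d)", i + 1, i + 1, j + 1);
          Tq[3 * i + k] += tk;
          // torque on j
          axis[k] = dtheta;
          quat_from_rotvec(axis, dq); quat_mul(dq, &quat[4 * j], qp);
          axis[k] = -dtheta;
          quat_from_rotvec(axis, dq); quat_mul(dq, &quat[4 * j], qm);
          quat_to_rot(qp, Rp); quat_to_rot(qm, Rm);
          Ep = pair_terms(A, B, &rot[9 * i], Rp, d, kappa, epsr, useDH, dhCutoff).total();
          Em = pair_terms(A, B, &rot[9 * i], Rm, d, kappa, epsr, useDH, dhCutoff).total();
          tk = -(Ep - Em) / (2.0 * dtheta);
          if (!std::isfinite(tk))
            stop("non-finite torque on solute %d (pair %d-%d)", j + 1, i + 1, j + 1);
          Tq[3 * j + k] += tk;
        }
      }

    // propagate (mean-field Ermak-McCammon reduction + rotational analog)
    for (int i = 0; i < N; ++i) {
      double st = std::sqrt(2.0 * Dt[i] * dt);
      for (int k = 0; k < 3; ++k) {
        double x = pos[3 * i + k] + Dt[i] / kBT * F[3 * i + k] * dt + st * norm_rand();
        if (periodic) {
          double shift = std::floor(x / boxSide + 0.5);
          x -= boxSide * shift;
          img[3 * i + k] += (int)shift;
        }
        pos[3 * i + k] = x;
      }
      double sr = std::sqrt(2.0 * Dr[i] * dt);
      double rv[3];
      for (int k = 0; k < 3; ++k)
        rv[k] = Dr[i] / kBT * Tq[3 * i + k] * dt + sr * norm_rand();
      double dq[4], qn[4];
      quat_from_rotvec(rv, dq);
      quat_mul(dq, &quat[4 * i], qn);
      double nq = std::sqrt(qn[0]*qn[0] + qn[1]*qn[1] + qn[2]*qn[2] + qn[3]*qn[3]);
      for (int k = 0; k < 4; ++k) quat[4 * i + k] = qn[k] / nq;
    }

    if (step % recordStride == 0) record(step);
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  outPos.attr("dim") = IntegerVector::create(N, 3, nFrames);
  outImg.attr("dim") = IntegerVector::create(N, 3, nFrames);
  outQuat.attr("dim") = IntegerVector::create(N, 4, nFrames);
  return List::create(_["times"] = outT, _["positions"] = outPos, _["images"] = outImg,
                      _["quaternions"] = outQuat, _["energies"] = outE, _["phi"] = outPhi);
}

// [[Rcpp::export]]
double cpp_tokuyama(double phi) { return tokuyama_ratio(phi); }

// [[Rcpp::export]]
double cpp_cichocki(double phi) { return cichocki_ratio(phi); }

// [[Rcpp::export]]
double cpp_lens_volume(double d, double r1, double r2) { return lens_volume(d, r1, r2); }
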