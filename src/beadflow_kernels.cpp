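// Numerical kernels: D3Q19 TRT lattice-Boltzmann steady-flow solver,
// wall-aware trilinear interpolation, streamline tracing, and overdamped
// Lagrangian bead tracking.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// D3Q19 lattice
static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const int OPP[19]= {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
static const double W[19] = {
  1.0/3,
  1.0/18,1.0/18,1.0/18,1.0/18,1.0/18,1.0/18,
  1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36,1.0/36};

// He-Luo incompressible equilibrium: density enters additively, so the
// steady momentum field is divergence-free (volumetric flux conserved).
static inline double feq(int i, double rho, double ux, double uy, double uz,
                         double usq) {
  double cu = CX[i]*ux + CY[i]*uy + CZ[i]*uz;
  return W[i]*(rho + 3.0*cu + 4.5*cu*cu - 1.5*usq);
}

// pair table: (i, opposite(i)) for the 9 mobile link pairs
static const int PI1[9] = {1, 3, 5, 7, 9, 11, 13, 15, 17};
static const int PI2[9] = {2, 4, 6, 8, 10, 12, 14, 16, 18};
// y-mirrored direction (cy sign flipped), for the symmetry-plane boundary
static const int MIRY[19] = {0, 1, 2, 4, 3, 5, 6, 9, 10, 7, 8,
                             11, 12, 13, 14, 17, 18, 15, 16};

// [[Rcpp::export(name = ".lbm_solve_cpp")]]
List lbm_solve_cpp(IntegerVector mask, IntegerVector dims,
                   double u_in, double tau, int max_steps, double tol,
                   int check_every, int ramp_steps, double magic_lambda,
                   bool regularized, bool sym_y_low, bool verbose,
                   Nullable<NumericVector> inlet_profile = R_NilValue,
                   Nullable<NumericVector> init_ux = R_NilValue,
                   Nullable<NumericVector> init_uy = R_NilValue,
                   Nullable<NumericVector> init_uz = R_NilValue,
                   Nullable<NumericVector> init_rho = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ncell = (R_xlen_t)nx*ny*nz;
  // fluid cell list and grid -> fluid index map
  std::vector<int32_t> gidx(ncell, -1);
  std::vector<int32_t> cells; cells.reserve(ncell/3);
  for (R_xlen_t g = 0; g < ncell; ++g)
    if (mask[g] > 0) { gidx[g] = (int32_t)cells.size(); cells.push_back((int32_t)g); }
  const int nf = (int)cells.size();
  if (nf == 0) stop("domain has no fluid cells");

  // pull-streaming source offsets g - stride[i]; the one-cell solid padding
  // keeps them in range except across the (optional) y-symmetry plane
  int stride[19];
  for (int i = 0; i < 19; ++i)
    stride[i] = CX[i] + nx*(CY[i] + ny*CZ[i]);

  std::vector<int8_t> ctype(nf);          // 1 fluid, 2 inlet, 3 outlet
  std::vector<uint8_t> on_sym(nf, 0);     // cell row adjoins the symmetry plane
  std::vector<int32_t> aux(nf, -1);       // inlet: downstream; outlet: upstream
  for (int j = 0; j < nf; ++j) {
    int g = cells[j];
    int i0 = g % nx, j0 = (g/nx) % ny;
    ctype[j] = (int8_t)mask[g];
    if (sym_y_low && j0 == 0) on_sym[j] = 1;
    if (mask[g] == 3 && i0 > 0) aux[j] = gidx[g - 1];
    if (mask[g] == 2 && i0 < nx-1) aux[j] = gidx[g + 1];
  }

  const double om_p = 1.0 / tau;
  const double tau_m = magic_lambda / (tau - 0.5) + 0.5;
  const double om_m = 1.0 / tau_m;

  // plane-major single-precision populations: f[(size_t)i*nf + j]
  std::vector<float> f((size_t)nf*19), fn((size_t)nf*19);
  std::vector<double> ux(nf), uy(nf), uz(nf), rho(nf, 1.0);
  std::vector<double> uxp(nf, 0.0), uyp(nf, 0.0), uzp(nf, 0.0);

  // per-cell inlet velocity (lattice units)
  std::vector<double> uin_cell(nf, 0.0);
  {
    NumericVector prof;
    bool has_prof = inlet_profile.isNotNull();
    if (has_prof) prof = inlet_profile.get();
    for (int j = 0; j < nf; ++j)
      if (ctype[j] == 2)
        uin_cell[j] = has_prof ? prof[cells[j]] : u_in;
  }

  // initial condition: velocity and (crucially) density -- the cavity
  // pressure field charges on a slow RC timescale, so restarts must carry
  // it and cold starts should prime it
  {
    NumericVector ix, iy, iz, irho;
    bool has_init = init_ux.isNotNull();
    bool has_rho = init_rho.isNotNull();
    if (has_init) { ix = init_ux.get(); iy = init_uy.get(); iz = init_uz.get(); }
    if (has_rho) irho = init_rho.get();
    for (int j = 0; j < nf; ++j) {
      double vx = 0, vy = 0, vz = 0, r0 = 1.0;
      int g = cells[j];
      if (has_init) { vx = ix[g]; vy = iy[g]; vz = iz[g]; }
      if (has_rho) { r0 = irho[g]; if (!(r0 > 0.1 && r0 < 10)) r0 = 1.0; }
      double usq = vx*vx + vy*vy + vz*vz;
      for (int i = 0; i < 19; ++i)
        f[(size_t)i*nf+j] = (float)feq(i, r0, vx, vy, vz, usq);
      ux[j] = vx; uy[j] = vy; uz[j] = vz; rho[j] = r0;
    }
  }

  std::vector<double> res_hist;
  bool converged = false;
  int step = 0;
  const double wa = 1.0/18, wd = 1.0/36, w0 = 1.0/3;
  // inlet flux-delivery correction: the equilibrium inlet loses a small
  // resolution-dependent flux fraction to the adjacent bounce-back walls;
  // a slow feedback on the profile amplitude makes the delivered flux
  // (first interior layer) match the nominal one
  double in_gain = 1.0;
  double q_target0 = 0.0;
  std::vector<int> in_cells;
  for (int j = 0; j < nf; ++j)
    if (ctype[j] == 2) { in_cells.push_back(j); q_target0 += uin_cell[j]; }
  const int32_t* GI = gidx.data();
  const int32_t* CL = cells.data();
  for (step = 1; step <= max_steps; ++step) {
    double ramp = (ramp_steps > 0 && step < ramp_steps
                   ? (double)step / ramp_steps : 1.0);
    const float* F = f.data();
    float* FN = fn.data();
    for (int j = 0; j < nf; ++j) {
      const int g = CL[j];
      double fin[19];
      fin[0] = F[j];
      if (!on_sym[j]) {
        for (int i = 1; i < 19; ++i) {
          int32_t s = GI[g - stride[i]];
          fin[i] = (s >= 0) ? F[(size_t)i*nf + s] : F[(size_t)OPP[i]*nf + j];
        }
      } else {
        // row adjoining the y = 0 symmetry plane: links arriving from
        // j = -1 reflect specularly off the plane (mirror cell, mirrored
        // population)
        int i0 = g % nx, k0 = g/(nx*ny);
        for (int i = 1; i < 19; ++i) {
          int is = i0 - CX[i], js = -CY[i], ks = k0 - CZ[i];
          int di = i;
          if (js < 0) { js = 0; di = MIRY[i]; }
          int32_t s = -1;
          if (is >= 0 && is < nx && ks >= 0 && ks < nz)
            s = GI[(R_xlen_t)is + (R_xlen_t)nx*(js + (R_xlen_t)ny*ks)];
          fin[i] = (s >= 0) ? F[(size_t)di*nf + s] : F[(size_t)OPP[i]*nf + j];
        }
      }
      if (ctype[j] != 1) {
        double vx, vy, vz, r;
        if (ctype[j] == 2) {                   // inlet: profile, extrap. rho
          int s = aux[j];
          r = (s >= 0) ? rho[s] : 1.0;
          vx = uin_cell[j] * ramp * in_gain; vy = 0.0; vz = 0.0;
        } else {                               // outlet: fixed density
          int s = aux[j];
          r = 1.0;
          vx = (s >= 0) ? ux[s] : 0.0;
          vy = (s >= 0) ? uy[s] : 0.0;
          vz = (s >= 0) ? uz[s] : 0.0;
        }
        double usq = vx*vx + vy*vy + vz*vz;
        for (int i = 0; i < 19; ++i)
          FN[(size_t)i*nf+j] = (float)feq(i, r, vx, vy, vz, usq);
        ux[j] = vx; uy[j] = vy; uz[j] = vz; rho[j] = r;
        continue;
      }
      double r = fin[0], vx = 0, vy = 0, vz = 0;
      for (int i = 1; i < 19; ++i) r += fin[i];
      vx = fin[1]-fin[2] + fin[7]-fin[8] + fin[9]-fin[10]
         + fin[11]-fin[12] + fin[13]-fin[14];
      vy = fin[3]-fin[4] + fin[7]-fin[8] - fin[9]+fin[10]
         + fin[15]-fin[16] + fin[17]-fin[18];
      vz = fin[5]-fin[6] + fin[11]-fin[12] - fin[13]+fin[14]
         + fin[15]-fin[16] - fin[17]+fin[18];
      double usq = vx*vx + vy*vy + vz*vz;
      double cu[9] = { vx, vy, vz, vx+vy, vx-vy, vx+vz, vx-vz, vy+vz, vy-vz };
      if (regularized) {
        // project f_neq onto its second-moment (hydrodynamic) part, then
        // relax at 1/tau: filters the ghost modes that destabilize BGK/TRT
        // at low lattice viscosity.  Pi_neq = sum(c c f) - (r/3 I + u u)
        // for the incompressible equilibrium; Q_i : Pi is shared within
        // each +/- link pair.
        double sxx = fin[1]+fin[2]+fin[7]+fin[8]+fin[9]+fin[10]
                   + fin[11]+fin[12]+fin[13]+fin[14];
        double syy = fin[3]+fin[4]+fin[7]+fin[8]+fin[9]+fin[10]
                   + fin[15]+fin[16]+fin[17]+fin[18];
        double szz = fin[5]+fin[6]+fin[11]+fin[12]+fin[13]+fin[14]
                   + fin[15]+fin[16]+fin[17]+fin[18];
        double pxx = sxx - r/3.0 - vx*vx;
        double pyy = syy - r/3.0 - vy*vy;
        double pzz = szz - r/3.0 - vz*vz;
        double pxy = fin[7]+fin[8]-fin[9]-fin[10] - vx*vy;
        double pxz = fin[11]+fin[12]-fin[13]-fin[14] - vx*vz;
        double pyz = fin[15]+fin[16]-fin[17]-fin[18] - vy*vz;
        double keep = 1.0 - om_p;
        double tr = pxx + pyy + pzz;
        double qp[9] = { pxx - tr/3.0, pyy - tr/3.0, pzz - tr/3.0,
                         pxx + pyy - tr/3.0 + 2.0*pxy,
                         pxx + pyy - tr/3.0 - 2.0*pxy,
                         pxx + pzz - tr/3.0 + 2.0*pxz,
                         pxx + pzz - tr/3.0 - 2.0*pxz,
                         pyy + pzz - tr/3.0 + 2.0*pyz,
                         pyy + pzz - tr/3.0 - 2.0*pyz };
        FN[j] = (float)(w0*(r - 1.5*usq) + keep * w0*4.5*(-tr/3.0));
        for (int p = 0; p < 9; ++p) {
          double wi = (p < 3) ? wa : wd;
          double c = cu[p];
          double fe_p = wi*(r + 4.5*c*c - 1.5*usq) + keep*wi*4.5*qp[p];
          double fe_m = wi*3.0*c;
          FN[(size_t)PI1[p]*nf+j] = (float)(fe_p + fe_m);
          FN[(size_t)PI2[p]*nf+j] = (float)(fe_p - fe_m);
        }
      } else {
        // TRT: symmetric/antisymmetric relaxation per link pair
        FN[j] = (float)(fin[0] - om_p*(fin[0] - w0*(r - 1.5*usq)));
        for (int p = 0; p < 9; ++p) {
          double wi = (p < 3) ? wa : wd;
          double c = cu[p];
          double fe_p = wi*(r + 4.5*c*c - 1.5*usq);
          double fe_m = wi*3.0*c;
          int i1 = PI1[p], i2 = PI2[p];
          double sp = 0.5*(fin[i1] + fin[i2]) - fe_p;
          double sm = 0.5*(fin[i1] - fin[i2]) - fe_m;
          double dp_ = om_p*sp, dm_ = om_m*sm;
          FN[(size_t)i1*nf+j] = (float)(fin[i1] - dp_ - dm_);
          FN[(size_t)i2*nf+j] = (float)(fin[i2] - dp_ + dm_);
        }
      }
      rho[j] = r; ux[j] = vx; uy[j] = vy; uz[j] = vz;
    }
    f.swap(fn);
    if (step % 200 == 0 && q_target0 > 0) {
      double q_del = 0.0;
      for (int jc : in_cells)
        if (aux[jc] >= 0) q_del += ux[aux[jc]];
      double q_tgt = q_target0 * ramp;
      if (q_del > 0.25 * q_tgt) {
        in_gain *= 1.0 + 0.5 * (q_tgt / q_del - 1.0);
        if (in_gain < 1.0) in_gain = 1.0;
        if (in_gain > 1.5) in_gain = 1.5;
      }
    }
    if (step % check_every == 0) {
      double num = 0, den = 0;
      for (int j = 0; j < nf; ++j) {
        double dx_ = ux[j]-uxp[j], dy_ = uy[j]-uyp[j], dz_ = uz[j]-uzp[j];
        num += dx_*dx_ + dy_*dy_ + dz_*dz_;
        den += ux[j]*ux[j] + uy[j]*uy[j] + uz[j]*uz[j];
        uxp[j] = ux[j]; uyp[j] = uy[j]; uzp[j] = uz[j];
      }
      double res = std::sqrt(num / (den > 0 ? den : 1.0));
      if (!std::isfinite(res))
        stop("lattice-Boltzmann instability: non-finite populations "
             "(reduce inlet Mach number or refine the grid)");
      res_hist.push_back(res);
      if (verbose)
        Rcout << "  step " << step << " residual " << res << std::endl;
      if (step > ramp_steps && res < tol) { converged = true; break; }
    }
  }
  if (step > max_steps) step = max_steps;

  NumericVector Ux(ncell), Uy(ncell), Uz(ncell), Rho(ncell);
  for (int j = 0; j < nf; ++j) {
    int g = cells[j];
    Ux[g] = ux[j]; Uy[g] = uy[j]; Uz[g] = uz[j]; Rho[g] = rho[j];
  }
  Ux.attr("dim") = dims; Uy.attr("dim") = dims; Uz.attr("dim") = dims;
  Rho.attr("dim") = dims;
  return List::create(_["ux"] = Ux, _["uy"] = Uy, _["uz"] = Uz,
                      _["rho"] = Rho, _["steps"] = step,
                      _["residuals"] = NumericVector(res_hist.begin(), res_hist.end()),
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Ghost-fill: set solid cells adjacent to fluid to minus the mean adjacent
// fluid velocity so that trilinear interpolation vanishes at the (halfway)
// wall, consistent with no-slip.
// [[Rcpp::export(name = ".fill_wall_ghosts_cpp")]]
List fill_wall_ghosts_cpp(NumericVector ux, NumericVector uy, NumericVector uz,
                          IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector gx = clone(ux), gy = clone(uy), gz = clone(uz);
  const int dx6[6] = {1,-1,0,0,0,0}, dy6[6] = {0,0,1,-1,0,0}, dz6[6] = {0,0,0,0,1,-1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t g = (R_xlen_t)i + (R_xlen_t)nx*(j + (R_xlen_t)ny*k);
        if (mask[g] > 0) continue;
        double sx = 0, sy = 0, sz = 0; int n = 0;
        for (int d = 0; d < 6; ++d) {
          int in = i + dx6[d], jn = j + dy6[d], kn = k + dz6[d];
          if (in < 0 || in >= nx || jn < 0 || jn >= ny || kn < 0 || kn >= nz)
            continue;
          R_xlen_t gn = (R_xlen_t)in + (R_xlen_t)nx*(jn + (R_xlen_t)ny*kn);
          if (mask[gn] > 0) { sx += ux[gn]; sy += uy[gn]; sz += uz[gn]; ++n; }
        }
        if (n > 0) { gx[g] = -sx/n; gy[g] = -sy/n; gz[g] = -sz/n; }
      }
  gx.attr("dim") = dims; gy.attr("dim") = dims; gz.attr("dim") = dims;
  return List::create(_["ux"] = gx, _["uy"] = gy, _["uz"] = gz);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation on the cell-centered grid.
struct Field3 {
  const double *ux, *uy, *uz;
  int nx, ny, nz;
  double ox, oy, oz, dx;
  inline void sample(double x, double y, double z,
                     double &vx, double &vy, double &vz) const {
    double gx = (x - ox)/dx, gy = (y - oy)/dx, gz = (z - oz)/dx;
    int i = (int)std::floor(gx), j = (int)std::floor(gy), k = (int)std::floor(gz);
    double fx = gx - i, fy = gy - j, fz = gz - k;
    vx = vy = vz = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          int ii = i+di, jj = j+dj, kk = k+dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          double w = (di ? fx : 1-fx)*(dj ? fy : 1-fy)*(dk ? fz : 1-fz);
          R_xlen_t g = (R_xlen_t)ii + (R_xlen_t)nx*(jj + (R_xlen_t)ny*kk);
          vx += w*ux[g]; vy += w*uy[g]; vz += w*uz[g];
        }
  }
};

// Bilinear (r, z) force table.
struct ForceTab {
  const double *Fr, *Fz;
  int nr, nz;
  double dr, dz, z0;
  bool active;
  inline void sample(double x, double y, double z,
                     double &fx, double &fy, double &fz) const {
    fx = fy = fz = 0.0;
    if (!active) return;
    double r = std::sqrt(x*x + y*y);
    double gr = r/dr, gz = (z - z0)/dz;
    int i = (int)std::floor(gr), k = (int)std::floor(gz);
    if (i < 0) i = 0; if (k < 0) k = 0;
    if (i > nr-2) i = nr-2; if (k > nz-2) k = nz-2;
    double fr_ = gr - i, fz_ = gz - k;
    if (fr_ < 0) fr_ = 0; if (fr_ > 1) fr_ = 1;
    if (fz_ < 0) fz_ = 0; if (fz_ > 1) fz_ = 1;
    double w00 = (1-fr_)*(1-fz_), w10 = fr_*(1-fz_),
           w01 = (1-fr_)*fz_,     w11 = fr_*fz_;
    R_xlen_t a = (R_xlen_t)i + (R_xlen_t)nr*k;
    double Frv = w00*Fr[a] + w10*Fr[a+1] + w01*Fr[a+nr] + w11*Fr[a+nr+1];
    double Fzv = w00*Fz[a] + w10*Fz[a+1] + w01*Fz[a+nr] + w11*Fz[a+nr+1];
    fz = Fzv;
    if (r > 1e-12) { fx = Frv*x/r; fy = Frv*y/r; }
  }
};

// [[Rcpp::export(name = ".trace_path_cpp")]]
List trace_path_cpp(NumericVector ux, NumericVector uy, NumericVector uz,
                    IntegerVector dims, NumericVector origin, double dx,
                    NumericVector seed, double hstep, double max_arc,
                    double outlet_x, double stag_speed, int max_pts) {
  Field3 F{REAL(ux), REAL(uy), REAL(uz), dims[0], dims[1], dims[2],
           origin[0], origin[1], origin[2], dx};
  std::vector<double> px, py, pz, sp;
  double x = seed[0], y = seed[1], z = seed[2];
  double arc = 0.0;
  int status = 1;  // 0 reached_outlet, 1 recirculating, 2 stagnated
  for (int n = 0; n < max_pts; ++n) {
    double vx, vy, vz;
    F.sample(x, y, z, vx, vy, vz);
    double s = std::sqrt(vx*vx + vy*vy + vz*vz);
    px.push_back(x); py.push_back(y); pz.push_back(z); sp.push_back(s);
    if (x >= outlet_x) { status = 0; break; }
    if (s < stag_speed) { status = 2; break; }
    if (arc >= max_arc) { status = 1; break; }
    double dt = hstep / s;
    // RK4
    double k1x = vx, k1y = vy, k1z = vz, v2x, v2y, v2z;
    F.sample(x + 0.5*dt*k1x, y + 0.5*dt*k1y, z + 0.5*dt*k1z, v2x, v2y, v2z);
    double k2x = v2x, k2y = v2y, k2z = v2z;
    F.sample(x + 0.5*dt*k2x, y + 0.5*dt*k2y, z + 0.5*dt*k2z, v2x, v2y, v2z);
    double k3x = v2x, k3y = v2y, k3z = v2z;
    F.sample(x + dt*k3x, y + dt*k3y, z + dt*k3z, v2x, v2y, v2z);
    double ddx = dt/6.0*(k1x + 2*k2x + 2*k3x + v2x);
    double ddy = dt/6.0*(k1y + 2*k2y + 2*k3y + v2y);
    double ddz = dt/6.0*(k1z + 2*k2z + 2*k3z + v2z);
    x += ddx; y += ddy; z += ddz;
    arc += std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
  }
  int np = (int)px.size();
  NumericMatrix pts(np, 3);
  NumericVector speed(np);
  for (int n = 0; n < np; ++n) {
    pts(n,0) = px[n]; pts(n,1) = py[n]; pts(n,2) = pz[n]; speed[n] = sp[n];
  }
  return List::create(_["points"] = pts, _["speed"] = speed,
                      _["arc_length"] = arc, _["status"] = status);
}

// ---------------------------------------------------------------------------
// Overdamped bead tracking.  mode: 0 capture, 1 release.
// Statuses: 0 active (in chamber, off the floor), 1 captured (on the
// bottom), 2 escaped/released (entered the outlet channel).
//
// Beads touching the bottom are NOT frozen by default: with no friction in
// the force balance, a settled bead keeps sliding under the wall-shear drag
// and the horizontal magnetic force (its wall-normal motion is blocked).
// The historical freeze-on-touch wall condition is available via `freeze`.
// [[Rcpp::export(name = ".track_particles_cpp")]]
List track_particles_cpp(NumericVector ux, NumericVector uy, NumericVector uz,
                         IntegerVector dims, NumericVector origin, double dx,
                         NumericVector ft_Fr, NumericVector ft_Fz,
                         IntegerVector ft_dims, double ft_dr, double ft_dz,
                         double ft_z0, bool ft_active,
                         NumericMatrix seeds, int mode, bool freeze,
                         List geom, double Rp, double gamma, double fg_z,
                         double max_time, double dt_max, double step_frac,
                         double v_stop, int n_traj, double traj_dt) {
  Field3 F{REAL(ux), REAL(uy), REAL(uz), dims[0], dims[1], dims[2],
           origin[0], origin[1], origin[2], dx};
  ForceTab FT{REAL(ft_Fr), REAL(ft_Fz), ft_dims[0], ft_dims[1],
              ft_dr, ft_dz, ft_z0, ft_active};
  const double R  = as<double>(geom["R"]);
  const double H  = as<double>(geom["H"]);
  const double w  = as<double>(geom["w"]);
  const double hc = as<double>(geom["h"]);
  const double L  = as<double>(geom["L"]);
  const int upper_inlet = as<int>(geom["upper_inlet"]);
  const double outlet_exit = R + L - 1.5*dx;
  const int N = seeds.nrow();

  IntegerVector status(N), stuck_top(N);
  NumericVector t_end(N), x_end(N), y_end(N), z_end(N);
  int nrec = std::max(0, (int)std::ceil(max_time/traj_dt) + 1);
  NumericVector traj((n_traj > 0) ? (R_xlen_t)n_traj*nrec*3 : 0, NA_REAL);

  // drift u + (F_m + F_g)/gamma; wall-normal component suppressed when the
  // bead is pressed against the bottom (pz = -1) or top (pz = +1)
  auto drift = [&](double x, double y, double z, int pz,
                   double &vx, double &vy, double &vz) {
    double fx, fy, fz;
    F.sample(x, y, z, vx, vy, vz);
    FT.sample(x, y, z, fx, fy, fz);
    vx += fx/gamma; vy += fy/gamma; vz += (fz + fg_z)/gamma;
    if (pz < 0 && vz < 0) vz = 0;
    if (pz > 0 && vz > 0) vz = 0;
  };

  auto clamp_pos = [&](double &x, double &y, double &z) {
    double x_circ = (std::fabs(y) < R) ? std::sqrt(R*R - y*y) : 0.0;
    bool in_chan_x = std::fabs(y) <= w/2 && (x < -x_circ || x > x_circ);
    if (in_chan_x) {
      if (y >  w/2 - Rp) y =  w/2 - Rp;
      if (y < -w/2 + Rp) y = -w/2 + Rp;
      double zlo = 0.0, zhi = hc;                    // lower channel
      if (x < 0 && upper_inlet) { zlo = H - hc; zhi = H; }  // upper inlet
      if (z < zlo + Rp) z = zlo + Rp;
      if (z > zhi - Rp) z = zhi - Rp;
      if (x < -(R+L) + Rp) x = -(R+L) + Rp;
    } else {
      double r = std::sqrt(x*x + y*y);
      if (r > R - Rp && r > 1e-12) { x *= (R - Rp)/r; y *= (R - Rp)/r; }
      if (z < Rp) z = Rp;
      if (z > H - Rp) z = H - Rp;
    }
    return in_chan_x;
  };

  const double dt_min = 1e-8;
  const double z_eps = 1e-9;
  for (int p = 0; p < N; ++p) {
    double x = seeds(p,0), y = seeds(p,1), z = seeds(p,2);
    double t = 0.0;
    int st = 0, stuck = 0;
    long nsteps = 0;
    double next_rec = 0.0;
    bool on_floor = false;
    while (t < max_time) {
      if (p < n_traj && t >= next_rec) {
        int ri = (int)std::round(next_rec/traj_dt);
        if (ri < nrec) {
          traj[(R_xlen_t)p + (R_xlen_t)n_traj*(ri)] = x;
          traj[(R_xlen_t)p + (R_xlen_t)n_traj*(ri + nrec)] = y;
          traj[(R_xlen_t)p + (R_xlen_t)n_traj*(ri + 2*nrec)] = z;
        }
        next_rec += traj_dt;
      }
      // pressed against a z-wall?  (floor everywhere; chamber ceiling)
      int pz = 0;
      {
        double vx0, vy0, vz0;
        drift(x, y, z, 0, vx0, vy0, vz0);
        double zlo_here = (upper_inlet && x < 0 &&
                           std::fabs(y) <= w/2 && z > H - hc) ? H - hc : 0.0;
        if (z <= zlo_here + Rp + z_eps && vz0 < 0) pz = -1;
        if (z >= H - Rp - z_eps && vz0 > 0) pz = +1;
      }
      on_floor = (pz < 0);
      if (mode == 0 && freeze && on_floor) { st = 1; break; }
      if (pz > 0) {
        double fx_, fy_, fz_;
        FT.sample(x, y, z, fx_, fy_, fz_);
        if (fz_ > 0) stuck = 1;   // over-attraction against the chamber top
      }
      double v1x, v1y, v1z;
      drift(x, y, z, pz, v1x, v1y, v1z);
      double s = std::sqrt(v1x*v1x + v1y*v1y + v1z*v1z);
      if (s < v_stop) {           // immobile: nothing will change hereafter
        if (mode == 0 && on_floor) st = 1;
        t = max_time;
        break;
      }
      double dt = step_frac*dx / s;
      if (dt > dt_max) dt = dt_max;
      if (dt < dt_min) dt = dt_min;
      if (t + dt > max_time) dt = max_time - t;
      double v2x, v2y, v2z, v3x, v3y, v3z, v4x, v4y, v4z;
      drift(x + 0.5*dt*v1x, y + 0.5*dt*v1y, z + 0.5*dt*v1z, pz, v2x, v2y, v2z);
      drift(x + 0.5*dt*v2x, y + 0.5*dt*v2y, z + 0.5*dt*v2z, pz, v3x, v3y, v3z);
      drift(x + dt*v3x, y + dt*v3y, z + dt*v3z, pz, v4x, v4y, v4z);
      x += dt/6.0*(v1x + 2*v2x + 2*v3x + v4x);
      y += dt/6.0*(v1y + 2*v2y + 2*v3y + v4y);
      z += dt/6.0*(v1z + 2*v2z + 2*v3z + v4z);
      t += dt;
      bool in_chan = clamp_pos(x, y, z);
      if (in_chan && x > 0) { st = 2; break; }   // entered the outlet channel
      if (x >= outlet_exit) { st = 2; break; }
      if (++nsteps > 50000000L) break;
    }
    if (st == 0 && mode == 0 && z <= Rp + 1e-8) st = 1;  // settled at window end
    status[p] = st; stuck_top[p] = stuck;
    t_end[p] = t; x_end[p] = x; y_end[p] = y; z_end[p] = z;
  }
  List out = List::create(_["status"] = status, _["t_end"] = t_end,
                          _["x"] = x_end, _["y"] = y_end, _["z"] = z_end,
                          _["stuck_top"] = stuck_top);
  if (n_traj > 0) {
    traj.attr("dim") = IntegerVector::create(n_traj, nrec, 3);
    out["traj"] = traj;
    out["traj_t"] = NumericVector::create();  // filled in R
  }
  return out;
}
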