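// Core immersed-boundary / Navier-Stokes stepper on a doubly periodic grid.
//
// Discretization: collocated uniform grid, skew-symmetric central-difference
// advection, semi-implicit (spectral) viscous step, FFT-based pressure
// projection.  Immersed boundaries are tethered Lagrangian points coupled to
// the grid through the 4-point cosine regularized delta kernel; inflow is
// driven by a penalty band that relaxes the in-band velocity toward a
// prescribed parabolic profile.

#include <RcppArmadillo.h>
using namespace arma;

// 4-point cosine kernel, argument in grid units, support |r| < 2.
static inline double phi4(double r) {
  double a = std::abs(r);
  if (a >= 2.0) return 0.0;
  return 0.25 * (1.0 + std::cos(M_PI * a / 2.0));
}

static inline int wrap(int i, int n) {
  int m = i % n;
  return (m < 0) ? m + n : m;
}

// Spread Lagrangian force density F (per unit arc length) to the grid:
//   f(x) = sum_k F_k phi_h(x - X_k) ds,   phi_h = phi4(dx/h) phi4(dy/h) / h^2
static void spread_add(mat& fx, mat& fy,
                       const vec& px, const vec& py,
                       const vec& Fx, const vec& Fy,
                       double h, double ds, int Nx, int Ny) {
  const double w = ds / (h * h);
  for (uword k = 0; k < px.n_elem; ++k) {
    double gx = px(k) / h, gy = py(k) / h;
    int i0 = (int)std::floor(gx) - 1, j0 = (int)std::floor(gy) - 1;
    for (int di = 0; di < 4; ++di) {
      int i = i0 + di;
      double wx = phi4(gx - i);
      if (wx == 0.0) continue;
      int iw = wrap(i, Nx);
      for (int dj = 0; dj < 4; ++dj) {
        int j = j0 + dj;
        double wy = phi4(gy - j);
        if (wy == 0.0) continue;
        int jw = wrap(j, Ny);
        double ww = wx * wy * w;
        fx(iw, jw) += Fx(k) * ww;
        fy(iw, jw) += Fy(k) * ww;
      }
    }
  }
}

// Interpolate grid fields at Lagrangian points with the same kernel
// (adjoint of spread_add up to the ds/h^2 weights).
static void interp_at(const mat& u, const mat& v,
                      const vec& px, const vec& py,
                      vec& ub, vec& vb, double h, int Nx, int Ny) {
  for (uword k = 0; k < px.n_elem; ++k) {
    double gx = px(k) / h, gy = py(k) / h;
    int i0 = (int)std::floor(gx) - 1, j0 = (int)std::floor(gy) - 1;
    double su = 0.0, sv = 0.0;
    for (int di = 0; di < 4; ++di) {
      int i = i0 + di;
      double wx = phi4(gx - i);
      if (wx == 0.0) continue;
      int iw = wrap(i, Nx);
      for (int dj = 0; dj < 4; ++dj) {
        int j = j0 + dj;
        double wy = phi4(gy - j);
        if (wy == 0.0) continue;
        int jw = wrap(j, Ny);
        su += u(iw, jw) * wx * wy;
        sv += v(iw, jw) * wx * wy;
      }
    }
    ub(k) = su;
    vb(k) = sv;
  }
}

// Central differences on the periodic grid (rows = x, cols = y).
static inline mat Dx(const mat& A, double h) {
  return (shift(A, -1, 0) - shift(A, 1, 0)) / (2.0 * h);
}
static inline mat Dy(const mat& A, double h) {
  return (shift(A, -1, 1) - shift(A, 1, 1)) / (2.0 * h);
}

// Inflow gain g(t): mode 0 steady (smooth cosine ramp over tau), mode 1
// pulsatile sin^2(pi t / T), mode 2 none.
static inline double inflow_gain(double t, int mode, double Vin,
                                 double T, double tau) {
  if (mode == 0) {
    if (t >= tau) return Vin;
    if (t <= 0.0) return 0.0;
    return Vin * 0.5 * (1.0 - std::cos(M_PI * t / tau));
  } else if (mode == 1) {
    double s = std::sin(M_PI * t / T);
    return Vin * s * s;
  }
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List ib_spread_cpp(arma::vec px, arma::vec py,
                         arma::vec Fx, arma::vec Fy,
                         int Nx, int Ny, double h, double ds) {
  mat fx(Nx, Ny, fill::zeros), fy(Nx, Ny, fill::zeros);
  spread_add(fx, fy, px, py, Fx, Fy, h, ds, Nx, Ny);
  return Rcpp::List::create(Rcpp::Named("fx") = fx, Rcpp::Named("fy") = fy);
}

// [[Rcpp::export]]
Rcpp::List ib_interp_cpp(arma::mat u, arma::mat v,
                         arma::vec px, arma::vec py, double h) {
  int Nx = u.n_rows, Ny = u.n_cols;
  vec ub(px.n_elem), vb(px.n_elem);
  interp_at(u, v, px, py, ub, vb, h, Nx, Ny);
  return Rcpp::List::create(Rcpp::Named("u") = ub, Rcpp::Named("v") = vb);
}

// Advance the coupled fluid-boundary system by nsteps time steps.
//
// band_mask: Nx x Ny 0/1 mask of the driving band; band_prof: unit-peak
// target x-velocity profile on the same grid (parabolic across the channel).
// Tether force per unit arc length is -K (X - X_target).
//
// [[Rcpp::export]]
Rcpp::List ib_advance_cpp(arma::mat u, arma::mat v,
                          arma::vec px, arma::vec py,
                          arma::vec tx, arma::vec ty,
                          double ds, double K,
                          double h, double Lx, double Ly, double nu,
                          double dt, int nsteps, double t0,
                          arma::mat band_mask, arma::mat band_prof,
                          double band_alpha,
                          int inflow_mode, double Vin, double T, double tau,
                          arma::mat ext_mask, double ext_alpha,
                          int df_iters, double df_gamma) {
  const int Nx = u.n_rows, Ny = u.n_cols;
  const int nb = px.n_elem;
  const bool has_boundary = nb > 0;
  const bool has_band = band_alpha > 0.0;

  // spectral wavenumbers
  vec kx(Nx), ky(Ny);
  for (int i = 0; i < Nx; ++i) {
    int m = (i <= Nx / 2) ? i : i - Nx;
    kx(i) = 2.0 * M_PI * m / Lx;
  }
  for (int j = 0; j < Ny; ++j) {
    int m = (j <= Ny / 2) ? j : j - Ny;
    ky(j) = 2.0 * M_PI * m / Ly;
  }
  mat KX = repmat(kx, 1, Ny);
  mat KY = repmat(ky.t(), Nx, 1);
  mat K2 = KX % KX + KY % KY;
  mat visc = 1.0 / (1.0 + dt * nu * K2);
  // projection uses the central-difference modified wavenumbers
  // sin(k h)/h so the discrete (central) divergence vanishes exactly
  mat KXm = sin(KX * h) / h;
  mat KYm = sin(KY * h) / h;
  mat K2m = KXm % KXm + KYm % KYm;
  K2m(0, 0) = 1.0;                 // zero mode: no projection, no division
  // Nyquist rows/cols have zero modified wavenumber; guard the division
  K2m.elem(find(K2m < 1e-14)).fill(1.0);

  double t = t0;
  double maxdev = 0.0;
  double res = NA_REAL;
  vec ub(nb), vb(nb), Fx(nb), Fy(nb);
  mat p(Nx, Ny, fill::zeros);

  const mat zero(Nx, Ny, fill::zeros);
  const cx_mat cKX(KXm, zero), cKY(KYm, zero), cK2(K2m, zero), cVisc(visc, zero);

  // index maps for k -> -k (packed real-pair FFT trick: one transform of
  // us + i vs carries both fields; u_hat(k) = (F(k) + conj(F(-k)))/2)
  uvec revx(Nx), revy(Ny);
  for (int i = 0; i < Nx; ++i) revx(i) = (Nx - i) % Nx;
  for (int j = 0; j < Ny; ++j) revy(j) = (Ny - j) % Ny;

  // diffuse (optional) + project a velocity pair, with 2 FFTs
  auto diffuse_project = [&](mat& A, mat& B, bool with_visc) {
    cx_mat F = fft2(cx_mat(A, B));
    cx_mat Fm = conj(F(revx, revy));
    cx_mat uh = 0.5 * (F + Fm);
    cx_mat vh = cx_double(0, -0.5) * (F - Fm);
    if (with_visc) {
      uh %= cVisc;
      vh %= cVisc;
    }
    cx_mat dot = (cKX % uh + cKY % vh) / cK2;
    dot(0, 0) = 0.0;
    uh -= cKX % dot;
    vh -= cKY % dot;
    cx_mat W = ifft2(uh + cx_double(0, 1) * vh);
    A = real(W);
    B = imag(W);
    return dot;   // projection potential (for the pressure)
  };

  // kernel self-interaction gain for the direct-forcing corrector:
  // mean of interp(spread(1)) over the boundary points
  double kappa = 1.0;
  if (has_boundary && df_iters > 0) {
    mat sx(Nx, Ny, fill::zeros), sy(Nx, Ny, fill::zeros);
    vec ones(nb, fill::ones), zeros_v(nb, fill::zeros);
    spread_add(sx, sy, px, py, ones, zeros_v, h, ds, Nx, Ny);
    vec kx_b(nb), ky_b(nb);
    interp_at(sx, sy, px, py, kx_b, ky_b, h, Nx, Ny);
    kappa = mean(kx_b);
    if (kappa <= 0) kappa = 1.0;
  }

  for (int s = 0; s < nsteps; ++s) {
    mat fx(Nx, Ny, fill::zeros), fy(Nx, Ny, fill::zeros);

    if (has_boundary) {
      for (int k = 0; k < nb; ++k) {
        Fx(k) = -K * (px(k) - tx(k));
        Fy(k) = -K * (py(k) - ty(k));
      }
      spread_add(fx, fy, px, py, Fx, Fy, h, ds, Nx, Ny);
    }

    if (has_band) {
      double g = inflow_gain(t, inflow_mode, Vin, T, tau);
      fx += band_alpha * (g * band_prof - u) % band_mask;
      fy += band_alpha * (-v) % band_mask;
    }
    if (ext_alpha > 0.0) {
      // weak Brinkman damping of the (model-exterior) region
      fx -= ext_alpha * u % ext_mask;
      fy -= ext_alpha * v % ext_mask;
    }

    // skew-symmetric advection
    mat Nu = 0.5 * (u % Dx(u, h) + v % Dy(u, h) + Dx(u % u, h) + Dy(v % u, h));
    mat Nv = 0.5 * (u % Dx(v, h) + v % Dy(v, h) + Dx(u % v, h) + Dy(v % v, h));

    mat un = u + dt * (fx - Nu);
    mat vn = v + dt * (fy - Nv);

    // implicit viscosity + projection in Fourier space
    cx_mat dot = diffuse_project(un, vn, true);

    // multidirect forcing: drive the projected velocity at the boundary
    // points toward the rigid target velocity 0, re-projecting after each
    // correction so the final field stays divergence-free
    if (has_boundary && df_iters > 0) {
      for (int it = 0; it < df_iters; ++it) {
        interp_at(un, vn, px, py, ub, vb, h, Nx, Ny);
        vec Fcx = -(df_gamma / kappa) * ub;
        vec Fcy = -(df_gamma / kappa) * vb;
        mat gx(Nx, Ny, fill::zeros), gy(Nx, Ny, fill::zeros);
        spread_add(gx, gy, px, py, Fcx, Fcy, h, ds, Nx, Ny);
        un += gx;
        vn += gy;
        diffuse_project(un, vn, false);
      }
    }

    if (s == nsteps - 1) {
      res = std::max(abs(un - u).max(), abs(vn - v).max()) / dt;
      // pressure from the projection potential: u_new = u* - dt grad p,
      // grad p in Fourier is i k p_hat, so p_hat = -i (k.u*)/ (k^2 dt)
      cx_mat ph = cx_double(0, -1) * dot / dt;
      p = real(ifft2(ph));
    }
    u = un;
    v = vn;

    if (has_boundary) {
      interp_at(u, v, px, py, ub, vb, h, Nx, Ny);
      px += dt * ub;
      py += dt * vb;
      double dev = 0.0;
      for (int k = 0; k < nb; ++k) {
        double dxk = px(k) - tx(k), dyk = py(k) - ty(k);
        double d = std::sqrt(dxk * dxk + dyk * dyk);
        if (d > dev) dev = d;
      }
      if (dev > maxdev) maxdev = dev;
    }
    t += dt;

    if (!u.is_finite()) {
      Rcpp::stop("ib_advance_cpp: solution lost finiteness at t=%g (step %d); "
                 "reduce dt or check parameters", t, s);
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("u") = u, Rcpp::Named("v") = v, Rcpp::Named("p") = p,
      Rcpp::Named("px") = px, Rcpp::Named("py") = py,
      Rcpp::Named("t") = t, Rcpp::Named("max_deviation") = maxdev,
      Rcpp::Named("residual") = res);
}

// Poisson solve  lap(psi) = -w  on the periodic grid (zero-mean gauge).
// [[Rcpp::export]]
arma::mat fft_poisson_cpp(arma::mat w, double Lx, double Ly) {
  int Nx = w.n_rows, Ny = w.n_cols;
  vec kx(Nx), ky(Ny);
  for (int i = 0; i < Nx; ++i) {
    int m = (i <= Nx / 2) ? i : i - Nx;
    kx(i) = 2.0 * M_PI * m / Lx;
  }
  for (int j = 0; j < Ny; ++j) {
    int m = (j <= Ny / 2) ? j : j - Ny;
    ky(j) = 2.0 * M_PI * m / Ly;
  }
  mat KX = repmat(kx, 1, Ny);
  mat KY = repmat(ky.t(), Nx, 1);
  mat K2 = KX % KX + KY % KY;
  K2(0, 0) = 1.0;
  cx_mat wh = fft2(cx_mat(w, mat(Nx, Ny, fill::zeros)));
  cx_mat psih = wh / cx_mat(K2, mat(Nx, Ny, fill::zeros));
  psih(0, 0) = 0.0;
  return real(ifft2(psih));
}
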