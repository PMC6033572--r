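// Pseudospectral time-domain Maxwell solver on a collocated uniform grid.
//
// Spatial derivatives are computed by FFT (exact for band-limited fields);
// time stepping is leapfrog: H lives at half-integer steps, E at integer
// steps. Absorption at the grid boundary uses an impedance-matched graded
// conductivity applied identically to E and H as a per-cell multiplicative
// factor. A planar magnetic current density injects the focused
// illumination. Running discrete Fourier transforms accumulate spectral
// fields at probe points, on a detection plane, and as incremental
// fiber-coupling overlaps.
//
// Internal units: lengths in um, time in fs, mu0 = 1, eps0 = 1/c^2
// (c in um/fs), so the medium impedance is c/n and fields are relative.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// i*k multipliers for an N-point periodic axis of spacing delta
static cx_vec ik_vector(uword n, double delta) {
  cx_vec ik(n, fill::zeros);
  if (n < 2) return ik;
  double dk = 2.0 * M_PI / (double(n) * delta);
  for (uword j = 0; j < n; ++j) {
    double kj;
    if (j <= (n - 1) / 2) kj = dk * double(j);
    else kj = dk * (double(j) - double(n));
    if (n % 2 == 0 && j == n / 2) kj = 0.0;  // Nyquist: odd derivative -> 0
    ik(j) = cx_double(0.0, kj);
  }
  return ik;
}

// Paired spectral derivatives: for real inputs a, b the transform of
// c = a + i b gives d/du c = (da/du) + i (db/du) with both parts real, so
// two field derivatives along the same axis share one FFT round trip.

// d/dx (axis 0) of two fields at once
static void deriv_x2(const cube& a, const cube& b, cube& da, cube& db,
                     const cx_vec& ik) {
  const uword nx = a.n_rows, nz = a.n_slices;
  if (nx < 2) { da.zeros(); db.zeros(); return; }
  for (uword s = 0; s < nz; ++s) {
    cx_mat f = cx_mat(a.slice(s), b.slice(s));
    f = fft(f);
    f.each_col() %= ik;
    f = ifft(f);
    da.slice(s) = real(f);
    db.slice(s) = imag(f);
  }
}

static void deriv_y2(const cube& a, const cube& b, cube& da, cube& db,
                     const cx_vec& ik) {
  const uword ny = a.n_cols, nz = a.n_slices;
  if (ny < 2) { da.zeros(); db.zeros(); return; }
  for (uword s = 0; s < nz; ++s) {
    cx_mat f = cx_mat(mat(a.slice(s).t()), mat(b.slice(s).t()));
    f = fft(f);
    f.each_col() %= ik;
    f = ifft(f);
    da.slice(s) = real(f).t();
    db.slice(s) = imag(f).t();
  }
}

static void deriv_z2(const cube& a, const cube& b, cube& da, cube& db,
                     const cx_vec& ik) {
  const uword nx = a.n_rows, ny = a.n_cols, nz = a.n_slices;
  if (nz < 2) { da.zeros(); db.zeros(); return; }
  mat ra(nz, nx * ny), rb(nz, nx * ny);
  for (uword s = 0; s < nz; ++s) {
    ra.row(s) = vectorise(a.slice(s)).t();
    rb.row(s) = vectorise(b.slice(s)).t();
  }
  cx_mat m(ra, rb);
  m = fft(m);
  m.each_col() %= ik;
  m = ifft(m);
  mat rda = real(m), rdb = imag(m);
  for (uword s = 0; s < nz; ++s) {
    da.slice(s) = reshape(rda.row(s).t(), nx, ny);
    db.slice(s) = reshape(rdb.row(s).t(), nx, ny);
  }
}

static cube as_cube(SEXP x, uword nx, uword ny, uword nz) {
  Rcpp::NumericVector v(x);
  if ((uword)v.size() != nx * ny * nz)
    Rcpp::stop("array has wrong number of elements");
  return cube(v.begin(), nx, ny, nz);  // copies
}

// [[Rcpp::export]]
Rcpp::List pstd_run_cpp(Rcpp::List cfg) {
  Rcpp::NumericVector nArr = cfg["n"];
  Rcpp::IntegerVector dims = nArr.attr("dim");
  const uword nx = dims[0], ny = dims[1], nz = dims[2];
  const double delta = Rcpp::as<double>(cfg["cell_size"]);
  const double dt = Rcpp::as<double>(cfg["dt"]);
  const int nsteps = Rcpp::as<int>(cfg["nsteps"]);
  const double c0 = Rcpp::as<double>(cfg["c0"]);

  cube nidx = as_cube(nArr, nx, ny, nz);
  cube damp = as_cube(cfg["damp"], nx, ny, nz);
  cube coefE = (dt * c0 * c0) / square(nidx);  // dt/eps with mu0 = 1
  const double coefH = dt;                     // dt/mu0

  // optional PEC mask (perfect electric conductor cells: E forced to zero)
  bool has_pec = cfg.containsElementNamed("pec") && !Rf_isNull(cfg["pec"]);
  cube pec;
  if (has_pec) pec = as_cube(cfg["pec"], nx, ny, nz);

  // source
  bool has_src = cfg.containsElementNamed("source") && !Rf_isNull(cfg["source"]);
  int src_z = -1; double omega0 = 0, t0 = 0, Wenv = 1;
  cx_mat src_ex, src_ey;
  if (has_src) {
    Rcpp::List s = cfg["source"];
    src_z = Rcpp::as<int>(s["z_index"]);
    omega0 = Rcpp::as<double>(s["omega0"]);
    t0 = Rcpp::as<double>(s["t0"]);
    Wenv = Rcpp::as<double>(s["W"]);
    src_ex = Rcpp::as<cx_mat>(s["ex"]);
    src_ey = Rcpp::as<cx_mat>(s["ey"]);
  }

  // scattered-field contrast source: drives Ex with
  // -((eps - eps_bg)/eps) dE_inc/dt for an analytic x-polarized plane-wave
  // pulse travelling along +z (used by plane-wave characterization runs)
  bool has_sf = cfg.containsElementNamed("sf_source") &&
    !Rf_isNull(cfg["sf_source"]);
  uvec sf_idx; vec sf_coef, sf_zrel;
  double sf_v = 1, sf_om = 0, sf_t0 = 0, sf_W = 1;
  if (has_sf) {
    Rcpp::List s = cfg["sf_source"];
    sf_idx = Rcpp::as<uvec>(s["idx"]);       // 0-based linear cell indices
    sf_coef = Rcpp::as<vec>(s["coef"]);      // (eps - eps_bg)/eps per cell
    sf_zrel = Rcpp::as<vec>(s["z_rel"]);     // z - z_ref per cell (um)
    sf_v = Rcpp::as<double>(s["v"]);         // phase velocity (um/fs)
    sf_om = Rcpp::as<double>(s["omega0"]);
    sf_t0 = Rcpp::as<double>(s["t0"]);
    sf_W = Rcpp::as<double>(s["W"]);
  }

  // spectral probes
  vec omegas = cfg.containsElementNamed("omegas") && !Rf_isNull(cfg["omegas"])
    ? Rcpp::as<vec>(cfg["omegas"]) : vec();
  const uword nk = omegas.n_elem;
  umat pidx;
  if (cfg.containsElementNamed("probe_idx") && !Rf_isNull(cfg["probe_idx"]))
    pidx = Rcpp::as<umat>(cfg["probe_idx"]);  // npts x 3, 0-based
  const uword npts = pidx.n_rows;
  cx_cube accE[3], accH[3];
  for (int c = 0; c < 3; ++c) {
    accE[c].zeros(npts > 0 ? npts : 1, nk > 0 ? nk : 1, 1);
    accH[c].zeros(npts > 0 ? npts : 1, nk > 0 ? nk : 1, 1);
  }
  uvec plin(npts);
  for (uword p = 0; p < npts; ++p)
    plin(p) = pidx(p, 0) + nx * pidx(p, 1) + nx * ny * pidx(p, 2);

  // detection plane spectral accumulation
  int plane_z = cfg.containsElementNamed("plane_z")
    ? Rcpp::as<int>(cfg["plane_z"]) : -1;
  cx_cube planeEx, planeEy;
  if (plane_z >= 0 && nk > 0) {
    planeEx.zeros(nx, ny, nk);
    planeEy.zeros(nx, ny, nk);
  }

  // incremental coupling: alpha_k += sum_r (wx Ex + wy Ey) e^{i w t} dt dA
  bool do_alpha = cfg.containsElementNamed("alpha_weights") &&
    !Rf_isNull(cfg["alpha_weights"]);
  cx_cube awx, awy;
  cx_vec alpha(nk > 0 ? nk : 1, fill::zeros);
  if (do_alpha) {
    Rcpp::List aw = cfg["alpha_weights"];
    awx = Rcpp::as<cx_cube>(aw["wx"]);  // nx x ny x nk
    awy = Rcpp::as<cx_cube>(aw["wy"]);
  }

  // time series of E at points
  umat tsidx;
  if (cfg.containsElementNamed("ts_idx") && !Rf_isNull(cfg["ts_idx"]))
    tsidx = Rcpp::as<umat>(cfg["ts_idx"]);
  const uword nts = tsidx.n_rows;
  mat tsEx(nsteps, nts > 0 ? nts : 1, fill::zeros);
  mat tsHy(nsteps, nts > 0 ? nts : 1, fill::zeros);
  uvec tslin(nts);
  for (uword p = 0; p < nts; ++p)
    tslin(p) = tsidx(p, 0) + nx * tsidx(p, 1) + nx * ny * tsidx(p, 2);

  bool energy_trace = cfg.containsElementNamed("energy_trace") &&
    Rcpp::as<bool>(cfg["energy_trace"]);
  vec energy(energy_trace ? nsteps : 0);

  bool return_fields = cfg.containsElementNamed("return_fields") &&
    Rcpp::as<bool>(cfg["return_fields"]);
  double diverge_threshold = cfg.containsElementNamed("diverge_threshold")
    ? Rcpp::as<double>(cfg["diverge_threshold"]) : 1e12;

  // fields
  cube Ex(nx, ny, nz, fill::zeros), Ey(Ex), Ez(Ex);
  cube Hx(Ex), Hy(Ex), Hz(Ex);
  if (cfg.containsElementNamed("init") && !Rf_isNull(cfg["init"])) {
    Rcpp::List in = cfg["init"];
    Ex = as_cube(in["Ex"], nx, ny, nz); Ey = as_cube(in["Ey"], nx, ny, nz);
    Ez = as_cube(in["Ez"], nx, ny, nz); Hx = as_cube(in["Hx"], nx, ny, nz);
    Hy = as_cube(in["Hy"], nx, ny, nz); Hz = as_cube(in["Hz"], nx, ny, nz);
  }

  cx_vec ikx = ik_vector(nx, delta), iky = ik_vector(ny, delta),
         ikz = ik_vector(nz, delta);
  cube dA(nx, ny, nz), dB(nx, ny, nz), dC(nx, ny, nz), dD(nx, ny, nz),
       dE(nx, ny, nz), dF(nx, ny, nz), upd(nx, ny, nz);

  std::vector<double> fieldmax;
  bool diverged = false;
  int steps_done = 0;

  // eps cube for energy diagnostic
  cube epsc = square(nidx) / (c0 * c0);

  for (int it = 0; it < nsteps; ++it) {
    const double tau = it * dt;  // time of current E fields
    double h_prod = 0.0;

    // ---- H update: H(tau - dt/2) -> H(tau + dt/2) ----
    deriv_y2(Ez, Ex, dA, dB, iky);   // dA = dEz/dy, dB = dEx/dy
    deriv_z2(Ey, Ex, dC, dD, ikz);   // dC = dEy/dz, dD = dEx/dz
    deriv_x2(Ez, Ey, dE, dF, ikx);   // dE = dEz/dx, dF = dEy/dx

    cx_double src_ph(0, 0);
    if (has_src && src_z >= 0) {
      double targ = tau - t0;
      src_ph = std::exp(cx_double(0, -omega0 * targ)) *
        std::exp(-M_PI * (targ / Wenv) * (targ / Wenv));
    }

    // Hx -= dt * (dEz/dy - dEy/dz) (+ source J*x = Re(ey ph))
    upd = Hx - coefH * (dA - dC);
    if (has_src && src_z >= 0) {
      upd.slice(src_z) -= (coefH / delta) * real(src_ey * src_ph);
    }
    if (energy_trace) h_prod += accu(Hx % upd);
    Hx = damp % upd;

    // Hy -= dt * (dEx/dz - dEz/dx) (+ source J*y = -Re(ex ph))
    upd = Hy - coefH * (dD - dE);
    if (has_src && src_z >= 0) {
      upd.slice(src_z) += (coefH / delta) * real(src_ex * src_ph);
    }
    if (energy_trace) h_prod += accu(Hy % upd);
    Hy = damp % upd;

    // Hz -= dt * (dEy/dx - dEx/dy)
    upd = Hz - coefH * (dF - dB);
    if (energy_trace) h_prod += accu(Hz % upd);
    Hz = damp % upd;

    // H probes at t = tau + dt/2
    if (nk > 0 && npts > 0) {
      double th = tau + 0.5 * dt;
      for (uword k = 0; k < nk; ++k) {
        cx_double ph = std::exp(cx_double(0, omegas(k) * th)) * dt;
        for (uword p = 0; p < npts; ++p) {
          accH[0](p, k, 0) += ph * Hx(plin(p));
          accH[1](p, k, 0) += ph * Hy(plin(p));
          accH[2](p, k, 0) += ph * Hz(plin(p));
        }
      }
    }

    // conserved leapfrog energy: pairs E(tau) with H(tau -/+ dt/2)
    if (energy_trace) {
      double e_part = 0.5 * accu(epsc % (square(Ex) + square(Ey) + square(Ez)));
      energy(it) = e_part + 0.5 * h_prod;
    }

    // ---- E update: E(tau) -> E(tau + dt) ----
    deriv_y2(Hz, Hx, dA, dB, iky);   // dA = dHz/dy, dB = dHx/dy
    deriv_z2(Hy, Hx, dC, dD, ikz);   // dC = dHy/dz, dD = dHx/dz
    deriv_x2(Hz, Hy, dE, dF, ikx);   // dE = dHz/dx, dF = dHy/dx
    Ex += coefE % (dA - dC);
    if (has_sf) {
      const double th = tau + 0.5 * dt;   // source centered in the E update
      for (uword p = 0; p < sf_idx.n_elem; ++p) {
        double u = th - sf_t0 - sf_zrel(p) / sf_v;
        double env = std::exp(-M_PI * (u / sf_W) * (u / sf_W));
        // d/dt [cos(w0 u) env(u)]
        double dEdt = (-sf_om * std::sin(sf_om * u) -
                       (2.0 * M_PI * u / (sf_W * sf_W)) * std::cos(sf_om * u)) * env;
        Ex(sf_idx(p)) -= dt * sf_coef(p) * dEdt;
      }
    }
    Ex %= damp;
    Ey += coefE % (dD - dE); Ey %= damp;
    Ez += coefE % (dF - dB); Ez %= damp;
    if (has_pec) {
      Ex %= (1.0 - pec); Ey %= (1.0 - pec); Ez %= (1.0 - pec);
    }

    const double tE = tau + dt;
    if (nk > 0) {
      for (uword k = 0; k < nk; ++k) {
        cx_double ph = std::exp(cx_double(0, omegas(k) * tE)) * dt;
        for (uword p = 0; p < npts; ++p) {
          accE[0](p, k, 0) += ph * Ex(plin(p));
          accE[1](p, k, 0) += ph * Ey(plin(p));
          accE[2](p, k, 0) += ph * Ez(plin(p));
        }
        if (plane_z >= 0) {
          planeEx.slice(k) += ph * conv_to<cx_mat>::from(Ex.slice(plane_z));
          planeEy.slice(k) += ph * conv_to<cx_mat>::from(Ey.slice(plane_z));
        }
        if (do_alpha && plane_z >= 0) {
          cx_double s(0, 0);
          const mat& ex = Ex.slice(plane_z);
          const mat& ey = Ey.slice(plane_z);
          for (uword j = 0; j < ny; ++j)
            for (uword i = 0; i < nx; ++i)
              s += awx(i, j, k) * ex(i, j) + awy(i, j, k) * ey(i, j);
          alpha(k) += ph * s * delta * delta;
        }
      }
    }

    for (uword p = 0; p < nts; ++p) {
      tsEx(it, p) = Ex(tslin(p));
      tsHy(it, p) = Hy(tslin(p));
    }

    steps_done = it + 1;
    if (it % 20 == 0 || it == nsteps - 1) {
      double mx = std::max({Ex.max(), -Ex.min(), Ey.max(), -Ey.min(),
                            Ez.max(), -Ez.min()});
      fieldmax.push_back(mx);
      if (!std::isfinite(mx) || mx > diverge_threshold) {
        diverged = true;
        break;
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("diverged") = diverged,
    Rcpp::Named("steps_done") = steps_done,
    Rcpp::Named("fieldmax") = fieldmax,
    Rcpp::Named("alpha") = alpha,
    Rcpp::Named("energy") = energy,
    Rcpp::Named("tsEx") = tsEx,
    Rcpp::Named("tsHy") = tsHy);
  if (npts > 0 && nk > 0) {
    // npts x nk complex matrices per component
    Rcpp::List pe(3), ph(3);
    for (int c = 0; c < 3; ++c) {
      pe[c] = Rcpp::wrap(cx_mat(accE[c].slice(0)));
      ph[c] = Rcpp::wrap(cx_mat(accH[c].slice(0)));
    }
    out["probe_E"] = pe;
    out["probe_H"] = ph;
  }
  if (plane_z >= 0 && nk > 0) {
    out["plane_Ex"] = Rcpp::wrap(planeEx);
    out["plane_Ey"] = Rcpp::wrap(planeEy);
  }
  if (return_fields) {
    out["fields"] = Rcpp::List::create(
      Rcpp::Named("Ex") = Ex, Rcpp::Named("Ey") = Ey, Rcpp::Named("Ez") = Ez,
      Rcpp::Named("Hx") = Hx, Rcpp::Named("Hy") = Hy, Rcpp::Named("Hz") = Hz);
  }
  return out;
}
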