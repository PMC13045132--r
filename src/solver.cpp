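#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Forward-Euler update of dC/dt = div(D_pix grad C) + S - kappa*C on a 2D
// grid, flux form with arithmetic-mean face diffusivity so that closed
// boundaries conserve mass to rounding. All lengths um, time ms, conc mol/L.
//
// mode:     0 = plain 2D, 1 = simplified-3D (per-step alpha-scaled kappa sink)
// boundary: 0 = leaky (border <- ef * previous inward neighbour),
//           1 = closed (no flux), 2 = periodic (toroidal)
//
// Events are injected at the top of their step; probes and snapshots are
// recorded at the top of a step too, i.e. the state at time k*dt after any
// injection at that time. A final record is taken at n_steps.

// [[Rcpp::export]]
List fd_run_2d(NumericMatrix alpha, NumericMatrix C0,
               double D_free, double dx_um, double dt_ms,
               int n_steps, int mode, int boundary, double ef,
               IntegerVector ev_step, IntegerVector ev_row,
               IntegerVector ev_col, NumericVector ev_conc,
               IntegerVector probe_row, IntegerVector probe_col,
               int record_every, IntegerVector snap_steps,
               double kappa_amp, double kappa_rate, double kappa_min_scale) {
  const int nr = alpha.nrow(), nc = alpha.ncol();
  const double r2 = dt_ms / (dx_um * dx_um);
  const double dt_s = dt_ms * 1e-3;
  const double kmin = kappa_min_scale * dt_s * dt_s;

  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> Cn(C.size());
  // face conductances (constant in time): arithmetic mean of the adjacent
  // pixel diffusivities, hard zero into pure cellular structure (alpha = 0)
  auto face = [D_free, r2](double a1, double a2) {
    return (a1 > 0.0 && a2 > 0.0) ? 0.5 * D_free * (a1 + a2) * r2 : 0.0;
  };
  std::vector<double> gV((size_t)(nr - 1) * nc), gH((size_t)nr * (nc - 1));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r + 1 < nr; ++r)
      gV[(size_t)r + (size_t)c * (nr - 1)] = face(alpha(r, c), alpha(r + 1, c));
  for (int c = 0; c + 1 < nc; ++c)
    for (int r = 0; r < nr; ++r)
      gH[(size_t)r + (size_t)c * nr] = face(alpha(r, c), alpha(r, c + 1));
  std::vector<double> gVw, gHw;  // wrap faces, periodic only
  if (boundary == 2) {
    gVw.resize(nc); gHw.resize(nr);
    for (int c = 0; c < nc; ++c)
      gVw[c] = face(alpha(nr - 1, c), alpha(0, c));
    for (int r = 0; r < nr; ++r)
      gHw[r] = face(alpha(r, nc - 1), alpha(r, 0));
  }

  const int n_ev = ev_step.size(), n_pr = probe_row.size();
  int ev_i = 0;
  std::vector<double> probe_vals, probe_times;
  std::vector<int> snap_at(snap_steps.begin(), snap_steps.end());
  List snaps;
  double injected = 0.0, escaped = 0.0, cleared = 0.0;
  double t_since_release = R_PosInf;  // seconds since last release event

  for (int k = 0; k <= n_steps; ++k) {
    while (ev_i < n_ev && ev_step[ev_i] == k) {
      C[(size_t)ev_row[ev_i] + (size_t)ev_col[ev_i] * nr] += ev_conc[ev_i];
      injected += ev_conc[ev_i];
      t_since_release = 0.0;
      ++ev_i;
    }
    if ((record_every > 0 && k % record_every == 0) || k == n_steps) {
      probe_times.push_back(k * dt_ms);
      for (int p = 0; p < n_pr; ++p)
        probe_vals.push_back(C[(size_t)probe_row[p] + (size_t)probe_col[p] * nr]);
    }
    for (size_t s = 0; s < snap_at.size(); ++s) {
      if (snap_at[s] == k) {
        NumericMatrix sm(nr, nc);
        std::copy(C.begin(), C.end(), sm.begin());
        snaps.push_back(sm);
      }
    }
    if (k == n_steps) break;

    // diffusion fluxes; one sweep per column keeps the working set hot
    std::copy(C.begin(), C.end(), Cn.begin());
    for (int c = 0; c < nc; ++c) {
      const double *Cc = &C[(size_t)c * nr];
      double *Nc = &Cn[(size_t)c * nr];
      const double *g = &gV[(size_t)c * (nr - 1)];
      for (int r = 0; r + 1 < nr; ++r) {
        const double f = g[r] * (Cc[r + 1] - Cc[r]);
        Nc[r] += f; Nc[r + 1] -= f;
      }
      if (c + 1 < nc) {
        const double *C2 = &C[(size_t)(c + 1) * nr];
        double *N2 = &Cn[(size_t)(c + 1) * nr];
        const double *gh = &gH[(size_t)c * nr];
        for (int r = 0; r < nr; ++r) {
          const double f = gh[r] * (C2[r] - Cc[r]);
          Nc[r] += f; N2[r] -= f;
        }
      }
    }
    if (boundary == 2) {  // wrap faces
      for (int c = 0; c < nc; ++c) {
        const double f = gVw[c] * (C[(size_t)c * nr] - C[(size_t)(nr - 1) + (size_t)c * nr]);
        Cn[(size_t)(nr - 1) + (size_t)c * nr] += f;
        Cn[(size_t)c * nr] -= f;
      }
      for (int r = 0; r < nr; ++r) {
        const double f = gHw[r] * (C[r] - C[(size_t)r + (size_t)(nc - 1) * nr]);
        Cn[(size_t)r + (size_t)(nc - 1) * nr] += f;
        Cn[(size_t)r] -= f;
      }
    }

    // simplified-3D clearance sink
    if (mode == 1 && R_finite(t_since_release)) {
      const double kap = kappa_amp * dt_s * std::exp(-kappa_rate * t_since_release) + kmin;
      for (int c = 0; c < nc; ++c) {
        const double *ac = &alpha[(size_t)c * nr];
        double *Nc = &Cn[(size_t)c * nr];
        for (int r = 0; r < nr; ++r) {
          const double loss = Nc[r] * ac[r] * kap;
          Nc[r] -= loss; cleared += loss;
        }
      }
    }
    if (R_finite(t_since_release)) t_since_release += dt_s;

    // leaky frame border: border <- ef * previous-step inward neighbour
    if (boundary == 0) {
      double before = 0.0, after = 0.0;
      for (int c = 0; c < nc; ++c) {
        const int ci = (c == 0) ? 1 : (c == nc - 1 ? nc - 2 : c);
        before += Cn[(size_t)c * nr] + Cn[(size_t)(nr - 1) + (size_t)c * nr];
        Cn[(size_t)c * nr] = ef * C[(size_t)1 + (size_t)ci * nr];
        Cn[(size_t)(nr - 1) + (size_t)c * nr] = ef * C[(size_t)(nr - 2) + (size_t)ci * nr];
        after += Cn[(size_t)c * nr] + Cn[(size_t)(nr - 1) + (size_t)c * nr];
      }
      for (int r = 1; r + 1 < nr; ++r) {
        before += Cn[(size_t)r] + Cn[(size_t)r + (size_t)(nc - 1) * nr];
        Cn[(size_t)r] = ef * C[(size_t)r + (size_t)1 * nr];
        Cn[(size_t)r + (size_t)(nc - 1) * nr] = ef * C[(size_t)r + (size_t)(nc - 2) * nr];
        after += Cn[(size_t)r] + Cn[(size_t)r + (size_t)(nc - 1) * nr];
      }
      escaped += before - after;
    }
    C.swap(Cn);
  }

  NumericMatrix Cout(nr, nc);
  std::copy(C.begin(), C.end(), Cout.begin());
  const int n_rec = probe_times.size();
  NumericMatrix pm(n_rec, n_pr);
  for (int t = 0; t < n_rec; ++t)
    for (int p = 0; p < n_pr; ++p) pm(t, p) = probe_vals[(size_t)t * n_pr + p];
  return List::create(_["C"] = Cout, _["probe_times_ms"] = probe_times,
                      _["probes"] = pm, _["snapshots"] = snaps,
                      _["injected"] = injected, _["escaped"] = escaped,
                      _["cleared"] = cleared);
}

// Full 3D variant on an (nr, nc, nz) stack. boundary: 0 leaky (ef on all six
// frame faces), 1 closed. Voxel depth dz_um may differ from lateral dx_um.

// [[Rcpp::export]]
List fd_run_3d(NumericVector alpha, IntegerVector adim, NumericVector C0,
               double D_free, double dx_um, double dz_um, double dt_ms,
               int n_steps, int boundary, double ef,
               IntegerVector ev_step, IntegerVector ev_row, IntegerVector ev_col,
               IntegerVector ev_pln, NumericVector ev_conc,
               IntegerVector probe_row, IntegerVector probe_col,
               IntegerVector probe_pln, int record_every) {
  const int nr = adim[0], nc = adim[1], nz = adim[2];
  const size_t np = (size_t)nr * nc, n = np * nz;
  const double rxy = dt_ms / (dx_um * dx_um), rz = dt_ms / (dz_um * dz_um);
  std::vector<double> C(C0.begin(), C0.end()), Cn(n);
  const double *A = alpha.begin();
  auto face = [D_free](double a1, double a2, double rr) {
    return (a1 > 0.0 && a2 > 0.0) ? 0.5 * D_free * (a1 + a2) * rr : 0.0;
  };
  auto idx = [&](int r, int c, int z) { return (size_t)r + (size_t)c * nr + (size_t)z * np; };

  const int n_ev = ev_step.size(), n_pr = probe_row.size();
  int ev_i = 0;
  std::vector<double> probe_vals, probe_times;
  double injected = 0.0, escaped = 0.0;

  for (int k = 0; k <= n_steps; ++k) {
    while (ev_i < n_ev && ev_step[ev_i] == k) {
      C[idx(ev_row[ev_i], ev_col[ev_i], ev_pln[ev_i])] += ev_conc[ev_i];
      injected += ev_conc[ev_i];
      ++ev_i;
    }
    if ((record_every > 0 && k % record_every == 0) || k == n_steps) {
      probe_times.push_back(k * dt_ms);
      for (int p = 0; p < n_pr; ++p)
        probe_vals.push_back(C[idx(probe_row[p], probe_col[p], probe_pln[p])]);
    }
    if (k == n_steps) break;

    std::copy(C.begin(), C.end(), Cn.begin());
    for (int z = 0; z < nz; ++z) {
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r + 1 < nr; ++r) {
          const size_t i = idx(r, c, z);
          const double f = face(A[i], A[i + 1], rxy) * (C[i + 1] - C[i]);
          Cn[i] += f; Cn[i + 1] -= f;
        }
      }
      for (int c = 0; c + 1 < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          const size_t i = idx(r, c, z);
          const double f = face(A[i], A[i + nr], rxy) * (C[i + nr] - C[i]);
          Cn[i] += f; Cn[i + nr] -= f;
        }
      }
    }
    for (int z = 0; z + 1 < nz; ++z)
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          const size_t i = idx(r, c, z);
          const double f = face(A[i], A[i + np], rz) * (C[i + np] - C[i]);
          Cn[i] += f; Cn[i + np] -= f;
        }

    if (boundary == 0) {
      double before = 0.0, after = 0.0;
      for (int z = 0; z < nz; ++z) {
        const int zi = (z == 0 && nz > 2) ? 1 : (z == nz - 1 && nz > 2 ? nz - 2 : z);
        for (int c = 0; c < nc; ++c) {
          const int ci = (c == 0) ? 1 : (c == nc - 1 ? nc - 2 : c);
          before += Cn[idx(0, c, z)] + Cn[idx(nr - 1, c, z)];
          Cn[idx(0, c, z)] = ef * C[idx(1, ci, zi)];
          Cn[idx(nr - 1, c, z)] = ef * C[idx(nr - 2, ci, zi)];
          after += Cn[idx(0, c, z)] + Cn[idx(nr - 1, c, z)];
        }
        for (int r = 1; r + 1 < nr; ++r) {
          before += Cn[idx(r, 0, z)] + Cn[idx(r, nc - 1, z)];
          Cn[idx(r, 0, z)] = ef * C[idx(r, 1, zi)];
          Cn[idx(r, nc - 1, z)] = ef * C[idx(r, nc - 2, zi)];
          after += Cn[idx(r, 0, z)] + Cn[idx(r, nc - 1, z)];
        }
      }
      if (nz > 2) {
        for (int c = 1; c + 1 < nc; ++c)
          for (int r = 1; r + 1 < nr; ++r) {
            before += Cn[idx(r, c, 0)] + Cn[idx(r, c, nz - 1)];
            Cn[idx(r, c, 0)] = ef * C[idx(r, c, 1)];
            Cn[idx(r, c, nz - 1)] = ef * C[idx(r, c, nz - 2)];
            after += Cn[idx(r, c, 0)] + Cn[idx(r, c, nz - 1)];
          }
      }
      escaped += before - after;
    }
    C.swap(Cn);
  }

  NumericVector Cout(n);
  std::copy(C.begin(), C.end(), Cout.begin());
  Cout.attr("dim") = adim;
  const int n_rec = probe_times.size();
  NumericMatrix pm(n_rec, n_pr);
  for (int t = 0; t < n_rec; ++t)
    for (int p = 0; p < n_pr; ++p) pm(t, p) = probe_vals[(size_t)t * n_pr + p];
  return List::create(_["C"] = Cout, _["probe_times_ms"] = probe_times,
                      _["probes"] = pm, _["injected"] = injected,
                      _["escaped"] = escaped);
}
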