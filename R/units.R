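#' Per-pixel effective diffusivity
#'
#' Linear mapping from accessibility to local diffusion coefficient:
#' `D_pix = alpha * D_free`. Diffusion is free in pure-ECS pixels, blocked in
#' pure-structure pixels and proportionally hindered in between.
#'
#' @param map an [alpha_map()].
#' @param D_free free diffusion coefficient, um^2/ms (glutamate 0.75,
#'   GABA 1.1).
#' @return Numeric grid of `D_pix` in um^2/ms, same shape as the map.
#' @export
pixel_diffusivity <- function(map, D_free) {
  stopifnot(is_alpha_map(map), D_free > 0)
  map$alpha * D_free
}

#' Molar concentration of an instantaneous point source
#'
#' Converts a molecule count deposited in one voxel into molarity:
#' `S = n / (N_A * dx * dy * dz)`, with voxel edges in nm and the result in
#' mol/L. For 2D maps the slice thickness defaults to the lateral pixel size.
#'
#' @param n number of molecules, `> 0`.
#' @param dx_nm,dy_nm,dz_nm voxel edge lengths in nm, `> 0`.
#' @return Concentration in mol/L added to the source voxel.
#' @examples
#' source_concentration(10000, 50, 50, 50)  # ~0.1329 mol/L
#' @export
source_concentration <- function(n, dx_nm, dy_nm = dx_nm, dz_nm = dx_nm) {
  if (n <= 0) stop("`n` must be positive")
  if (dx_nm <= 0 || dy_nm <= 0 || dz_nm <= 0) stop("voxel dimensions must be positive")
  vol_L <- dx_nm * dy_nm * dz_nm / NM3_PER_L
  n / (N_AVOGADRO * vol_L)
}

#' Time-dependent out-of-plane clearance fraction
#'
#' The simplified-3D mode replaces the axial diffusion term by a per-step,
#' per-pixel sink that removes the fraction `alpha * kappa(t)` of the local
#' concentration, where
#' `kappa(t) = 15000 * dt * exp(-6000 * t) + 75e6 * dt^2`
#' with `t` the time in seconds since the most recent release and `dt` the
#' step in seconds. Clearance is strongest right after release (when axial
#' gradients out of the imaged plane are steepest), decays exponentially and
#' settles at the floor `kappa_min = 75e6 * dt^2`. The constants were
#' calibrated against full-3D simulations of peak concentration, time to
#' peak and decay time constants.
#'
#' @param t_s time since the last release event, seconds, `>= 0`.
#' @param dt_s solver time step, seconds.
#' @param amp,rate,min_scale the three constants (defaults 15000, 6000 per
#'   second, 75e6).
#' @return Dimensionless per-step clearance fraction (before alpha scaling).
#' @export
kappa_t <- function(t_s, dt_s, amp = 15000, rate = 6000, min_scale = 75e6) {
  stopifnot(all(t_s >= 0), dt_s > 0)
  amp * dt_s * exp(-rate * t_s) + min_scale * dt_s^2
}

#' Convert a diffusion coefficient from m^2/s to um^2/ms
#'
#' Literature values are often quoted in m^2/s (e.g. GABA,
#' 1.1e-9 m^2/s = 1.1 um^2/ms); the solvers work in um^2/ms.
#'
#' @param m2_per_s diffusion coefficient in m^2/s.
#' @return The same coefficient in um^2/ms.
#' @export
diffusivity_um2_ms <- function(m2_per_s) m2_per_s * 1e9
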