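#' Solver configuration for bulk diffusion runs
#'
#' Collects the physical and numerical parameters of the finite-difference
#' engine, which integrates
#' `dC/dt = div(D_pix grad C) + S - kappa C`
#' by the explicit forward-Euler method on the accessibility map, with
#' `D_pix = alpha * D_free`.
#'
#' Modes:
#' * `"2D"` - in-plane diffusion only.
#' * `"3D_smpl"` (default) - in-plane diffusion plus the time-dependent,
#'   alpha-scaled clearance sink [kappa_t()] standing in for out-of-plane
#'   escape, for single-plane images.
#' * `"3D"` - full 7-point stencil on an image stack.
#'
#' Boundaries: `"leaky"` sets every frame-border pixel to `ef` times its
#' previous-step inward neighbour, emulating an infinite surround into which
#' a fraction `1 - ef` escapes per step; `"closed"` is the no-flux variant
#' used for conservation testing; `"periodic"` wraps the frame toroidally
#' (2D only), matching the Monte Carlo engine.
#'
#' @param D_free free diffusion coefficient, um^2/ms.
#' @param dt_us time step in microseconds, or `NULL` to use 90% of the
#'   stability bound `dt <= min(dx, dy, dz)^2 / (2 * n_dims * max(D_pix))`.
#' @param mode `"3D_smpl"`, `"2D"` or `"3D"`.
#' @param ef border escape factor in `(0, 1]`, default 0.9.
#' @param boundary `"leaky"`, `"closed"` or `"periodic"`.
#' @param kappa_amp,kappa_rate,kappa_min_scale clearance constants, see
#'   [kappa_t()].
#' @return An object of class `difflux_config`.
#' @export
difflux_config <- function(D_free = 0.75, dt_us = NULL,
                           mode = c("3D_smpl", "2D", "3D"),
                           ef = 0.9,
                           boundary = c("leaky", "closed", "periodic"),
                           kappa_amp = 15000, kappa_rate = 6000,
                           kappa_min_scale = 75e6) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary)
  if (D_free <= 0) stop("`D_free` must be positive")
  if (!is.null(dt_us) && dt_us <= 0) stop("`dt_us` must be positive")
  if (ef <= 0 || ef > 1) stop("`ef` must be in (0, 1]")
  if (mode == "3D" && boundary == "periodic")
    stop("periodic boundaries are only available in 2D modes")
  structure(list(D_free = D_free, dt_us = dt_us, mode = mode, ef = ef,
                 boundary = boundary, kappa_amp = kappa_amp,
                 kappa_rate = kappa_rate, kappa_min_scale = kappa_min_scale),
            class = "difflux_config")
}

#' Stability limit of the explicit scheme
#'
#' Largest admissible time step
#' `dt = min(dx, dy, dz)^2 / (2 * n_dims * max(D_pix))` for the explicit
#' update to remain stable and non-negative. With 50 nm pixels and
#' D = 0.75 um^2/ms this is about 0.8 us, i.e. steps on the microsecond
#' scale.
#'
#' @param map an [alpha_map()].
#' @param cfg a [difflux_config()].
#' @return Limit in microseconds.
#' @export
stability_limit_us <- function(map, cfg) {
  stopifnot(is_alpha_map(map))
  dmax <- cfg$D_free * max(map$alpha)
  if (dmax <= 0) stop("map has no accessible pixels")
  dx_um <- map$pixel_size_nm / 1000
  sizes <- dx_um
  ndims <- 2L
  if (cfg$mode == "3D") {
    sizes <- c(dx_um, map$z_step_nm / 1000)
    ndims <- 3L
  }
  min(sizes)^2 / (2 * ndims * dmax) * 1000  # ms -> us
}

#' Point-source release events and trains
#'
#' `release_event()` builds a single instantaneous release (the full molecule
#' count is deposited in one voxel at its time step); `release_schedule()`
#' bundles events time-sorted; `release_train()` builds synchronous periodic
#' trains across positions with events at `t = 0, 1/f, 2/f, ...` strictly
#' before `duration_ms` (half-open convention, so 100 Hz over 100 ms gives
#' 10 events per site at 0, 10, ..., 90 ms).
#'
#' @param row,col,plane 1-based pixel coordinates (`plane` for stacks).
#' @param n_molecules molecules released, `> 0`.
#' @param time_ms release time in ms.
#' @return A `release_schedule` data frame with columns
#'   `row, col, plane, n_molecules, time_ms`.
#' @export
release_event <- function(row, col, n_molecules, time_ms = 0, plane = NA_integer_) {
  if (n_molecules <= 0) stop("`n_molecules` must be positive")
  release_schedule(data.frame(row = as.integer(row), col = as.integer(col),
                              plane = as.integer(plane),
                              n_molecules = n_molecules, time_ms = time_ms))
}

#' @rdname release_event
#' @param events data frame with the schedule columns.
#' @export
release_schedule <- function(events) {
  need <- c("row", "col", "n_molecules", "time_ms")
  if (!all(need %in% names(events))) stop("missing schedule columns")
  if (is.null(events$plane)) events$plane <- NA_integer_
  if (any(events$n_molecules <= 0)) stop("molecule counts must be positive")
  if (any(events$time_ms < 0)) stop("release times must be >= 0")
  events <- events[order(events$time_ms), , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- c("release_schedule", "data.frame")
  events
}

#' @rdname release_event
#' @param positions matrix of release positions, one row per site
#'   (`row, col[, plane]`).
#' @param freq_hz release frequency per site, Hz.
#' @param duration_ms train duration, ms.
#' @export
release_train <- function(positions, freq_hz, n_molecules, duration_ms) {
  if (freq_hz <= 0) stop("`freq_hz` must be positive")
  positions <- rbind(positions)
  period <- 1000 / freq_hz
  n_ev <- ceiling(duration_ms / period - 1e-9)
  if (n_ev < 1) stop("train contains no events")
  times <- (seq_len(n_ev) - 1) * period
  ev <- expand.grid(site = seq_len(nrow(positions)), time_ms = times)
  release_schedule(data.frame(row = positions[ev$site, 1],
                              col = positions[ev$site, 2],
                              plane = if (ncol(positions) >= 3)
                                positions[ev$site, 3] else NA_integer_,
                              n_molecules = n_molecules,
                              time_ms = ev$time_ms))
}

#' A concentration field at a time point
#'
#' @param C molar concentration grid (mol/L), matrix or 3D array.
#' @param t_ms field time since simulation start, ms.
#' @param pixel_size_nm,z_step_nm physical pixel sizes.
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(C, t_ms, pixel_size_nm, z_step_nm = NULL) {
  if (min(C) < -1e-12) stop("concentrations must be non-negative")
  structure(list(C = C, t_ms = t_ms, pixel_size_nm = pixel_size_nm,
                 z_step_nm = z_step_nm),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("<concentration_field> %s px at t = %.4g ms, peak %.4g uM\n",
              paste(dim(x$C), collapse = " x "), x$t_ms, max(x$C) * 1e6))
  invisible(x)
}

#' @export
plot.concentration_field <- function(x, log = TRUE, ...) {
  z <- x$C * 1e6
  if (log) z <- log10(z + max(z) * 1e-6)
  sz <- x$pixel_size_nm / 1000
  image(x = seq_len(ncol(z)) * sz, y = seq_len(nrow(z)) * sz,
        z = t(z)[, nrow(z):1], col = hcl.colors(128, "inferno"),
        xlab = "x (um)", ylab = "y (um)", asp = 1, useRaster = TRUE, ...)
  invisible(x)
}

resolve_dz_nm <- function(map) {
  if (!is.null(map$z_step_nm)) map$z_step_nm else map$pixel_size_nm
}

boundary_code <- function(b) match(b, c("leaky", "closed", "periodic")) - 1L

#' Simulate point-source release and diffusion on an accessibility map
#'
#' Runs the forward-Euler engine over a release schedule, recording probe
#' concentrations at a regular interval and full-field snapshots at requested
#' times. Released molecule counts are converted to molarity with
#' [source_concentration()] using the voxel volume (for 2D maps the slice
#' thickness defaults to the lateral pixel size).
#'
#' @param map an [alpha_map()] (2D for modes `"2D"`/`"3D_smpl"`, 3D for
#'   `"3D"`).
#' @param schedule a [release_schedule()].
#' @param cfg a [difflux_config()].
#' @param duration_ms simulated time, ms.
#' @param probes matrix of probe pixel coordinates (one per row,
#'   `row, col[, plane]`), optionally with rownames as probe ids.
#' @param record_interval_ms probe sampling interval (default about 500
#'   samples over the run).
#' @param snapshot_times_ms times at which to keep full concentration fields.
#' @return An object of class `difflux_sim` with elements `times_ms`,
#'   `conc_M` (samples x probes matrix), `snapshots` (list of
#'   [concentration_field()]), `field` (final state), `mass` (audit of
#'   injected, boundary-escaped and clearance-removed amounts, as summed
#'   molarity and as molecules) and the effective `dt_us`.
#' @export
difflux_simulate <- function(map, schedule, cfg = difflux_config(),
                             duration_ms, probes = NULL,
                             record_interval_ms = NULL,
                             snapshot_times_ms = NULL) {
  stopifnot(is_alpha_map(map), inherits(schedule, "release_schedule"))
  if (duration_ms <= 0) stop("`duration_ms` must be positive")
  d <- dim(map$alpha)
  is3d <- length(d) == 3L
  if (cfg$mode == "3D" && !is3d) stop("mode '3D' needs a 3D alpha map")
  if (cfg$mode != "3D" && is3d) stop("2D modes need a 2D alpha map")

  lim_us <- stability_limit_us(map, cfg)
  dt_us <- if (is.null(cfg$dt_us)) 0.9 * lim_us else cfg$dt_us
  if (dt_us > lim_us * (1 + 1e-9))
    stop(sprintf("dt = %.3g us violates the stability bound; use dt <= %.3g us",
                 dt_us, lim_us))
  dt_ms <- dt_us / 1000
  n_steps <- as.integer(ceiling(duration_ms / dt_ms))

  px <- map$pixel_size_nm
  dz <- resolve_dz_nm(map)
  check_pos <- function(r, c, p, what) {
    if (any(r < 1L | r > d[1] | c < 1L | c > d[2]))
      stop(sprintf("%s outside the grid", what))
    if (is3d && any(is.na(p) | p < 1L | p > d[3]))
      stop(sprintf("%s outside the stack", what))
  }
  check_pos(schedule$row, schedule$col, schedule$plane, "release position")
  ev_conc <- vapply(schedule$n_molecules, source_concentration, 0, dx_nm = px,
                    dy_nm = px, dz_nm = dz)
  ev_step <- as.integer(round(schedule$time_ms / dt_ms))
  if (any(ev_step > n_steps)) stop("release events beyond the run duration")
  ord <- order(ev_step)

  if (!is.null(probes)) {
    probes <- rbind(probes)
    check_pos(probes[, 1], probes[, 2], if (is3d) probes[, 3] else NA, "probe")
    av <- if (is3d) map$alpha[probes[, , drop = FALSE]] else
      map$alpha[probes[, 1:2, drop = FALSE]]
    if (any(av == 0))
      warning("probe on an alpha = 0 pixel; its concentration stays 0")
    pnames <- rownames(probes)
    if (is.null(pnames)) pnames <- paste0("probe", seq_len(nrow(probes)))
  } else {
    probes <- matrix(integer(), 0, if (is3d) 3 else 2)
    pnames <- character()
  }
  record_every <- if (is.null(record_interval_ms))
    max(1L, n_steps %/% 500L) else max(1L, as.integer(round(record_interval_ms / dt_ms)))
  snap_steps <- if (is.null(snapshot_times_ms)) integer() else
    as.integer(round(snapshot_times_ms / dt_ms))

  if (!is3d) {
    res <- fd_run_2d(map$alpha, matrix(0, d[1], d[2]),
                     cfg$D_free, px / 1000, dt_ms, n_steps,
                     mode = if (cfg$mode == "3D_smpl") 1L else 0L,
                     boundary = boundary_code(cfg$boundary), ef = cfg$ef,
                     ev_step = ev_step[ord] , ev_row = schedule$row[ord] - 1L,
                     ev_col = schedule$col[ord] - 1L, ev_conc = ev_conc[ord],
                     probe_row = probes[, 1] - 1L, probe_col = probes[, 2] - 1L,
                     record_every = record_every, snap_steps = snap_steps,
                     kappa_amp = cfg$kappa_amp, kappa_rate = cfg$kappa_rate,
                     kappa_min_scale = cfg$kappa_min_scale)
  } else {
    res <- fd_run_3d(as.numeric(map$alpha), dim(map$alpha),
                     as.numeric(array(0, d)), cfg$D_free, px / 1000, dz / 1000,
                     dt_ms, n_steps, boundary = boundary_code(cfg$boundary),
                     ef = cfg$ef, ev_step = ev_step[ord],
                     ev_row = schedule$row[ord] - 1L,
                     ev_col = schedule$col[ord] - 1L,
                     ev_pln = schedule$plane[ord] - 1L, ev_conc = ev_conc[ord],
                     probe_row = probes[, 1] - 1L, probe_col = probes[, 2] - 1L,
                     probe_pln = if (ncol(probes) >= 3) probes[, 3] - 1L else
                       integer(nrow(probes)),
                     record_every = record_every)
    res$cleared <- 0
    res$snapshots <- list()
  }

  conc <- res$probes
  colnames(conc) <- pnames
  snaps <- lapply(res$snapshots, function(m)
    concentration_field(m, NA_real_, px, map$z_step_nm))
  if (length(snaps)) {
    st <- sort(unique(snap_steps)) * dt_ms
    for (i in seq_along(snaps)) snaps[[i]]$t_ms <- st[i]
  }
  vox_L <- px * px * dz / NM3_PER_L
  mass <- list(injected_M = res$injected, escaped_M = res$escaped,
               cleared_M = res$cleared,
               injected_molecules = res$injected * vox_L * N_AVOGADRO,
               escaped_molecules = res$escaped * vox_L * N_AVOGADRO,
               cleared_molecules = res$cleared * vox_L * N_AVOGADRO)
  structure(list(times_ms = res$probe_times_ms, conc_M = conc,
                 probes = probes, snapshots = snaps,
                 field = concentration_field(res$C, n_steps * dt_ms, px,
                                             map$z_step_nm),
                 mass = mass, dt_us = dt_us, n_steps = n_steps, cfg = cfg),
            class = "difflux_sim")
}

#' @export
print.difflux_sim <- function(x, ...) {
  cat(sprintf("<difflux_sim> %s, %d steps of %.3g us, %d probe(s)\n",
              x$cfg$mode, x$n_steps, x$dt_us, ncol(x$conc_M)))
  cat(sprintf("  mass: injected %.3g, border-escaped %.3g, cleared %.3g molecules\n",
              x$mass$injected_molecules, x$mass$escaped_molecules,
              x$mass$cleared_molecules))
  if (ncol(x$conc_M) > 0) print(probe_metrics(x))
  invisible(x)
}

#' @export
plot.difflux_sim <- function(x, log = FALSE, ...) {
  if (ncol(x$conc_M) == 0) stop("no probes recorded")
  uM <- x$conc_M * 1e6
  ylim <- range(uM)
  plot(NA, xlim = range(x$times_ms), ylim = ylim, xlab = "time (ms)",
       ylab = "concentration (uM)", log = if (log) "y" else "", ...)
  for (j in seq_len(ncol(uM))) lines(x$times_ms, uM[, j], col = j)
  invisible(x)
}

#' @export
as.data.frame.difflux_sim <- function(x, ...) {
  if (ncol(x$conc_M) == 0)
    return(data.frame(time_ms = numeric(), probe = character(),
                      conc_uM = numeric()))
  data.frame(time_ms = rep(x$times_ms, ncol(x$conc_M)),
             probe = rep(colnames(x$conc_M), each = length(x$times_ms)),
             conc_uM = as.numeric(x$conc_M) * 1e6)
}

#' Peak, time-to-peak and decay constant per probe
#'
#' The decay time constant is a mono-exponential fit (linear regression of
#' log concentration on time) over the samples after the peak, down to 1% of
#' the peak value.
#'
#' @param sim a [difflux_simulate()] result.
#' @return Data frame with `probe`, `peak_uM`, `t_peak_ms`, `tau_ms` (NA when
#'   the decay is not sampled).
#' @export
probe_metrics <- function(sim) {
  stopifnot(inherits(sim, "difflux_sim"))
  t <- sim$times_ms
  out <- lapply(seq_len(ncol(sim$conc_M)), function(j) {
    c_uM <- sim$conc_M[, j] * 1e6
    ip <- which.max(c_uM)
    peak <- c_uM[ip]
    tau <- NA_real_
    if (peak > 0) {
      sel <- seq_along(c_uM) > ip & c_uM > 0.01 * peak
      if (sum(sel) >= 3) {
        fit <- lm(log(c_uM[sel]) ~ t[sel])
        sl <- coef(fit)[2]
        if (is.finite(sl) && sl < 0) tau <- -1 / sl
      }
    }
    data.frame(probe = colnames(sim$conc_M)[j], peak_uM = peak,
               t_peak_ms = t[ip], tau_ms = tau)
  })
  do.call(rbind, out)
}

#' Advance a concentration field by one explicit Euler step
#'
#' Single-step access to the engine used by [difflux_simulate()], mainly for
#' verification: one flux update (and clearance/boundary handling per the
#' configuration) with no sources.
#'
#' @param field a [concentration_field()].
#' @param map the matching [alpha_map()].
#' @param cfg a [difflux_config()]; `dt_us` must be set.
#' @param t_since_release_s time since last release, seconds (for the
#'   clearance term in `"3D_smpl"` mode).
#' @return The advanced [concentration_field()].
#' @export
difflux_step <- function(field, map, cfg, t_since_release_s = 0) {
  stopifnot(inherits(field, "concentration_field"), is_alpha_map(map))
  if (is.null(cfg$dt_us)) stop("`cfg$dt_us` must be set for single stepping")
  if (!identical(dim(field$C), dim(map$alpha))) stop("shape mismatch")
  lim <- stability_limit_us(map, cfg)
  if (cfg$dt_us > lim * (1 + 1e-9))
    stop(sprintf("dt = %.3g us violates the stability bound; use dt <= %.3g us",
                 cfg$dt_us, lim))
  dt_ms <- cfg$dt_us / 1000
  # fold the elapsed release time into the amplitude so the C++ kernel
  # (which measures time from its own start) applies kappa(t_since_release_s)
  amp <- cfg$kappa_amp * exp(-cfg$kappa_rate * t_since_release_s)
  res <- fd_run_2d(map$alpha, field$C, cfg$D_free, map$pixel_size_nm / 1000,
                   dt_ms, 1L, mode = if (cfg$mode == "3D_smpl") 1L else 0L,
                   boundary = boundary_code(cfg$boundary), ef = cfg$ef,
                   ev_step = 0L, ev_row = 0L, ev_col = 0L, ev_conc = 0,
                   probe_row = integer(), probe_col = integer(),
                   record_every = 0L, snap_steps = integer(),
                   kappa_amp = amp, kappa_rate = cfg$kappa_rate,
                   kappa_min_scale = cfg$kappa_min_scale)
  concentration_field(res$C, field$t_ms + dt_ms, field$pixel_size_nm,
                      field$z_step_nm)
}

#' Apply the leaky frame-border rule to a field
#'
#' Sets every border pixel to `ef` times its inward neighbour (corners use
#' the diagonal inward neighbour), the border condition emulating escape into
#' an infinite surround.
#'
#' @param field a 2D [concentration_field()].
#' @param ef escape factor in `(0, 1]`.
#' @return The updated field.
#' @export
apply_leaky_boundary <- function(field, ef = 0.9) {
  stopifnot(inherits(field, "concentration_field"))
  C <- field$C
  d <- dim(C)
  if (length(d) != 2L) stop("2D fields only")
  nr <- d[1]; nc <- d[2]
  old <- C
  ci <- pmin(pmax(seq_len(nc), 2L), nc - 1L)
  ri <- pmin(pmax(seq_len(nr), 2L), nr - 1L)
  C[1, ] <- ef * old[cbind(2L, ci)]
  C[nr, ] <- ef * old[cbind(nr - 1L, ci)]
  C[, 1] <- ef * old[cbind(ri, 2L)]
  C[, nc] <- ef * old[cbind(ri, nc - 1L)]
  # corners from the diagonal inward neighbour
  C[1, 1] <- ef * old[2, 2]; C[1, nc] <- ef * old[2, nc - 1]
  C[nr, 1] <- ef * old[nr - 1, 2]; C[nr, nc] <- ef * old[nr - 1, nc - 1]
  field$C <- C
  field
}
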