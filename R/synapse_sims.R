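#' Synaptic crosstalk versus the volume-averaged control
#'
#' Simulates a single vesicular release at a source synapse and records the
#' concentration reaching neighbouring synapses, once on the structured
#' accessibility map and once on its [homogenize()]d control (same mean
#' alpha, no structure), with an identical schedule and probes. The
#' per-neighbour ratio of homogenised over structured peak quantifies how
#' much the real ECS geometry suppresses (ratio > 1) or enhances (ratio < 1)
#' crosstalk relative to the volume-averaged prediction.
#'
#' @param map a 2D [alpha_map()].
#' @param source release pixel `c(row, col)` (alpha > 0).
#' @param neighbors matrix of neighbour synapse pixels, one per row;
#'   rownames become probe ids.
#' @param n_molecules molecules in the release (default 10000).
#' @param duration_ms simulated spread time (default 3 ms).
#' @param cfg a [difflux_config()] (default simplified-3D, leaky borders).
#' @return An object of class `crosstalk_result`: `structured` and
#'   `homogenized` [difflux_simulate()] runs plus a `metrics` data frame
#'   with per-neighbour peaks, times to peak and the
#'   `ratio_homogenized_over_structured`.
#' @export
crosstalk_experiment <- function(map, source, neighbors, n_molecules = 10000,
                                 duration_ms = 3, cfg = difflux_config()) {
  stopifnot(is_alpha_map(map))
  neighbors <- rbind(neighbors)
  if (is.null(rownames(neighbors)))
    rownames(neighbors) <- paste0("neighbor", seq_len(nrow(neighbors)))
  probes <- rbind(source = source, neighbors)
  sched <- release_event(source[1], source[2], n_molecules)
  sim_s <- difflux_simulate(map, sched, cfg, duration_ms, probes = probes)
  sim_h <- difflux_simulate(homogenize(map), sched, cfg, duration_ms,
                            probes = probes)
  ms <- probe_metrics(sim_s); mh <- probe_metrics(sim_h)
  sel <- ms$probe != "source"
  metrics <- data.frame(neighbor = ms$probe[sel],
                        peak_uM_structured = ms$peak_uM[sel],
                        t_peak_ms_structured = ms$t_peak_ms[sel],
                        peak_uM_homogenized = mh$peak_uM[sel],
                        t_peak_ms_homogenized = mh$t_peak_ms[sel])
  metrics$ratio_homogenized_over_structured <-
    metrics$peak_uM_homogenized / metrics$peak_uM_structured
  structure(list(structured = sim_s, homogenized = sim_h, metrics = metrics),
            class = "crosstalk_result")
}

#' @export
print.crosstalk_result <- function(x, ...) {
  cat("crosstalk experiment (structured vs volume-averaged):\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Frequency-dependent spillover versus the volume-averaged control
#'
#' Builds a synchronous periodic release train ([release_train()]) across
#' the given sites and simulates it on the structured map and on its
#' homogenised control. For each probe the steady-state plateau is estimated
#' as the mean concentration over the final fraction of the run (with its
#' residual slope, so stationarity can be checked), and structured over
#' homogenised concentration ratios are reported at requested snapshot
#' times.
#'
#' @param map a 2D [alpha_map()].
#' @param release_sites matrix of release pixels, one per row.
#' @param freq_hz release frequency per site, Hz.
#' @param n_molecules molecules per release per site (default 10000).
#' @param duration_ms train duration (default 200 ms).
#' @param probes matrix of probe pixels with rownames.
#' @param cfg a [difflux_config()]; the default uses the GABA free
#'   diffusivity 1.1 um^2/ms in simplified-3D mode.
#' @param ratio_times_ms times at which concentration ratios are reported
#'   (kept within the run).
#' @param plateau_frac final fraction of the run averaged for the plateau.
#' @return An object of class `spillover_result` with both runs, a
#'   `plateau` data frame (per probe and arm, mean and slope) and a
#'   `ratios` data frame (per probe and time,
#'   `ratio_structured_over_homogenized`).
#' @export
spillover_experiment <- function(map, release_sites, freq_hz,
                                 n_molecules = 10000, duration_ms = 200,
                                 probes, cfg = difflux_config(D_free = 1.1),
                                 ratio_times_ms = c(4, 100),
                                 plateau_frac = 0.2) {
  stopifnot(is_alpha_map(map), freq_hz > 0)
  sched <- release_train(release_sites, freq_hz, n_molecules, duration_ms)
  sim_s <- difflux_simulate(map, sched, cfg, duration_ms, probes = probes)
  sim_h <- difflux_simulate(homogenize(map), sched, cfg, duration_ms,
                            probes = probes)
  plateau_one <- function(sim, arm) {
    t0 <- (1 - plateau_frac) * duration_ms
    sel <- sim$times_ms >= t0
    do.call(rbind, lapply(seq_len(ncol(sim$conc_M)), function(j) {
      y <- sim$conc_M[sel, j] * 1e6
      sl <- if (length(y) > 2) unname(coef(lm(y ~ sim$times_ms[sel]))[2]) else NA_real_
      data.frame(probe = colnames(sim$conc_M)[j], arm = arm,
                 plateau_uM = mean(y), slope_uM_per_ms = sl)
    }))
  }
  plateau <- rbind(plateau_one(sim_s, "structured"),
                   plateau_one(sim_h, "homogenized"))
  ratio_times_ms <- ratio_times_ms[ratio_times_ms <= duration_ms]
  ratios <- do.call(rbind, lapply(ratio_times_ms, function(tt) {
    i <- which.min(abs(sim_s$times_ms - tt))
    data.frame(time_ms = sim_s$times_ms[i],
               probe = colnames(sim_s$conc_M),
               conc_uM_structured = sim_s$conc_M[i, ] * 1e6,
               conc_uM_homogenized = sim_h$conc_M[i, ] * 1e6,
               ratio_structured_over_homogenized =
                 ifelse(sim_h$conc_M[i, ] > 0,
                        sim_s$conc_M[i, ] / sim_h$conc_M[i, ], NA_real_))
  }))
  rownames(ratios) <- NULL
  structure(list(structured = sim_s, homogenized = sim_h,
                 freq_hz = freq_hz, plateau = plateau, ratios = ratios),
            class = "spillover_result")
}

#' @export
print.spillover_result <- function(x, ...) {
  cat(sprintf("spillover experiment at %g Hz:\n", x$freq_hz))
  print(x$plateau, row.names = FALSE)
  invisible(x)
}

#' Plateau-versus-frequency sweep
#'
#' Runs [spillover_experiment()] at each frequency and tabulates the
#' steady-state plateaus.
#'
#' @inheritParams spillover_experiment
#' @param freqs_hz frequencies to sweep (default 10, 25, 50, 100 Hz).
#' @return List with `results` (one [spillover_experiment()] per frequency)
#'   and `plateaus` (data frame `freq_hz`, `probe`, `arm`, `plateau_uM`).
#' @export
spillover_sweep <- function(map, release_sites, freqs_hz = c(10, 25, 50, 100),
                            n_molecules = 10000, duration_ms = 200, probes,
                            cfg = difflux_config(D_free = 1.1), ...) {
  results <- lapply(freqs_hz, function(f)
    spillover_experiment(map, release_sites, f, n_molecules, duration_ms,
                         probes, cfg, ...))
  names(results) <- paste0(freqs_hz, "Hz")
  plateaus <- do.call(rbind, lapply(seq_along(freqs_hz), function(i)
    cbind(freq_hz = freqs_hz[i], results[[i]]$plateau)))
  rownames(plateaus) <- NULL
  list(results = results, plateaus = plateaus)
}
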