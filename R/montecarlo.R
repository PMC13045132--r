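#' Configuration for lattice Monte Carlo walks
#'
#' Single particles hop between pixel centres. The lattice step length is the
#' pixel size `h`, and the step time is `dt = h^2 / (2 * dims * D_free)`, so
#' that a walk whose every move is accepted reproduces the free diffusion
#' coefficient; the acceptance rule (move into a target pixel with
#' probability `alpha(target)`, bounce otherwise) then scales the effective
#' local diffusivity linearly with alpha.
#'
#' @param D_free free diffusion coefficient, um^2/ms.
#' @param n_particles particles per source point.
#' @param duration_ms walk duration, ms.
#' @param dims 2 or 3; must match the map rank.
#' @param seed integer seed for the per-particle counter-based generator.
#' @param record_every record positions every this many steps (`NULL`: about
#'   300 samples per walk).
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(D_free = 0.75, n_particles = 1000, duration_ms = 300,
                        dims = 2, seed = 1, record_every = NULL) {
  stopifnot(D_free > 0, n_particles >= 1, duration_ms > 0, dims %in% c(2, 3))
  structure(list(D_free = D_free, n_particles = as.integer(n_particles),
                 duration_ms = duration_ms, dims = as.integer(dims),
                 seed = as.integer(seed), record_every = record_every),
            class = "walk_config")
}

#' One obstacle-bouncing lattice step (reference implementation)
#'
#' Draws an axis uniformly (`p_dir = 1/2` in 2D, `1/3` in 3D), a direction
#' uniformly (`p_i = 1/2`), then accepts the move with probability
#' `alpha(target)`: a uniform draw below the bounce probability
#' `p_b = 1 - alpha(target)` keeps the particle in place. Borders wrap
#' toroidally. Uses R's RNG; the bulk simulator
#' implements the same rule in compiled code with per-particle substreams.
#'
#' @param pos integer pixel position `c(row, col[, plane])`.
#' @param map an [alpha_map()].
#' @return The new position (same length as `pos`).
#' @export
mc_step <- function(pos, map) {
  stopifnot(is_alpha_map(map))
  d <- dim(map$alpha)
  dims <- length(d)
  stopifnot(length(pos) == dims)
  axis <- if (dims == 2) (runif(1) >= 0.5) + 1L else
    pmin(floor(runif(1) * 3) + 1L, 3L)
  dir <- if (runif(1) < 0.5) -1L else 1L
  target <- pos
  target[axis] <- (pos[axis] - 1L + dir + d[axis]) %% d[axis] + 1L
  a <- map$alpha[matrix(target, 1)]
  if (runif(1) < 1 - a) pos else target
}

#' Simulate independent particle walks on an accessibility map
#'
#' Releases `cfg$n_particles` particles from each source point and runs the
#' obstacle-bouncing walk with toroidal borders. Unwrapped positions (not
#' folded back at the borders) are recorded at a regular stride for MSD
#' analysis. Reproducible under the seed; particles use independent
#' counter-based substreams.
#'
#' @param map an [alpha_map()].
#' @param sources matrix of source pixel coordinates, one per row.
#' @param cfg a [walk_config()].
#' @return An object of class `mc_trajectories`: `unwrapped` array
#'   (samples x particles x dims, pixel units), `times_ms`, `source_index`
#'   per particle, `wrapped_final`, plus the map pixel size and config.
#' @export
simulate_walk <- function(map, sources, cfg = walk_config()) {
  stopifnot(is_alpha_map(map))
  d <- dim(map$alpha)
  if (cfg$dims != length(d))
    stop("`cfg$dims` must match the map rank (3D walks need a 3D map)")
  sources <- rbind(sources)
  if (ncol(sources) != cfg$dims) stop("source coordinates have wrong length")
  if (any(sources < 1L) || any(t(sources) > d))
    stop("sources must lie inside the grid")
  if (any(map$alpha[sources] == 0))
    stop("sources must sit on alpha > 0 pixels")

  h_um <- map$pixel_size_nm / 1000
  dt_ms <- h_um^2 / (2 * cfg$dims * cfg$D_free)
  n_steps <- as.integer(round(cfg$duration_ms / dt_ms))
  record_every <- if (is.null(cfg$record_every))
    max(1L, n_steps %/% 300L) else as.integer(cfg$record_every)
  start <- sources[rep(seq_len(nrow(sources)), each = cfg$n_particles), ,
                   drop = FALSE]
  res <- mc_run(as.numeric(map$alpha), d, start - 1L, n_steps, record_every,
                as.double(cfg$seed))
  unwrapped <- res$unwrapped + 1  # back to 1-based pixel coordinates
  structure(list(unwrapped = unwrapped, map_dim = d,
                 times_ms = res$record_steps * dt_ms,
                 source_index = rep(seq_len(nrow(sources)),
                                    each = cfg$n_particles),
                 sources = sources, wrapped_final = res$wrapped + 1L,
                 pixel_size_nm = map$pixel_size_nm, dt_ms = dt_ms,
                 n_steps = n_steps, cfg = cfg),
            class = "mc_trajectories")
}

#' @export
print.mc_trajectories <- function(x, ...) {
  cat(sprintf("<mc_trajectories> %d particles from %d source(s), %d steps of %.3g us (%g ms)\n",
              dim(x$unwrapped)[2], nrow(x$sources), x$n_steps,
              x$dt_ms * 1000, x$cfg$duration_ms))
  cat(sprintf("  %d recorded samples, seed %d\n", dim(x$unwrapped)[1],
              x$cfg$seed))
  invisible(x)
}

#' Particle density histogram
#'
#' Bins final (wrapped) particle positions per pixel, for comparison with a
#' bulk concentration field.
#'
#' @param traj an [simulate_walk()] result.
#' @return Integer matrix/array of counts with the map's shape.
#' @export
mc_density <- function(traj) {
  stopifnot(inherits(traj, "mc_trajectories"))
  d <- traj$map_dim
  w <- traj$wrapped_final
  lin <- w[, 1]
  mult <- 1L
  for (k in seq_len(ncol(w))[-1]) {
    mult <- mult * d[k - 1]
    lin <- lin + (w[, k] - 1L) * mult
  }
  counts <- tabulate(lin, nbins = prod(d))
  array(counts, dim = d)
}

#' Mean squared displacement of a trajectory set
#'
#' `<r^2>(tau)` averaged over particles, measured from each particle's release
#' point at `t = 0` (matching per-source MSD analysis). A sliding-lag
#' estimator (time-averaged over all start samples) is available as an
#' option.
#'
#' @param traj an [simulate_walk()] result.
#' @param method `"origin"` (default) or `"sliding"`.
#' @return An object of class `msd_curve`: data frame `lag_ms`, `msd_um2`,
#'   `n` with pixel size and method attributes.
#' @export
msd <- function(traj, method = c("origin", "sliding")) {
  stopifnot(inherits(traj, "mc_trajectories"))
  method <- match.arg(method)
  u <- traj$unwrapped
  px_um <- traj$pixel_size_nm / 1000
  nrec <- dim(u)[1]; npart <- dim(u)[2]; dims <- dim(u)[3]
  if (method == "origin") {
    r2 <- numeric(nrec)
    for (k in seq_len(dims)) {
      disp <- u[, , k] - matrix(u[1, , k], nrec, npart, byrow = TRUE)
      r2 <- r2 + rowMeans(disp^2)
    }
    out <- data.frame(lag_ms = traj$times_ms, msd_um2 = r2 * px_um^2,
                      n = npart)
  } else {
    # average over all (start, start + lag) sample pairs
    r2 <- numeric(nrec)
    cnt <- integer(nrec)
    for (lag in 0:(nrec - 1)) {
      s <- 0
      nseg <- nrec - lag
      for (k in seq_len(dims)) {
        d1 <- u[seq_len(nseg) + lag, , k, drop = FALSE] -
          u[seq_len(nseg), , k, drop = FALSE]
        s <- s + sum(d1^2)
      }
      r2[lag + 1] <- s / (nseg * npart)
      cnt[lag + 1] <- nseg * npart
    }
    out <- data.frame(lag_ms = traj$times_ms - traj$times_ms[1],
                      msd_um2 = r2 * px_um^2, n = cnt)
  }
  structure(out, class = c("msd_curve", "data.frame"),
            pixel_size_nm = traj$pixel_size_nm, method = method,
            dims = dims)
}

#' Average MSD curves across source points or frames
#'
#' @param curves list of [msd()] results on identical lag grids.
#' @return A single `msd_curve`, the pointwise mean.
#' @export
aggregate_msd <- function(curves) {
  stopifnot(length(curves) >= 1)
  lag <- curves[[1]]$lag_ms
  for (cv in curves) if (!isTRUE(all.equal(cv$lag_ms, lag)))
    stop("lag grids differ")
  m <- rowMeans(sapply(curves, function(cv) cv$msd_um2))
  out <- data.frame(lag_ms = lag, msd_um2 = m,
                    n = Reduce(`+`, lapply(curves, function(cv) cv$n)))
  attributes(out)[c("class", "pixel_size_nm", "method", "dims")] <-
    attributes(curves[[1]])[c("class", "pixel_size_nm", "method", "dims")]
  out
}

#' Fit the anomalous diffusion exponent gamma
#'
#' Least-squares fit of `log <r^2>` against `log t` over a lag window,
#' `<r^2> ~ t^gamma`. `gamma = 1` is normal diffusion; `gamma < 1` indicates
#' sub-diffusion from obstruction. The default window drops the first two
#' positive lags (single-lattice-step artefacts) and the final 10% of lags
#' (poorly averaged for origin-referenced MSD).
#'
#' @param curve an [msd()] result.
#' @param window optional `c(min_lag_ms, max_lag_ms)`.
#' @return An object of class `gamma_fit`: `gamma`, `se`, `ci` (95%),
#'   `prefactor`, the window and the `lm` fit.
#' @export
fit_gamma <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  pos <- curve$lag_ms > 0 & curve$msd_um2 > 0
  lag <- curve$lag_ms[pos]; m <- curve$msd_um2[pos]
  if (length(lag) < 2) stop("need at least two positive lags")
  if (is.null(window)) {
    lo <- if (length(lag) > 4) lag[3] else lag[1]
    hi <- lag[max(which(lag <= max(lag) * 0.9))]
    window <- c(lo, hi)
  }
  sel <- lag >= window[1] & lag <= window[2]
  if (sum(sel) < 2) stop("fit window contains fewer than two lags")
  fit <- lm(log(m[sel]) ~ log(lag[sel]))
  gamma <- unname(coef(fit)[2])
  # noiseless (exact power-law) input is legitimate; summary() warns then
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  ci <- suppressWarnings(tryCatch(unname(confint(fit)[2, ]),
                                  error = function(e) gamma + c(-1.96, 1.96) * se))
  structure(list(gamma = gamma, se = se, ci = ci,
                 prefactor = exp(unname(coef(fit)[1])), window = window,
                 n_lags = sum(sel), fit = fit),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma = %.3f (se %.3f, 95%% CI %.3f-%.3f) over lags %.3g-%.3g ms (%d points)\n",
              x$gamma, x$se, x$ci[1], x$ci[2], x$window[1], x$window[2],
              x$n_lags))
  invisible(x)
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' Slope of `<r^2>` against lag over a window, divided by `2 * dims`
#' (Einstein relation `<r^2> = 2 * dims * D * t`).
#'
#' @param curve an [msd()] result.
#' @param window optional `c(min_lag_ms, max_lag_ms)`; defaults to the
#'   [fit_gamma()] window.
#' @return Apparent D in um^2/ms.
#' @export
msd_diffusivity <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  dims <- attr(curve, "dims")
  lag <- curve$lag_ms; m <- curve$msd_um2
  pos <- lag > 0
  if (is.null(window)) {
    lp <- lag[pos]
    window <- c(if (sum(pos) > 4) lp[3] else lp[1], max(lp) * 0.9)
  }
  sel <- pos & lag >= window[1] & lag <= window[2]
  fit <- lm(m[sel] ~ lag[sel])
  unname(coef(fit)[2]) / (2 * dims)
}

#' @export
plot.msd_curve <- function(x, log = TRUE, ...) {
  sel <- x$lag_ms > 0 & x$msd_um2 > 0
  plot(x$lag_ms[sel], x$msd_um2[sel], type = "l",
       log = if (log) "xy" else "", xlab = "lag (ms)",
       ylab = expression("<" * r^2 * "> (" * mu * m^2 * ")"), ...)
  invisible(x)
}
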