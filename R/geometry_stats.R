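#' Radially averaged spatial power spectral density
#'
#' Fourier analysis of ECS structure: the plane is mean-subtracted (optional
#' Hann taper), transformed, and the power `|F|^2` (normalised so that the
#' summed power equals the image variance, Parseval) is averaged over annular
#' frequency bins. The bin width is one frequency-grid step of the shorter
#' image axis and the curve extends to that axis's Nyquist frequency.
#'
#' @param x numeric matrix (a 2D image plane) or a 2D [alpha_map()].
#' @param pixel_size_nm lateral pixel size in nm (taken from the map when
#'   `x` is an `alpha_map`).
#' @param window `"none"` (default) or `"hann"`.
#' @return An object of class `psd_curve`: data frame `freq_um` (bin centre,
#'   cycles/um), `power`, `n` (grid points per bin).
#' @export
radial_psd <- function(x, pixel_size_nm = NULL, window = c("none", "hann")) {
  window <- match.arg(window)
  if (is_alpha_map(x)) {
    if (is.null(pixel_size_nm)) pixel_size_nm <- x$pixel_size_nm
    x <- x$alpha
  }
  if (length(dim(x)) != 2L) stop("radial PSD is defined on 2D planes")
  if (is.null(pixel_size_nm)) stop("pixel size unknown; pass `pixel_size_nm`")
  nr <- nrow(x); nc <- ncol(x)
  dx_um <- pixel_size_nm / 1000
  z <- x - mean(x)
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
    z <- z * outer(wr, wc)
  }
  F <- fft(z)
  P <- Mod(F)^2 / (as.numeric(nr) * nc)^2
  fr <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr) / (nr * dx_um)
  fc <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc) / (nc * dx_um)
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  df <- 1 / (min(nr, nc) * dx_um)
  nyq <- 0.5 / dx_um
  bin <- as.integer(round(fmag / df))
  keep <- bin >= 1L & fmag <= nyq + df / 2
  power <- tapply(P[keep], bin[keep], mean)
  n <- tapply(P[keep], bin[keep], length)
  ks <- as.integer(names(power))
  out <- data.frame(freq_um = ks * df, power = as.numeric(power),
                    n = as.integer(n))
  out <- out[order(out$freq_um), ]
  rownames(out) <- NULL
  structure(out, class = c("psd_curve", "data.frame"),
            pixel_size_nm = pixel_size_nm, level = "plane",
            total_power = sum(P) - P[1, 1], variance = mean((x - mean(x))^2))
}

#' Two-level average of PSD curves
#'
#' Averages per-plane curves within each stack first, then across stacks, so
#' stacks contribute equally regardless of their plane counts.
#'
#' @param curves list of [radial_psd()] curves on a common frequency grid.
#' @param stacks grouping vector (one entry per curve); a single group by
#'   default.
#' @return A `psd_curve` tagged `"grand"` (or `"stack"` for one group).
#' @export
aggregate_psd <- function(curves, stacks = NULL) {
  stopifnot(length(curves) >= 1)
  f <- curves[[1]]$freq_um
  for (cv in curves) if (!isTRUE(all.equal(cv$freq_um, f)))
    stop("frequency grids differ")
  if (is.null(stacks)) stacks <- rep(1L, length(curves))
  stacks <- as.factor(stacks)
  pm <- sapply(curves, function(cv) cv$power)
  stack_means <- sapply(levels(stacks), function(s)
    rowMeans(pm[, stacks == s, drop = FALSE]))
  out <- data.frame(freq_um = f, power = rowMeans(stack_means),
                    n = curves[[1]]$n)
  structure(out, class = c("psd_curve", "data.frame"),
            pixel_size_nm = attr(curves[[1]], "pixel_size_nm"),
            level = if (nlevels(stacks) > 1) "grand" else "stack")
}

#' Band-wise power-law fit of a PSD curve
#'
#' Linear regression of log power on log frequency within `[f_min, f_max]`;
#' the spectral exponent is `beta = -slope` of `PSD ~ 1/f^beta`. Typical
#' analysis bands are 0.13-0.5 cycles/um (somas, large dendrites) and
#' 0.5-2 cycles/um (finer structure); frequencies above 2 cycles/um are
#' dominated by detector noise and excluded from structural fits.
#'
#' @param curve a [radial_psd()] or [aggregate_psd()] result.
#' @param f_min,f_max band limits in cycles/um.
#' @return An object of class `power_law_fit`: `beta`, `ci` (95%), `se`,
#'   `band`, `n_bins`, the `lm` fit.
#' @export
fit_psd_band <- function(curve, f_min, f_max) {
  stopifnot(inherits(curve, "psd_curve"), f_min < f_max)
  sel <- curve$freq_um >= f_min & curve$freq_um <= f_max & curve$power > 0
  if (sum(sel) < 3) stop("need at least 3 bins inside the band")
  lf <- log(curve$freq_um[sel]); lp <- log(curve$power[sel])
  fit <- lm(lp ~ lf)
  beta <- -unname(coef(fit)[2])
  # noiseless (exact power-law) input is legitimate; summary() warns then
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  ci <- rev(-unname(suppressWarnings(confint(fit))[2, ]))
  structure(list(beta = beta, se = se, ci = ci, band = c(f_min, f_max),
                 n_bins = sum(sel), fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("PSD ~ 1/f^beta: beta = %.3f (95%% CI %.3f-%.3f) over %.3g-%.3g cycles/um (%d bins)\n",
              x$beta, x$ci[1], x$ci[2], x$band[1], x$band[2], x$n_bins))
  invisible(x)
}

#' @export
plot.psd_curve <- function(x, ...) {
  sel <- x$power > 0
  plot(x$freq_um[sel], x$power[sel], type = "l", log = "xy",
       xlab = expression("spatial frequency (" * mu * m^-1 * ")"),
       ylab = "radially averaged power", ...)
  invisible(x)
}

#' Normalised index of dispersion of concentrations around a source
#'
#' Quantifies diffusion anisotropy: at each radius, concentrations are
#' sampled on the ring of accessible pixels (alpha > 0, pixel-centre distance
#' within half a pixel of the radius) and summarised by the index of
#' dispersion `var/mean`. The normalised index divides once more by the ring
#' mean, making it invariant under rescaling `C -> c*C`; an isotropic spread
#' gives 0 at every radius.
#'
#' @param field a 2D [concentration_field()].
#' @param map the matching [alpha_map()] (rings use accessible pixels only).
#' @param source source pixel `c(row, col)`.
#' @param radii_um radii to sample, um.
#' @return Data frame `radius_um`, `n` (ring pixels), `index` (var/mean),
#'   `normalized` (var/mean^2).
#' @export
dispersion_index <- function(field, map, source, radii_um) {
  stopifnot(inherits(field, "concentration_field"), is_alpha_map(map))
  C <- field$C
  if (length(dim(C)) != 2L) stop("2D fields only")
  px_um <- field$pixel_size_nm / 1000
  rr <- (seq_len(nrow(C)) - source[1]) * px_um
  cc <- (seq_len(ncol(C)) - source[2]) * px_um
  dist <- sqrt(outer(rr^2, cc^2, `+`))
  open <- map$alpha > 0
  out <- lapply(radii_um, function(r) {
    ring <- abs(dist - r) <= px_um / 2 & open
    n <- sum(ring)
    if (n == 0)
      stop(sprintf("no accessible pixels on the ring at %.3g um", r))
    v <- C[ring]
    m <- mean(v)
    idx <- if (m > 0) var(v) / m else 0
    data.frame(radius_um = r, n = n, index = idx,
               normalized = if (m > 0) idx / m else 0)
  })
  do.call(rbind, out)
}
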