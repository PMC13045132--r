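# even-odd ray-crossing point-in-polygon test
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Extract the diffusion cloud around a point source
#'
#' The cloud is the connected component (4-connectivity) containing the
#' source among pixels with `C >= threshold * max(C)`. Its perimeter is the
#' sub-pixel iso-concentration contour at the threshold level (the polygon
#' enclosing the source), which avoids the half-pixel quantisation that
#' would otherwise make even a perfectly circular cloud look weakly
#' anisotropic; when no closed contour encloses the source (cloud clipped by
#' the frame), the boundary pixels of the component are used instead.
#' Perimeter distances to the source, in um, feed the directionality
#' statistics.
#'
#' @param field a 2D [concentration_field()] from a single-source run.
#' @param source source pixel `c(row, col)`.
#' @param threshold cloud boundary as a fraction of the field peak
#'   (default 0.01).
#' @return An object of class `diffusion_cloud`: `source`, `mask`,
#'   `perimeter` (n x 2, possibly fractional pixel coordinates),
#'   `distances_um`, `t_ms`, `pixel_size_nm`.
#' @export
extract_cloud <- function(field, source, threshold = 0.01) {
  stopifnot(inherits(field, "concentration_field"))
  C <- field$C
  if (length(dim(C)) != 2L) stop("2D fields only")
  peak <- max(C)
  if (peak <= 0) stop("field is empty")
  mask <- C >= threshold * peak
  if (!mask[source[1], source[2]])
    stop("source pixel is below the cloud threshold")
  comp <- flood_component(mask, source[1] - 1L, source[2] - 1L)
  nr <- nrow(C); nc <- ncol(C)
  per <- NULL
  if (threshold * peak < peak) {
    cl <- grDevices::contourLines(seq_len(nr), seq_len(nc), C,
                                  levels = threshold * peak)
    hit <- Filter(function(p) point_in_polygon(source[1], source[2],
                                               p$x, p$y), cl)
    if (length(hit)) {
      # outermost enclosing polygon (largest bounding box)
      ext <- vapply(hit, function(p) diff(range(p$x)) + diff(range(p$y)), 0)
      p <- hit[[which.max(ext)]]
      per <- cbind(p$x, p$y)
    }
  }
  if (is.null(per)) {
    # fallback: boundary pixels of the component
    pad <- rbind(FALSE, cbind(FALSE, comp, FALSE), FALSE)
    core <- pad[2:(nr + 1), 2:(nc + 1)] &
      pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
      pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
    per <- which(comp & !core, arr.ind = TRUE)
  }
  px_um <- field$pixel_size_nm / 1000
  d_um <- sqrt((per[, 1] - source[1])^2 + (per[, 2] - source[2])^2) * px_um
  structure(list(source = source, mask = comp,
                 perimeter = unname(per), distances_um = unname(d_um),
                 t_ms = field$t_ms, pixel_size_nm = field$pixel_size_nm,
                 threshold = threshold),
            class = "diffusion_cloud")
}

#' @export
print.diffusion_cloud <- function(x, ...) {
  cat(sprintf("<diffusion_cloud> %d px, %d perimeter points, max reach %.3g um (t = %.4g ms)\n",
              sum(x$mask), nrow(x$perimeter), max(x$distances_um), x$t_ms))
  invisible(x)
}

furthest_point <- function(cloud) {
  d <- cloud$distances_um
  imax <- which(d == max(d))
  if (length(imax) > 1) {
    # deterministic tie-break: lowest (row, col) lexicographic
    p <- cloud$perimeter[imax, , drop = FALSE]
    imax <- imax[order(p[, 1], p[, 2])][1]
  }
  cloud$perimeter[imax, ]
}

#' Main diffusion direction of a cloud
#'
#' The cloud axis is the principal axis (orthogonal / total least squares)
#' of the perimeter points; the furthest-from-source perimeter point (ties
#' broken by lowest row then column) picks which of the two axis directions
#' is reported. Goodness of fit is the normalised eigenvalue contrast
#' `(l1 - l2) / (l1 + l2)` in `[0, 1]`: 1 for a perfect line, 0 for a circle
#' (no preferred axis, the angle is then unreliable).
#'
#' Angles are degrees counter-clockwise from the +x (column) axis with y
#' pointing up (decreasing row), in `[0, 360)`.
#'
#' @param cloud an [extract_cloud()] result.
#' @return List with `angle_deg`, `folded_deg` (modulo 180) and `gof`.
#' @export
main_direction <- function(cloud) {
  stopifnot(inherits(cloud, "diffusion_cloud"))
  per <- cloud$perimeter
  if (nrow(per) < 2) stop("degenerate cloud: fewer than 2 perimeter points")
  x <- per[, 2] - mean(per[, 2])
  y <- -(per[, 1] - mean(per[, 1]))
  cv <- cov(cbind(x, y))
  eg <- eigen(cv, symmetric = TRUE)
  l <- pmax(eg$values, 0)
  gof <- if (sum(l) > 0) (l[1] - l[2]) / (l[1] + l[2]) else 0
  v <- eg$vectors[, 1]
  fp <- furthest_point(cloud)
  dir <- c(fp[2] - cloud$source[2], -(fp[1] - cloud$source[1]))
  if (sum(v * dir) < 0) v <- -v
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 360
  list(angle_deg = ang, folded_deg = ang %% 180, gof = gof)
}

#' Directionality coefficient of a cloud
#'
#' Perimeter distances are normalised by the furthest distance and their
#' cumulative distribution integrated; the coefficient is the normalised
#' area above the diagonal of that scale, computed as
#' `1 - mean(d) / max(d)`. A circular cloud (all perimeter distances equal)
#' gives exactly 0; the more elongated the cloud, the closer to 1.
#'
#' @param cloud an [extract_cloud()] result.
#' @return Coefficient in `[0, 1)`.
#' @export
directionality_coefficient <- function(cloud) {
  stopifnot(inherits(cloud, "diffusion_cloud"))
  d <- cloud$distances_um
  if (length(d) < 2) stop("degenerate cloud: fewer than 2 perimeter points")
  if (max(d) <= 0) stop("all perimeter distances are zero")
  1 - mean(d) / max(d)
}

#' Build the diffusion tensor of a cloud
#'
#' The tensor is the main-direction vector scaled by the directionality
#' coefficient: `magnitude = max_distance * coefficient` (um), so isotropic
#' spread yields a vanishing tensor. `strength` additionally weighs the
#' magnitude by the direction goodness of fit.
#'
#' @param cloud an [extract_cloud()] result.
#' @return An object of class `diffusion_tensor` with `angle_deg`,
#'   `folded_deg`, `magnitude_um`, `coefficient`, `r2` and `strength`.
#' @export
diffusion_tensor <- function(cloud) {
  md <- main_direction(cloud)
  coef <- directionality_coefficient(cloud)
  structure(list(angle_deg = md$angle_deg, folded_deg = md$folded_deg,
                 magnitude_um = max(cloud$distances_um) * coef,
                 coefficient = coef, r2 = md$gof,
                 strength = max(cloud$distances_um) * coef * md$gof),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat(sprintf("tensor: angle %.1f deg (folded %.1f), magnitude %.3g um, coefficient %.3f, r2 %.3f\n",
              x$angle_deg, x$folded_deg, x$magnitude_um, x$coefficient, x$r2))
  invisible(x)
}

#' Diffusion tensor map over a regular source grid
#'
#' Releases a short test pulse from every grid point on accessible pixels,
#' snapshots the field (default 100 us after release) and condenses each
#' diffusion cloud to a tensor. Each release is simulated on a local window
#' around its source (closed borders; the window comfortably contains the
#' cloud), which makes grids of hundreds of sources cheap.
#'
#' @param map a 2D [alpha_map()].
#' @param spacing_px grid spacing in pixels, `>= 2`.
#' @param cfg a [difflux_config()]; default pure-2D diffusion, since the
#'   in-plane clearance sink is isotropic and cancels from directionality.
#' @param snapshot_us cloud snapshot time after release, us.
#' @param n_molecules molecules per test release.
#' @param threshold cloud threshold, fraction of peak.
#' @param alpha_min sources with `alpha <` this are skipped (default: any
#'   zero-accessibility pixel).
#' @return A `tensor_field` data frame: one row per source with `row`,
#'   `col`, `x_um`, `y_um`, `angle_deg`, `folded_deg`, `magnitude_um`,
#'   `coefficient`, `r2`, `strength`; skipped grid points in
#'   `attr(, "n_skipped")`.
#' @export
tensor_grid <- function(map, spacing_px, cfg = NULL, snapshot_us = 100,
                        n_molecules = 5000, threshold = 0.01,
                        alpha_min = .Machine$double.eps) {
  stopifnot(is_alpha_map(map), spacing_px >= 2)
  if (is.null(cfg)) cfg <- difflux_config(mode = "2D", boundary = "closed")
  a <- map$alpha
  if (length(dim(a)) != 2L) stop("tensor maps are built on 2D maps")
  px_um <- map$pixel_size_nm / 1000
  t_ms <- snapshot_us / 1000
  sigma_px <- sqrt(4 * cfg$D_free * t_ms) / px_um
  half <- as.integer(ceiling(3.5 * sigma_px) + 4L)
  rows <- seq(1L + spacing_px %/% 2L, nrow(a), by = spacing_px)
  cols <- seq(1L + spacing_px %/% 2L, ncol(a), by = spacing_px)
  out <- list()
  skipped <- 0L
  for (r in rows) for (cl in cols) {
    if (a[r, cl] < alpha_min) { skipped <- skipped + 1L; next }
    r0 <- max(1L, r - half); r1 <- min(nrow(a), r + half)
    c0 <- max(1L, cl - half); c1 <- min(ncol(a), cl + half)
    sub <- alpha_map(a[r0:r1, c0:c1, drop = FALSE], map$pixel_size_nm,
                     map$z_step_nm)
    src <- c(r - r0 + 1L, cl - c0 + 1L)
    sim <- difflux_simulate(sub, release_event(src[1], src[2], n_molecules),
                            cfg, duration_ms = t_ms, record_interval_ms = t_ms)
    cloud <- tryCatch(extract_cloud(sim$field, src, threshold),
                      error = function(e) NULL)
    if (is.null(cloud) || nrow(cloud$perimeter) < 2 ||
        max(cloud$distances_um) <= 0) { skipped <- skipped + 1L; next }
    tn <- diffusion_tensor(cloud)
    out[[length(out) + 1L]] <-
      data.frame(row = r, col = cl, x_um = (cl - 1) * px_um,
                 y_um = (r - 1) * px_um, angle_deg = tn$angle_deg,
                 folded_deg = tn$folded_deg, magnitude_um = tn$magnitude_um,
                 coefficient = tn$coefficient, r2 = tn$r2,
                 strength = tn$strength)
  }
  if (!length(out)) stop("no accessible grid sources")
  res <- do.call(rbind, out)
  structure(res, class = c("tensor_field", "data.frame"),
            spacing_px = spacing_px, snapshot_us = snapshot_us,
            threshold = threshold, n_skipped = skipped,
            pixel_size_nm = map$pixel_size_nm)
}

#' @export
plot.tensor_field <- function(x, scale = 1, length = 0.03, ...) {
  plot(x$x_um, -x$y_um, pch = 16, cex = 0.3, asp = 1,
       xlab = "x (um)", ylab = "-y (um)", ...)
  th <- x$angle_deg * pi / 180
  arrows(x$x_um, -x$y_um, x$x_um + scale * x$magnitude_um * cos(th),
         -x$y_um + scale * x$magnitude_um * sin(th), length = length)
  invisible(x)
}

#' Angle and strength summaries of a tensor field
#'
#' Bins full angles into 30-degree sectors over `[0, 360)`, reports folded
#' (orientation, modulo 180) medians and interquartile ranges, strength mean
#' and SD, and, when a reference (e.g. dendrite) angle is given, the folded
#' angular deviations from it (wrapped into `[0, 90]`).
#'
#' @param tensors a [tensor_grid()] result (or data frame with `angle_deg`,
#'   `folded_deg`, `strength`).
#' @param reference_deg optional reference orientation in degrees.
#' @return An object of class `angle_summary`.
#' @export
summarize_angles <- function(tensors, reference_deg = NULL) {
  ang <- tensors$angle_deg %% 360
  fold <- tensors$folded_deg %% 180
  breaks <- seq(0, 360, by = 30)
  counts <- table(cut(ang, breaks, right = FALSE, include.lowest = TRUE))
  out <- list(bins_deg = breaks, counts = as.integer(counts),
              folded_median = median(fold),
              folded_iqr = unname(quantile(fold, c(0.25, 0.75))),
              strength_mean = mean(tensors$strength),
              strength_sd = sd(tensors$strength),
              n = length(ang), reference_deg = reference_deg)
  if (!is.null(reference_deg)) {
    dev <- abs(fold - reference_deg %% 180)
    dev <- pmin(dev, 180 - dev)
    out$deviation_median <- median(dev)
    out$deviation_deg <- dev
  }
  class(out) <- "angle_summary"
  out
}

#' @export
print.angle_summary <- function(x, ...) {
  cat(sprintf("%d tensors: folded median %.1f deg (IQR %.1f-%.1f), strength %.3g +/- %.3g\n",
              x$n, x$folded_median, x$folded_iqr[1], x$folded_iqr[2],
              x$strength_mean, x$strength_sd))
  lab <- sprintf("%d-%d", head(x$bins_deg, -1), x$bins_deg[-1])
  cat("  30-deg bins:", paste(sprintf("%s:%d", lab, x$counts), collapse = " "),
      "\n")
  if (!is.null(x$reference_deg))
    cat(sprintf("  median deviation from %.1f deg reference: %.1f deg\n",
                x$reference_deg, x$deviation_median))
  invisible(x)
}
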