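#' Construct a diffusional-accessibility (alpha) map
#'
#' An `alpha_map` holds the per-pixel ECS volume fraction alpha in `[0, 1]`
#' on a 2D plane or a 3D stack, together with its physical pixel sizes.
#' Alpha is the diffusionally accessible fraction of each pixel: 1 is pure
#' interstitial fluid, 0 is pure cellular structure, intermediate values are
#' partial-volume pixels. It is the central input to both simulation engines.
#'
#' Pixel indices are 1-based `(row, column[, plane])`; physical positions are
#' pixel centres, with the centre of pixel `(1, 1)` at the origin.
#'
#' @param alpha numeric matrix (2D) or 3D array of volume fractions in
#'   `[0, 1]`.
#' @param pixel_size_nm lateral pixel size in nanometres.
#' @param z_step_nm axial step in nanometres (3D stacks only).
#' @return An object of class `alpha_map`.
#' @examples
#' m <- alpha_map(matrix(0.25, 64, 64), pixel_size_nm = 50)
#' frame_alpha(m)
#' @export
alpha_map <- function(alpha, pixel_size_nm, z_step_nm = NULL) {
  if (!is.numeric(alpha) || !(length(dim(alpha)) %in% c(2L, 3L)))
    stop("`alpha` must be a numeric matrix or 3D array")
  if (anyNA(alpha) || min(alpha) < 0 || max(alpha) > 1)
    stop("alpha values must lie in [0, 1]")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive number")
  is3d <- length(dim(alpha)) == 3L
  if (is3d && is.null(z_step_nm))
    stop("3D alpha maps need `z_step_nm`")
  if (!is.null(z_step_nm) && z_step_nm <= 0)
    stop("`z_step_nm` must be positive")
  structure(list(alpha = alpha,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 z_step_nm = if (is3d) as.numeric(z_step_nm) else NULL),
            class = "alpha_map")
}

#' @export
is_alpha_map <- function(x) inherits(x, "alpha_map")

#' @export
dim.alpha_map <- function(x) dim(x$alpha)

#' @export
as.matrix.alpha_map <- function(x, ...) {
  if (length(dim(x$alpha)) == 3L) stop("alpha map is a 3D stack")
  x$alpha
}

#' @export
print.alpha_map <- function(x, ...) {
  d <- dim(x$alpha)
  kind <- if (length(d) == 3L) "3D stack" else "2D plane"
  cat(sprintf("<alpha_map> %s %s px, %.0f nm/px%s\n", kind,
              paste(d, collapse = " x "), x$pixel_size_nm,
              if (!is.null(x$z_step_nm)) sprintf(", z step %.0f nm", x$z_step_nm) else ""))
  cat(sprintf("  alpha: mean %.3f, median %.3f, range [%.3f, %.3f]\n",
              mean(x$alpha), median(x$alpha), min(x$alpha), max(x$alpha)))
  invisible(x)
}

#' @export
summary.alpha_map <- function(object, ...) {
  a <- object$alpha
  out <- list(dim = dim(a), pixel_size_nm = object$pixel_size_nm,
              z_step_nm = object$z_step_nm,
              mean_alpha = mean(a), median_alpha = median(a),
              sd_alpha = sd(as.numeric(a)), range = range(a),
              frac_zero = mean(a == 0))
  class(out) <- "summary.alpha_map"
  out
}

#' @export
print.summary.alpha_map <- function(x, ...) {
  cat(sprintf("alpha map %s px at %.0f nm/px\n",
              paste(x$dim, collapse = " x "), x$pixel_size_nm))
  cat(sprintf("  mean %.4f  median %.4f  sd %.4f  range [%.3f, %.3f]  %.1f%% blocked\n",
              x$mean_alpha, x$median_alpha, x$sd_alpha,
              x$range[1], x$range[2], 100 * x$frac_zero))
  invisible(x)
}

#' @export
plot.alpha_map <- function(x, plane = NULL, ...) {
  a <- x$alpha
  if (length(dim(a)) == 3L) {
    if (is.null(plane)) plane <- ceiling(dim(a)[3] / 2)
    a <- a[, , plane]
  }
  sz <- x$pixel_size_nm / 1000
  image(x = seq_len(ncol(a)) * sz, y = seq_len(nrow(a)) * sz,
        z = t(a)[, nrow(a):1], zlim = c(0, 1), col = gray(seq(0, 1, length.out = 256)),
        xlab = "x (um)", ylab = "y (um)", asp = 1, useRaster = TRUE, ...)
  invisible(x)
}

#' Frame or region volume fraction
#'
#' Summarises an alpha map by the median (default, following how frame alpha
#' is read out from normalised pixel values) or the mean of its pixels,
#' optionally restricted to a logical mask.
#'
#' @param map an [alpha_map()].
#' @param mask optional logical array of the same shape selecting a region.
#' @param stat `"median"` or `"mean"`.
#' @return A single alpha value.
#' @export
frame_alpha <- function(map, mask = NULL, stat = c("median", "mean")) {
  stopifnot(is_alpha_map(map))
  stat <- match.arg(stat)
  a <- map$alpha
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(a))) stop("mask shape must match the map")
    if (!any(mask)) stop("mask selects no pixels")
    a <- a[mask]
  }
  if (stat == "median") median(a) else mean(a)
}

#' Volume-averaged (homogenised) control map
#'
#' Replaces every pixel with the frame mean alpha, producing the structureless
#' volume-averaged control with the same total ECS volume as the input.
#' Idempotent; the mean (not the median) is used so that the summed alpha is
#' conserved exactly.
#'
#' @param map an [alpha_map()].
#' @return A uniform `alpha_map` of the same shape and pixel sizes.
#' @export
homogenize <- function(map) {
  stopifnot(is_alpha_map(map))
  a <- map$alpha
  a[] <- mean(a)
  alpha_map(a, map$pixel_size_nm, map$z_step_nm)
}

#' Alpha values along a line segment
#'
#' Samples alpha along the rasterised segment between two pixel coordinates
#' (nearest-pixel stepping, each pixel once) and summarises it by the median,
#' as used for radial line-profile readouts of the local volume fraction.
#'
#' @param map a 2D [alpha_map()].
#' @param start,end integer pixel coordinates `c(row, col)`, inside the image.
#' @return A list with `profile` (sampled alpha values), `rows`, `cols`
#'   (pixel indices) and `alpha` (median of the profile).
#' @export
line_profile_alpha <- function(map, start, end) {
  stopifnot(is_alpha_map(map))
  a <- map$alpha
  if (length(dim(a)) != 2L) stop("line profiles are defined on 2D maps")
  start <- as.integer(round(start)); end <- as.integer(round(end))
  d <- dim(a)
  if (any(start < 1L) || any(end < 1L) || start[1] > d[1] || end[1] > d[1] ||
      start[2] > d[2] || end[2] > d[2])
    stop("line endpoints must lie inside the image")
  n <- max(abs(end - start)) + 1L
  if (n == 1L) stop("zero-length line")
  rows <- as.integer(round(seq(start[1], end[1], length.out = n)))
  cols <- as.integer(round(seq(start[2], end[2], length.out = n)))
  keep <- c(TRUE, diff(rows) != 0L | diff(cols) != 0L)
  rows <- rows[keep]; cols <- cols[keep]
  prof <- a[cbind(rows, cols)]
  list(profile = prof, rows = rows, cols = cols, alpha = median(prof))
}
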