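# Phantom alpha-map generators. These emulate the imaged ECS geometries --
# uniform fields, angled dendrite tubes with a bright ECS rim, blob-like
# dense neuropil with power-law spatial structure, and spine/soma scenes
# with named source and probe positions -- so the full pipeline can run and
# be tested without microscopy data.

fft_gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  fr <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr) / nr
  fc <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc) / nc
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, `+`))
  Re(fft(fft(m) * H, inverse = TRUE)) / (nr * nc)
}

#' Uniform accessibility phantom
#'
#' @param alpha constant volume fraction in `[0, 1]`.
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm lateral pixel size, nm.
#' @return An [alpha_map()].
#' @export
make_uniform <- function(alpha, shape = c(128, 128), pixel_size_nm = 50) {
  alpha_map(matrix(alpha, shape[1], shape[2]), pixel_size_nm)
}

#' Blob-neuropil phantom with a connected ECS channel network
#'
#' Emulates dense neuropil at super-resolution pixel sizes: cellular
#' structures appear as blobs of near-zero accessibility, while the ECS is
#' the thin, connected sheet network between them, sampled as partial-volume
#' pixels. A Gaussian random field is smoothed to the requested correlation
#' length (the cell-structure size scale) and standardised; accessibility is
#' then placed along the field's zero-level contour network - which
#' percolates, like real interstitial sheets - via
#' `alpha = alpha_max * exp(-f^2 / (2 w^2))`, with the channel width `w`
#' chosen from the Gaussian expectation
#' `E[alpha] = alpha_max * w / sqrt(1 + w^2)` to meet the target mean
#' (followed by a small exact rescale). The realised frame mean is within
#' 0.01 of the target and the radial PSD decays as an approximate power law
#' whose exponent grows with the correlation length.
#'
#' @param target_alpha target frame mean alpha in `(0, alpha_max)`.
#' @param correlation_length_um cellular blob size scale, um.
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm lateral pixel size, nm.
#' @param seed integer seed; the same seed reproduces the map.
#' @param alpha_max accessibility at the channel centres (default 0.9; fine
#'   ECS rarely fills a pixel completely).
#' @return An [alpha_map()].
#' @export
make_blob_neuropil <- function(target_alpha = 0.25, correlation_length_um = 0.5,
                               shape = c(256, 256), pixel_size_nm = 50,
                               seed = 1, alpha_max = 0.9) {
  if (target_alpha <= 0 || target_alpha >= alpha_max)
    stop("`target_alpha` must lie in (0, alpha_max)")
  set.seed(seed)
  noise <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  sigma_px <- correlation_length_um * 1000 / pixel_size_nm
  f <- fft_gaussian_blur(noise, sigma_px)
  f <- (f - mean(f)) / sd(as.numeric(f))
  r <- target_alpha / alpha_max
  w <- sqrt(r^2 / (1 - r^2))
  a <- alpha_max * exp(-f^2 / (2 * w^2))
  a <- pmin(a * (target_alpha / mean(a)), 1)
  alpha_map(a, pixel_size_nm)
}

#' Angled dendrite-tube phantom
#'
#' An impermeable cylinder (the dendrite, alpha = 0) through the frame
#' centre at a given angle, wrapped in a high-accessibility ECS rim and
#' embedded in a uniform or blob background. The canonical fixture for
#' directionality analyses: diffusion tensors inside the rim should align
#' with the tube.
#'
#' @param angle_deg tube direction, degrees counter-clockwise from +x
#'   (y pointing up, i.e. decreasing row).
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm lateral pixel size, nm.
#' @param tube_width_um dendrite diameter, um.
#' @param rim_width_um ECS rim thickness on each side, um.
#' @param rim_alpha rim accessibility.
#' @param background `"uniform"` or `"blob"`.
#' @param bg_alpha background (target) alpha.
#' @param correlation_length_um blob background scale, um.
#' @param seed seed for the blob background.
#' @return An [alpha_map()].
#' @export
make_tube <- function(angle_deg, shape = c(200, 200), pixel_size_nm = 50,
                      tube_width_um = 1, rim_width_um = 0.3, rim_alpha = 0.9,
                      background = c("uniform", "blob"), bg_alpha = 0.25,
                      correlation_length_um = 0.5, seed = 1) {
  background <- match.arg(background)
  px_um <- pixel_size_nm / 1000
  if (tube_width_um + 2 * rim_width_um >= min(shape) * px_um)
    stop("tube does not fit in the frame")
  base <- if (background == "uniform")
    matrix(bg_alpha, shape[1], shape[2])
  else make_blob_neuropil(bg_alpha, correlation_length_um, shape,
                          pixel_size_nm, seed)$alpha
  th <- angle_deg * pi / 180
  cx <- (shape[2] + 1) / 2; cy <- (shape[1] + 1) / 2
  x <- (matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - cx) * px_um
  y <- -(matrix(seq_len(shape[1]), shape[1], shape[2]) - cy) * px_um
  d <- abs(-sin(th) * x + cos(th) * y)
  a <- base
  a[d <= tube_width_um / 2 + rim_width_um] <- rim_alpha
  a[d <= tube_width_um / 2] <- 0
  alpha_map(a, pixel_size_nm)
}

#' Spine-triad scene for crosstalk experiments
#'
#' A horizontal dendritic shaft carrying three spines (necks and heads are
#' cellular structure, alpha = 0), with the release synapse in the ECS just
#' above the central spine head and neighbour synapses above the flanking
#' heads, 2 um to each side. Partial obstacle walls between the source and
#' its neighbours force diffusional detours, emulating the intervening
#' neuropil structure that a volume-averaged control lacks.
#'
#' @param pixel_size_nm lateral pixel size, nm (frame is 10 x 10 um at the
#'   50 nm default).
#' @param bg_alpha background accessibility.
#' @return List with `map` (an [alpha_map()]), `source` and `neighbors`
#'   (pixel coordinates, neighbours as a 2-row matrix).
#' @export
make_spine_scene <- function(pixel_size_nm = 50, bg_alpha = 0.3) {
  px_um <- pixel_size_nm / 1000
  n <- as.integer(round(10 / px_um))  # 10 um frame
  a <- matrix(bg_alpha, n, n)
  um2row <- function(y) as.integer(round(y / px_um)) + 1L
  um2col <- function(x) as.integer(round(x / px_um)) + 1L
  # dendritic shaft
  a[um2row(7.2):um2row(8.2), ] <- 0
  heads_x <- c(3, 5, 7)
  rr <- as.integer(round(0.3 / px_um))
  for (x0 in heads_x) {
    cc <- um2col(x0)
    a[um2row(6.4):um2row(7.2), (cc - 1L):(cc + 1L)] <- 0  # neck
    hr <- um2row(6.0)
    for (r in (hr - rr):(hr + rr)) for (cl in (cc - rr):(cc + rr))
      if ((r - hr)^2 + (cl - cc)^2 <= rr^2) a[r, cl] <- 0
  }
  # partial walls between source and neighbours (gap above y = 4.6)
  for (x0 in c(4, 6)) {
    cc <- um2col(x0)
    a[um2row(4.6):um2row(6.8), cc:(cc + 1L)] <- 0
  }
  syn_row <- um2row(5.5)
  src <- c(syn_row, um2col(5))
  nb <- rbind(spine1 = c(syn_row, um2col(3)),
              spine2 = c(syn_row, um2col(7)))
  stopifnot(a[src[1], src[2]] > 0, all(a[nb] > 0))
  list(map = alpha_map(a, pixel_size_nm), source = src, neighbors = nb)
}

#' Soma-rim scene for spillover experiments
#'
#' A large impermeable soma disc with a thin bright ECS rim - the smooth
#' perisomatic sheet seen in shadow images - in a uniform neuropil
#' background. In tissue that sheet is sandwiched between the soma and the
#' cell bodies and processes abutting it, so the rim here is confined on its
#' outer side by a low-accessibility shell with a few openings into the
#' neuropil; this restriction is what lets perisomatic release events pile
#' up along the membrane. Release sites sit on the rim, spaced about 5 um
#' apart along the membrane, plus a matching column of neuropil release
#' sites at the same spacing. Two named probes sit at the same distance
#' (about 1.2 um) from their nearest release site: one on the rim next to
#' the soma membrane, one in open neuropil.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param pixel_size_nm lateral pixel size, nm.
#' @param bg_alpha neuropil background accessibility.
#' @param rim_alpha rim accessibility.
#' @param soma_radius_um soma radius, um.
#' @param site_spacing_um spacing of release sites along the rim and in the
#'   neuropil, um.
#' @param shell_alpha accessibility of the abutting-cell shell outside the
#'   rim (set to `bg_alpha` for an unconfined rim).
#' @return List with `map`, `release_sites` (matrix, rim sites then neuropil
#'   sites), `probes` (2-row matrix, rownames `membrane` and `neuropil`).
#' @export
make_soma_rim <- function(shape = c(128, 128), pixel_size_nm = 100,
                          bg_alpha = 0.25, rim_alpha = 0.75,
                          soma_radius_um = 3, site_spacing_um = 5,
                          shell_alpha = 0.05) {
  px_um <- pixel_size_nm / 1000
  nr <- shape[1]; nc <- shape[2]
  a <- matrix(bg_alpha, nr, nc)
  cy <- nr / 2 * px_um; cx <- nc * 0.36 * px_um
  rim_w <- 0.3
  yy <- (matrix(seq_len(nr), nr, nc) - 1) * px_um
  xx <- (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 1) * px_um
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  ang <- atan2(yy - cy, xx - cx)
  # abutting cells: low-alpha shell with four 0.5 rad openings
  shell <- d > soma_radius_um + rim_w & d <= soma_radius_um + rim_w + 0.6
  gaps <- (ang %% (pi / 2)) < 0.5
  a[shell & !gaps] <- shell_alpha
  a[d <= soma_radius_um + rim_w] <- rim_alpha
  a[d <= soma_radius_um] <- 0
  r_site <- soma_radius_um + rim_w / 2
  dth <- site_spacing_um / r_site
  angles <- seq(0, 2 * pi - dth / 2, by = dth)
  snap <- function(y, x) c(as.integer(round(y / px_um)) + 1L,
                           as.integer(round(x / px_um)) + 1L)
  rim_sites <- t(vapply(angles, function(t.)
    snap(cy + r_site * sin(t.), cx + r_site * cos(t.)), integer(2)))
  # neuropil sites: vertical line in the open right-hand region
  x_np <- nc * 0.85 * px_um
  y_np <- seq(px_um * 4, (nr - 4) * px_um, by = site_spacing_um)
  np_sites <- t(vapply(y_np, function(y) snap(y, x_np), integer(2)))
  sites <- rbind(rim_sites, np_sites)
  keep <- sites[, 1] >= 1 & sites[, 1] <= nr & sites[, 2] >= 1 &
    sites[, 2] <= nc
  sites <- sites[keep, , drop = FALSE]
  stopifnot(all(a[sites] > 0))
  # probes 1.2 um from their nearest site
  th_p <- angles[1] + 1.2 / r_site
  membrane <- snap(cy + r_site * sin(th_p), cx + r_site * cos(th_p))
  neuropil <- snap(y_np[1] + 1.2, x_np)
  probes <- rbind(membrane = membrane, neuropil = neuropil)
  stopifnot(all(a[probes] > 0))
  list(map = alpha_map(a, pixel_size_nm), release_sites = sites,
       probes = probes)
}
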