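#' Read a grayscale microscopy image or stack from TIFF
#'
#' Reads single-plane or multi-page TIFF into an integer matrix (2D) or array
#' (3D, planes stacked along the third dimension). Values are returned on
#' their native integer scale. Pixel sizes are not reliably stored in TIFF
#' tags across acquisition software, so they are supplied explicitly.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm lateral pixel size in nm.
#' @param z_step_nm axial step in nm for stacks.
#' @return Integer matrix/array with attributes `pixel_size_nm`,
#'   `z_step_nm` and `bit_depth`.
#' @export
read_image_tiff <- function(path, pixel_size_nm, z_step_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel
    p
  })
  img <- if (length(pages) == 1L) pages[[1]] else
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  storage.mode(img) <- "integer"
  attr(img, "pixel_size_nm") <- pixel_size_nm
  attr(img, "z_step_nm") <- z_step_nm
  attr(img, "bit_depth") <- if (max(img) > 255L) 16L else 8L
  img
}

#' Write an alpha map as 32-bit float TIFF
#'
#' @param map an [alpha_map()].
#' @param path output file path.
#' @export
write_alpha_tiff <- function(map, path) {
  stopifnot(is_alpha_map(map))
  a <- map$alpha
  if (length(dim(a)) == 3L) {
    planes <- lapply(seq_len(dim(a)[3]), function(k) a[, , k])
    tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(a, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read an alpha map written as float TIFF
#'
#' @inheritParams read_image_tiff
#' @return An [alpha_map()].
#' @export
read_alpha_tiff <- function(path, pixel_size_nm, z_step_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- if (length(pages) == 1L) pages[[1]] else
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  alpha_map(a, pixel_size_nm, z_step_nm)
}

#' Remove single-pixel detector noise with a 1-pixel median filter
#'
#' Replaces each pixel with the median of its 3x3 neighbourhood (replicate
#' padding at borders, applied per z-plane for stacks). This is the only
#' pre-processing applied to raw images before normalisation: it removes
#' isolated dark-count pixels without smoothing structure.
#'
#' @param img integer/numeric matrix or 3D array.
#' @return Filtered image of the same shape, attributes preserved.
#' @export
median_filter_1px <- function(img) {
  d <- dim(img)
  if (is.null(d) || any(d[1:2] < 3L))
    stop("image must be at least 3 x 3")
  at <- attributes(img)
  if (length(d) == 3L) {
    out <- img
    for (k in seq_len(d[3])) out[, , k] <- median3x3(matrix(as.numeric(img[, , k]), d[1], d[2]))
  } else {
    out <- median3x3(matrix(as.numeric(img), d[1], d[2]))
  }
  if (is.integer(img)) storage.mode(out) <- "integer"
  attributes(out) <- at
  out
}

#' Intensity-normalise a raw fluorescence image to 8 bits
#'
#' Maps raw intensities linearly so that the background level (imaged inside
#' somas, devoid of fluorophore) becomes 0 and the maximum (a pure
#' fluorophore-filled ECS volume) becomes 255:
#' `F_pix = (F_raw - F_bckg) / (F_max - F_bckg) * 255`,
#' clamped to `[0, 255]` and rounded half-to-even to integers.
#'
#' @param img raw image matrix/array.
#' @param f_bckg background intensity, `>= 0`.
#' @param f_max maximum ECS intensity, `> f_bckg`.
#' @return 8-bit integer image, same shape, attributes preserved.
#' @export
normalize_image <- function(img, f_bckg, f_max) {
  if (!is.numeric(f_bckg) || !is.numeric(f_max) || f_bckg < 0 || f_max <= f_bckg)
    stop("invalid normalisation parameters: need f_max > f_bckg >= 0")
  at <- attributes(img)
  out <- (as.numeric(img) - f_bckg) / (f_max - f_bckg) * 255
  out <- round(pmin(pmax(out, 0), 255))  # round() is half-to-even
  out <- as.integer(out)
  attributes(out) <- at
  attr(out, "bit_depth") <- 8L
  out
}

#' Build an alpha map from a normalised 8-bit image
#'
#' The per-pixel ECS volume fraction is read out directly as the relative
#' pixel intensity `F_pix / 255` of the intensity-normalised image.
#'
#' @param img 8-bit normalised image (matrix or 3D array).
#' @param pixel_size_nm lateral pixel size in nm; taken from the image
#'   attribute when omitted.
#' @param z_step_nm axial step in nm for stacks.
#' @return An [alpha_map()].
#' @export
alpha_from_image <- function(img, pixel_size_nm = attr(img, "pixel_size_nm"),
                             z_step_nm = attr(img, "z_step_nm")) {
  if (is.null(pixel_size_nm)) stop("pixel size unknown; pass `pixel_size_nm`")
  if (min(img) < 0 || max(img) > 255)
    stop("image is not 8-bit normalised; run normalize_image() first")
  a <- as.numeric(img) / 255
  dim(a) <- dim(img)
  alpha_map(a, pixel_size_nm, z_step_nm)
}
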