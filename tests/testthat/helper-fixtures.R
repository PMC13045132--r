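# Shared fixtures, built in code.

# Random field with a prescribed isotropic power-law spectrum 1/f^beta,
# rescaled to [0, 1]; the independent generator used to check spectral
# exponent recovery.
gen_beta_field <- function(beta, n = 256, pixel_size_nm = 50, seed = 1) {
  set.seed(seed)
  f1 <- ifelse(0:(n - 1) <= n / 2, 0:(n - 1), 0:(n - 1) - n) /
    (n * pixel_size_nm / 1000)
  fm <- sqrt(outer(f1^2, f1^2, `+`))
  amp <- fm^(-beta / 2)
  amp[1, 1] <- 0
  ph <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  x <- Re(fft(amp * ph, inverse = TRUE))
  (x - min(x)) / (max(x) - min(x))
}

# n source pixels with alpha above a floor, drawn reproducibly
pick_open_sources <- function(map, n, seed, alpha_min = 0.5) {
  ok <- which(map$alpha > alpha_min, arr.ind = TRUE)
  set.seed(seed)
  ok[sample(nrow(ok), n), , drop = FALSE]
}

# hand-built diffusion cloud from explicit perimeter points (row, col)
cloud_from_points <- function(per, source = c(0, 0), pixel_size_nm = 1000) {
  d_um <- sqrt((per[, 1] - source[1])^2 + (per[, 2] - source[2])^2) *
    pixel_size_nm / 1000
  structure(list(source = source, mask = NULL, perimeter = per,
                 distances_um = d_um, t_ms = 0.1,
                 pixel_size_nm = pixel_size_nm, threshold = 0.01),
            class = "diffusion_cloud")
}

# closed-form 2D free-diffusion Gaussian for a point release of
# concentration S in one pixel of side px_um
gaussian2d_field <- function(n, src, S, px_um, D, t_ms) {
  r2 <- outer(((seq_len(n)) - src[1])^2, ((seq_len(n)) - src[2])^2, `+`) *
    px_um^2
  S * px_um^2 * exp(-r2 / (4 * D * t_ms)) / (4 * pi * D * t_ms)
}
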