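test_that("clouds from symmetric fields are circular with near-equal reach", {
  n <- 65
  m <- make_uniform(1, c(n, n), 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed")
  sim <- difflux_simulate(m, release_event(33, 33, 5000), cfg, 0.1)
  cl <- extract_cloud(sim$field, c(33, 33))
  d <- cl$distances_um
  expect_lt((max(d) - min(d)) / mean(d), 0.02)
  expect_lt(directionality_coefficient(cl), 0.01)
  md <- main_direction(cl)
  expect_lt(md$gof, 0.05)

  # threshold 1: the cloud degenerates to the peak pixel
  cl1 <- extract_cloud(sim$field, c(33, 33), threshold = 1)
  expect_equal(sum(cl1$mask), 1)
  expect_error(main_direction(cl1), "degenerate")
})

test_that("the cloud respects blocked geometry", {
  n <- 65
  a <- matrix(1, n, n); a[, 1:30] <- 0
  m <- alpha_map(a, 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed")
  sim <- difflux_simulate(m, release_event(33, 33, 5000), cfg, 0.1)
  cl <- extract_cloud(sim$field, c(33, 33))
  expect_true(all(!cl$mask[, 1:30]))
  # blocked half-plane: perimeter reach is asymmetric, unlike a free cloud
  expect_gt(directionality_coefficient(cl), 0.1)
})

test_that("main direction recovers a constructed 16-degree axis", {
  t_seq <- seq(-1, 1, length.out = 41)
  th <- 16 * pi / 180
  per <- cbind(-40 * t_seq * sin(th), 40 * t_seq * cos(th))  # (row, col)
  cl <- cloud_from_points(per)
  md <- main_direction(cl)
  expect_equal(md$folded_deg, 16, tolerance = 0.5)
  expect_gt(md$gof, 0.999)
  # the full angle points toward the furthest point
  expect_true(md$angle_deg %in% c(md$folded_deg, md$folded_deg + 180))
})

test_that("furthest-point ties break deterministically by lowest row then column", {
  per <- rbind(c(-5, 0), c(5, 0), c(0, -5), c(0, 5), c(-1, 1), c(1, -1))
  cl <- cloud_from_points(per)
  fp <- difflux:::furthest_point(cl)
  expect_equal(fp, c(-5, 0))
  md1 <- main_direction(cl); md2 <- main_direction(cl)
  expect_identical(md1, md2)
})

test_that("directionality coefficient is 0 for circles and grows with elongation", {
  th <- seq(0, 2 * pi, length.out = 721)[-1]
  circ <- cloud_from_points(cbind(10 * sin(th), 10 * cos(th)))
  expect_equal(directionality_coefficient(circ), 0, tolerance = 1e-12)
  expect_equal(diffusion_tensor(circ)$magnitude_um, 0, tolerance = 1e-10)

  coefs <- sapply(c(1, 1.5, 2, 3, 5), function(ar) {
    per <- cbind(10 / ar * sin(th), 10 * cos(th))
    directionality_coefficient(cloud_from_points(per))
  })
  expect_true(all(diff(coefs) > 0))
  expect_true(all(coefs >= 0 & coefs < 1))
  # numeric oracle for the 2:1 ellipse: quadrature over the same
  # eccentric-anomaly parametrisation, 1 - mean(d)/max(d)
  d_fun <- function(t) sqrt(25 * sin(t)^2 + 100 * cos(t)^2)
  mean_d <- integrate(d_fun, 0, 2 * pi)$value / (2 * pi)
  expect_equal(coefs[3], 1 - mean_d / 10, tolerance = 1e-3)
})

test_that("tensor grids align with dendrite tubes and rotate equivariantly", {
  tb0 <- make_tube(0, shape = c(120, 120), background = "uniform",
                   bg_alpha = 0.25)
  tb90 <- make_tube(90, shape = c(120, 120), background = "uniform",
                    bg_alpha = 0.25)
  tf0 <- tensor_grid(tb0, 10)
  tf90 <- tensor_grid(tb90, 10)
  top0 <- tf0[order(-tf0$strength)[1:10], ]
  top90 <- tf90[order(-tf90$strength)[1:10], ]
  dev0 <- (top0$folded_deg + 90) %% 180 - 90
  dev90 <- (top90$folded_deg - 90 + 90) %% 180 - 90
  expect_lt(abs(median(dev0)), 5)
  expect_lt(abs(median(dev90)), 5)
  # rotating the map by 90 degrees leaves the magnitudes unchanged
  expect_equal(median(top90$magnitude_um), median(top0$magnitude_um),
               tolerance = 0.15)
})

test_that("tensor strength is higher in the tube rim than in blob neuropil", {
  tb <- make_tube(16, shape = c(160, 160), background = "blob",
                  bg_alpha = 0.25, seed = 4)
  tf <- tensor_grid(tb, 10)
  rim <- tb$alpha[cbind(tf$row, tf$col)] > 0.85
  expect_gt(sum(rim), 3)
  expect_gt(mean(tf$strength[rim]), mean(tf$strength[!rim]))
})

test_that("angle summaries bin, fold and compare against a reference", {
  tens <- data.frame(angle_deg = rep(c(16, 196), 10),
                     folded_deg = rep(16, 20), strength = rep(0.5, 20))
  s <- summarize_angles(tens, reference_deg = 16)
  expect_equal(sum(s$counts > 0), 2)  # bins 0-30 and 180-210 only
  expect_equal(s$counts[1], 10)
  expect_equal(s$counts[7], 10)
  expect_equal(s$folded_median, 16)
  expect_equal(s$deviation_median, 0)
  # folding identity
  expect_equal(196 %% 180, 16)
  # uniform random orientations have a folded median near 90
  set.seed(31)
  rnd <- data.frame(angle_deg = runif(600, 0, 360))
  rnd$folded_deg <- rnd$angle_deg %% 180
  rnd$strength <- 1
  expect_lt(abs(summarize_angles(rnd)$folded_median - 90), 12)
})
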