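test_that("source concentration follows n / (N_A * voxel volume)", {
  # Avogadro's number of molecules in one litre is one molar
  expect_equal(source_concentration(6.02214076e23, 1e8, 1e8, 1e8), 1)
  s <- source_concentration(10000, 50)
  expect_equal(s, 1e4 / (6.02214076e23 * 1.25e-19), tolerance = 1e-12)
  expect_equal(source_concentration(5000, 50), s / 2)
  expect_error(source_concentration(0, 50), "positive")
  expect_error(source_concentration(10, -50), "positive")
})

test_that("clearance fraction follows the exponential-with-floor law", {
  expect_equal(kappa_t(0, 1e-6), 0.015075)
  expect_equal(kappa_t(10, 1e-6), 75e6 * 1e-12, tolerance = 1e-6)
  k <- kappa_t(seq(0, 0.01, 1e-4), 1e-6)
  expect_true(all(diff(k) <= 0))       # decays to the floor
  expect_true(all(diff(k[1:5]) < 0))   # strictly, while the exponential lives
})

test_that("pixel diffusivity maps alpha linearly onto D_free", {
  m <- alpha_map(matrix(c(0, 0.25, 1), 1, 3), 50)
  expect_equal(as.numeric(pixel_diffusivity(m, 0.75)), c(0, 0.1875, 0.75))
})

test_that("diffusivity unit conversion from m^2/s is correct", {
  expect_equal(diffusivity_um2_ms(1.1e-9), 1.1)
})

test_that("the stability bound is enforced with a suggestion", {
  m <- make_uniform(1, c(16, 16), 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", dt_us = 50)
  expect_error(difflux_simulate(m, release_event(8, 8, 100), cfg, 0.1),
               "stability")
  lim <- stability_limit_us(m, cfg)
  expect_equal(lim, 0.05^2 / (2 * 2 * 0.75) * 1000)
})

test_that("a uniform field without sources is a fixed point", {
  m <- make_uniform(0.5, c(12, 12), 50)
  f <- concentration_field(matrix(2e-6, 12, 12), 0, 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed",
                        dt_us = 0.5)
  f2 <- difflux_step(f, m, cfg)
  expect_equal(f2$C, f$C)
})

test_that("an alpha = 0 column blocks all flux between chambers", {
  a <- matrix(1, 20, 21)
  a[, 11] <- 0
  m <- alpha_map(a, 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed")
  sim <- difflux_simulate(m, release_event(10, 5, 1000), cfg,
                          duration_ms = 0.2)
  expect_true(all(sim$field$C[, 12:21] == 0))
  expect_gt(sum(sim$field$C[, 1:10]), 0)
})

test_that("free diffusion from a point matches the closed-form Gaussian", {
  n <- 128
  m <- make_uniform(1, c(n, n), 50)
  cfg <- difflux_config(D_free = 0.5, mode = "2D", boundary = "closed",
                        dt_us = 1)
  t_ms <- 0.09  # sigma = sqrt(2 D t) = 6 px
  sim <- difflux_simulate(m, release_event(64, 64, 10000), cfg, t_ms)
  ana <- gaussian2d_field(n, c(64, 64), source_concentration(10000, 50),
                          0.05, 0.5, t_ms)
  expect_lt(max(abs(sim$field$C - ana)) / max(ana), 0.02)
})

test_that("the leaky border rule reproduces ef times the inward neighbour", {
  set.seed(1)
  C <- matrix(runif(49, 0, 1e-6), 7, 7)
  f <- apply_leaky_boundary(concentration_field(C, 0, 50), ef = 0.9)
  expect_equal(f$C[1, 4], 0.9 * C[2, 4])
  expect_equal(f$C[7, 4], 0.9 * C[6, 4])
  expect_equal(f$C[4, 1], 0.9 * C[4, 2])
  expect_equal(f$C[4, 7], 0.9 * C[4, 6])
  expect_equal(f$C[1, 1], 0.9 * C[2, 2])
  # ef = 1 with a flat interior leaves the border at the interior level
  flat <- apply_leaky_boundary(concentration_field(matrix(1e-6, 5, 5), 0, 50),
                               ef = 1)
  expect_equal(flat$C, matrix(1e-6, 5, 5))
})

test_that("leaky borders only remove mass once the cloud reaches them", {
  m <- make_uniform(1, c(32, 32), 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "leaky")
  sim <- difflux_simulate(m, release_event(16, 16, 1000), cfg,
                          duration_ms = 0.5, record_interval_ms = 0.01)
  expect_gt(sim$mass$escaped_M, 0)
  total <- sum(sim$field$C)
  expect_equal(total + sim$mass$escaped_M, sim$mass$injected_M,
               tolerance = 1e-9)
})

test_that("responses are linear in the release schedule", {
  m <- make_blob_neuropil(0.4, 0.3, c(48, 48), 50, seed = 9)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed")
  e1 <- release_event(20, 20, 5000)
  e2 <- release_event(30, 28, 8000, time_ms = 0.05)
  both <- release_schedule(rbind(e1, e2))
  s1 <- difflux_simulate(m, e1, cfg, 0.3)
  s2 <- difflux_simulate(m, e2, cfg, 0.3)
  s12 <- difflux_simulate(m, both, cfg, 0.3)
  expect_equal(s12$field$C, s1$field$C + s2$field$C, tolerance = 1e-12)
})

test_that("a centred point source keeps the grid's dihedral symmetry", {
  n <- 33
  m <- make_uniform(0.6, c(n, n), 50)
  cfg <- difflux_config(D_free = 0.75, mode = "2D", boundary = "closed")
  sim <- difflux_simulate(m, release_event(17, 17, 1000), cfg, 0.1)
  C <- sim$field$C
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_equal(C, C[n:1, ], tolerance = 1e-12)
  expect_equal(C, C[, n:1], tolerance = 1e-12)
  expect_true(min(C) >= 0)
})

test_that("release trains follow the half-open convention and sort by time", {
  tr <- release_train(c(5, 5), 100, 1000, 100)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$time_ms, seq(0, 90, 10))
  expect_equal(nrow(release_train(c(5, 5), 10, 1000, 100)), 1)
  tr2 <- release_train(rbind(c(2, 2), c(8, 8)), 30, 500, 100)
  expect_equal(nrow(tr2), 6)
  expect_true(!is.unsorted(tr2$time_ms))
})

test_that("probes report peak, time to peak and a decay constant", {
  m <- make_uniform(0.8, c(48, 48), 50)
  cfg <- difflux_config(D_free = 0.75, mode = "3D_smpl", boundary = "leaky")
  sim <- difflux_simulate(m, release_event(24, 24, 10000), cfg, 1,
                          probes = rbind(at_source = c(24, 24),
                                         off = c(28, 24)))
  pm <- probe_metrics(sim)
  expect_equal(pm$probe, c("at_source", "off"))
  # at the source: immediate peak then monotone-ish decay
  expect_lt(pm$t_peak_ms[1], 0.01)
  expect_gt(pm$t_peak_ms[2], pm$t_peak_ms[1])
  expect_gt(pm$peak_uM[1], pm$peak_uM[2])
  expect_true(is.finite(pm$tau_ms[1]) && pm$tau_ms[1] > 0)
  # a probe on a blocked pixel stays silent, with a warning
  a <- m$alpha; a[10, 10] <- 0
  m0 <- alpha_map(a, 50)
  expect_warning(s0 <- difflux_simulate(m0, release_event(24, 24, 100),
                                        cfg, 0.05,
                                        probes = rbind(dead = c(10, 10))),
                 "alpha = 0")
  expect_true(all(s0$conc_M == 0))
  # no release events: flat zero everywhere
  expect_error(difflux_simulate(m, release_event(60, 60, 10), cfg, 0.05),
               "outside")
})

test_that("full 3D conserves mass when closed and the simplified mode sits between 2D and 3D", {
  a3 <- array(0.25, c(40, 40, 11))
  m3 <- alpha_map(a3, 50, 100)
  cfg3 <- difflux_config(D_free = 0.75, mode = "3D", boundary = "closed",
                         dt_us = 1)
  sim3 <- difflux_simulate(m3, release_event(20, 20, 10000, plane = 6), cfg3,
                           duration_ms = 0.2)
  expect_equal(sum(sim3$field$C), sim3$mass$injected_M, tolerance = 1e-11)

  probe3 <- rbind(near = c(23, 20, 6))
  cfg3l <- difflux_config(D_free = 0.75, mode = "3D", boundary = "leaky",
                          dt_us = 1)
  p3 <- probe_metrics(difflux_simulate(m3, release_event(20, 20, 10000,
                                                         plane = 6),
                                       cfg3l, 1, probes = probe3))
  m2 <- alpha_map(matrix(0.25, 40, 40), 50, 100)
  probe2 <- rbind(near = c(23, 20))
  ev <- release_event(20, 20, 10000)
  ps <- probe_metrics(difflux_simulate(m2, ev,
    difflux_config(D_free = 0.75, mode = "3D_smpl", dt_us = 1), 1,
    probes = probe2))
  p2 <- probe_metrics(difflux_simulate(m2, ev,
    difflux_config(D_free = 0.75, mode = "2D", dt_us = 1), 1,
    probes = probe2))
  # the clearance sink moves the plane simulation from 2D toward full 3D
  expect_true(p2$peak_uM > ps$peak_uM && ps$peak_uM > p3$peak_uM)
  expect_true(p2$tau_ms > ps$tau_ms && ps$tau_ms > p3$tau_ms)
})

test_that("clearance removes nothing where alpha is zero", {
  a <- matrix(0.5, 10, 10); a[3, 3] <- 0
  m <- alpha_map(a, 50)
  C0 <- matrix(1e-6, 10, 10)
  cfg <- difflux_config(D_free = 0.75, mode = "3D_smpl", boundary = "closed",
                        dt_us = 0.5)
  # alpha = 0 pixel: no diffusion in or out and no clearance -> unchanged
  f <- concentration_field(C0, 0, 50)
  f1 <- difflux_step(f, m, cfg)
  expect_equal(f1$C[3, 3], 1e-6)
  # accessible pixels lose the alpha-scaled fraction
  kap <- kappa_t(0, 0.5e-6)
  expect_equal(f1$C[6, 6], 1e-6 * (1 - 0.5 * kap), tolerance = 1e-9)
})
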