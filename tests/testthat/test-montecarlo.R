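test_that("single steps accept moves with probability alpha(target)", {
  free <- make_uniform(1, c(9, 9), 50)
  blocked <- make_uniform(0, c(9, 9), 50)
  set.seed(11)
  for (i in 1:50) expect_false(all(mc_step(c(5, 5), free) == c(5, 5)))
  for (i in 1:50) expect_equal(mc_step(c(5, 5), blocked), c(5, 5))

  m25 <- make_uniform(0.25, c(9, 9), 50)
  set.seed(12)
  n_draw <- 4000
  moved <- sum(vapply(seq_len(n_draw), function(i)
    any(mc_step(c(5, 5), m25) != c(5, 5)), TRUE))
  # binomial 99.9% interval around p = 0.25
  expect_lt(abs(moved / n_draw - 0.25), 3.3 * sqrt(0.25 * 0.75 / n_draw))
  # moves change exactly one coordinate by one pixel
  set.seed(13)
  p <- mc_step(c(5, 5), free)
  expect_equal(sum(abs(p - c(5, 5))), 1)
})

test_that("walks are reproducible under the seed and start at the source", {
  m <- make_blob_neuropil(0.3, 0.5, c(48, 48), 50, seed = 2)
  src <- pick_open_sources(m, 3, seed = 2)
  cfg <- walk_config(n_particles = 20, duration_ms = 2, seed = 77)
  t1 <- simulate_walk(m, src, cfg)
  t2 <- simulate_walk(m, src, cfg)
  expect_identical(t1$unwrapped, t2$unwrapped)
  t3 <- simulate_walk(m, src, walk_config(n_particles = 20, duration_ms = 2,
                                          seed = 78))
  expect_false(identical(t1$unwrapped, t3$unwrapped))
  # sample 0 is the source for every particle
  expect_equal(t1$unwrapped[1, , 1], rep(src[t1$source_index, 1], 1))
  expect_equal(t1$unwrapped[1, , 2], rep(src[t1$source_index, 2], 1))
})

test_that("walk steps move at most one pixel along one axis and wrap toroidally", {
  m <- make_uniform(1, c(10, 10), 50)
  cfg <- walk_config(n_particles = 5, duration_ms = 0.1, seed = 4,
                     record_every = 1)
  tr <- simulate_walk(m, c(1, 1), cfg)  # at the corner, wraps immediately
  u <- tr$unwrapped
  steps <- abs(u[-1, , , drop = FALSE] - u[-dim(u)[1], , , drop = FALSE])
  expect_true(all(steps %in% c(0, 1)))
  expect_true(all(apply(steps, c(1, 2), sum) <= 1))
  # wrapped positions stay on the grid; particle count is preserved
  expect_true(all(tr$wrapped_final >= 1 & tr$wrapped_final <= 10))
  expect_equal(sum(mc_density(tr)), 5)
})

test_that("sources on blocked pixels and rank mismatches are rejected", {
  a <- matrix(0.5, 8, 8); a[4, 4] <- 0
  m <- alpha_map(a, 50)
  expect_error(simulate_walk(m, c(4, 4), walk_config(n_particles = 1)),
               "alpha > 0")
  expect_error(simulate_walk(m, c(2, 2), walk_config(dims = 3)),
               "rank")
})

test_that("MSD reproduces hand-computed displacements and the free-field law", {
  # hand-built trajectory set: 1 particle, known unwrapped path
  path <- rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1), c(2, 2))
  traj <- structure(list(
    unwrapped = array(c(path[, 1], path[, 2]), dim = c(5, 1, 2)),
    times_ms = 0:4, map_dim = c(10, 10), source_index = 1,
    sources = rbind(c(0, 0)), wrapped_final = rbind(c(3L, 3L)),
    pixel_size_nm = 1000, dt_ms = 1, n_steps = 4,
    cfg = walk_config(n_particles = 1, duration_ms = 4)),
    class = "mc_trajectories")
  mm <- msd(traj)
  expect_equal(mm$msd_um2, c(0, 1, 2, 5, 8))
  # sliding estimator averages all pairs at each lag
  ms <- msd(traj, method = "sliding")
  expect_equal(ms$msd_um2[1], 0)
  expect_equal(ms$msd_um2[2], mean(c(1, 1, 1, 1)))  # all single steps
  expect_equal(ms$msd_um2[3], mean(c(2, 2, 2)))

  # free field: <r^2> = 4 D t
  mfree <- make_uniform(1, c(64, 64), 50)
  cfg <- walk_config(D_free = 0.75, n_particles = 3000, duration_ms = 4,
                     seed = 5)
  curve <- msd(simulate_walk(mfree, c(32, 32), cfg))
  sel <- curve$lag_ms > 1
  expect_equal(curve$msd_um2[sel] / (4 * 0.75 * curve$lag_ms[sel]),
               rep(1, sum(sel)), tolerance = 0.05)
})

test_that("gamma fits recover constructed exponents", {
  lag <- seq(0.1, 10, by = 0.1)
  mk <- function(y) structure(data.frame(lag_ms = lag, msd_um2 = y, n = 100),
                              class = c("msd_curve", "data.frame"),
                              pixel_size_nm = 50, method = "origin", dims = 2)
  g1 <- fit_gamma(mk(4 * 0.75 * lag))
  expect_equal(g1$gamma, 1, tolerance = 1e-10)
  g08 <- fit_gamma(mk(0.3 * lag^0.8))
  expect_equal(g08$gamma, 0.8, tolerance = 1e-10)
  expect_true(g08$ci[1] <= 0.8 && 0.8 <= g08$ci[2])
  expect_error(fit_gamma(mk(rep(0, length(lag)))), "two positive lags")
  # apparent diffusivity from the Einstein relation
  expect_equal(msd_diffusivity(mk(4 * 0.6 * lag)), 0.6, tolerance = 1e-10)
})

test_that("zero-duration walks keep particles at their sources", {
  m <- make_uniform(0.8, c(16, 16), 50)
  cfg <- walk_config(n_particles = 10, duration_ms = 1e-9, seed = 1)
  tr <- simulate_walk(m, c(8, 8), cfg)
  expect_true(all(tr$wrapped_final[, 1] == 8 & tr$wrapped_final[, 2] == 8))
  expect_equal(max(abs(msd(tr)$msd_um2)), 0)
})

test_that("averaging MSD curves across sources is a pointwise mean", {
  m <- make_uniform(1, c(32, 32), 50)
  cfg <- walk_config(n_particles = 50, duration_ms = 1, seed = 3)
  c1 <- msd(simulate_walk(m, c(10, 10), cfg))
  c2 <- msd(simulate_walk(m, c(20, 20),
                          walk_config(n_particles = 50, duration_ms = 1,
                                      seed = 9)))
  agg <- aggregate_msd(list(c1, c2))
  expect_equal(agg$msd_um2, (c1$msd_um2 + c2$msd_um2) / 2)
})
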