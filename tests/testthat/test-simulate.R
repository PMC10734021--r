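test_that("bubble arrivals are Poisson with rate concentration x flow", {
  expect_equal(nrow(seed_bubbles(0, 0.02, 1)), 0)
  expect_equal(nrow(seed_bubbles(6.4e6, 0.02, 0)), 0)

  set.seed(42)
  # lambda = 6.4e6 * 0.02 / 60 ~ 2133 arrivals per second
  lambda <- 6.4e6 * 0.02 / 60
  t_total <- 2
  n <- sum(vapply(1:500, function(i) {
    nrow(seed_bubbles(6.4e6, 0.02, t_total / 500))
  }, numeric(1)))
  expect_lt(abs(n - lambda * t_total), 3 * sqrt(lambda * t_total))
})

test_that("entry offsets follow the flux-weighted distribution", {
  set.seed(7)
  u <- seed_bubbles(6.4e6, 0.2, 1)$lateral_offset
  expect_true(all(u >= -1 & u <= 1))
  # E[u^2] under p(u) ~ (1 - u^2) is 1/5
  expect_equal(mean(u^2), 0.2, tolerance = 0.02)
})

test_that("scatterer fields are static, off-channel and binomial in count", {
  set.seed(1)
  expect_equal(nrow(make_scatterer_field(0, 128, 128)), 0)

  n <- nrow(make_scatterer_field(0.005, 128, 128))
  expect_lt(abs(n - 0.005 * 128^2), 4 * sqrt(0.005 * 128^2))

  set.seed(99)
  a <- make_scatterer_field(0.01, 64, 64)
  set.seed(99)
  b <- make_scatterer_field(0.01, 64, 64)
  expect_identical(a, b)

  mask <- matrix(FALSE, 64, 64); mask[20:40, ] <- TRUE
  set.seed(3)
  sc <- make_scatterer_field(0.05, 64, 64, channel_mask = mask)
  expect_true(all(!mask[cbind(sc$row, sc$col)]))
})

test_that("CPS weights cancel linear scatterers exactly", {
  cfg <- acquisition_config(rows = 64, cols = 64, noise_sd = 0, mode = "CPS")
  set.seed(5)
  sc <- make_scatterer_field(0.02, 64, 64)
  fr <- render_frame(no_scatterers(), sc, cfg)
  expect_identical(max(abs(fr)), 0)

  fr0 <- render_frame(no_scatterers(), no_scatterers(), cfg)
  expect_identical(max(abs(fr0)), 0)
})

test_that("B-mode rendering equals direct PSF evaluation", {
  cfg <- acquisition_config(rows = 48, cols = 48, noise_sd = 0,
                            mode = "BMODE", psf_sigma_px = 1.5)
  fr <- render_frame(tibble::tibble(row = 20.4, col = 31.7, amp = 1),
                     no_scatterers(), cfg)
  oracle <- outer(1:48, 1:48, function(i, j) {
    exp(-((i - 20.4)^2 + (j - 31.7)^2) / (2 * 1.5^2))
  })
  # the stamp truncates the PSF at 4 sigma; the tail bound is exp(-8)
  expect_lt(max(abs(fr - oracle)), 4e-4)
  expect_equal(max(fr), max(oracle), tolerance = 1e-6)
})

test_that("advection follows the local profile and junction flow", {
  net <- single_channel(300, 1.4, 0.02)
  v_mean <- segment_velocities(net)$mean_v_mm_s
  b <- tibble::tibble(id = 1L, seg = 1L, s_mm = 0.3, u = 0, stuck = FALSE,
                      birth_frame = 1L)
  expect_identical(advect_bubbles(b, net, 0)$s_mm, 0.3)

  dt <- 0.004
  moved <- advect_bubbles(b, net, dt)
  expect_equal(moved$s_mm - 0.3, 1.5 * v_mean * dt, tolerance = 1e-12)

  # bubbles exiting the outlet are removed
  far <- tibble::tibble(id = 1L, seg = 1L, s_mm = 1.399, u = 0,
                        stuck = FALSE, birth_frame = 1L)
  expect_equal(nrow(advect_bubbles(far, net, 1)), 0)

  # junction: daughters are entered roughly in proportion to flow
  bi <- flow_split(build_bifurcation(300, 300, 45), flow_config(0.02))
  set.seed(11)
  picks <- vapply(1:200, function(i) {
    b <- tibble::tibble(id = 1L, seg = 1L, s_mm = 1.49, u = 0,
                        stuck = FALSE, birth_frame = 1L)
    advect_bubbles(b, bi, 0.02)$seg
  }, integer(1))
  expect_gt(mean(picks == 2), 0.35)   # symmetric split: ~half each
  expect_lt(mean(picks == 2), 0.65)
})

test_that("radiation drift immobilises bubbles only at the far (+z) wall", {
  net <- single_channel(300, 1.4, 0.02)
  drift <- list(drift_mm_s = 0.3, stick_prob = 0.3)
  set.seed(21)
  b <- tibble::tibble(id = 1:30, seg = 1L, s_mm = runif(30, 0, 0.2),
                      u = runif(30, -0.5, 0.5), stuck = FALSE,
                      birth_frame = 1L)
  for (i in 1:200) b <- advect_bubbles(b, net, 0.004, drift)
  stuck <- b[b$stuck, ]
  expect_gt(nrow(stuck), 0)
  # channel runs along +x, so its +z wall is the u = +1 side
  expect_true(all(stuck$u > 0.99))
})

test_that("generated sequences are reproducible and geometrically consistent", {
  net <- flow_split(build_bifurcation(300, 300, 45,
                                      lengths_mm = c(0.6, 0.8)),
                    flow_config(0.02))
  acq <- acquisition_config(rows = 64, cols = 64, n_frames = 40,
                            rng_seed = 123)
  sim1 <- generate_sequence(net, flow_config(0.02), acq)
  sim2 <- generate_sequence(net, flow_config(0.02), acq)
  expect_identical(unclass(sim1$stack), unclass(sim2$stack))
  expect_identical(sim1$truth, sim2$truth)

  # every true position lies inside the channel geometry
  loc <- local_velocity(net, sim1$truth$x_mm, sim1$truth$z_mm)
  expect_true(all(!is.na(loc$segment)))

  # and nearly all rasterise into the channel mask (wall positions can
  # round to a pixel centre just outside)
  px <- round((sim1$truth$z_mm - sim1$origin[2]) / 0.025) + 1
  py <- round((sim1$truth$x_mm - sim1$origin[1]) / 0.025) + 1
  inside <- sim1$mask[cbind(px, py)]
  expect_gt(mean(inside), 0.95)
})

test_that("zero concentration yields empty truth and pure background", {
  net <- single_channel()
  acq <- acquisition_config(rows = 48, cols = 48, n_frames = 10,
                            concentration = 0, noise_sd = 0,
                            scatterer_density = 0.02, rng_seed = 1)
  sim <- generate_sequence(net, flow_config(0.02), acq)
  expect_equal(nrow(sim$truth), 0)
  expect_identical(max(abs(sim$stack)), 0)  # CPS cancels the scatterers

  acq_b <- acquisition_config(rows = 48, cols = 48, n_frames = 10,
                              concentration = 0, noise_sd = 0,
                              scatterer_density = 0.02, mode = "BMODE",
                              rng_seed = 1)
  sim_b <- generate_sequence(net, flow_config(0.02), acq_b)
  expect_gt(max(sim_b$stack), 0)            # B-mode keeps them
})

test_that("bubble count per frame obeys flux balance", {
  # mean live count at age t -> lambda x E[min(T, t)], with transit time
  # T(u) = L / (1.5 v_mean (1 - u^2)) under the flux-weighted entry density
  # p(u) = 3/4 (1 - u^2); quadrature oracle, including the slow near-wall
  # tail that has not yet cleared the channel
  net <- single_channel(300, 1.4, 0.02)
  v_mean <- segment_velocities(net)$mean_v_mm_s
  acq <- acquisition_config(rows = 64, cols = 64, n_frames = 500,
                            detect_fraction = 0.05, rng_seed = 17,
                            noise_sd = 0)
  sim <- generate_sequence(net, flow_config(0.02), acq)
  counts <- as.integer(table(factor(sim$truth$frame, levels = 1:500)))
  lambda <- 6.4e6 * 0.02 / 60 * 0.05
  u <- seq(-0.99999, 0.99999, length.out = 20001)
  transit <- 1.4 / (1.5 * v_mean * (1 - u^2))
  p <- 0.75 * (1 - u^2)
  expected_at <- vapply(c(200, 350, 500), function(k) {
    lambda * sum(p * pmin(transit, k / 250)) * (u[2] - u[1])
  }, numeric(1))
  obs_at <- vapply(c(200, 350, 500), function(k) {
    mean(counts[(k - 50):k])
  }, numeric(1))
  expect_equal(obs_at, expected_at, tolerance = 0.15)
})

test_that("ground-truth track speeds match the flux-weighted expectation", {
  net <- single_channel(300, 1.4, 0.02)
  v_mean <- segment_velocities(net)$mean_v_mm_s
  acq <- acquisition_config(rows = 64, cols = 64, n_frames = 400,
                            detect_fraction = 0.05, rng_seed = 31,
                            noise_sd = 0)
  sim <- generate_sequence(net, flow_config(0.02), acq)
  expect_gt(nrow(sim$truth), 1000)
  per_track <- tapply(sim$truth$speed_mm_s, sim$truth$id, mean)
  expect_equal(mean(per_track), flux_weighted_mean_speed(v_mean),
               tolerance = 0.05)
})

test_that("frame stacks round-trip through TIFF plus sidecar", {
  set.seed(2)
  arr <- array(runif(32 * 32 * 5, 0, 7), dim = c(32, 32, 5))
  st <- frame_stack(arr, 250, 0.025, origin = c(-0.3, 0.1))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, path)
  back <- read_frame_stack(path)
  expect_equal(unclass(back), unclass(st), tolerance = 1e-6)
  expect_equal(attr(back, "frame_rate"), 250)
  expect_equal(attr(back, "pixel_size_mm"), 0.025)
  expect_equal(attr(back, "origin"), c(-0.3, 0.1))
})
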