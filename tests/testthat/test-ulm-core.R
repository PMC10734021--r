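test_that("bicubic upsampling preserves constants and the identity factor", {
  m <- matrix(3.7, 6, 9)
  up <- upsample_frame(m, 2L)
  expect_equal(dim(up), c(12, 18))
  expect_equal(max(abs(up - 3.7)), 0, tolerance = 1e-12)
  expect_identical(upsample_frame(m, 1L), m)
  expect_error(upsample_frame(m, 0), "factor")
})

test_that("bicubic upsampling matches a naive kernel-sum oracle", {
  set.seed(4)
  m <- matrix(runif(30), 5, 6)
  for (f in c(2L, 3L)) {
    expect_equal(upsample_frame(m, f), naive_bicubic(m, f),
                 tolerance = 1e-10)
  }
  # a linear ramp stays linear away from the clamped edges
  ramp <- outer(1:8, 1:8, function(i, j) i + 2 * j)
  up <- upsample_frame(ramp, 2L)
  expect_equal(up, naive_bicubic(ramp, 2L), tolerance = 1e-10)
  expect_equal(diff(up[5:11, 8]), rep(0.5, 6), tolerance = 1e-10)
})

test_that("SVD clutter filter removes low-rank clutter and keeps the rest", {
  # a static scene is rank one: removing two components leaves ~nothing
  static <- frame_stack(array(rep(gaussian_frame(16, 8, 8), 10),
                              dim = c(16, 16, 10)), 250, 0.025)
  filt <- svd_clutter_filter(static, 2)
  expect_lt(sum(filt^2) / sum(static^2), 1e-10)

  set.seed(8)
  arr <- array(runif(16 * 16 * 8), dim = c(16, 16, 8))
  st <- frame_stack(arr, 250, 0.025)
  expect_equal(unclass(svd_clutter_filter(st, 0)), unclass(st))
  expect_error(svd_clutter_filter(st, 8), "n_remove")
  expect_error(svd_clutter_filter(st, -1), "n_remove")
})

test_that("SVD filter equals direct rank truncation by an independent SVD", {
  set.seed(9)
  arr <- array(rnorm(2 * 2 * 3), dim = c(2, 2, 3))
  st <- frame_stack(arr, 250, 0.025)
  for (k in 1:2) {
    filt <- svd_clutter_filter(st, k)
    cas <- matrix(arr, 4, 3)
    sv <- svd(cas)
    dd <- sv$d; dd[seq_len(k)] <- 0
    oracle <- sv$u %*% diag(dd) %*% t(sv$v)
    expect_equal(matrix(filt, 4, 3), oracle, tolerance = 1e-8)
  }
})

test_that("filtered stack is orthogonal to the removed singular subspace", {
  set.seed(10)
  arr <- array(rnorm(12 * 12 * 20), dim = c(12, 12, 20))
  arr <- arr + 5  # strong DC component to remove
  st <- frame_stack(arr, 250, 0.025)
  filt <- svd_clutter_filter(st, 2)
  cas <- matrix(arr, 144, 20)
  sv <- svd(cas)
  proj <- t(sv$u[, 1:2]) %*% matrix(filt, 144, 20)
  expect_lt(max(abs(proj)) / sqrt(sum(cas^2)), 1e-6)
})

test_that("temporal high-pass rejects DC and passes Nyquist", {
  const <- frame_stack(array(2, dim = c(4, 4, 50)), 250, 0.025)
  hp <- temporal_highpass(const, 2, 0.01)
  expect_lt(max(abs(hp)) / 2, 1e-8)

  arr <- array(0, dim = c(2, 2, 200))
  for (f in 1:200) arr[, , f] <- (-1)^f
  hp2 <- temporal_highpass(frame_stack(arr, 250, 0.025), 2, 0.1)
  mid <- hp2[1, 1, 50:150]
  expect_equal(max(abs(mid)), 1, tolerance = 0.01)

  expect_error(temporal_highpass(frame_stack(array(1, dim = c(2, 2, 5)),
                                             250, 0.025), 2, 0.1),
               "frames")
})

test_that("attenuation at the cutoff matches the Butterworth magnitude", {
  # forward-backward second-order Butterworth at its cutoff: |H|^2 = 1/2
  n <- 2000; cutoff <- 0.1; fs <- 2   # frequencies as fractions of Nyquist
  t <- seq_len(n)
  x <- sin(pi * cutoff * t)           # frequency = cutoff x Nyquist
  arr <- array(rep(x, each = 1), dim = c(1, 1, n))
  hp <- temporal_highpass(frame_stack(arr, 250, 0.025), 2, cutoff)
  y <- hp[1, 1, 500:1500]
  xc <- x[500:1500]
  amp <- sqrt(mean(y^2)) / sqrt(mean(xc^2))
  expect_equal(amp, 0.5, tolerance = 0.05)
})

test_that("peak detection enforces threshold and minimum separation", {
  expect_equal(nrow(detect_peaks(matrix(1, 20, 20))), 0)

  # two equal Gaussians 3 px apart with min separation 4: one detection
  fr <- gaussian_frame(21, 10, 9, sigma = 1) + gaussian_frame(21, 10, 12,
                                                              sigma = 1)
  pk <- detect_peaks(fr, min_separation = 4, threshold = 0.2)
  expect_equal(nrow(pk), 1)

  # five well-separated planted peaks at high SNR: exactly five, at the
  # planted pixels
  planted <- rbind(c(8, 8), c(8, 40), c(40, 8), c(40, 40), c(24, 24))
  fr <- matrix(0, 48, 48)
  for (i in 1:5) fr <- fr + gaussian_frame(48, planted[i, 1], planted[i, 2],
                                           sigma = 1.5)
  set.seed(12)
  fr <- fr + matrix(rnorm(48 * 48, sd = 0.02), 48, 48)
  pk <- detect_peaks(fr, min_separation = 4, k = 4)
  expect_equal(nrow(pk), 5)
  found <- pk[order(pk$row, pk$col), c("row", "col")]
  want <- planted[order(planted[, 1], planted[, 2]), ]
  expect_equal(as.matrix(found), want, ignore_attr = TRUE)

  # deterministic
  expect_identical(detect_peaks(fr, 4, 4), detect_peaks(fr, 4, 4))
})

test_that("weighted-centroid localization is subpixel accurate", {
  # symmetric PSF on a pixel centre
  fr <- gaussian_frame(21, 11, 11, sigma = 1.5)
  lc <- localize(fr, tibble::tibble(row = 11, col = 11), 5)
  expect_lt(abs(lc$row - 11) + abs(lc$col - 11), 1e-6)

  # planted +0.30 px offset: centroid of the sampled Gaussian
  fr <- gaussian_frame(21, 11.3, 11, sigma = 1)
  lc <- localize(fr, tibble::tibble(row = 11, col = 11), 5)
  expect_lt(abs(lc$row - 11.3), 0.1)

  # degenerate single-pixel mass
  fr <- matrix(0, 15, 15); fr[4, 9] <- 3
  lc <- localize(fr, tibble::tibble(row = 4, col = 9), 5)
  expect_equal(c(lc$row, lc$col), c(4, 9))
  expect_equal(lc$intensity, 3)

  # window clipped at the border still returns finite coordinates
  fr <- gaussian_frame(15, 2, 2, sigma = 1)
  lc <- localize(fr, tibble::tibble(row = 2, col = 2), 7)
  expect_true(is.finite(lc$row) && is.finite(lc$col))
  expect_error(localize(fr, tibble::tibble(row = 2, col = 2), 4), "odd")
})

test_that("localization RMS error is below 0.25 upsampled px when noise-free", {
  set.seed(14)
  errs <- replicate(30, {
    r <- runif(1, 15, 30); c <- runif(1, 15, 30)
    cfg <- acquisition_config(rows = 48, cols = 48, noise_sd = 0,
                              mode = "BMODE")
    fr <- render_frame(tibble::tibble(row = r, col = c, amp = 1),
                       no_scatterers(), cfg)
    up <- upsample_frame(fr, 2L)
    pk <- detect_peaks(up, 4, 4)
    lc <- localize(up, pk[1, ], 5)
    # true position on the 2x grid: i = 2 r - 0.5
    sqrt((lc$row - (2 * r - 0.5))^2 + (lc$col - (2 * c - 0.5))^2)
  })
  expect_lt(sqrt(mean(errs^2)), 0.25)
})

test_that("detection recall and precision reach 0.95 at SNR 10", {
  # frames are built the way the chain presents them to the detector:
  # PSFs plus symmetric Gaussian noise (sd = amplitude / 10), magnitude
  # taken after upsampling
  set.seed(15)
  tp <- 0; fn <- 0; fp <- 0
  for (rep in 1:20) {
    # sample 6 positions with >= 6 original px pairwise separation
    pos <- matrix(numeric(0), 0, 2)
    while (nrow(pos) < 6) {
      p <- c(runif(1, 6, 26), runif(1, 6, 26))
      if (nrow(pos) == 0 ||
          min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >= 6) {
        pos <- rbind(pos, p)
      }
    }
    cfg <- acquisition_config(rows = 32, cols = 32, noise_sd = 0,
                              mode = "BMODE", rng_seed = rep)
    fr <- render_frame(tibble::tibble(row = pos[, 1], col = pos[, 2],
                                      amp = 1), no_scatterers(), cfg)
    fr <- fr + matrix(rnorm(32 * 32, sd = 0.1), 32, 32)
    up <- upsample_frame(fr, 2L)
    pk <- detect_peaks(up, 4, 4)
    truth_up <- cbind(2 * pos[, 1] - 0.5, 2 * pos[, 2] - 0.5)
    used <- rep(FALSE, nrow(pk))
    for (i in seq_len(nrow(truth_up))) {
      d <- sqrt((pk$row - truth_up[i, 1])^2 + (pk$col - truth_up[i, 2])^2)
      j <- which(!used & d < 3)
      if (length(j) > 0) { tp <- tp + 1; used[j[1]] <- TRUE }
      else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("the localization chain is deterministic end to end", {
  net <- single_channel()
  acq <- acquisition_config(rows = 48, cols = 48, n_frames = 60,
                            rng_seed = 5)
  sim <- generate_sequence(net, flow_config(0.02), acq)
  a <- ulm_localize(sim$stack)
  b <- ulm_localize(sim$stack)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(c("frame", "row", "col", "x_mm", "z_mm", "intensity")
                  %in% names(a)))
})
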