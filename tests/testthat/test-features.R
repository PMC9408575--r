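test_that("detect_saccades counts planted jumps and ignores jitter", {
  # stationary gaze with sub-threshold jitter
  set.seed(1)
  n <- 300
  tr <- gaze_trace((0:(n - 1)) / 60, 960 + rnorm(n, 0, 3),
                   540 + rnorm(n, 0, 3))
  expect_identical(detect_saccades(tr)$S, 0L)

  # one instantaneous jump between two long fixations
  x <- c(rep(500, 100), rep(1400, 100)) + rnorm(200, 0, 2)
  tr <- gaze_trace((0:199) / 60, x, rep(540, 200) + rnorm(200, 0, 2))
  d <- detect_saccades(tr)
  expect_identical(d$S, 1L)
  expect_equal(nrow(d$intervals), 1)

  # generator ground truth for several planted counts
  for (k in c(0L, 3L, 7L, 12L)) {
    gg <- generate_gaze(gaze_spec(duration = 20, n_saccades = k,
                                  seed = 100 + k))
    expect_identical(detect_saccades(gg$trace)$S, gg$S_true)
  }
  expect_error(
    detect_saccades(gaze_trace(c(0, 1), c(1, 2), c(1, 2),
                               valid = c(FALSE, FALSE))),
    "valid")
})

test_that("saccade count is invariant to time shifts and invalid padding", {
  gg <- generate_gaze(gaze_spec(duration = 15, n_saccades = 5, seed = 9))
  tr <- gg$trace
  s0 <- detect_saccades(tr)$S
  shifted <- gaze_trace(tr$t + 123.4, tr$x, tr$y, tr$valid,
                        tr$rate, tr$screen)
  expect_identical(detect_saccades(shifted)$S, s0)
  padded <- gaze_trace(c(tr$t, max(tr$t) + (1:10) / 60),
                       c(tr$x, rep(0, 10)), c(tr$y, rep(0, 10)),
                       c(tr$valid, rep(FALSE, 10)), tr$rate, tr$screen)
  expect_identical(detect_saccades(padded)$S, s0)
})

test_that("gaze_heatmap preserves mass, is linear and permutation-invariant", {
  tr1 <- gaze_trace(0, 800, 500)
  h1 <- gaze_heatmap(tr1)
  expect_equal(sum(h1), 1, tolerance = 1e-6)
  peak <- which(unclass(h1) == max(h1), arr.ind = TRUE)
  expect_equal(as.integer(peak), c(50, 80))  # 10-px cells

  # two identical samples: exactly double the single-sample field
  tr2 <- gaze_trace(c(0, 1 / 60), c(800, 800), c(500, 500))
  expect_equal(as.numeric(gaze_heatmap(tr2)), 2 * as.numeric(h1),
               tolerance = 1e-12)

  # permutation invariance
  set.seed(4)
  xs <- runif(50, 100, 1800); ys <- runif(50, 100, 1000)
  ha <- gaze_heatmap(gaze_trace((0:49) / 60, xs, ys))
  p <- sample(50)
  hb <- gaze_heatmap(gaze_trace((0:49) / 60, xs[p], ys[p]))
  expect_equal(unclass(ha), unclass(hb), tolerance = 1e-12)
  expect_error(gaze_heatmap(tr1, grid = c(0, 10)), "grid")
})

test_that("gaze_extent reflects dispersion and is scale-invariant", {
  conc <- generate_gaze(gaze_spec(dispersion = 60, seed = 5))
  disp <- generate_gaze(gaze_spec(dispersion = 320, seed = 5))
  hc <- gaze_heatmap(conc$trace); hd <- gaze_heatmap(disp$trace)
  expect_lt(gaze_extent(hc), gaze_extent(hd))
  # doubling densities leaves E unchanged
  h2 <- unclass(hd) * 2
  expect_identical(gaze_extent(h2), gaze_extent(hd))
  # all mass in one cell: E = 1 at a high quantile
  one <- matrix(0, 5, 5); one[3, 3] <- 7
  expect_identical(gaze_extent(one, 0.5), 1L)
})

test_that("planted dispersion and computed extent are positively related", {
  set.seed(10)
  disp <- runif(15, 50, 350)
  E <- vapply(seq_along(disp), function(i) {
    gg <- generate_gaze(gaze_spec(duration = 10, dispersion = disp[i],
                                  seed = 900 + i))
    as.numeric(gaze_extent(gaze_heatmap(gg$trace)))
  }, numeric(1))
  expect_gt(cor(disp, E, method = "spearman"), 0)
})

test_that("gabor features respond to orientation and are deterministic", {
  flat <- matrix(0.5, 160, 160)
  f_flat <- gabor_frame_features(flat)
  # grating modulated along the kernel's theta = 0 axis (rows), at the
  # first scale's wavelength
  grat <- matrix(rep(sin(2 * pi * (1:160) / 8), times = 160), 160, 160)
  f_grat <- gabor_frame_features(grat)
  expect_lt(max(f_flat), 1e-6 * max(f_grat))
  # channel energy by filter: 8 filters x 64 blocks, scale-major
  ch <- function(fv) {
    vapply(seq_len(8), function(i) mean(fv[((i - 1) * 64 + 1):(i * 64)]),
           numeric(1))
  }
  # theta = 0 filter modulates along x (columns): matches a vertical grating
  expect_identical(which.max(ch(f_grat)), 1L)
  expect_identical(gabor_frame_features(grat), f_grat)
  expect_error(gabor_frame_features(matrix(0, 100, 100)), "160x160")
})

test_that("image-mode smile frames pass through the gabor path", {
  sq <- generate_smile_sequence(smile_spec(n_cycles = 1,
                                           frames_per_cycle = 12,
                                           mode = "images", seed = 2))
  expect_identical(dim(sq$features), c(12L, 512L))
  expect_true(all(is.finite(sq$features)))
  # smiling and neutral renders differ
  i_neu <- which.min(sq$intensity); i_sm <- which.max(sq$intensity)
  expect_gt(sum(abs(sq$features[i_sm, ] - sq$features[i_neu, ])), 0)
})
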