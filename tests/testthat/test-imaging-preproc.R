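step_traces <- function(n_cells, n_t = 40) {
  tmat <- matrix(0, n_cells, n_t)
  for (i in seq_len(n_cells)) {
    on <- 5 + (i %% 5) * 6
    tmat[i, on:min(n_t, on + 6)] <- 0.8
  }
  tmat
}

test_that("registration recovers planted integer shifts exactly", {
  tmat <- step_traces(15)
  mc <- movie_config(frame_size = c(96, 96), n_cells = 15, noise_sd = 0,
                     drift_amplitude = 3, seed = 6)
  mv <- generate_movie(mc, tmat)
  reg <- register_movie(mv$frames)
  # shifts are defined up to a common anchor; compare relative to frame 1
  rel <- sweep(reg$shifts, 2, reg$shifts[1, ])
  expect_identical(unname(rel), unname(-mv$shifts))
  # zero drift -> zero shifts; re-registration is the identity
  mv0 <- generate_movie(movie_config(frame_size = c(96, 96), n_cells = 15,
                                     noise_sd = 0, seed = 6), tmat)
  r0 <- register_movie(mv0$frames)
  expect_true(all(r0$shifts == 0))
  r00 <- register_movie(r0$frames)
  expect_true(all(r00$shifts == 0))
  expect_warning(register_movie(array(1, c(8, 8, 3))), "constant")
})

test_that("activity map highlights somata and ignores static background", {
  tmat <- step_traces(1)
  mv <- generate_movie(movie_config(frame_size = c(48, 48), n_cells = 1,
                                    noise_sd = 0, seed = 4), tmat[1, ,
                                                                  drop = FALSE])
  am <- activity_map(mv$frames)
  expect_true(all(am >= 0 & am <= 1))
  # only pixels of the active soma vary at all
  expect_true(all(am[mv$masks == 0] == 0))
  expect_gt(max(am[mv$masks == 1]), 0)
})

test_that("activity map separates 20 somata from noisy background", {
  tmat <- step_traces(20)
  mv <- generate_movie(movie_config(frame_size = c(120, 120), n_cells = 20,
                                    noise_sd = 2, seed = 9), tmat)
  am <- activity_map(mv$frames)
  inside <- mean(am[mv$masks > 0])
  bg99 <- quantile(am[mv$masks == 0], 0.99)
  expect_gt(inside, bg99)
})

test_that("segmentation recovers well-separated somata", {
  tmat <- step_traces(20)
  mv <- generate_movie(movie_config(frame_size = c(120, 120), n_cells = 20,
                                    noise_sd = 0, seed = 9), tmat)
  rois <- segment_rois(activity_map(mv$frames))
  iou <- function(a, b) sum(a & b) / sum(a | b)
  recall <- mean(sapply(1:20, function(i) {
    tm <- mv$masks == i
    any(sapply(seq_len(rois$n), function(g) iou(tm, rois$masks == g) >= 0.5))
  }))
  expect_gte(recall, 0.9)
  # single soma: one ROI with high overlap
  mv1 <- generate_movie(movie_config(frame_size = c(48, 48), n_cells = 1,
                                     noise_sd = 0, seed = 4),
                        tmat[1, , drop = FALSE])
  r1 <- segment_rois(activity_map(mv1$frames))
  expect_equal(r1$n, 1)
  expect_gte(iou(r1$masks == 1, mv1$masks == 1), 0.8)
  # empty map
  r0 <- segment_rois(matrix(0, 32, 32))
  expect_equal(r0$n, 0)
})

test_that("pure-noise movies yield no accepted ROI", {
  set.seed(12)
  noise <- array(100 + rnorm(48 * 48 * 60), c(48, 48, 60))
  rois <- segment_rois(activity_map(noise))
  expect_equal(rois$n, 0)
})

test_that("trace extraction separates soma and neuropil", {
  # uniform movie: both traces equal the constant
  masks <- matrix(0L, 30, 30); masks[10:13, 10:13] <- 1L
  uni <- array(7, c(30, 30, 5))
  ft <- extract_traces(uni, masks, pixel_size_um = 2)
  expect_true(all(ft$F_raw == 7) && all(ft$F_neuropil == 7))
  # rendered soma = 2 on background = 1
  mov <- array(1, c(30, 30, 5))
  for (t in 1:5) { fr <- mov[, , t]; fr[masks == 1] <- 2; mov[, , t] <- fr }
  ft2 <- extract_traces(mov, masks, pixel_size_um = 2)
  expect_true(all(ft2$F_raw == 2))
  expect_true(all(ft2$F_neuropil == 1))
  # two abutting ROIs never contribute to each other's annulus
  m2 <- matrix(0L, 30, 30); m2[10:13, 10:13] <- 1L; m2[10:13, 14:17] <- 2L
  mov2 <- array(1, c(30, 30, 4))
  for (t in 1:4) {
    fr <- mov2[, , t]; fr[m2 == 1] <- 5; fr[m2 == 2] <- 9; mov2[, , t] <- fr
  }
  ft3 <- extract_traces(mov2, m2, pixel_size_um = 2)
  expect_true(all(ft3$F_neuropil == 1))
})

test_that("neuropil correction follows the scaled-subtraction rule", {
  tr <- list(F_raw = matrix(2, 1, 10), F_neuropil = matrix(1, 1, 10))
  expect_equal(neuropil_correct(tr)$F_corrected[1, 1], 2 - 0.7 * 1)
  expect_equal(neuropil_correct(tr, coef = 0)$F_corrected, tr$F_raw)
  tr0 <- list(F_raw = matrix(3, 1, 10), F_neuropil = matrix(0, 1, 10))
  expect_equal(neuropil_correct(tr0)$F_corrected, tr0$F_raw)
  bad <- list(F_raw = matrix(1, 1, 10), F_neuropil = matrix(1, 1, 9))
  expect_error(neuropil_correct(bad), "length")
})

test_that("dF/F uses the fluorescence mode and is scale invariant", {
  f_const <- rep(1, 50)
  d0 <- compute_dff(f_const)
  expect_equal(d0$f0, 1); expect_true(all(d0$dff == 0))
  set.seed(3)
  f <- c(1 + rnorm(180, 0, 0.01), seq(1, 2, length.out = 20))
  d <- compute_dff(f)
  expect_equal(d$f0, 1, tolerance = 0.05)
  expect_equal(max(d$dff), (2 - d$f0) / d$f0, tolerance = 1e-12)
  dk <- compute_dff(3 * f)
  expect_lt(max(abs(dk$dff - d$dff)), 0.05)
  d_kde <- compute_dff(f, method = "kde")
  expect_equal(d_kde$f0, 1, tolerance = 0.05)
  expect_error(compute_dff(f - 5), "F0")
})

test_that("duplicate ROI removal applies both thresholds and keeps the brighter", {
  set.seed(7)
  base <- rnorm(200)
  mk <- function(mean_f, r = 1) mean_f + r * base + rnorm(200, 0, 0.05)
  # correlated and close: drop the dimmer
  f <- rbind(mk(10), mk(8))
  cent <- rbind(c(0, 0), c(5, 0))
  expect_identical(remove_duplicates(f, cent), 1L)
  # far apart: keep both
  cent_far <- rbind(c(0, 0), c(20, 0))
  expect_identical(remove_duplicates(f, cent_far), c(1L, 2L))
  # uncorrelated but close: keep both
  f2 <- rbind(mk(10), 8 + rnorm(200))
  expect_identical(remove_duplicates(f2, cent), c(1L, 2L))
  # transitive chain collapses to the brightest
  f3 <- rbind(mk(10), mk(9), mk(8))
  cent3 <- rbind(c(0, 0), c(10, 0), c(20, 0))  # 1-3 not directly violating
  expect_identical(remove_duplicates(f3, cent3), 1L)
})
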