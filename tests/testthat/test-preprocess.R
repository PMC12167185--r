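test_that("Gaussian smoothing preserves constants and unit mass", {
  g <- voxel_grid(array(7, c(12, 12, 12)), spacing = c(0.5, 0.5, 0.5))
  sm <- gaussian_smooth(g, 1.5)
  expect_equal(sm$data, g$data)
  expect_error(gaussian_smooth(g, 0), class = "mpmri_param_error")
})

test_that("impulse response matches the analytic kernel via dense convolution", {
  d <- c(15, 15, 15)
  x <- array(0, d); x[8, 8, 8] <- 1
  g <- voxel_grid(x, spacing = c(0.5, 0.5, 0.5))
  sm <- gaussian_smooth(g, 1.5)
  sigma_vox <- rep(1.5 / (2 * sqrt(2 * log(2))) / 0.5, 3)
  expect_equal(sigma_vox[1], 1.2739827, tolerance = 1e-6)
  oracle <- dense_gaussian_conv(x, sigma_vox)
  expect_equal(sm$data, oracle, tolerance = 1e-12)
  expect_equal(sum(sm$data), 1, tolerance = 1e-3)
})

test_that("smoothing twice with width w approximates once with w*sqrt(2)", {
  x <- smooth_random_image(c(26, 26, 26), seed = 5, width = 2,
                           spacing = c(0.5, 0.5, 0.5))
  g <- voxel_grid(x, spacing = c(0.5, 0.5, 0.5))
  twice <- gaussian_smooth(gaussian_smooth(g, 1.5), 1.5)
  once <- gaussian_smooth(g, 1.5 * sqrt(2))
  i <- 9:18
  rel <- max(abs(twice$data[i, i, i] - once$data[i, i, i])) /
    max(abs(once$data[i, i, i]))
  expect_lt(rel, 1e-3)
})

test_that("dropout rule flags exactly the repetitions below 2/3 of the bright-half mean", {
  # nine repetitions at ~100, one at 60: threshold 2/3 * 100 ~ 66.7
  vols <- array(100, c(8, 8, 1, 10, 2))
  vols[, , 1, 4, 1] <- 60
  set.seed(2)
  vols <- vols + array(rnorm(length(vols), 0, 0.3), dim(vols))
  st <- dwi_stack(vols, b_values = c(0, 500))
  dd <- detect_signal_dropout(st)
  flagged <- dd$report[dd$report$excluded, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$repetition, 4L)
  expect_equal(flagged$b_index, 1L)
  expect_true(all(dd$stack$excluded[1, 4, 1]))
  # identical (structured) repetitions: nothing excluded
  base <- smooth_random_image(c(6, 6, 2), seed = 4, width = 2)^2 + 10
  vols2 <- aperm(array(rep(base, 4), c(6, 6, 2, 4)), c(1, 2, 3, 4))
  dim(vols2) <- c(6, 6, 2, 4, 1)
  st2 <- dwi_stack(vols2, b_values = 0)
  dd2 <- detect_signal_dropout(st2)
  expect_false(any(dd2$report$excluded))
  # threshold 0 excludes nothing even with a dropout present
  dd0 <- detect_signal_dropout(st, threshold_frac = 0)
  expect_false(any(dd0$report$excluded))
})

test_that("dropout decisions equal an independent brute-force restatement", {
  set.seed(33)
  for (rep_i in 1:5) {
    nrep <- sample(3:8, 1)
    scales <- runif(nrep, 0.3, 1.2)
    base <- smooth_random_image(c(12, 12, 1), seed = 100 + rep_i, width = 2)^2 + 50
    vols <- array(0, c(12, 12, 1, nrep, 1))
    for (r in seq_len(nrep)) vols[, , 1, r, 1] <- base * scales[r]
    st <- dwi_stack(vols, b_values = 0)
    dd <- suppressWarnings(detect_signal_dropout(st))
    rep_rows <- dd$report[order(dd$report$repetition), ]
    # oracle: recompute per-repetition foreground means from the same
    # median-image foreground definition, then apply the rule directly
    med <- apply(vols[, , 1, , 1], c(1, 2), median)
    fg <- med > otsu_threshold(med)
    m_r <- vapply(seq_len(nrep), function(r) mean(vols[, , 1, r, 1][fg]),
                  numeric(1))
    expect_equal(rep_rows$excluded, unname(bruteforce_dropout(m_r)))
    # permutation invariance in repetition index
    perm <- sample(nrep)
    stp <- dwi_stack(vols[, , , perm, , drop = FALSE], b_values = 0)
    ddp <- suppressWarnings(detect_signal_dropout(stp))
    expect_equal(ddp$report$excluded[order(ddp$report$repetition)],
                 rep_rows$excluded[perm])
  }
})

test_that("known in-plane shifts are recovered within a quarter voxel", {
  img <- smooth_random_image(c(32, 32, 1), seed = 9, width = 2.5)[, , 1]
  for (true_shift in list(c(2, -3), c(1.5, 0), c(-0.5, 2.5))) {
    shifted <- translate_image(img, true_shift)
    rec <- register_translation(shifted, img)
    expect_lt(max(abs(rec + true_shift)), 0.25)
  }
  # unshifted image: exact zero
  expect_equal(as.numeric(register_translation(img, img)), c(0, 0))
  # constant slice: zero shift with a warning
  expect_warning(register_translation(matrix(1, 8, 8), matrix(1, 8, 8)),
                 class = "mpmri_degenerate_registration_warning")
})

test_that("3-D volume shifts are recovered within a quarter voxel", {
  vol <- smooth_random_image(c(16, 16, 8), seed = 12, width = 2.5)
  for (true_shift in list(c(0, 0, 1), c(-2, 1, 0), c(0.5, -1.5, 0.5))) {
    shifted <- translate_image(vol, true_shift)
    rec <- register_translation(shifted, vol)
    expect_lt(max(abs(rec + true_shift)), 0.25)
  }
})

test_that("motion correction recovers deliberately injected slice shifts", {
  ph <- make_dwi_phantom(
    model = "adc", noise_sigma = 2, seed = 8,
    shifts = data.frame(b_index = 1L, repetition = 2L, z = 2L,
                        dx = 2, dy = -3),
    dim3 = c(24L, 24L, 3L))
  mc <- inplane_motion_correct(ph$stack)
  row <- mc$shifts[mc$shifts$b_index == 1 & mc$shifts$z == 2 &
                     mc$shifts$repetition == 2, ]
  expect_lt(abs(row$shift_x - (-2)), 0.25)
  expect_lt(abs(row$shift_y - 3), 0.25)
  # all other slice-repetitions essentially unshifted
  others <- mc$shifts[!(mc$shifts$b_index == 1 & mc$shifts$z == 2 &
                          mc$shifts$repetition == 2), ]
  expect_lt(max(abs(c(others$shift_x, others$shift_y))), 0.5)
})

test_that("DCE volume correction is robust to enhancement-only changes", {
  ph <- make_dce_phantom(seed = 14, times = seq(0, 60, 1.5), noise_sd = 0.2)
  mc <- volume_motion_correct(ph$series, n_baseline = 5)
  expect_lt(max(abs(as.matrix(mc$shifts[, c("shift_x", "shift_y", "shift_z")]))),
            0.5)
  # a genuinely shifted frame is detected and corrected
  s2 <- ph$series
  s2$frames[, , , 20] <- translate_image(s2$frames[, , , 20], c(0, 0, 1))
  mc2 <- volume_motion_correct(s2, n_baseline = 5)
  expect_lt(abs(mc2$shifts$shift_z[20] - (-1)), 0.3)
})

test_that("repetition averaging uses only non-excluded repetitions", {
  ph <- make_dwi_phantom(model = "adc", noise_sigma = 4, seed = 10,
                         dropout = data.frame(b_index = 3L, repetition = 1L,
                                              z = 1L, scale = 0.4),
                         dim3 = c(12L, 12L, 2L))
  dd <- detect_signal_dropout(ph$stack)
  avg <- average_repetitions(dd$stack)
  expect_equal(avg$counts[1, 3], 3L)
  # oracle: direct mean of the three kept repetitions
  keep <- which(!dd$stack$excluded[1, , 3])
  oracle <- apply(dd$stack$volumes[, , 1, keep, 3], c(1, 2), mean)
  expect_equal(avg$volumes[[3]]$data[, , 1], oracle)
  # all-excluded slice becomes NaN with a warning
  st <- dd$stack
  st$excluded[2, , 5] <- TRUE
  expect_warning(avg2 <- average_repetitions(st),
                 class = "mpmri_all_excluded_warning")
  expect_true(all(is.nan(avg2$volumes[[5]]$data[, , 2])))
  expect_false(anyNA(avg2$volumes[[5]]$data[, , 1]))
})
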