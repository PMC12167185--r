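test_that("signal models evaluate to their closed forms", {
  expect_equal(monoexp_signal(1000, 1.0e-3, 1000), 1000 * exp(-1))
  expect_equal(monoexp_signal(800, 0.8e-3, 0), 800)
  expect_equal(monoexp_signal(500, 0, c(0, 400, 800)), rep(500, 3))
  # triexponential reduces to monoexponential without perfusion/water terms
  expect_equal(triexp_signal(1000, 0, 50e-3, 0, 1e-3, 500), 1000 * exp(-0.5))
  expect_equal(triexp_signal(1000, 10, 50e-3, 5, 0.7e-3, 0), 1000)
  # arithmetic oracle: independent three-term sum
  b <- 800
  direct <- 1000 * (0.10 * exp(-b * 50e-3) + 0.05 * exp(-b * 3.0e-3) +
                      0.85 * exp(-b * 0.7e-3))
  expect_equal(triexp_signal(1000, 10, 50e-3, 5, 0.7e-3, b), direct)
  expect_error(triexp_signal(1000, 60, 50e-3, 50, 0.7e-3, b),
               class = "mpmri_param_error")
})

test_that("noiseless monoexponential curves are recovered to 1e-8", {
  b <- c(0, 50, 100, 200, 400, 600, 800)
  fit <- fit_adc(monoexp_signal(800, 0.8e-3, b), b)
  expect_lt(abs(fit$ADC - 0.8e-3) / 0.8e-3, 1e-8)
  expect_lt(abs(fit$S0 - 800) / 800, 1e-8)
  expect_true(fit$converged)
  # constant signal: boundary solution ADC = 0
  fitc <- fit_adc(rep(500, length(b)), b)
  expect_equal(fitc$ADC, 0)
  expect_equal(fitc$S0, 500, tolerance = 1e-8)
  expect_error(fit_adc(rep(-1, 7), b), class = "mpmri_fit_error")
  expect_error(fit_adc(c(1, 2, 3), c(100, 100, 100)),
               class = "mpmri_input_error")
})

test_that("noisy ADC fits beat a dense grid-search oracle voxel-wise", {
  b <- default_b_values()
  set.seed(42)
  S0 <- 1000; sigma <- S0 / 50
  n_vox <- 120
  adcs <- numeric(n_vox)
  grid_beaten <- logical(n_vox)
  S0_grid <- seq(800, 1200, length.out = 41)
  ADC_grid <- seq(0.4e-3, 1.2e-3, length.out = 61)
  for (i in seq_len(n_vox)) {
    s <- rician_noise(monoexp_signal(S0, 0.8e-3, b), sigma)
    fit <- fit_adc(s, b)
    adcs[i] <- fit$ADC
    # dense grid oracle: rss over the (S0, ADC) grid
    rss_grid <- outer(S0_grid, ADC_grid, Vectorize(function(s0, a)
      sum((monoexp_signal(s0, a, b) - s)^2)))
    grid_beaten[i] <- fit$rss <= min(rss_grid) + 1e-9
    # reported rss is the true residual sum of squares
    expect_equal(fit$rss, sum((monoexp_signal(fit$S0, fit$ADC, b) - s)^2),
                 tolerance = 1e-10)
  }
  expect_true(all(grid_beaten))
  expect_lt(abs(median(adcs) - 0.8e-3) / 0.8e-3, 0.02)
})

test_that("noiseless triexponential curves are recovered to 1 percent", {
  b <- default_b_values()
  truth <- list(S0 = 1000, f = 8, D_star = 60e-3, f_water = 4, D = 0.6e-3)
  s <- triexp_signal(truth$S0, truth$f, truth$D_star, truth$f_water, truth$D, b)
  fit <- fit_ivim_triexp(s, b)
  for (pn in names(truth)) {
    expect_lt(abs(fit[[pn]] - truth[[pn]]) / truth[[pn]], 0.01,
              label = sprintf("relative error of %s", pn))
  }
  expect_equal(fit$D_water, 3.0e-3)
  expect_true(fit$converged)
})

test_that("pure-tissue decay yields near-zero perfusion and water fractions", {
  b <- default_b_values()
  s <- triexp_signal(900, 0, 50e-3, 0, 0.8e-3, b)
  fit <- fit_ivim_triexp(s, b)
  expect_lt(fit$f, 0.5)
  expect_lt(fit$f_water, 0.5)
  expect_lt(abs(fit$D - 0.8e-3) / 0.8e-3, 0.01)
})

test_that("noisy IVIM fits reach the truth-neighborhood grid floor", {
  b <- default_b_values()
  set.seed(7)
  S0 <- 1000
  truth <- c(S0 = 1000, f = 8, D_star = 60e-3, f_water = 4, D = 0.6e-3)
  # coarse 5-D grid around the truth (+-25% per axis)
  gr <- expand.grid(S0 = truth["S0"] * c(0.75, 1, 1.25),
                    f = truth["f"] * c(0.75, 1, 1.25),
                    D_star = truth["D_star"] * c(0.75, 1, 1.25),
                    f_water = truth["f_water"] * c(0.75, 1, 1.25),
                    D = truth["D"] * c(0.75, 1, 1.25))
  n_vox <- 60
  beaten <- logical(n_vox)
  for (i in seq_len(n_vox)) {
    s <- rician_noise(triexp_signal(truth["S0"], truth["f"], truth["D_star"],
                                    truth["f_water"], truth["D"], b), S0 / 60)
    fit <- fit_ivim_triexp(s, b)
    rss_grid <- min(vapply(seq_len(nrow(gr)), function(k)
      sum((triexp_signal(gr$S0[k], gr$f[k], gr$D_star[k], gr$f_water[k],
                         gr$D[k], b) - s)^2), numeric(1)))
    beaten[i] <- fit$rss <= rss_grid + 1e-9
  }
  expect_gte(mean(beaten), 0.95)
})

test_that("monoexponential ADC of a triexponential curve lies between D and D*", {
  b <- default_b_values()
  set.seed(19)
  for (i in 1:10) {
    D <- runif(1, 0.3e-3, 1.5e-3)
    Ds <- runif(1, max(10 * D, 6e-3), 0.2)
    f <- runif(1, 2, 15); fw <- runif(1, 0, 8)
    s <- triexp_signal(1000, f, Ds, fw, D, b)
    fit <- fit_adc(s, b)
    expect_gt(fit$ADC, D)
    expect_lt(fit$ADC, Ds)
  }
})

test_that("Rician bias of the fitted ADC shrinks monotonically with SNR", {
  # deterministic check: fit the analytic expected magnitude signal
  b <- default_b_values()
  S0 <- 1000; adc <- 0.8e-3
  bias <- vapply(c(10, 25, 50, 100), function(snr) {
    s_expected <- rician_mean(monoexp_signal(S0, adc, b), S0 / snr)
    fit_adc(s_expected, b)$ADC - adc
  }, numeric(1))
  # magnitude bias inflates the high-b floor, slowing the apparent decay:
  # the ADC is underestimated, less so as SNR grows
  expect_true(all(bias < 0))
  expect_true(all(diff(abs(bias)) < 0))
})

test_that("voxel-wise map fitting aggregates ROI means correctly", {
  b <- c(0, 100, 300, 600, 800)
  d <- c(4, 4, 2)
  mk_vols <- function(adc_map, S0 = 800) {
    lapply(b, function(bb) voxel_grid(S0 * exp(-bb * adc_map)))
  }
  # uniform phantom: ROI mean equals the single-voxel fit
  uni <- mk_vols(array(0.9e-3, d))
  mask <- roi_mask(array(TRUE, d), "tumor")
  mf <- map_fit(uni, b, mask, model = "adc")
  single <- fit_adc(800 * exp(-b * 0.9e-3), b)
  expect_equal(unname(mf$roi_means["ADC"]), single$ADC, tolerance = 1e-6)
  # two-region phantom with equal volumes: mean is the midpoint
  adc_map <- array(0.7e-3, d); adc_map[, , 2] <- 1.2e-3
  mf2 <- map_fit(mk_vols(adc_map), b, mask, model = "adc")
  expect_equal(unname(mf2$roi_means["ADC"]), 0.95e-3, tolerance = 1e-6)
  # masked-out voxels are NaN and excluded from the mean
  m3 <- array(TRUE, d); m3[1, 1, 1] <- FALSE
  mf3 <- map_fit(mk_vols(adc_map), b, roi_mask(m3, "tumor"), model = "adc")
  expect_true(is.nan(mf3$maps$ADC$data[1, 1, 1]))
  expect_false(anyNA(mf3$maps$ADC$data[2, , ]))
})
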