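make_test_aif <- function(dt = 1.5, t_end = 300) {
  make_aif(seq(0, t_end, dt), a = 5, alpha = 2, tau = 6, t0 = 12)
}

test_that("signal enhancement subtracts the per-voxel baseline", {
  d <- c(3, 3, 2); nt <- 10
  frames <- array(100, c(d, nt))
  ser <- dce_series(frames, times = seq_len(nt))
  enh <- signal_enhancement(ser, 4)
  expect_true(all(enh$frames == 0))
  # step from 100 to 150 after the baseline window
  frames2 <- frames
  frames2[, , , 5:nt] <- 150
  enh2 <- signal_enhancement(dce_series(frames2, seq_len(nt)), 4)
  expect_true(all(enh2$frames[, , , 1:4] == 0))
  expect_true(all(enh2$frames[, , , 5:nt] == 50))
  expect_error(signal_enhancement(ser, 10), class = "mpmri_param_error")
  # noisy baseline: mean pre-bolus enhancement within 2 SE of zero
  set.seed(31)
  frames3 <- frames + array(rnorm(length(frames), 0, 5), dim(frames))
  enh3 <- signal_enhancement(dce_series(frames3, seq_len(nt)), 4)
  pre <- enh3$frames[, , , 1:4]
  expect_lt(abs(mean(pre)), 2 * 5 / sqrt(length(pre)))
})

test_that("AIF extraction finds the bolus arrival from the aorta ROI", {
  ph <- make_dce_phantom(seed = 2, noise_sd = 0.3, times = seq(0, 120, 1.5))
  aif <- extract_aif(ph$series, ph$aorta_mask, n_baseline = 5)
  # bolus injected at t0 = 12 s: detected arrival within 2 frames of that
  expect_lt(abs(ph$series$times[aif$bolus_arrival_index] - 12), 3.1)
  expect_lt(abs(mean(aif$enhancement[1:5])), 1)
  # flat series: no bolus to find
  flat <- dce_series(array(100, c(4, 4, 2, 10)), seq_len(10))
  m <- roi_mask(array(TRUE, c(4, 4, 2)), "aorta")
  expect_error(extract_aif(flat, m, 4), class = "mpmri_no_bolus_error")
  # single-voxel mask equals that voxel's enhancement curve
  m1 <- array(FALSE, dim(ph$aorta_mask$mask)); m1[1, 1, 1] <- TRUE
  aif1 <- extract_aif(ph$series, roi_mask(m1, "aorta"), n_baseline = 5)
  vox <- ph$series$frames[1, 1, 1, ]
  expect_equal(aif1$enhancement, vox - mean(vox[1:5]))
})

test_that("convolution and ODE routes of the 2CXM agree to 1e-6", {
  aif <- make_test_aif()
  for (pars in list(list(PF = 60, PV = 13, PS = 10, ve = 20, t0 = 0),
                    list(PF = 200, PV = 5, PS = 0, ve = 30, t0 = 0),
                    list(PF = 30, PV = 25, PS = 80, ve = 50, t0 = 4),
                    list(PF = 500, PV = 2, PS = 1, ve = 5, t0 = 0))) {
    ct_conv <- twocxm_forward(aif, pars, method = "convolution")
    ct_ode <- twocxm_forward(aif, pars, method = "ode")
    expect_lt(max(abs(ct_conv - ct_ode)) / max(abs(ct_conv)), 1e-6)
  }
})

test_that("PS = 0 reduces to the one-compartment convolution (quadrature oracle)", {
  aif <- make_test_aif()
  pars <- list(PF = 60, PV = 13, PS = 0, ve = 20, t0 = 0)
  ct <- twocxm_forward(aif, pars)
  # independent oracle: fine-grid trapezoidal quadrature of
  # Fp int ca(tau) exp(-(t - tau) Fp / vp) dtau with the same linear AIF
  Fp <- 60 / 6000; vp <- 0.13
  ca <- approxfun(aif$times, aif$enhancement, yleft = 0, rule = 2)
  tg <- seq(0, 300, 0.01)
  cag <- ca(tg)
  for (k in c(21L, 41L, 101L, 200L)) {
    t_eval <- aif$times[k]
    sub <- tg <= t_eval
    integrand <- cag[sub] * exp(-(t_eval - tg[sub]) * Fp / vp)
    oracle <- Fp * sum((integrand[-1] + integrand[-sum(sub)]) / 2) * 0.01
    expect_lt(abs(ct[k] - oracle) / max(ct), 1e-4)
  }
})

test_that("a sustained constant input equilibrates to (vp + ve) * c", {
  # c_a == 5 held long enough: tissue concentration approaches the total
  # accessible volume fraction times the input level
  times <- seq(0, 3000, 2)
  aif <- aif_curve(times, rep(5, length(times)), 1)
  pars <- list(PF = 60, PV = 13, PS = 10, ve = 20, t0 = 0)
  ct <- twocxm_forward(aif, pars)
  expect_lt(abs(ct[length(ct)] - (0.13 + 0.20) * 5) / ((0.13 + 0.20) * 5),
            1e-3)
})

test_that("tracer mass is conserved: integral of Ct = (vp + ve) * integral of ca", {
  times <- seq(0, 2500, 2)
  aif <- make_aif(times, a = 5, alpha = 2, tau = 6, t0 = 12)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  for (ps in c(5, 50, 500)) {
    pars <- list(PF = 60, PV = 13, PS = ps, ve = 20, t0 = 0)
    ct <- twocxm_forward(aif, pars)
    expect_lt(abs(trapz(times, ct) -
                    (0.13 + 0.20) * trapz(times, aif$enhancement)) /
                ((0.13 + 0.20) * trapz(times, aif$enhancement)), 5e-3)
  }
})

test_that("degenerate volumes are handled per the reduced-model contract", {
  aif <- make_test_aif()
  # ve = 0 with exchange reduces to the plasma-only compartment
  p0 <- list(PF = 60, PV = 13, PS = 10, ve = 0, t0 = 0)
  p1 <- list(PF = 60, PV = 13, PS = 0, ve = 0, t0 = 0)
  expect_equal(twocxm_forward(aif, p0), twocxm_forward(aif, p1))
  expect_error(validate_2cxm_params <- twocxm_forward(
    aif, list(PF = 60, PV = -1, PS = 0, ve = 0, t0 = 0)),
    class = "mpmri_param_error")
})

test_that("noiseless 2CXM curves return PF and PV within 2 percent", {
  aif <- make_test_aif()
  truth <- list(PF = 60, PV = 13, PS = 10, ve = 20, t0 = 0)
  ct <- twocxm_forward(aif, truth)
  fit <- fit_2cxm(ct, aif)
  expect_lt(abs(fit$PF - truth$PF) / truth$PF, 0.02)
  expect_lt(abs(fit$PV - truth$PV) / truth$PV, 0.02)
  expect_true(fit$converged)
  # a zero tissue curve must not produce spurious perfusion
  fit0 <- fit_2cxm(rep(0, length(aif$times)), aif)
  expect_true(!fit0$converged || fit0$PF <= 1)
})

test_that("PF/PV recovery degrades monotonically with coarser sampling", {
  truth <- list(PF = 60, PV = 13, PS = 10, ve = 20, t0 = 0)
  med_err <- vapply(c(1, 2, 4, 8), function(dt) {
    times <- seq(0, 300, dt)
    aif <- make_aif(times)
    ct <- twocxm_forward(aif, truth)
    sdn <- 0.05 * max(ct)
    set.seed(123)
    errs <- replicate(10, {
      y <- ct + rnorm(length(ct), 0, sdn)
      f <- fit_2cxm(y, aif)
      (abs(f$PF - truth$PF) / truth$PF + abs(f$PV - truth$PV) / truth$PV) / 2
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})

test_that("joint rescaling of tissue and AIF leaves PF and PV unchanged", {
  aif <- make_test_aif()
  truth <- list(PF = 60, PV = 13, PS = 10, ve = 20, t0 = 0)
  ct <- twocxm_forward(aif, truth)
  fit1 <- fit_2cxm(ct, aif)
  aif_s <- aif_curve(aif$times, aif$enhancement * 3.7, aif$bolus_arrival_index)
  fit2 <- fit_2cxm(ct * 3.7, aif_s)
  expect_equal(fit2$PF, fit1$PF, tolerance = 1e-6)
  expect_equal(fit2$PV, fit1$PV, tolerance = 1e-6)
})

test_that("voxel-wise DCE maps aggregate to correct ROI means", {
  times <- seq(0, 150, 3)
  ph <- make_dce_phantom(seed = 17, times = times, noise_sd = 0,
                         dim3 = c(6L, 6L, 2L))
  # restrict to a handful of tumor voxels to keep the fit count small
  idx <- which(ph$tumor_mask$mask)[1:4]
  m <- array(FALSE, dim(ph$tumor_mask$mask)); m[idx] <- TRUE
  mask <- roi_mask(m, "tumor", ph$tumor_mask$spacing)
  aif <- extract_aif(ph$series, ph$aorta_mask, n_baseline = 5)
  res <- dce_map_fit(ph$series, mask, aif, n_baseline = 5)
  # homogeneous tumor: ROI mean equals each single-voxel fit
  single <- fit_2cxm(ph$truth$tissue_curve, aif)
  expect_equal(unname(res$roi_means["PF"]), single$PF, tolerance = 1e-4)
  expect_equal(unname(res$roi_means["PV"]), single$PV, tolerance = 1e-4)
  expect_lt(abs(res$roi_means[["PF"]] - 60) / 60, 0.02)
  # voxels outside the mask are NaN
  expect_true(all(is.nan(res$maps$PF$data[!m])))
})
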