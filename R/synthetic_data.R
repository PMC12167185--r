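#' Rician magnitude noise
#'
#' Magnitude-MRI noise model: `S_noisy = sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, sigma^2)` i.i.d. Positively biases low-SNR signals.
#'
#' @param S noiseless signal (vector or array).
#' @param sigma Gaussian channel noise SD.
#' @return Noisy signal, same shape as `S`.
#' @export
rician_noise <- function(S, sigma) {
  assert_that(is_number(sigma) && sigma >= 0, "`sigma` must be >= 0")
  if (sigma == 0) return(S)
  n <- length(S)
  out <- sqrt((S + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(S))) dim(out) <- dim(S)
  out
}

# truncated-normal draws by rejection
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                        max_tries = 10000L) {
  if (sd == 0) {
    assert_that(mean >= lower && mean <= upper,
                "degenerate distribution outside truncation range",
                class = "mpmri_spec_error")
    return(rep(mean, n))
  }
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    tries <- tries + 1L
    if (tries > max_tries) {
      stop_mpmri("truncation range has negligible probability mass",
                 "mpmri_spec_error")
    }
  }
  out[seq_len(n)]
}

# ellipsoidal mask centred in a grid, semi-axes in voxels
ellipsoid_mask <- function(dim3, center = (dim3 + 1) / 2, semi_axes) {
  co <- expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                    z = seq_len(dim3[3]))
  r2 <- ((co$x - center[1]) / semi_axes[1])^2 +
    ((co$y - center[2]) / semi_axes[2])^2 +
    ((co$z - center[3]) / semi_axes[3])^2
  array(r2 <= 1, dim3)
}

#' Synthetic multi-b-value DWI phantom with known truth
#'
#' An ellipsoidal "tumor" inside a uniform background, both with known
#' diffusion parameters, sampled at the requested b-values with the chosen
#' signal model, corrupted by Rician noise, and optionally carrying injected
#' motion artifacts: whole slice-repetitions scaled down (signal dropout)
#' and/or translated in-plane by known offsets. Everything injected is
#' recorded in the returned truth object, so detection operators can be
#' scored exactly. Regeneration from the same arguments and seed is
#' bit-identical.
#'
#' @param model `"adc"` (monoexponential) or `"ivim"` (triexponential).
#' @param tumor_params,background_params named lists of model parameters
#'   (`S0`, `ADC` for adc; `S0`, `f`, `D_star`, `f_water`, `D` for ivim).
#' @param b_values b-values in s/mm2 (default: the 14-point grid).
#' @param n_repetitions repetitions per b-value (default 4).
#' @param noise_sigma Rician channel SD in signal units (0 = noiseless).
#' @param dropout data.frame `(b_index, repetition, z, scale)` of
#'   slice-repetitions to scale by `scale < 1` (default none). Scales must
#'   be below the 2/3 exclusion threshold to be detectable by design.
#' @param shifts data.frame `(b_index, repetition, z, dx, dy)` of in-plane
#'   translations in voxels to inject (default none).
#' @param dim3 grid size (default `c(24, 24, 4)`).
#' @param spacing voxel spacing in mm (default 0.5 mm isotropic).
#' @param tumor_frac tumor semi-axes as a fraction of the grid (default 0.35).
#' @param seed RNG seed (required).
#' @return List with `stack` (a [dwi_stack]), `tumor_mask` (an [roi_mask])
#'   and `truth` (class `phantom_truth`): truth maps, noise model, injected
#'   dropout and shifts, and the seed.
#' @export
make_dwi_phantom <- function(model = c("adc", "ivim"),
                             tumor_params = NULL, background_params = NULL,
                             b_values = default_b_values(),
                             n_repetitions = 4L, noise_sigma = 0,
                             dropout = NULL, shifts = NULL,
                             dim3 = c(24L, 24L, 4L), spacing = c(0.5, 0.5, 0.5),
                             tumor_frac = 0.35, seed) {
  model <- match.arg(model)
  assert_that(!missing(seed) && is_number(seed), "`seed` is required",
              class = "mpmri_spec_error")
  if (!is.null(dropout)) {
    assert_that(all(dropout$scale < 1), "dropout scales must be < 1",
                class = "mpmri_spec_error")
  }
  tumor_params <- tumor_params %||%
    (if (model == "adc") list(S0 = 800, ADC = 0.8e-3)
     else list(S0 = 800, f = 5, D_star = 60e-3, f_water = 4, D = 0.6e-3))
  background_params <- background_params %||%
    (if (model == "adc") list(S0 = 400, ADC = 1.5e-3)
     else list(S0 = 400, f = 2, D_star = 30e-3, f_water = 10, D = 1.2e-3))
  set.seed(seed)
  nb <- length(b_values); nrep <- as.integer(n_repetitions)
  tmask <- ellipsoid_mask(dim3, semi_axes = tumor_frac * dim3)
  signal_for <- function(pars, b) {
    if (model == "adc") monoexp_signal(pars$S0, pars$ADC, b)
    else triexp_eval(pars$S0, pars$f, pars$D_star, pars$f_water, pars$D, b)
  }
  par_names <- names(tumor_params)
  truth_maps <- lapply(par_names, function(pn) {
    m <- array(background_params[[pn]], dim3)
    m[tmask] <- tumor_params[[pn]]
    m
  })
  names(truth_maps) <- par_names

  vols <- array(0, dim = c(dim3, nrep, nb))
  for (bi in seq_len(nb)) {
    clean <- array(signal_for(background_params, b_values[bi]), dim3)
    clean[tmask] <- signal_for(tumor_params, b_values[bi])
    for (r in seq_len(nrep)) {
      vols[, , , r, bi] <- rician_noise(clean, noise_sigma)
    }
  }
  if (!is.null(shifts)) {
    for (i in seq_len(nrow(shifts))) {
      s <- shifts[i, ]
      vols[, , s$z, s$repetition, s$b_index] <-
        translate_image(vols[, , s$z, s$repetition, s$b_index],
                        c(s$dx, s$dy))
    }
  }
  if (!is.null(dropout)) {
    for (i in seq_len(nrow(dropout))) {
      dr <- dropout[i, ]
      vols[, , dr$z, dr$repetition, dr$b_index] <-
        vols[, , dr$z, dr$repetition, dr$b_index] * dr$scale
    }
  }
  stack <- dwi_stack(vols, b_values = b_values, spacing = spacing)
  truth <- structure(list(model = model, maps = truth_maps,
                          tumor_params = tumor_params,
                          background_params = background_params,
                          noise = list(model = "rician", sigma = noise_sigma),
                          dropout = dropout, shifts = shifts, seed = seed),
                     class = "phantom_truth")
  list(stack = stack,
       tumor_mask = roi_mask(tmask, "tumor", spacing = spacing),
       truth = truth)
}

#' Default b-value grid
#'
#' The 14-point grid used for triexponential identifiability: dense low-b
#' sampling for the pseudodiffusion compartment plus high-b anchors for
#' tissue diffusion.
#'
#' @return Numeric vector of b-values in s/mm2.
#' @export
default_b_values <- function() {
  c(0, 10, 20, 30, 40, 60, 80, 100, 150, 200, 300, 400, 600, 800)
}

#' Gamma-variate arterial input function
#'
#' `c_a(t) = a (t - t0)^alpha exp(-(t - t0) / tau)` for `t > t0`, else 0;
#' the analytic peak is at `t0 + alpha tau` and the integral is
#' `a tau^(alpha + 1) Gamma(alpha + 1)`. A standard bolus shape standing in
#' for an artery-measured input.
#'
#' @param times sample times in s.
#' @param a amplitude (arbitrary units).
#' @param alpha shape (> 0).
#' @param tau timescale in s (> 0).
#' @param t0 bolus arrival time in s.
#' @return An [aif_curve] sampled at `times`.
#' @export
make_aif <- function(times, a = 5, alpha = 2, tau = 6, t0 = 12) {
  assert_that(alpha > 0 && tau > 0, "`alpha` and `tau` must be > 0",
              class = "mpmri_spec_error")
  tt <- times - t0
  enh <- ifelse(tt > 0, a * tt^alpha * exp(-tt / tau), 0)
  arrival <- which(enh > 0)[1]
  if (is.na(arrival)) arrival <- length(times)
  aif_curve(times, enh, bolus_arrival_index = arrival)
}

#' Synthetic DCE phantom with 2CXM truth
#'
#' A small volume holding three regions: an "aorta" whose voxels carry the
#' gamma-variate AIF, an ellipsoidal "tumor" whose voxels carry the 2CXM
#' tissue response to that AIF with known parameters, and a non-enhancing
#' background. All regions sit on a constant pre-contrast signal level, and
#' additive Gaussian noise (the DCE noise model) is applied on top.
#'
#' @param tumor_params list with `PF`, `PV`, `PS`, `ve` (and optional `t0`).
#' @param times frame times in s (default 0..300 s at 1.5 s).
#' @param aif_params list passed to [make_aif] (`a`, `alpha`, `tau`, `t0`).
#' @param noise_sd additive Gaussian SD in signal units (0 = noiseless).
#' @param baseline_level pre-contrast signal level of the background; tumor
#'   and aorta sit at 1.5x and 2x this level so the pre-contrast volume has
#'   anatomical contrast for registration.
#' @param n_baseline_frames frames before the nominal bolus arrival used by
#'   downstream enhancement conversion (recorded in truth).
#' @param dim3 grid size (default `c(12, 12, 4)`).
#' @param spacing voxel spacing in mm.
#' @param seed RNG seed (required).
#' @return List with `series` (a [dce_series]), `tumor_mask`, `aorta_mask`
#'   ([roi_mask]s), `aif_truth` (the noiseless [aif_curve]) and `truth`
#'   (class `phantom_truth`).
#' @export
make_dce_phantom <- function(tumor_params = list(PF = 60, PV = 13, PS = 10,
                                                 ve = 20, t0 = 0),
                             times = seq(0, 300, by = 1.5),
                             aif_params = list(a = 5, alpha = 2, tau = 6,
                                               t0 = 12),
                             noise_sd = 0, baseline_level = 100,
                             n_baseline_frames = 5L,
                             dim3 = c(12L, 12L, 4L), spacing = c(0.5, 0.5, 0.5),
                             seed) {
  assert_that(!missing(seed) && is_number(seed), "`seed` is required",
              class = "mpmri_spec_error")
  validate_2cxm_params(tumor_params)
  set.seed(seed)
  aif <- do.call(make_aif, c(list(times = times), aif_params))
  tissue <- twocxm_forward(aif, tumor_params, times = times)
  tmask <- ellipsoid_mask(dim3, semi_axes = 0.3 * dim3)
  # aorta: a small tube in a corner, clear of the tumor
  amask <- array(FALSE, dim3)
  amask[1:2, 1:2, ] <- TRUE
  amask[tmask] <- FALSE
  nt <- length(times)
  frames <- array(baseline_level, dim = c(dim3, nt))
  for (ti in seq_len(nt)) {
    fr <- frames[, , , ti]
    fr[amask] <- 2 * baseline_level + aif$enhancement[ti]
    fr[tmask] <- 1.5 * baseline_level + tissue[ti]
    frames[, , , ti] <- fr
  }
  if (noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                             dim = dim(frames))
  }
  truth <- structure(list(model = "2cxm", tumor_params = tumor_params,
                          aif_params = aif_params,
                          tissue_curve = tissue,
                          noise = list(model = "gaussian", sd = noise_sd),
                          baseline_level = baseline_level,
                          n_baseline_frames = as.integer(n_baseline_frames),
                          seed = seed),
                     class = "phantom_truth")
  list(series = dce_series(frames, times = times, spacing = spacing),
       tumor_mask = roi_mask(tmask, "tumor", spacing = spacing),
       aorta_mask = roi_mask(amask, "aorta", spacing = spacing),
       aif_truth = aif, truth = truth)
}

#' Default two-arm cohort design
#'
#' Group sizes and per-parameter, per-group, per-timepoint means and SDs of
#' a 14 + 14 therapy/control, baseline/follow-up murine study; the numeric
#' defaults reproduce the summary statistics reported for this study design
#' (ADC and IVIM diffusivities in 1e-3 mm2/s, f in %, PF in mL/100 mL/min,
#' PV in mL/100 mL, tumor volume in mm3). Distributions are truncated
#' normals over physical ranges; `correlation` is the assumed within-subject
#' baseline/follow-up correlation (Gaussian copula), and
#' `baseline_missing_prob` the probability that a subject's baseline tumor
#' is too small to assess (all baseline values missing for that subject).
#'
#' @param n_therapy,n_control group sizes.
#' @param baseline_missing_prob per-subject baseline missingness probability.
#' @param correlation within-subject baseline/follow-up correlation.
#' @return List of class `cohort_design`.
#' @export
default_cohort_design <- function(n_therapy = 14L, n_control = 14L,
                                  baseline_missing_prob = 0.3,
                                  correlation = 0.5) {
  # mean/sd per group x timepoint: list(control_baseline, therapy_baseline,
  # control_followup, therapy_followup)
  p <- list(
    volume = list(units = "mm^3", range = c(0, Inf),
                  control = list(baseline = c(160, 117), follow_up = c(1009, 715)),
                  therapy = list(baseline = c(121, 84), follow_up = c(781, 447))),
    ADC = list(units = "1e-3 mm^2/s", range = c(0.05, 3),
               control = list(baseline = c(0.759, 0.069), follow_up = c(0.833, 0.054)),
               therapy = list(baseline = c(0.786, 0.077), follow_up = c(0.754, 0.051))),
    D = list(units = "1e-3 mm^2/s", range = c(0.05, 3),
             control = list(baseline = c(0.588, 0.060), follow_up = c(0.633, 0.084)),
             therapy = list(baseline = c(0.613, 0.080), follow_up = c(0.592, 0.067))),
    D_star = list(units = "1e-3 mm^2/s", range = c(5, 500),
                  control = list(baseline = c(52.3, 22.7), follow_up = c(61.0, 20.2)),
                  therapy = list(baseline = c(67.4, 26.7), follow_up = c(70.9, 18.6))),
    f = list(units = "%", range = c(0, 100),
             control = list(baseline = c(5.81, 2.77), follow_up = c(4.82, 2.07)),
             therapy = list(baseline = c(4.86, 2.14), follow_up = c(5.17, 1.20))),
    PF = list(units = "mL/100mL/min", range = c(0, Inf),
              control = list(baseline = c(97.4, 167.9), follow_up = c(46.9, 28.0)),
              therapy = list(baseline = c(54.5, 35.6), follow_up = c(63.6, 52.2))),
    PV = list(units = "mL/100mL", range = c(0, 100),
              control = list(baseline = c(12.6, 5.8), follow_up = c(12.4, 5.6)),
              therapy = list(baseline = c(12.9, 3.4), follow_up = c(13.6, 3.7)))
  )
  structure(list(n_therapy = as.integer(n_therapy),
                 n_control = as.integer(n_control),
                 parameters = p,
                 baseline_missing_prob = baseline_missing_prob,
                 correlation = correlation),
            class = "cohort_design")
}

#' Simulate a two-group, two-timepoint cohort
#'
#' Draws subject-level parameter values from per-group, per-timepoint
#' truncated normal distributions, with a configurable within-subject
#' baseline/follow-up correlation (applied on the underlying Gaussian), and
#' applies baseline missingness: with probability
#' `design$baseline_missing_prob` a subject's baseline values are all
#' missing ("tumor too small for assessment").
#'
#' @param design a `cohort_design` (see [default_cohort_design]).
#' @param seed RNG seed (required).
#' @return A [cohort_table] with one row per subject, timepoint and
#'   parameter.
#' @export
make_cohort <- function(design = default_cohort_design(), seed) {
  assert_that(inherits(design, "cohort_design"), "`design` must be a cohort_design")
  assert_that(!missing(seed) && is_number(seed), "`seed` is required",
              class = "mpmri_spec_error")
  assert_that(design$n_therapy >= 1L && design$n_control >= 1L,
              "group sizes must be >= 1", class = "mpmri_spec_error")
  set.seed(seed)
  rho <- design$correlation
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(design$n_therapy + design$n_control)),
    group = rep(c("therapy", "control"),
                c(design$n_therapy, design$n_control)))
  missing_base <- stats::runif(nrow(subjects)) < design$baseline_missing_prob
  rows <- list()
  for (pn in names(design$parameters)) {
    spec <- design$parameters[[pn]]
    for (si in seq_len(nrow(subjects))) {
      g <- subjects$group[si]
      mb <- spec[[g]]$baseline; mf <- spec[[g]]$follow_up
      # correlated standard-normal pair, then per-timepoint location/scale,
      # jointly re-drawn until inside the truncation range
      ok <- FALSE
      for (try in 1:1000) {
        z1 <- stats::rnorm(1)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
        vb <- mb[1] + mb[2] * z1
        vf <- mf[1] + mf[2] * z2
        if (vb >= spec$range[1] && vb <= spec$range[2] &&
            vf >= spec$range[1] && vf <= spec$range[2]) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop_mpmri(
        sprintf("truncation range infeasible for parameter %s", pn),
        "mpmri_spec_error")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subjects$subject_id[si], group = g,
        timepoint = c("baseline", "follow_up"),
        parameter = pn,
        value = c(if (missing_base[si]) NA_real_ else vb, vf),
        units = spec$units)
    }
  }
  cohort_table(do.call(rbind, rows))
}
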