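#' Monoexponential diffusion signal model
#'
#' `S(b) = S0 * exp(-b * ADC)`.
#'
#' @param S0 signal at b = 0 (arbitrary units).
#' @param ADC apparent diffusion coefficient in mm2/s.
#' @param b b-value(s) in s/mm2 (>= 0).
#' @return Signal at each `b`.
#' @export
monoexp_signal <- function(S0, ADC, b) {
  assert_that(all(b >= 0), "b-values must be >= 0")
  S0 * exp(-b * ADC)
}

#' Triexponential IVIM signal model with a fixed free-water compartment
#'
#' `S(b) = S0 * [ (f/100) exp(-b D*) + (f_water/100) exp(-b D_water)
#'              + (1 - f/100 - f_water/100) exp(-b D) ]`
#' with the free-water diffusivity frozen at `D_water = 3.0e-3` mm2/s. The
#' perfusion fraction `f` and water fraction `f_water` are expressed in
#' percent.
#'
#' @param S0 signal at b = 0.
#' @param f perfusion fraction in percent.
#' @param D_star pseudodiffusion coefficient in mm2/s.
#' @param f_water free-water fraction in percent.
#' @param D tissue diffusion coefficient in mm2/s.
#' @param b b-value(s) in s/mm2.
#' @param D_water free-water diffusivity in mm2/s (fixed, 3.0e-3).
#' @return Signal at each `b`.
#' @export
triexp_signal <- function(S0, f, D_star, f_water, D, b, D_water = 3.0e-3) {
  assert_that(f >= 0 && f_water >= 0 && f + f_water <= 100,
              "need f >= 0, f_water >= 0 and f + f_water <= 100 (percent)")
  assert_that(all(b >= 0), "b-values must be >= 0")
  triexp_eval(S0, f, D_star, f_water, D, b, D_water)
}

# unchecked fast path used inside the optimizer
triexp_eval <- function(S0, f, D_star, f_water, D, b, D_water = 3.0e-3) {
  fp <- f / 100; fw <- f_water / 100
  S0 * (fp * exp(-b * D_star) + fw * exp(-b * D_water) +
          (1 - fp - fw) * exp(-b * D))
}

#' Fit the monoexponential ADC model to one voxel's signal decay
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over `(S0, ADC)`
#' with `ADC` constrained to `[0, 1e-2]` mm2/s, initialized from a
#' log-linear regression on the strictly positive signals.
#'
#' @param signals signal at each b-value.
#' @param b_values b-values in s/mm2 (>= 3 points, >= 2 distinct).
#' @return List of class `adc_fit`: `S0`, `ADC` (mm2/s), `rss`, `converged`.
#' @export
fit_adc <- function(signals, b_values) {
  assert_that(length(signals) == length(b_values) && length(signals) >= 3L,
              "need >= 3 (b, signal) pairs", class = "mpmri_input_error")
  assert_that(length(unique(b_values)) >= 2L,
              "need >= 2 distinct b-values", class = "mpmri_input_error")
  assert_that(all(is.finite(signals)), "signals must be finite",
              class = "mpmri_input_error")
  if (all(signals <= 0)) {
    stop_mpmri("all signals non-positive; cannot fit", "mpmri_fit_error")
  }
  pos <- signals > 0
  if (sum(pos) >= 2L && length(unique(b_values[pos])) >= 2L) {
    cf <- stats::coef(stats::lm(log(signals[pos]) ~ b_values[pos]))
    S0_init <- exp(cf[[1]])
    ADC_init <- min(max(-cf[[2]], 0), 1e-2)
  } else {
    S0_init <- max(signals)
    ADC_init <- 1e-3
  }
  res <- minpack.lm::nls.lm(
    par = c(S0 = S0_init, ADC = ADC_init),
    lower = c(0, 0), upper = c(Inf, 1e-2),
    fn = function(p) monoexp_signal(p[1], p[2], b_values) - signals,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14, gtol = 0))
  p <- res$par
  structure(list(S0 = unname(p[1]), ADC = unname(p[2]),
                 rss = sum(res$fvec^2),
                 converged = res$info %in% 1:4),
            class = "adc_fit")
}

# transform between natural IVIM parameters and the box-bounded internal
# parameterization that enforces D* >= max(5e-3, 10 D) and f + f_water <= 100
ivim_to_internal <- function(S0, f, D_star, f_water, D) {
  dmin <- max(5e-3, 10 * D)
  u <- (D_star - dmin) / (0.5 - dmin)
  w <- if (f >= 100) 0 else f_water / (100 - f)
  c(S0 = S0, f = f, u = min(max(u, 0), 1), w = min(max(w, 0), 1), D = D)
}

ivim_from_internal <- function(p) {
  D <- p[[5]]
  dmin <- max(5e-3, 10 * D)
  list(S0 = p[[1]], f = p[[2]], D_star = dmin + p[[3]] * (0.5 - dmin),
       f_water = p[[4]] * (100 - p[[2]]), D = D)
}

#' Fit the triexponential IVIM model to one voxel's signal decay
#'
#' Constrained Levenberg-Marquardt least squares over
#' `(S0, f, D_star, f_water, D)` with `D_water` frozen at 3.0e-3 mm2/s.
#' Box bounds are `D` in `[0.1e-3, 2.0e-3]`, `D_star` in `[5e-3, 0.5]`
#' mm2/s; the compartment-separation constraint `D_star >= 10 D` and the
#' fraction budget `f + f_water <= 100` are enforced through an internal
#' reparameterization, so every iterate is feasible.
#'
#' Initialization is two-stage: a monoexponential fit on `b >= b_split`
#' seeds `D` and the tissue amplitude; the residual low-b amplitude seeds
#' `f`. A deterministic multistart list crosses `D_star` starts
#' `{10, 30, 80, 150} x 1e-3` mm2/s with `f_water` starts `{2, 6}` percent
#' (8 starts); the lowest residual sum of squares wins.
#'
#' @param signals signal at each b-value.
#' @param b_values b-values in s/mm2; >= 6 points spanning b < 100 and
#'   b >= 400 are required for identifiability.
#' @param b_split b-value above which the decay is treated as tissue-only
#'   for initialization (default 200 s/mm2).
#' @return List of class `ivim_fit`: `S0`, `f` (%), `D_star` (mm2/s),
#'   `f_water` (%), `D` (mm2/s), `D_water`, `rss`, `converged`.
#' @export
fit_ivim_triexp <- function(signals, b_values, b_split = 200) {
  assert_that(length(signals) == length(b_values) && length(signals) >= 6L,
              "need >= 6 (b, signal) pairs", class = "mpmri_input_error")
  assert_that(any(b_values < 100) && any(b_values >= 400),
              "b-values must span the low (< 100) and high (>= 400) regime",
              class = "mpmri_input_error")
  assert_that(all(is.finite(signals)), "signals must be finite",
              class = "mpmri_input_error")
  if (all(signals <= 0)) {
    stop_mpmri("all signals non-positive; cannot fit", "mpmri_fit_error")
  }
  hi <- b_values >= b_split
  D_init <- 0.8e-3
  A_t <- max(signals)
  if (sum(hi) >= 3L && length(unique(b_values[hi])) >= 2L) {
    mono <- tryCatch(fit_adc(signals[hi], b_values[hi]), error = function(e) NULL)
    if (!is.null(mono)) {
      D_init <- min(max(mono$ADC, 1.2e-4), 1.9e-3)
      A_t <- mono$S0
    }
  }
  S0_init <- max(signals[which.min(b_values)], A_t)
  f_init <- min(max(100 * (S0_init - A_t) / max(S0_init, .Machine$double.eps), 0.5), 40)

  lower <- c(0, 0, 0, 0, 1e-4)
  upper <- c(Inf, 100, 1, 1, 2e-3)
  resid_fn <- function(p) {
    q <- ivim_from_internal(p)
    triexp_eval(q$S0, q$f, q$D_star, q$f_water, q$D, b_values) - signals
  }
  starts <- expand.grid(D_star = c(10e-3, 30e-3, 80e-3, 150e-3),
                        f_water = c(2, 6))
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    fw0 <- starts$f_water[si]
    f0 <- max(f_init - fw0 / 2, 0.25)
    p0 <- ivim_to_internal(S0_init, f0, starts$D_star[si], fw0, D_init)
    res <- tryCatch(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-13,
                                           ptol = 1e-13, gtol = 0)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(res = res, rss = rss)
      if (rss < 1e-20 * max(sum(signals^2), 1)) break
    }
  }
  if (is.null(best)) {
    stop_mpmri("all multistart fits failed", "mpmri_fit_error")
  }
  q <- ivim_from_internal(best$res$par)
  structure(c(q, list(D_water = 3.0e-3, rss = best$rss,
                      converged = best$res$info %in% 1:4)),
            class = "ivim_fit")
}

#' Voxel-wise diffusion model fitting over an ROI
#'
#' Fits the chosen model in every mask voxel of a per-b-value volume set
#' (e.g. the output of [average_repetitions]) and reports parameter maps
#' plus ROI means over the successfully fitted voxels ("fit voxel-wise,
#' then average").
#'
#' @param volumes list of [voxel_grid], one per b-value, aligned.
#' @param b_values b-values in s/mm2 matching `volumes`.
#' @param mask an [roi_mask] over the same grid.
#' @param model `"adc"` or `"ivim"`.
#' @param ... passed to the per-voxel fitter.
#' @return List with `maps` (named list of [voxel_grid], `NaN` outside the
#'   mask and at failed voxels), `roi_means` (named numeric), `n_voxels`,
#'   `n_failed`.
#' @export
map_fit <- function(volumes, b_values, mask, model = c("adc", "ivim"), ...) {
  model <- match.arg(model)
  assert_that(is.list(volumes) && length(volumes) == length(b_values),
              "`volumes` must be a list with one voxel_grid per b-value")
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  d <- dim(volumes[[1]]$data)
  assert_that(identical(dim(mask$mask), d), "mask/volume shape mismatch",
              class = "mpmri_layout_error")
  idx <- which(mask$mask)
  sig <- vapply(volumes, function(v) v$data[idx], numeric(length(idx)))
  sig <- matrix(sig, nrow = length(idx))
  par_names <- if (model == "adc") c("S0", "ADC") else
    c("S0", "f", "D_star", "f_water", "D")
  units <- c(S0 = "a.u.", ADC = "mm^2/s", f = "%", D_star = "mm^2/s",
             f_water = "%", D = "mm^2/s")
  vals <- matrix(NA_real_, length(idx), length(par_names),
                 dimnames = list(NULL, par_names))
  n_failed <- 0L
  for (i in seq_along(idx)) {
    s <- sig[i, ]
    if (!all(is.finite(s))) { n_failed <- n_failed + 1L; next }
    fit <- tryCatch(
      if (model == "adc") fit_adc(s, b_values)
      else fit_ivim_triexp(s, b_values, ...),
      mpmri_error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) {
      n_failed <- n_failed + 1L
      next
    }
    vals[i, ] <- unlist(fit[par_names])
  }
  if (n_failed > length(idx) / 2) {
    warn_mpmri(sprintf("%d of %d voxels failed to fit", n_failed, length(idx)),
               "mpmri_fit_quality_warning")
  }
  maps <- lapply(par_names, function(pn) {
    m <- array(NaN, d)
    m[idx] <- vals[, pn]
    g <- voxel_grid(m, spacing = mask$spacing)
    attr(g, "parameter") <- pn
    attr(g, "units") <- unname(units[pn])
    g
  })
  names(maps) <- par_names
  roi_means <- colMeans(vals, na.rm = TRUE)
  list(maps = maps, roi_means = roi_means,
       n_voxels = length(idx), n_failed = n_failed)
}
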