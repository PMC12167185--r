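#' Volumetric Gaussian smoothing with a physical-width kernel
#'
#' Separable 3-D Gaussian convolution whose width is given as the kernel
#' FWHM in mm (the usual radiology convention), so the per-axis sigma in
#' voxels is `width_mm / (2 sqrt(2 log 2)) / spacing_axis`. The discrete
#' kernel is truncated at 3 sigma and normalized to unit sum; boundaries
#' are handled by reflection, so constant images are preserved exactly.
#'
#' @param grid a [voxel_grid].
#' @param width_mm kernel FWHM in mm (> 0); the DWI default in this pipeline
#'   is 1.5 mm and the DCE default 1.0 mm.
#' @return Smoothed [voxel_grid].
#' @export
gaussian_smooth <- function(grid, width_mm) {
  assert_that(inherits(grid, "voxel_grid"), "`grid` must be a voxel_grid")
  assert_that(is_number(width_mm) && width_mm > 0,
              "`width_mm` must be a positive number")
  sigma_vox <- width_mm / (2 * sqrt(2 * log(2))) / grid$spacing
  out <- grid$data
  for (axis in 1:3) {
    out <- convolve_axis_gaussian(out, axis, sigma_vox[axis])
  }
  voxel_grid(out, spacing = grid$spacing, origin = grid$origin)
}

# 1-D Gaussian convolution along `axis` of a 3-D array, reflective boundary.
convolve_axis_gaussian <- function(x, axis, sigma) {
  r <- ceiling(3 * sigma)
  if (r < 1L) return(x)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- dim(x)[axis]
  # reflective index map for positions 1-r .. n+r ("symmetric" reflection
  # with period 2n, valid for any r: ... 2 1 | 1 2 ... n | n n-1 ...)
  idx <- seq(1L - r, n + r)
  j <- ((idx - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  idx <- ifelse(j < n, j + 1L, 2L * n - j)
  xp <- slice_along(x, axis, idx)
  out <- array(0, dim(x))
  for (j in seq_along(k)) {
    out <- out + k[j] * slice_along(xp, axis, seq.int(j, length.out = n))
  }
  out
}

#' Otsu intensity threshold
#'
#' Histogram-based threshold maximizing between-class variance; used to
#' define the foreground of a slice for the dropout rule. Returns a value
#' `t` such that `x > t` is foreground. For (near-)constant input the
#' maximum is returned, giving an empty foreground.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x[is.finite(x)])
  assert_that(length(x) > 0L, "no finite intensities")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(hi)
  h <- tabulate(pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                       # class-0 probability at cut k
  mu <- cumsum(p * seq_len(n_bins))        # class-0 first moment
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)                      # cut after bin k
  lo + k / n_bins * (hi - lo)
}

#' Detect motion-induced signal dropout in a DWI stack
#'
#' Implements the exclusion rule for motion-corrupted repetitions: for each
#' slice and b-value, a repetition is excluded when its mean foreground
#' signal falls below `threshold_frac` (default 2/3) of the mean foreground
#' signal of the brightest 50 percent of all repetitions of that slice and
#' b-value (with odd R, the brightest `ceiling(R/2)`).
#'
#' The foreground is computed once per (slice, b-value) as the voxels above
#' the Otsu threshold of the across-repetition median image, so every
#' repetition is scored against the same mask and the mask is stable against
#' the dropout being tested. A slice with an empty foreground is flagged
#' all-excluded with a warning.
#'
#' @param stack a [dwi_stack] with >= 2 repetitions.
#' @param threshold_frac exclusion threshold as a fraction of the bright-half
#'   mean (default 2/3).
#' @return List with `stack` (the input with `excluded` filled in) and
#'   `report`, a data.frame with one row per (b_index, repetition, z):
#'   `b_index, repetition, z, mean_foreground_signal, threshold, excluded`.
#' @export
detect_signal_dropout <- function(stack, threshold_frac = 2 / 3) {
  assert_that(inherits(stack, "dwi_stack"), "`stack` must be a dwi_stack")
  d <- dim(stack$volumes)
  nz <- d[3]; nrep <- d[4]; nb <- d[5]
  assert_that(nrep >= 2L, "dropout detection needs at least 2 repetitions")
  assert_that(is_number(threshold_frac) && threshold_frac >= 0,
              "`threshold_frac` must be a non-negative number")
  rows <- vector("list", nz * nb)
  ri <- 0L
  for (bi in seq_len(nb)) {
    for (zi in seq_len(nz)) {
      sl <- stack$volumes[, , zi, , bi, drop = TRUE]      # [x, y, rep]
      dim(sl) <- c(d[1], d[2], nrep)
      med <- apply(sl, c(1, 2), stats::median)
      thr <- otsu_threshold(med)
      fg <- med > thr
      ri <- ri + 1L
      if (!any(fg)) {
        warn_mpmri(sprintf(
          "empty foreground for slice z=%d, b_index=%d; all repetitions excluded",
          zi, bi), "mpmri_empty_foreground_warning")
        stack$excluded[zi, , bi] <- TRUE
        rows[[ri]] <- data.frame(b_index = bi, repetition = seq_len(nrep),
                                 z = zi, mean_foreground_signal = NA_real_,
                                 threshold = NA_real_, excluded = TRUE)
        next
      }
      m <- vapply(seq_len(nrep), function(r) mean(sl[, , r][fg]), numeric(1))
      n_top <- ceiling(nrep / 2)
      bright <- mean(sort(m, decreasing = TRUE)[seq_len(n_top)])
      thr_val <- threshold_frac * bright
      excl <- m < thr_val
      stack$excluded[zi, , bi] <- excl
      rows[[ri]] <- data.frame(b_index = bi, repetition = seq_len(nrep),
                               z = zi, mean_foreground_signal = m,
                               threshold = thr_val, excluded = excl)
    }
  }
  report <- do.call(rbind, rows)
  report <- report[order(report$b_index, report$z, report$repetition), ]
  rownames(report) <- NULL
  list(stack = stack, report = report)
}

# ---- rigid translation registration ---------------------------------------

# Normalized cross-correlation of the overlap between `moving` shifted by
# integer `shift` and `fixed` (2-D or 3-D arrays of equal dim).
ncc_at_shift <- function(moving, fixed, shift) {
  d <- dim(fixed)
  nd <- length(d)
  idx_f <- idx_m <- vector("list", nd)
  for (a in seq_len(nd)) {
    s <- shift[a]
    # moving voxel i aligns with fixed voxel i + s
    lo_f <- max(1L, 1L + s); hi_f <- min(d[a], d[a] + s)
    if (lo_f > hi_f) return(NA_real_)
    idx_f[[a]] <- lo_f:hi_f
    idx_m[[a]] <- (lo_f - s):(hi_f - s)
  }
  fv <- do.call(`[`, c(list(fixed), idx_f))
  mv <- do.call(`[`, c(list(moving), idx_m))
  sf <- stats::sd(fv); sm <- stats::sd(mv)
  if (!is.finite(sf) || !is.finite(sm) || sf == 0 || sm == 0) return(NA_real_)
  mean((fv - mean(fv)) * (mv - mean(mv))) / (sf * sm)
}

# Quadratic (parabolic) sub-sample refinement of a 1-D peak from the values
# at the peak and its two neighbours; returns offset in (-0.5, 0.5).
parabolic_offset <- function(cm1, c0, cp1) {
  den <- cm1 - 2 * c0 + cp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (cm1 - cp1) / den
  max(-0.5, min(0.5, off))
}

#' Estimate a rigid translation by normalized cross-correlation
#'
#' Exhaustive integer-shift search within `max_shift` voxels per axis,
#' refined to subvoxel precision by quadratic interpolation of the NCC
#' surface around the integer peak. Works for 2-D and 3-D arrays. The
#' returned shift is the translation to apply to `moving` (via
#' [translate_image]) to align it with `fixed`.
#'
#' @param moving,fixed numeric arrays of identical dimension.
#' @param max_shift search half-window in voxels (default 5).
#' @return Numeric shift vector (one entry per axis), with attribute
#'   `"ncc"` (peak correlation); zero with a warning for degenerate input.
#' @export
register_translation <- function(moving, fixed, max_shift = 5L) {
  d <- dim(fixed)
  nd <- length(d)
  assert_that(nd %in% c(2L, 3L) && identical(dim(moving), d),
              "`moving` and `fixed` must be 2-D or 3-D arrays of equal dim")
  if (stats::sd(moving) == 0 || stats::sd(fixed) == 0) {
    warn_mpmri("constant image; returning zero shift",
               "mpmri_degenerate_registration_warning")
    return(structure(rep(0, nd), ncc = NA_real_))
  }
  # per-axis window capped at half the axis length so the overlap never
  # drops below ~50% (guards against spurious small-overlap NCC peaks)
  win <- pmin(max_shift, floor(d / 2))
  shifts <- as.matrix(expand.grid(lapply(win, function(w) seq.int(-w, w))))
  cc <- apply(shifts, 1L, function(s) ncc_at_shift(moving, fixed, s))
  if (all(is.na(cc))) {
    warn_mpmri("no valid overlap in registration search; returning zero shift",
               "mpmri_degenerate_registration_warning")
    return(structure(rep(0, nd), ncc = NA_real_))
  }
  # smallest-shift tie-break among near-equal correlation peaks
  near <- which(cc >= max(cc, na.rm = TRUE) - 1e-9)
  best <- near[which.min(rowSums(shifts[near, , drop = FALSE]^2))]
  s0 <- shifts[best, ]
  # per-axis parabolic refinement where both neighbours are in the window
  refined <- as.numeric(s0)
  for (a in seq_len(nd)) {
    if (abs(s0[a]) >= win[a]) next
    sm <- s0; sm[a] <- s0[a] - 1L
    sp <- s0; sp[a] <- s0[a] + 1L
    cm1 <- cc[match_shift_row(shifts, sm)]
    cp1 <- cc[match_shift_row(shifts, sp)]
    if (is.na(cm1) || is.na(cp1)) next
    refined[a] <- s0[a] + parabolic_offset(cm1, cc[best], cp1)
  }
  structure(refined, ncc = cc[best])
}

match_shift_row <- function(shifts, s) {
  which(rowSums(abs(sweep(shifts, 2L, s)) ) == 0)[1]
}

#' Translate an image by a (sub)voxel shift
#'
#' Rigid translation with multilinear interpolation; voxels sampled outside
#' the array take the nearest edge value, so intensity statistics of an
#' unshifted image are unchanged.
#'
#' @param img 2-D or 3-D numeric array.
#' @param shift numeric shift per axis in voxels; `translate_image(x, s)`
#'   moves content of `x` by `+s` voxels along each axis.
#' @return Shifted array of the same dimension.
#' @export
translate_image <- function(img, shift) {
  d <- dim(img)
  nd <- length(d)
  assert_that(nd %in% c(2L, 3L) && length(shift) == nd,
              "`img` must be 2-D or 3-D with one shift per axis")
  if (all(shift == 0)) return(img)
  # output voxel i samples input at i - shift
  coords <- lapply(seq_len(nd), function(a) seq_len(d[a]) - shift[a])
  f <- lapply(seq_len(nd), function(a) pmin(pmax(floor(coords[[a]]), 1L), d[a]))
  cl <- lapply(seq_len(nd), function(a) pmin(f[[a]] + 1L, d[a]))
  w <- lapply(seq_len(nd), function(a)
    pmin(pmax(coords[[a]] - f[[a]], 0), 1))
  out <- array(0, d)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    corner <- corners[ci, ]
    idx <- lapply(seq_len(nd), function(a)
      if (corner[a] == 0) f[[a]] else cl[[a]])
    warr <- array(1, d)
    for (a in seq_len(nd)) {
      wa <- if (corner[a] == 0) 1 - w[[a]] else w[[a]]
      warr <- warr * slice_broadcast(wa, a, d)
    }
    sub <- do.call(`[`, c(list(img), idx))
    out <- out + warr * array(sub, d)
  }
  out
}

# broadcast a per-axis weight vector to the full array dim
slice_broadcast <- function(v, axis, d) {
  shape <- rep(1L, length(d)); shape[axis] <- d[axis]
  aperm(array(v, dim = c(d[axis], d[-axis])),
        order(c(axis, seq_along(d)[-axis])))
}

#' In-plane rigid motion correction of a DWI stack
#'
#' Each 2-D slice-repetition is translated onto the reference repetition of
#' its (slice, b-value) — the repetition with the highest mean foreground
#' signal — using NCC-based registration with quadratic subvoxel refinement
#' (search window `max_shift` voxels).
#'
#' @param stack a [dwi_stack].
#' @param max_shift search half-window in voxels.
#' @return List with `stack` (corrected) and `shifts`, a data.frame
#'   `(b_index, repetition, z, shift_x, shift_y, reference)`.
#' @export
inplane_motion_correct <- function(stack, max_shift = 5L) {
  assert_that(inherits(stack, "dwi_stack"), "`stack` must be a dwi_stack")
  d <- dim(stack$volumes)
  nz <- d[3]; nrep <- d[4]; nb <- d[5]
  rows <- vector("list", nz * nb)
  ri <- 0L
  for (bi in seq_len(nb)) {
    for (zi in seq_len(nz)) {
      sl <- stack$volumes[, , zi, , bi, drop = TRUE]
      dim(sl) <- c(d[1], d[2], nrep)
      med <- apply(sl, c(1, 2), stats::median)
      fg <- med > otsu_threshold(med)
      if (!any(fg)) fg <- array(TRUE, dim(med))
      m <- vapply(seq_len(nrep), function(r) mean(sl[, , r][fg]), numeric(1))
      ref <- which.max(m)
      sh <- matrix(0, nrep, 2)
      for (r in seq_len(nrep)) {
        if (r == ref) next
        s <- withCallingHandlers(
          register_translation(sl[, , r], sl[, , ref], max_shift = max_shift),
          mpmri_degenerate_registration_warning = function(w)
            invokeRestart("muffleWarning"))
        sh[r, ] <- s
        if (any(s != 0)) {
          stack$volumes[, , zi, r, bi] <- translate_image(sl[, , r], s)
        }
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(b_index = bi, repetition = seq_len(nrep),
                               z = zi, shift_x = sh[, 1], shift_y = sh[, 2],
                               reference = ref)
    }
  }
  shifts <- do.call(rbind, rows)
  rownames(shifts) <- NULL
  list(stack = stack, shifts = shifts)
}

#' 3-D rigid motion correction of a DCE series
#'
#' Each frame is translated in 3-D onto the mean of the first `n_baseline`
#' (pre-bolus) frames, by the same NCC contract as
#' [inplane_motion_correct] extended to 3-D.
#'
#' @param series a [dce_series].
#' @param n_baseline number of pre-bolus frames defining the reference.
#' @param max_shift search half-window in voxels.
#' @return List with `series` (corrected) and `shifts` data.frame
#'   `(frame, shift_x, shift_y, shift_z)`.
#' @export
volume_motion_correct <- function(series, n_baseline, max_shift = 5L) {
  assert_that(inherits(series, "dce_series"), "`series` must be a dce_series")
  nt <- dim(series$frames)[4]
  assert_that(is_number(n_baseline) && n_baseline >= 1 && n_baseline < nt,
              "`n_baseline` must be in [1, n_frames)")
  ref <- apply(series$frames[, , , seq_len(n_baseline), drop = FALSE],
               c(1, 2, 3), mean)
  sh <- matrix(0, nt, 3)
  for (ti in seq_len(nt)) {
    fr <- series$frames[, , , ti]
    s <- withCallingHandlers(
      register_translation(fr, ref, max_shift = max_shift),
      mpmri_degenerate_registration_warning = function(w)
        invokeRestart("muffleWarning"))
    sh[ti, ] <- s
    if (any(s != 0)) series$frames[, , , ti] <- translate_image(fr, s)
  }
  list(series = series,
       shifts = data.frame(frame = seq_len(nt), shift_x = sh[, 1],
                           shift_y = sh[, 2], shift_z = sh[, 3]))
}

#' Average non-excluded repetitions per b-value
#'
#' Voxel-wise mean over the repetitions that survived the dropout rule.
#' Slices whose repetitions were all excluded become `NaN` with a warning,
#' so downstream fits skip them rather than use corrupted data.
#'
#' @param stack a [dwi_stack] (after [detect_signal_dropout]).
#' @return List with `volumes`, a list (one [voxel_grid] per b-value), and
#'   `counts`, an array `[z, b]` of repetitions used per slice.
#' @export
average_repetitions <- function(stack) {
  assert_that(inherits(stack, "dwi_stack"), "`stack` must be a dwi_stack")
  d <- dim(stack$volumes)
  nz <- d[3]; nrep <- d[4]; nb <- d[5]
  counts <- array(0L, dim = c(nz, nb))
  vols <- vector("list", nb)
  for (bi in seq_len(nb)) {
    out <- array(NA_real_, d[1:3])
    for (zi in seq_len(nz)) {
      keep <- which(!stack$excluded[zi, , bi])
      counts[zi, bi] <- length(keep)
      if (length(keep) == 0L) {
        warn_mpmri(sprintf(
          "all repetitions excluded for slice z=%d, b_index=%d; slice set to NaN",
          zi, bi), "mpmri_all_excluded_warning")
        out[, , zi] <- NaN
        next
      }
      sl <- stack$volumes[, , zi, keep, bi, drop = FALSE]
      out[, , zi] <- apply(array(sl, c(d[1], d[2], length(keep))), c(1, 2), mean)
    }
    vols[[bi]] <- voxel_grid(out, spacing = stack$spacing)
  }
  names(vols) <- paste0("b", stack$b_values)
  list(volumes = vols, counts = counts)
}
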