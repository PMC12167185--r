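#' Default run configuration
#'
#' All tunables of the pipeline with their defaults: Gaussian widths 1.5 mm
#' (DWI) and 1.0 mm (DCE), dropout threshold 2/3, the 14-point b-value
#' grid, 1.5-s DCE sampling over 5 min, 5 baseline frames, and the cohort
#' design of [default_cohort_design]. Every run writes the resolved
#' configuration next to its outputs.
#'
#' @param seed RNG seed recorded and used for every stochastic stage.
#' @param mode `"simulate_cohort"` (subject-level parameter draws, no
#'   imaging), `"simulate_imaging"` (per-subject phantoms through the full
#'   image pipeline) or `"files"` (NIfTI inputs listed under `subjects`).
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, mode = "simulate_cohort") {
  structure(list(
    mode = mode,
    seed = as.integer(seed),
    b_values = default_b_values(),
    n_repetitions = 4L,
    dwi_smooth_mm = 1.5,
    dce_smooth_mm = 1.0,
    dropout_frac = 2 / 3,
    registration_max_shift = 5L,
    n_baseline = 5L,
    arrival_k = 5,
    dce_times = seq(0, 300, by = 1.5),
    dwi_models = c("adc", "ivim"),
    dwi_fit_scope = "voxel",     # "voxel" (fit voxel-wise, then average) or "roi"
    dce_fit_scope = "voxel",
    zero_method = "drop",
    alpha = 0.05,
    n_therapy = 14L,
    n_control = 14L,
    baseline_missing_prob = 0.3,
    correlation = 0.5,
    subjects = NULL
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_run_config].
#'
#' @param path YAML file.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  assert_that(file.exists(path), paste("config not found:", path),
              class = "mpmri_config_error")
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(cfg), names(base))
  assert_that(length(unknown) == 0L,
              paste("unknown config keys:", paste(unknown, collapse = ", ")),
              class = "mpmri_config_error")
  for (k in names(cfg)) base[[k]] <- cfg[[k]]
  base$seed <- as.integer(base$seed)
  validate_run_config(base)
  base
}

validate_run_config <- function(config) {
  assert_that(config$mode %in% c("simulate_cohort", "simulate_imaging", "files"),
              "mode must be simulate_cohort, simulate_imaging or files",
              class = "mpmri_config_error")
  assert_that(config$dwi_smooth_mm > 0 && config$dce_smooth_mm > 0,
              "smoothing widths must be > 0", class = "mpmri_config_error")
  assert_that(config$dropout_frac >= 0, "dropout_frac must be >= 0",
              class = "mpmri_config_error")
  assert_that(all(config$dwi_models %in% c("adc", "ivim")),
              "dwi_models must be a subset of {adc, ivim}",
              class = "mpmri_config_error")
  invisible(TRUE)
}

#' Preprocess and fit one subject's DWI stack
#'
#' Stage order: in-plane motion correction, dropout detection/exclusion,
#' repetition averaging, Gaussian smoothing, then model fitting (smoothing
#' last so misaligned data are never blurred together).
#'
#' @param stack a [dwi_stack].
#' @param tumor_mask an [roi_mask].
#' @param config a `run_config`.
#' @return List with `roi_means` (named, per model parameter), `dropout`
#'   report, `shifts` log, `maps`.
#' @export
process_dwi <- function(stack, tumor_mask, config = default_run_config()) {
  mc <- inplane_motion_correct(stack, max_shift = config$registration_max_shift)
  dd <- detect_signal_dropout(mc$stack, threshold_frac = config$dropout_frac)
  avg <- suppressWarnings(average_repetitions(dd$stack))
  smoothed <- lapply(avg$volumes, gaussian_smooth, width_mm = config$dwi_smooth_mm)
  roi_means <- c()
  maps <- list()
  for (model in config$dwi_models) {
    if (config$dwi_fit_scope == "roi") {
      sig <- vapply(smoothed, function(v) mean(v$data[tumor_mask$mask],
                                               na.rm = TRUE), numeric(1))
      fit <- if (model == "adc") fit_adc(sig, stack$b_values)
             else fit_ivim_triexp(sig, stack$b_values)
      pars <- if (model == "adc") c("ADC") else c("D", "D_star", "f", "f_water")
      roi_means <- c(roi_means, unlist(fit[pars]))
    } else {
      mf <- map_fit(smoothed, stack$b_values, tumor_mask, model = model)
      pars <- if (model == "adc") c("ADC") else c("D", "D_star", "f", "f_water")
      roi_means <- c(roi_means, mf$roi_means[pars])
      maps[[model]] <- mf$maps
    }
  }
  list(roi_means = roi_means, dropout = dd$report, shifts = mc$shifts,
       maps = maps)
}

#' Preprocess and fit one subject's DCE series
#'
#' 3-D motion correction, Gaussian smoothing, AIF extraction from the aorta
#' ROI, then 2CXM fitting (voxel-wise or on the ROI-mean curve).
#'
#' @param series a [dce_series].
#' @param tumor_mask,aorta_mask [roi_mask]s.
#' @param config a `run_config`.
#' @return List with `roi_means` (`PF`, `PV`), `aif`, `shifts`, `maps`.
#' @export
process_dce <- function(series, tumor_mask, aorta_mask,
                        config = default_run_config()) {
  mc <- volume_motion_correct(series, n_baseline = config$n_baseline,
                              max_shift = config$registration_max_shift)
  sm_frames <- mc$series$frames
  for (ti in seq_len(dim(sm_frames)[4])) {
    sm_frames[, , , ti] <- gaussian_smooth(
      voxel_grid(sm_frames[, , , ti], spacing = series$spacing),
      width_mm = config$dce_smooth_mm)$data
  }
  sm <- dce_series(sm_frames, times = series$times, spacing = series$spacing)
  aif <- extract_aif(sm, aorta_mask, n_baseline = config$n_baseline,
                     k = config$arrival_k)
  maps <- list()
  if (config$dce_fit_scope == "roi") {
    enh <- signal_enhancement(sm, config$n_baseline)
    idx <- which(tumor_mask$mask)
    nt <- dim(enh$frames)[4]
    curve <- vapply(seq_len(nt), function(ti) mean(enh$frames[, , , ti][idx]),
                    numeric(1))
    fit <- fit_2cxm(curve, aif)
    roi_means <- c(PF = fit$PF, PV = fit$PV)
  } else {
    df <- dce_map_fit(sm, tumor_mask, aif, n_baseline = config$n_baseline)
    roi_means <- df$roi_means[c("PF", "PV")]
    maps <- df$maps
  }
  list(roi_means = roi_means, aif = aif, shifts = mc$shifts, maps = maps)
}

# cohort design derived from a run_config
config_cohort_design <- function(config) {
  default_cohort_design(n_therapy = config$n_therapy,
                        n_control = config$n_control,
                        baseline_missing_prob = config$baseline_missing_prob,
                        correlation = config$correlation)
}

#' Full cohort statistics report
#'
#' Group summaries (mean +/- SD), Mann-Whitney intergroup tests per
#' parameter and timepoint, Wilcoxon signed-rank intragroup tests per
#' parameter and group (after pairwise deletion), and the Spearman
#' correlation matrix. All p-values are raw: no multiplicity adjustment.
#'
#' @param table a [cohort_table].
#' @param alpha significance level for the correlation mask.
#' @param zero_method zero-difference handling for the Wilcoxon test.
#' @return List with `summary`, `tests` (data.frame), `correlation`.
#' @export
cohort_report <- function(table, alpha = 0.05, zero_method = "drop") {
  table <- cohort_table(table)
  params <- sort(unique(table$parameter))
  tests <- list()
  for (pn in params) {
    sub <- table[table$parameter == pn, ]
    for (tp in c("baseline", "follow_up")) {
      xs <- sub$value[sub$timepoint == tp & sub$group == "therapy"]
      ys <- sub$value[sub$timepoint == tp & sub$group == "control"]
      res <- tryCatch(mann_whitney_u(xs, ys), mpmri_input_error = function(e) NULL)
      if (is.null(res)) next
      tests[[length(tests) + 1L]] <- data.frame(
        parameter = pn, comparison = "therapy vs control", stratum = tp,
        test = res$test, n1 = res$n1, n2 = res$n2,
        statistic = res$statistic, p = res$p_value, method = res$method)
    }
    for (g in c("therapy", "control")) {
      gs <- sub[sub$group == g, ]
      base <- gs$value[match(unique(gs$subject_id),
                             gs$subject_id[gs$timepoint == "baseline"])]
      wide <- merge(gs[gs$timepoint == "baseline", c("subject_id", "value")],
                    gs[gs$timepoint == "follow_up", c("subject_id", "value")],
                    by = "subject_id", all = TRUE,
                    suffixes = c("_baseline", "_follow_up"))
      res <- tryCatch(suppressWarnings(
        wilcoxon_signed_rank(wide$value_baseline, wide$value_follow_up,
                             zero_method = zero_method)),
        mpmri_input_error = function(e) NULL)
      if (is.null(res)) next
      tests[[length(tests) + 1L]] <- data.frame(
        parameter = pn, comparison = "baseline vs follow_up", stratum = g,
        test = res$test, n1 = res$n_pairs, n2 = res$n_pairs,
        statistic = res$statistic, p = res$p_value, method = res$method)
    }
  }
  tests <- do.call(rbind, tests)
  corr <- spearman_matrix(table, alpha = alpha)
  list(summary = group_summary(table), tests = tests, correlation = corr)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate/read, preprocess, fit, aggregate and statistics,
#' writing all artifacts to `out_dir`: the resolved config
#' (`config.yaml`), the cohort table (`cohort.csv`), group summaries
#' (`group_summary.csv`), test results (`stats_tests.csv`), the Spearman
#' matrix (`correlation_rho.csv`, `correlation_p.csv`,
#' `correlation_heatmap.png`), per-subject dropout/shift logs, and
#' `run.log` with the seed. Reruns with the same config and seed reproduce
#' all numeric outputs bit-identically.
#'
#' @param config a `run_config` (see [default_run_config],
#'   [read_run_config]).
#' @param out_dir output directory (created if needed).
#' @return List with `cohort`, `report`, and per-subject processing
#'   details, invisibly.
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("mpmri_run_")) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config[setdiff(names(config), "subjects")],
                   file.path(out_dir, "config.yaml"))
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = file.path(out_dir, "run.log"),
                               append = TRUE)
  logline("run_all start; mode=%s seed=%d", config$mode, config$seed)
  details <- list()

  if (config$mode == "simulate_cohort") {
    cohort <- make_cohort(config_cohort_design(config), seed = config$seed)
  } else if (config$mode == "simulate_imaging") {
    cohort <- simulate_imaging_cohort(config, out_dir, logline)
    details <- attr(cohort, "details")
    attr(cohort, "details") <- NULL
  } else {
    cohort <- process_subject_files(config, out_dir, logline)
  }
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))

  report <- cohort_report(cohort, alpha = config$alpha,
                          zero_method = config$zero_method)
  utils::write.csv(report$summary, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(out_dir, "stats_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$correlation$rho),
                   file.path(out_dir, "correlation_rho.csv"))
  utils::write.csv(as.data.frame(report$correlation$p),
                   file.path(out_dir, "correlation_p.csv"))
  try(plot_correlation_matrix(report$correlation,
                              file.path(out_dir, "correlation_heatmap.png")),
      silent = TRUE)
  logline("run_all done")
  invisible(list(cohort = cohort, report = report, details = details,
                 out_dir = out_dir))
}

# Per-subject imaging simulation: draw subject-level truth from the cohort
# design, build DWI and DCE phantoms, run the image pipeline, collect ROI
# means into a cohort table.
simulate_imaging_cohort <- function(config, out_dir, logline) {
  design <- config_cohort_design(config)
  set.seed(config$seed)
  subj_seeds <- sample.int(2^30, (config$n_therapy + config$n_control) * 2)
  groups <- rep(c("therapy", "control"), c(config$n_therapy, config$n_control))
  rows <- list()
  details <- list()
  si <- 0L
  for (subj in seq_along(groups)) {
    g <- groups[subj]
    id <- sprintf("S%02d", subj)
    for (tp in c("baseline", "follow_up")) {
      si <- si + 1L
      adc_truth <- rtrunc_norm(1, design$parameters$ADC[[g]][[tp]][1],
                               design$parameters$ADC[[g]][[tp]][2],
                               lower = 0.1, upper = 2.5) * 1e-3
      pf_truth <- rtrunc_norm(1, design$parameters$PF[[g]][[tp]][1],
                              design$parameters$PF[[g]][[tp]][2],
                              lower = 5, upper = 400)
      pv_truth <- rtrunc_norm(1, design$parameters$PV[[g]][[tp]][1],
                              design$parameters$PV[[g]][[tp]][2],
                              lower = 2, upper = 40)
      dwi <- make_dwi_phantom(model = "adc",
                              tumor_params = list(S0 = 800, ADC = adc_truth),
                              b_values = config$b_values,
                              n_repetitions = config$n_repetitions,
                              noise_sigma = 8, dim3 = c(20L, 20L, 6L),
                              seed = subj_seeds[si])
      pd <- process_dwi(dwi$stack, dwi$tumor_mask, config)
      dce <- make_dce_phantom(
        tumor_params = list(PF = pf_truth, PV = pv_truth, PS = 10, ve = 20,
                            t0 = 0),
        times = config$dce_times, noise_sd = 0.5,
        dim3 = c(10L, 10L, 3L), seed = subj_seeds[si] + 1L)
      pc <- process_dce(dce$series, dce$tumor_mask, dce$aorta_mask, config)
      vol <- compute_roi_volume(dwi$tumor_mask)
      vals <- c(volume = vol, ADC = unname(pd$roi_means[["ADC"]]) * 1e3,
                pc$roi_means)
      unit_of <- c(volume = "mm^3", ADC = "1e-3 mm^2/s",
                   PF = "mL/100mL/min", PV = "mL/100mL")
      rows[[si]] <- data.frame(subject_id = id, group = g, timepoint = tp,
                               parameter = names(vals), value = unname(vals),
                               units = unit_of[names(vals)])
      details[[paste(id, tp, sep = "_")]] <-
        list(dropout = pd$dropout, shifts = pd$shifts,
             truth = list(ADC = adc_truth, PF = pf_truth, PV = pv_truth))
      logline("subject %s %s processed (seed %d)", id, tp, subj_seeds[si])
    }
  }
  cohort <- cohort_table(do.call(rbind, rows))
  attr(cohort, "details") <- details
  cohort
}

# File mode: each config$subjects entry names NIfTI inputs for one subject
# and timepoint.
process_subject_files <- function(config, out_dir, logline) {
  assert_that(!is.null(config$subjects) && length(config$subjects) > 0,
              "mode 'files' requires a non-empty `subjects` list",
              class = "mpmri_config_error")
  rows <- list()
  for (entry in config$subjects) {
    id <- entry$id; g <- entry$group; tp <- entry$timepoint
    vals <- c(); unit_of <- c()
    stage <- "read"
    res <- tryCatch({
      if (!is.null(entry$dwi)) {
        stack <- read_nifti(entry$dwi, layout = "dwi",
                            b_values = config$b_values,
                            n_repetitions = config$n_repetitions,
                            packing = entry$packing %||% "b_then_rep")
        tmask <- read_nifti(entry$tumor_mask, layout = "mask", label = "tumor")
        stage <- "dwi"
        pd <- process_dwi(stack, tmask, config)
        vals <- c(vals, volume = compute_roi_volume(tmask),
                  ADC = unname(pd$roi_means[["ADC"]]) * 1e3)
        unit_of <- c(unit_of, volume = "mm^3", ADC = "1e-3 mm^2/s")
        utils::write.csv(pd$dropout,
                         file.path(out_dir, sprintf("%s_%s_dropout.csv", id, tp)),
                         row.names = FALSE)
        utils::write.csv(pd$shifts,
                         file.path(out_dir, sprintf("%s_%s_dwi_shifts.csv", id, tp)),
                         row.names = FALSE)
      }
      if (!is.null(entry$dce)) {
        series <- read_nifti(entry$dce, layout = "dce", times = config$dce_times)
        tmask <- read_nifti(entry$tumor_mask, layout = "mask", label = "tumor")
        amask <- read_nifti(entry$aorta_mask, layout = "mask", label = "aorta")
        stage <- "dce"
        pc <- process_dce(series, tmask, amask, config)
        vals <- c(vals, pc$roi_means)
        unit_of <- c(unit_of, PF = "mL/100mL/min", PV = "mL/100mL")
      }
      TRUE
    }, mpmri_error = function(e) {
      stop_mpmri(sprintf("stage '%s' failed for subject %s (%s): %s",
                         stage, id, tp, conditionMessage(e)),
                 "mpmri_stage_error")
    })
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = id, group = g, timepoint = tp,
      parameter = names(vals), value = unname(vals),
      units = unit_of[names(vals)])
    logline("subject %s %s processed from files", id, tp)
  }
  cohort_table(do.call(rbind, rows))
}
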