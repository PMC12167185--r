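#' Spatial 3-D image grid
#'
#' The basic container for all image arithmetic: a 3-D scalar array in
#' native intensity units together with its voxel spacing and origin in mm.
#' Arrays are stored in NIfTI axis order `[x, y, z]`.
#'
#' @param data 3-D numeric array.
#' @param spacing length-3 positive numeric, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin length-3 numeric, position of the first voxel in mm.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  assert_that(length(dim(data)) == 3L, "`data` must be a 3-D array")
  assert_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
              "`spacing` must be 3 positive numbers (mm)")
  assert_that(is.numeric(origin) && length(origin) == 3L,
              "`origin` must be 3 numbers (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Multi-b-value, multi-repetition DWI stack
#'
#' Holds diffusion-weighted volumes acquired at several b-values with
#' repeated acquisitions per b-value, as a 5-D array `[x, y, z, rep, b]`.
#' The `excluded` flag array `[z, rep, b]` marks slice-repetitions dropped
#' by the signal-dropout rule; it starts all-`FALSE`.
#'
#' @param volumes 5-D numeric array `[x, y, z, repetition, b_index]`.
#' @param b_values numeric, strictly increasing b-values in s/mm2; the first
#'   must be below 50 s/mm2 (a b~0 anchor).
#' @param spacing voxel spacing in mm.
#' @param excluded optional logical array `[z, rep, b]`.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(volumes, b_values, spacing = c(1, 1, 1), excluded = NULL) {
  volumes <- as.array(volumes)
  assert_that(length(dim(volumes)) == 5L,
              "`volumes` must be 5-D [x, y, z, rep, b]")
  nb <- dim(volumes)[5]; nrep <- dim(volumes)[4]; nz <- dim(volumes)[3]
  assert_that(length(b_values) == nb,
              "length(b_values) must match the 5th dimension of `volumes`",
              class = "mpmri_layout_error")
  assert_that(all(diff(b_values) > 0) && all(b_values >= 0),
              "`b_values` must be non-negative and strictly increasing")
  assert_that(b_values[1] < 50,
              "need at least one b-value < 50 s/mm2 as a b~0 anchor")
  assert_that(nrep >= 1L, "need at least one repetition")
  if (is.null(excluded)) {
    excluded <- array(FALSE, dim = c(nz, nrep, nb))
  }
  assert_that(identical(dim(excluded), as.integer(c(nz, nrep, nb))),
              "`excluded` must have dim [z, rep, b]")
  assert_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
              "`spacing` must be 3 positive numbers (mm)")
  structure(list(volumes = volumes, b_values = as.numeric(b_values),
                 spacing = as.numeric(spacing), excluded = excluded),
            class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$volumes)
  cat("<dwi_stack> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " repetitions, b = {", paste(x$b_values, collapse = ", "),
      "} s/mm2; ", sum(x$excluded), " slice-repetitions excluded\n", sep = "")
  invisible(x)
}

#' Dynamic contrast-enhanced series
#'
#' A 4-D dynamic series `[x, y, z, t]` with strictly increasing frame times
#' in seconds since acquisition start.
#'
#' @param frames 4-D numeric array `[x, y, z, t]`.
#' @param times numeric, frame times in s, strictly increasing; >= 8 frames.
#' @param spacing voxel spacing in mm.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(frames, times, spacing = c(1, 1, 1)) {
  frames <- as.array(frames)
  assert_that(length(dim(frames)) == 4L, "`frames` must be 4-D [x, y, z, t]")
  assert_that(length(times) == dim(frames)[4],
              "length(times) must match the 4th dimension of `frames`",
              class = "mpmri_layout_error")
  assert_that(length(times) >= 8L, "a DCE series needs at least 8 frames")
  assert_that(all(diff(times) > 0), "`times` must be strictly increasing")
  assert_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
              "`spacing` must be 3 positive numbers (mm)")
  structure(list(frames = frames, times = as.numeric(times),
                 spacing = as.numeric(spacing)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$frames)
  cat("<dce_series> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " frames over ", signif(diff(range(x$times)), 4), " s\n", sep = "")
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param mask logical 3-D array with at least one `TRUE` voxel.
#' @param label ROI label, `"tumor"` or `"aorta"`.
#' @param spacing voxel spacing in mm (must match the companion image).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("tumor", "aorta"), spacing = c(1, 1, 1)) {
  label <- match.arg(label)
  mask <- as.array(mask)
  assert_that(length(dim(mask)) == 3L, "`mask` must be a 3-D array")
  storage.mode(mask) <- "logical"
  assert_that(!anyNA(mask), "`mask` must not contain NA")
  assert_that(any(mask), "ROI mask is empty", class = "mpmri_empty_roi_error")
  assert_that(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0),
              "`spacing` must be 3 positive numbers (mm)")
  structure(list(mask = mask, label = label, spacing = as.numeric(spacing)),
            class = "roi_mask")
}

#' ROI volume in mm3
#'
#' Volume of a region of interest as voxel count times voxel volume.
#'
#' @param mask an [roi_mask].
#' @return Volume in mm3.
#' @export
compute_roi_volume <- function(mask) {
  assert_that(inherits(mask, "roi_mask"), "`mask` must be an roi_mask")
  sum(mask$mask) * prod(mask$spacing)
}

# ---- cohort table ----------------------------------------------------------

cohort_columns <- c("subject_id", "group", "timepoint", "parameter",
                    "value", "units")

#' Long-format cohort table
#'
#' One row per (subject, timepoint, parameter) measurement; `group` is
#' `"therapy"` or `"control"`, `timepoint` is `"baseline"` or `"follow_up"`.
#' Missing measurements are `NA` values, never absent rows, so pairwise
#' deletion in the paired tests is explicit.
#'
#' @param df data.frame with columns subject_id, group, timepoint, parameter,
#'   value, units.
#' @return Validated data.frame of class `cohort_table`.
#' @export
cohort_table <- function(df) {
  assert_that(is.data.frame(df), "`df` must be a data.frame")
  missing_cols <- setdiff(cohort_columns, names(df))
  assert_that(length(missing_cols) == 0L,
              paste("missing columns:", paste(missing_cols, collapse = ", ")),
              class = "mpmri_integrity_error")
  df <- as.data.frame(df)[cohort_columns]
  df$subject_id <- as.character(df$subject_id)
  df$group <- as.character(df$group)
  df$timepoint <- as.character(df$timepoint)
  df$parameter <- as.character(df$parameter)
  df$value <- as.numeric(df$value)
  df$units <- as.character(df$units)
  assert_that(all(df$group %in% c("therapy", "control")),
              "group must be 'therapy' or 'control'",
              class = "mpmri_integrity_error")
  assert_that(all(df$timepoint %in% c("baseline", "follow_up")),
              "timepoint must be 'baseline' or 'follow_up'",
              class = "mpmri_integrity_error")
  key <- paste(df$subject_id, df$timepoint, df$parameter, sep = "\r")
  assert_that(!anyDuplicated(key),
              "duplicate (subject_id, timepoint, parameter) rows",
              class = "mpmri_integrity_error")
  assert_that(!any(is.infinite(df$value)),
              "values must be finite or NA", class = "mpmri_integrity_error")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' Rows are sorted by (subject_id, timepoint, parameter) for stable diffs;
#' missing values are written as empty fields.
#'
#' @param table a [cohort_table].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  table <- cohort_table(table)
  ord <- order(table$subject_id, table$timepoint, table$parameter)
  utils::write.csv(as.data.frame(table)[ord, , drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV written by [write_cohort_csv].
#' @return A [cohort_table]; empty value fields become `NA`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    subject_id = "character", group = "character", timepoint = "character",
    parameter = "character", value = "numeric", units = "character"),
    na.strings = "")
  df$units[is.na(df$units)] <- ""
  cohort_table(df)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a NIfTI-1 image as a typed container
#'
#' The file's axis meaning is never guessed from headers: the `layout`
#' argument declares whether the file is a plain 3-D volume, a mask, a DWI
#' stack or a DCE series, and how the 4th/5th dimensions are packed.
#'
#' For `layout = "dwi"` supply `b_values` and `n_repetitions`. A 5-D file
#' holds `[x, y, z, A, B]` where `(A, B)` is `(b, rep)` for
#' `packing = "b_then_rep"` or `(rep, b)` for `packing = "rep_then_b"`;
#' a 4-D file holds the same pairs flattened along the 4th axis with the
#' first of the pair varying fastest.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param layout one of "volume", "mask", "dwi", "dce".
#' @param b_values,n_repetitions,packing DWI layout declaration.
#' @param times frame times in s for `layout = "dce"`.
#' @param label mask label for `layout = "mask"`.
#' @return A [voxel_grid], [roi_mask], [dwi_stack] or [dce_series];
#'   spacing is taken from the NIfTI `pixdim`.
#' @export
read_nifti <- function(path, layout = c("volume", "mask", "dwi", "dce"),
                       b_values = NULL, n_repetitions = NULL,
                       packing = c("b_then_rep", "rep_then_b"),
                       times = NULL, label = "tumor") {
  layout <- match.arg(layout)
  packing <- match.arg(packing)
  assert_that(file.exists(path), paste("file not found:", path),
              class = "mpmri_format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_mpmri(
                    paste("malformed NIfTI file:", conditionMessage(e)),
                    "mpmri_format_error"))
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # strip header attributes
  spacing <- abs(RNifti::pixdim(img))[seq_len(min(3L, length(dim(arr))))]
  spacing <- c(spacing, rep(1, 3 - length(spacing)))
  nd <- length(dim(arr))

  if (layout == "volume" || layout == "mask") {
    if (nd == 4L && dim(arr)[4] == 1L) arr <- array(arr, dim(arr)[1:3])
    assert_that(length(dim(arr)) == 3L,
                sprintf("expected a 3-D volume, got %d dimensions", nd),
                class = "mpmri_layout_error")
    if (layout == "mask") return(roi_mask(arr > 0, label = label, spacing = spacing))
    return(voxel_grid(arr, spacing = spacing))
  }

  if (layout == "dce") {
    assert_that(nd == 4L, "a DCE series must be a 4-D file",
                class = "mpmri_layout_error")
    assert_that(!is.null(times), "`times` must be declared for layout 'dce'",
                class = "mpmri_layout_error")
    assert_that(length(times) == dim(arr)[4],
                sprintf("declared %d frame times but file has %d frames",
                        length(times), dim(arr)[4]),
                class = "mpmri_layout_error")
    return(dce_series(arr, times = times, spacing = spacing))
  }

  # layout == "dwi"
  assert_that(!is.null(b_values) && !is.null(n_repetitions),
              "`b_values` and `n_repetitions` must be declared for layout 'dwi'",
              class = "mpmri_layout_error")
  nb <- length(b_values); nrep <- as.integer(n_repetitions)
  if (nd == 4L) {
    assert_that(dim(arr)[4] == nb * nrep,
                sprintf("4th dimension (%d) != n_b x n_rep (%d x %d)",
                        dim(arr)[4], nb, nrep),
                class = "mpmri_layout_error")
    inner <- if (packing == "b_then_rep") c(nb, nrep) else c(nrep, nb)
    arr <- array(arr, dim = c(dim(arr)[1:3], inner))
    nd <- 5L
  }
  assert_that(nd == 5L, "a DWI stack must be a 4-D or 5-D file",
              class = "mpmri_layout_error")
  expected <- if (packing == "b_then_rep") c(nb, nrep) else c(nrep, nb)
  assert_that(all(dim(arr)[4:5] == expected),
              sprintf("file dims [%s] inconsistent with declared %d b-values x %d repetitions (%s)",
                      paste(dim(arr)[4:5], collapse = ","), nb, nrep, packing),
              class = "mpmri_layout_error")
  if (packing == "b_then_rep") arr <- aperm(arr, c(1, 2, 3, 5, 4))
  dwi_stack(arr, b_values = b_values, spacing = spacing)
}

#' Write an image container to NIfTI-1
#'
#' Data are written as float32 (the interchange precision for parameter
#' maps); masks are written as uint8. DWI stacks are written 5-D as
#' `[x, y, z, b, rep]` (`packing = "b_then_rep"`).
#'
#' @param x a [voxel_grid], [roi_mask], [dwi_stack] or [dce_series].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "voxel_grid")) {
    arr <- x$data; spacing <- x$spacing; dt <- "float"
  } else if (inherits(x, "roi_mask")) {
    arr <- array(as.integer(x$mask), dim(x$mask)); spacing <- x$spacing
    dt <- "uint8"
  } else if (inherits(x, "dwi_stack")) {
    arr <- aperm(x$volumes, c(1, 2, 3, 5, 4)); spacing <- x$spacing
    dt <- "float"
  } else if (inherits(x, "dce_series")) {
    arr <- x$frames; spacing <- x$spacing; dt <- "float"
  } else {
    stop_mpmri("unsupported object for write_nifti", "mpmri_param_error")
  }
  attr(arr, "pixdim") <- c(spacing, rep(1, length(dim(arr)) - 3L))
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
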