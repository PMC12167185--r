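#' Mann-Whitney U test (two-sided) for two independent samples
#'
#' Intergroup comparison used at each timepoint. Missing values are dropped
#' per sample. The exact null distribution (full enumeration over labelings)
#' is used when `min(n1, n2) <= exact_max_n` and the pooled data are
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. The reported statistic is
#' `U = min(U1, U2)`.
#'
#' @param x,y numeric samples (therapy / control).
#' @param exact_max_n exact-path threshold on the smaller sample size
#'   (default 8).
#' @return List of class `stat_result`: `test`, `statistic`, `p_value`,
#'   `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 8L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  assert_that(n1 >= 1L && n2 >= 1L, "both samples must be non-empty after deletion",
              class = "mpmri_input_error")
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && min(n1, n2) <= exact_max_n) {
    p <- min(1, 2 * stats::pwilcox(U, n1, n2))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    N <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      method <- "degenerate (all values tied)"
    } else {
      z <- (abs(U1 - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
      method <- "normal approximation, tie and continuity corrected"
    }
  }
  structure(list(test = "Mann-Whitney U", statistic = U, p_value = p,
                 n1 = n1, n2 = n2, method = method),
            class = "stat_result")
}

#' Wilcoxon signed-rank test (two-sided) for paired samples
#'
#' Intragroup baseline-vs-follow-up comparison after pairwise deletion:
#' pairs with either member missing are removed first, and `n_pairs`
#' reports the post-deletion count. Zero differences are dropped by default
#' (classic convention; `zero_method = "pratt"` keeps them in the ranking).
#' The exact null (enumeration over sign assignments) is used when the
#' post-deletion, post-zero-drop `n <= exact_max_n` and the absolute
#' differences are tie-free; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param before,after paired numeric vectors aligned by subject.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_max_n exact-path threshold (default 15).
#' @return List of class `stat_result` with `statistic` (W = smaller signed
#'   rank sum), `p_value`, `n_pairs`, `method`.
#' @export
wilcoxon_signed_rank <- function(before, after, zero_method = c("drop", "pratt"),
                                 exact_max_n = 15L) {
  zero_method <- match.arg(zero_method)
  assert_that(length(before) == length(after),
              "`before` and `after` must be aligned by subject",
              class = "mpmri_input_error")
  keep <- is.finite(before) & is.finite(after)
  n_pairs <- sum(keep)
  assert_that(n_pairs >= 1L, "no complete pairs after pairwise deletion",
              class = "mpmri_input_error")
  d <- after[keep] - before[keep]
  if (zero_method == "drop") {
    d_nz <- d[d != 0]
    n <- length(d_nz)
    if (n == 0L) {
      warn_mpmri("all differences are zero; p reported as 1",
                 "mpmri_degenerate_test_warning")
      return(structure(list(test = "Wilcoxon signed-rank", statistic = NA_real_,
                            p_value = 1, n_pairs = n_pairs,
                            method = "degenerate (all differences zero)"),
                       class = "stat_result"))
    }
    r <- rank(abs(d_nz))
    Wpos <- sum(r[d_nz > 0])
    Wneg <- sum(r[d_nz < 0])
    W <- min(Wpos, Wneg)
    ties <- anyDuplicated(abs(d_nz)) > 0L
    if (!ties && n <= exact_max_n) {
      p <- min(1, 2 * stats::psignrank(W, n))
      method <- "exact"
    } else {
      mu <- n * (n + 1) / 4
      tie_tab <- table(abs(d_nz))
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
      if (sigma2 <= 0) {
        p <- 1; method <- "degenerate (all ranks tied)"
      } else {
        z <- (abs(Wpos - mu) - 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(-max(z, 0)))
        method <- "normal approximation, tie and continuity corrected"
      }
    }
  } else {
    # Pratt: rank including zeros, drop the zero ranks from the sums
    n_all <- length(d)
    n0 <- sum(d == 0)
    if (n0 == n_all) {
      warn_mpmri("all differences are zero; p reported as 1",
                 "mpmri_degenerate_test_warning")
      return(structure(list(test = "Wilcoxon signed-rank", statistic = NA_real_,
                            p_value = 1, n_pairs = n_pairs,
                            method = "degenerate (all differences zero)"),
                       class = "stat_result"))
    }
    r <- rank(abs(d))
    Wpos <- sum(r[d > 0])
    mu <- (n_all * (n_all + 1) - n0 * (n0 + 1)) / 4
    tie_tab <- table(abs(d[d != 0]))
    sigma2 <- (n_all * (n_all + 1) * (2 * n_all + 1) -
                 n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    W <- Wpos
    if (sigma2 <= 0) {
      p <- 1; method <- "degenerate"
    } else {
      z <- (abs(Wpos - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
      method <- "normal approximation (Pratt zero handling)"
    }
  }
  structure(list(test = "Wilcoxon signed-rank", statistic = W, p_value = p,
                 n_pairs = n_pairs, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  ns <- if (!is.null(x$n_pairs)) paste0("n_pairs = ", x$n_pairs)
        else paste0("n1 = ", x$n1, ", n2 = ", x$n2)
  cat(sprintf("%s: statistic = %s, p = %.4g (%s; %s)\n", x$test,
              format(x$statistic), x$p_value, ns, x$method))
  invisible(x)
}

# Spearman rho and t-approximation p for one pairwise-complete pair
spearman_pair <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  n <- sum(keep)
  if (n < 3L) return(c(rho = NA_real_, p = NA_real_, n = n))
  a <- a[keep]; b <- b[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(a), rank(b))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Spearman correlation matrix across quantitative parameters
#'
#' Rank correlation (Pearson correlation of average ranks) between every
#' pair of parameters over the cohort's observations (one observation per
#' subject and timepoint), using pairwise-complete cases. p-values use the
#' t-distribution approximation with `n - 2` degrees of freedom; the
#' significance mask applies the study's alpha = 0.05 with no multiplicity
#' adjustment.
#'
#' @param table a [cohort_table].
#' @param parameters character vector of parameter names (default: all in
#'   the table).
#' @param alpha significance level for the mask (default 0.05).
#' @return List of class `correlation_matrix`: `parameters`, `rho`, `p`,
#'   `n`, `significant`.
#' @export
spearman_matrix <- function(table, parameters = NULL, alpha = 0.05) {
  table <- cohort_table(table)
  parameters <- parameters %||% sort(unique(table$parameter))
  obs_key <- unique(table[c("subject_id", "timepoint")])
  wide <- matrix(NA_real_, nrow(obs_key), length(parameters),
                 dimnames = list(NULL, parameters))
  for (j in seq_along(parameters)) {
    sub <- table[table$parameter == parameters[j], ]
    m <- match(paste(obs_key$subject_id, obs_key$timepoint),
               paste(sub$subject_id, sub$timepoint))
    wide[, j] <- sub$value[m]
  }
  k <- length(parameters)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(parameters, parameters))
  n <- matrix(0L, k, k, dimnames = list(parameters, parameters))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    n[i, i] <- sum(is.finite(wide[, i]))
    for (j in seq_len(k)) {
      if (j <= i) next
      res <- spearman_pair(wide[, i], wide[, j])
      rho[i, j] <- rho[j, i] <- res[["rho"]]
      p[i, j] <- p[j, i] <- res[["p"]]
      n[i, j] <- n[j, i] <- as.integer(res[["n"]])
    }
  }
  structure(list(parameters = parameters, rho = rho, p = p, n = n,
                 significant = !is.na(p) & p < alpha, alpha = alpha),
            class = "correlation_matrix")
}

#' Group summaries (mean +/- SD) per group, timepoint and parameter
#'
#' Sample standard deviation (n - 1 denominator); missing values are
#' excluded per cell with the remaining `n` reported. A single-observation
#' cell reports `NaN` SD.
#'
#' @param table a [cohort_table].
#' @return data.frame with columns group, timepoint, parameter, n, mean,
#'   sd, units.
#' @export
group_summary <- function(table) {
  table <- cohort_table(table)
  key <- interaction(table$group, table$timepoint, table$parameter, drop = TRUE)
  rows <- lapply(split(table, key), function(sub) {
    v <- sub$value[is.finite(sub$value)]
    data.frame(group = sub$group[1], timepoint = sub$timepoint[1],
               parameter = sub$parameter[1], n = length(v),
               mean = if (length(v)) mean(v) else NaN,
               sd = if (length(v) > 1) stats::sd(v) else NaN,
               units = sub$units[1])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$parameter, out$timepoint, out$group), ]
  rownames(out) <- NULL
  out
}

#' Render a correlation heatmap
#'
#' Circle-style correlation matrix: circle area and colour encode rho, a
#' cross marks non-significant pairs (p >= alpha, unadjusted).
#'
#' @param cm a `correlation_matrix` from [spearman_matrix].
#' @param path optional PNG output path; if `NULL`, draws on the active
#'   device.
#' @return `path`, invisibly.
#' @export
plot_correlation_matrix <- function(cm, path = NULL) {
  assert_that(inherits(cm, "correlation_matrix"),
              "`cm` must be a correlation_matrix")
  k <- length(cm$parameters)
  if (!is.null(path)) {
    grDevices::png(path, width = 150 * k + 200, height = 150 * k + 120,
                   res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(201)
  graphics::par(mar = c(1, 6, 6, 1))
  graphics::plot(NULL, xlim = c(0.5, k + 0.5), ylim = c(0.5, k + 0.5),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::axis(3, at = seq_len(k), labels = cm$parameters, las = 2,
                 tick = FALSE)
  graphics::axis(2, at = rev(seq_len(k)), labels = cm$parameters, las = 2,
                 tick = FALSE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      r <- cm$rho[i, j]
      if (is.na(r)) next
      col <- pal[round((r + 1) * 100) + 1]
      graphics::symbols(j, k + 1 - i, circles = 0.45 * sqrt(abs(r)),
                        inches = FALSE, add = TRUE, bg = col, fg = "grey40")
      if (i != j && isFALSE(cm$significant[i, j])) {
        graphics::points(j, k + 1 - i, pch = 4, cex = 1.4, col = "grey20")
      }
    }
  }
  invisible(path)
}
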