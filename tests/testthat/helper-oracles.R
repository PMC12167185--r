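# Independent brute-force oracles used across tests. These re-derive the
# quantities under test from first principles (enumeration, dense
# convolution, quadrature) and never call the implementation paths they
# check.

# Exact two-sided Mann-Whitney p by enumeration over all C(n1+n2, n1)
# labelings of the pooled sample (tie-free data): doubled exact lower tail
# of U = min(U1, U2), capped at 1.
bruteforce_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  u_min <- min(obs, n1 * n2 - obs)
  u1s <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  min(1, 2 * mean(u1s <= u_min))
}

# Exact two-sided Wilcoxon signed-rank p by enumeration over all 2^n sign
# assignments (tie-free |differences|).
bruteforce_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(pos) {
    wp <- sum(r[pos])
    min(wp, n * (n + 1) / 2 - wp)
  })
  # the min-statistic tail already aggregates both sides: no doubling
  mean(ws <= w_obs)
}

# Classic Spearman rho for tie-free data: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_formula <- function(a, b) {
  n <- length(a)
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Dense direct 3-D convolution with the analytic separable Gaussian kernel
# (no separable shortcut), reflective boundary, for small arrays.
dense_gaussian_conv <- function(x, sigma_vox) {
  d <- dim(x)
  r <- ceiling(3 * sigma_vox)
  ks <- lapply(1:3, function(a) {
    k <- exp(-(seq(-r[a], r[a]))^2 / (2 * sigma_vox[a]^2))
    k / sum(k)
  })
  reflect <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- array(0, d)
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) for (iz in seq_len(d[3])) {
    acc <- 0
    for (ox in -r[1]:r[1]) for (oy in -r[2]:r[2]) for (oz in -r[3]:r[3]) {
      acc <- acc + ks[[1]][ox + r[1] + 1] * ks[[2]][oy + r[2] + 1] *
        ks[[3]][oz + r[3] + 1] *
        x[reflect(ix + ox, d[1]), reflect(iy + oy, d[2]), reflect(iz + oz, d[3])]
    }
    out[ix, iy, iz] <- acc
  }
  out
}

# Analytic mean of the Rician distribution: E[S] = sigma sqrt(pi/2)
# L_{1/2}(-nu^2 / (2 sigma^2)), via the Laguerre half-order identity
# L_{1/2}(x) = exp(x/2) ((1 - x) I0(-x/2) - x I1(-x/2)).
rician_mean <- function(nu, sigma) {
  y <- nu^2 / (4 * sigma^2)
  # exp(-y) cancelled against exponentially scaled Bessel functions
  l_half <- (1 + 2 * y) * besselI(y, 0, expon.scaled = TRUE) +
    2 * y * besselI(y, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l_half
}

# Brute-force re-statement of the dropout rule, computed independently per
# (z, b) from per-repetition foreground means.
bruteforce_dropout <- function(m_r, frac = 2 / 3) {
  n_top <- ceiling(length(m_r) / 2)
  bright <- mean(sort(m_r, decreasing = TRUE)[seq_len(n_top)])
  m_r < frac * bright
}

# a smooth random test image (band-limited so interpolation-based checks
# are meaningful)
smooth_random_image <- function(dim3, seed, width = 2, spacing = c(1, 1, 1)) {
  set.seed(seed)
  g <- mpmri::voxel_grid(array(stats::rnorm(prod(dim3)), dim3),
                         spacing = spacing)
  mpmri::gaussian_smooth(g, width)$data
}
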