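# small grids and models shared across tests
tiny_grid <- function(half_extent = 8, spacing = 0.1, n_feature = 8)
  spatial_grid(spacing = spacing, half_extent = half_extent,
               n_feature = n_feature, sup_space_width = 1)

# brute-force O(N^2) separable convolution oracle for pooled_drive:
# zero-padded over space, wrapped over the feature axis
oracle_pool <- function(drive, space_width, feature_width) {
  grid <- drive$grid
  pos <- grid$positions
  n <- length(pos)
  ks <- dnorm(seq(-ceiling(5 * space_width / grid$spacing),
                  ceiling(5 * space_width / grid$spacing)) * grid$spacing,
              sd = space_width)
  ks <- ks / sum(ks)
  off <- seq_along(ks) - (length(ks) + 1) / 2
  out_s <- matrix(0, n, ncol(drive$values))
  for (i in seq_len(n)) for (m in seq_along(ks)) {
    j <- i - off[m]
    if (j >= 1 && j <= n)
      out_s[i, ] <- out_s[i, ] + ks[m] * drive$values[j, ]
  }
  nf <- length(grid$features)
  kf <- numeric(nf)
  centers <- (seq_len(nf) - 1) * grid$feature_spacing
  for (wr in -5:5)
    kf <- kf + dnorm(centers + wr * nf * grid$feature_spacing,
                     sd = feature_width)
  kf <- kf / sum(kf)
  out <- matrix(0, n, nf)
  for (j in seq_len(nf)) for (m in seq_len(nf)) {
    src <- ((j - 1) - (m - 1)) %% nf + 1
    out[, j] <- out[, j] + kf[m] * out_s[, src]
  }
  out
}

# deterministic simulated observer for staircase tests
flat_observer <- function(alpha, beta = 3)
  function(duration, condition) weibull_p_correct(duration, alpha, beta)
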