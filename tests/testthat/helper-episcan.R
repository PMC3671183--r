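# Shared fixtures and independent oracles for the test suite.

# Small flat-lamina continuous model; intensities per the two layers.
flat_model <- function(intensities = c(0.8, 0.8), boundary = 0.6,
                       height = 160L, width = 64L, baseline = 120,
                       noise_sd = 0, blob_density = 0, seed = 1L, ...) {
  epithelium_model(
    image_height_px = height, image_width_px = width,
    lamina_baseline_px = baseline, lamina_amplitude_px = 0,
    lamina_wavelength_px = 100,
    layer_boundaries = boundary,
    probe_profiles = list(probeA = intensities),
    background_level = 0.1, noise_sd = noise_sd,
    blob_density_per_um2 = blob_density, seed = seed, ...)
}

# Normalized synthetic profile on [0,1] from a function with max 1.
profile_from_fun <- function(f, n = 101L, meta = list(probe = "p")) {
  x <- seq(0, 1, length.out = n)
  intensity_profile(x, f(x), normalized = TRUE, meta = meta)
}

# Brute-force two-sample KS statistic: enumerate every pooled threshold and
# count, no sorting shortcuts. Independent of the package's implementation.
brute_ks_D <- function(a, b) {
  D <- 0
  for (v in c(a, b)) {
    d <- abs(sum(a <= v) / length(a) - sum(b <= v) / length(b))
    if (d > D) D <- d
  }
  D
}

# Direct sums-of-squares one-way ANOVA F (textbook formula).
direct_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); N <- length(values)
  means <- tapply(values, groups, mean)
  n_i <- table(groups)
  ssb <- sum(n_i * (means - mean(values))^2)
  ssw <- sum((values - means[groups])^2)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Permutation max-|q| reference for Tukey adjusted p-values: for each
# permutation of the pooled observations compute every pairwise studentized
# q and record the maximum; the adjusted p of an observed pair is the
# fraction of permutations whose max-q reaches its observed q. Exploits that
# the total sum of squares is permutation-invariant, so
# MS_within = (TSS - SS_between) / (N - k).
# Returns adjusted p per pair in utils::combn(levels, 2) order.
perm_tukey_ref <- function(values, groups, n_perm = 1e5L) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  n_i <- as.vector(table(groups)[lev])
  idx <- split(seq_along(values), groups)[lev]
  N <- length(values)
  grand <- mean(values)
  tss <- sum((values - grand)^2)
  combos <- utils::combn(k, 2)

  q_pairs <- function(means_mat, msw) {
    # means_mat: n x k matrix, msw: n vector -> n x npairs matrix of q
    sapply(seq_len(ncol(combos)), function(j) {
      i1 <- combos[1, j]; i2 <- combos[2, j]
      se <- sqrt(msw / 2 * (1 / n_i[i1] + 1 / n_i[i2]))
      abs(means_mat[, i1] - means_mat[, i2]) / se
    })
  }
  obs_means <- matrix(vapply(idx, function(ii) mean(values[ii]), numeric(1)),
                      nrow = 1)
  obs_ssb <- sum(n_i * (obs_means - grand)^2)
  q_obs <- q_pairs(obs_means, (tss - obs_ssb) / (N - k))

  perm <- t(vapply(seq_len(n_perm), function(i) sample(values), numeric(N)))
  means_mat <- sapply(idx, function(ii) rowMeans(perm[, ii, drop = FALSE]))
  ssb <- as.vector((means_mat - grand)^2 %*% n_i)
  msw <- (tss - ssb) / (N - k)
  maxq <- apply(q_pairs(means_mat, msw), 1, max)
  vapply(as.vector(q_obs), function(q) mean(maxq >= q), numeric(1))
}
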