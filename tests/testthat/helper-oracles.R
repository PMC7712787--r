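# Independent exhaustive-enumeration oracles and small fixture builders.
# The oracles deliberately use plain voxel/pair loops, not the package's
# vectorized code paths.

brute_voi_voxels <- function(volume, voi) {
  d <- dim(volume$values); sp <- volume$spacing
  hits <- matrix(0L, 0L, 3L)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    u2 <- ((i - voi$center[1]) * sp[1] / voi$radii[1])^2 +
      ((j - voi$center[2]) * sp[2] / voi$radii[2])^2 +
      ((k - voi$center[3]) * sp[3] / voi$radii[3])^2
    if (u2 <= 1) hits <- rbind(hits, c(i, j, k))
  }
  hits
}

brute_suv_max <- function(volume, voi) {
  hits <- brute_voi_voxels(volume, voi)
  max(volume$values[hits])
}

brute_mtv <- function(volume, voi, threshold = 2.5) {
  hits <- brute_voi_voxels(volume, voi)
  v <- volume$values[hits]
  sum(v >= threshold) * prod(volume$spacing) / 1000
}

brute_tlg <- function(volume, voi, threshold = 2.5) {
  hits <- brute_voi_voxels(volume, voi)
  v <- volume$values[hits]
  q <- v[v >= threshold]
  if (length(q) == 0L) return(0)
  length(q) * prod(volume$spacing) / 1000 * mean(q)
}

brute_roi_mean <- function(adc, roi) {
  d <- dim(adc$values); sp <- adc$spacing
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (((i - roi$center[1]) * sp[1])^2 + ((j - roi$center[2]) * sp[2])^2 <= roi$radius^2) {
      v <- adc$values[i, j, roi$slice_index]
      if (!is.na(v)) vals <- c(vals, v)
    }
  }
  mean(vals)
}

# AUC as the fraction of (positive, negative) pairs correctly ordered, ties 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive two-sided Mann-Whitney p-value from pairwise-comparison U
# statistics over all group assignments
brute_mw_p <- function(x, y) {
  pooled <- c(x, y); m <- length(x); N <- length(pooled)
  u_of <- function(xs, ys) {
    tot <- 0
    for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
    tot
  }
  mu <- m * (N - m) / 2
  dev_obs <- abs(u_of(x, y) - mu)
  sets <- utils::combn(N, m)
  devs <- apply(sets, 2L, function(ix) abs(u_of(pooled[ix], pooled[-ix]) - mu))
  mean(devs >= dev_obs - 1e-9)
}

random_suv_volume <- function(dims, spacing = c(2, 2, 2)) {
  voxel_volume(array(runif(prod(dims), 0, 6), dim = dims), spacing, "SUV")
}

# a small VOI guaranteed to intersect the grid interior
random_voi <- function(dims, spacing = c(2, 2, 2)) {
  center <- vapply(dims, function(d) sample(2:(d - 1), 1L), integer(1))
  ellipsoid_voi(center, runif(3, 1.5, 6) * spacing)
}

# synthetic 64x64 crops with a purely morphological class signal:
# responders carry a large bright disk, non-responders a small one
separable_crops <- function(n_per_class, modality = "PET0") {
  idx <- seq_len(64) - 32.5
  r2 <- outer(idx^2, idx^2, "+")
  crops <- list()
  for (i in seq_len(2 * n_per_class)) {
    responder <- i <= n_per_class
    disk <- (r2 <= if (responder) 20^2 else 8^2) * 1.0
    crops[[i]] <- lesion_crop(disk, sprintf("S%03d", i), modality, responder)
  }
  crops
}

# tiny noiseless cohort shared across tests
tiny_cohort <- function(n_resp = 3, n_non = 5, seed = 42, noise = 0,
                        grid = c(24L, 24L, 24L), radii = c(5, 8), ...) {
  generate_cohort(cohort_config(
    n_responders = n_resp, n_nonresponders = n_non,
    grid_shape = grid, voxel_spacing = c(2, 2, 2),
    tumor_radius_range = radii, noise_sigma = noise, seed = seed, ...))
}
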