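# Shared fixtures and independent oracles used across test files.

# small, quick phantom configuration
small_config <- function(n_nuclei = 40, seed = 3, ...) {
  phantom_config(volume_shape = c(32, 64, 64), n_nuclei = n_nuclei,
                 marker_channels = FALSE, seed = seed, ...)
}

# brute-force minimum-distance oracle: plain double loop in R
brute_min_dist <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    min(sqrt(colSums((t(ref) - query[i, ])^2)))
  }, numeric(1))
}

# direct-summation hypergeometric upper-tail oracle
hyper_oracle <- function(N, K, n, k) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# rasterize a tube polyline into a tracheal_map (test geometry helper)
tube_map <- function(points_um, shape = c(40, 120, 120),
                     voxel_size = c(1, 0.5, 0.5), radius_um = 1.0) {
  idx <- rasterize_tube(points_um, shape, voxel_size, radius_um)
  coords <- cbind(((idx - 1) %% shape[1]) * voxel_size[1],
                  (((idx - 1) %/% shape[1]) %% shape[2]) * voxel_size[2],
                  (((idx - 1) %/% (shape[1] * shape[2]))) * voxel_size[3])
  tracheal_map(coords, voxel_size, shape, voxel_idx = idx)
}

# match detected centroids to ground-truth nuclei by nearest centre
match_detections <- function(detected, truth, tol_um = 2.2) {
  d <- vapply(seq_len(nrow(detected)), function(i) {
    p <- c(detected$z_um[i], detected$y_um[i], detected$x_um[i])
    dd <- sqrt((truth$z_um - p[1])^2 + (truth$y_um - p[2])^2 +
                 (truth$x_um - p[3])^2)
    j <- which.min(dd)
    c(j, dd[j])
  }, numeric(2))
  list(nearest = d[1, ], dist = d[2, ],
       tp = length(unique(d[1, d[2, ] < tol_um])),
       n_matched = sum(d[2, ] < tol_um))
}
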