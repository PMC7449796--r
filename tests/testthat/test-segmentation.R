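test_that("well-separated noiseless spheres are segmented exactly", {
  cfg <- phantom_config(volume_shape = c(32, 80, 80), n_nuclei = 10,
                        noise_cv = 0, read_noise_sd = 0, background = 0,
                        marker_channels = FALSE, seed = 7)
  ph <- generate_phantom(cfg)
  seg <- segment_nuclei(ph$stack)
  expect_equal(seg$labels$n_labels, 10)
  m <- match_detections(seg$nuclei, ph$truth$nuclei)
  expect_equal(m$tp, 10)
  # centroids within one voxel of the truth
  expect_lt(max(m$dist), max(ph$stack$voxel_size))
})

test_that("a blank channel yields zero nuclei with a warning", {
  st <- image_stack(array(0, c(1, 8, 16, 16)), c(1, 0.5, 0.5), "rfp")
  expect_warning(seg <- segment_nuclei(st, "rfp"), "empty|threshold")
  expect_equal(seg$labels$n_labels, 0)
  expect_equal(nrow(seg$nuclei), 0)
})

test_that("touching nuclei split under watershed and merge without it", {
  sh <- c(32, 64, 64); vs <- c(1, 0.5, 0.5); r <- 3
  c1 <- c(16, 16, 16); c2 <- c1 + c(0, 1.8 * r, 0)  # 20% radius overlap
  arr <- array(0, sh)
  for (ctr in list(c1, c2)) {
    sv <- hypoxiamap:::sphere_voxels(ctr, r, sh, vs)
    arr[sv$idx] <- pmax(arr[sv$idx], exp(-sv$d^2 / (2 * (r / 2)^2)))
  }
  st <- image_stack(array(arr, c(1, sh)), vs, "rfp")
  off <- segment_nuclei(st, "rfp", background_radius = 0,
                        split_touching = FALSE)
  on <- segment_nuclei(st, "rfp", background_radius = 0,
                       split_touching = TRUE)
  expect_equal(off$labels$n_labels, 1)
  expect_equal(on$labels$n_labels, 2)
})

test_that("segmentation meets the separable-phantom benchmark", {
  cfg <- phantom_config(volume_shape = c(64, 160, 160), n_nuclei = 200,
                        noise_cv = 0.1, marker_channels = FALSE, seed = 42)
  ph <- generate_phantom(cfg)
  seg <- segment_nuclei(ph$stack)
  m <- match_detections(seg$nuclei, ph$truth$nuclei)
  precision <- m$n_matched / nrow(seg$nuclei)
  recall <- m$tp / nrow(ph$truth$nuclei)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("extracted tracheal map contains the tube and nothing far from it", {
  cfg <- small_config(noise_cv = 0, read_noise_sd = 0, background = 0,
                      seed = 13)
  ph <- generate_phantom(cfg)
  tm <- extract_tracheal_map(ph$stack)
  truth <- ph$truth$trachea
  # every true tube voxel is recovered
  got <- paste(round(tm$coords_um[, 1], 3), round(tm$coords_um[, 2], 3),
               round(tm$coords_um[, 3], 3))
  want <- paste(round(truth$coords_um[, 1], 3), round(truth$coords_um[, 2], 3),
                round(truth$coords_um[, 3], 3))
  expect_true(all(want %in% got))
  # and nothing farther than 2 voxels from the true tube
  d <- brute_min_dist(tm$coords_um, truth$coords_um)
  expect_lte(max(d), 2 * max(cfg$voxel_size))
})

test_that("blank and below-threshold tracheal channels give empty maps", {
  st <- image_stack(array(0, c(1, 8, 16, 16)), c(1, 0.5, 0.5), "trachea")
  expect_warning(tm <- extract_tracheal_map(st), "empty")
  expect_equal(nrow(tm$coords_um), 0)
  set.seed(1)
  noise <- array(abs(rnorm(8 * 16 * 16, 0, 0.01)), c(1, 8, 16, 16))
  st2 <- image_stack(noise, c(1, 0.5, 0.5), "trachea")
  expect_warning(tm2 <- extract_tracheal_map(st2, threshold = 0.5), "empty")
  expect_equal(nrow(tm2$coords_um), 0)
})

test_that("skeleton length recovers analytic tube lengths", {
  # straight 50 um tube: within 2 voxels
  tm <- tube_map(rbind(c(20, 5, 30), c(20, 55, 30)))
  expect_lte(abs(skeleton_total_length(tm) - 50), 2)
  # L-shape of two 30 um arms: within 3 voxels
  tmL <- tube_map(rbind(c(20, 5, 20), c(20, 35, 20), c(20, 35, 50)))
  expect_lt(abs(skeleton_total_length(tmL) - 60), 3)
  # empty map
  empty <- tracheal_map(matrix(numeric(0), 0, 3), c(1, 0.5, 0.5),
                        c(8, 8, 8))
  expect_equal(skeleton_total_length(empty), 0)
})

test_that("an roi mask restricts the skeleton length to the region", {
  tm <- tube_map(rbind(c(20, 5, 30), c(20, 55, 30)))
  roi <- array(FALSE, c(40, 120, 120))
  roi[, 1:60, ] <- TRUE  # y < 30 um: covers half of the 5..55 um tube
  half <- skeleton_total_length(tm, roi_mask = roi)
  expect_lt(abs(half - 25), 3)
})

test_that("tracheolation index is length over volume", {
  expect_equal(tracheolation_index(100, 1000), 0.1)
  expect_equal(tracheolation_index(0, 1000), 0)
  expect_error(tracheolation_index(10, 0), "volume")
  # late-larval optic lobe: 684.3 um of tracheoles in 2271840.1 um^3
  idx <- tracheolation_index(684.3, 2271840.1)
  expect_equal(idx, 684.3 / 2271840.1, tolerance = 1e-12)
  expect_equal(signif(idx, 3), 3.01e-4)
})
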