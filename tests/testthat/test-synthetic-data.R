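test_that("config validation rejects inconsistent phantom parameters", {
  expect_error(phantom_config(tracheal_density_cb = 1.5), "densities")
  expect_error(phantom_config(n_nuclei = -1), "n_nuclei")
  expect_error(phantom_config(voxel_size = c(1, 0, 0.5)), "positive")
  expect_error(phantom_config(celltype_proportions = c(neuroblast = 0.5,
                                                       neuron = 0.4)),
               "sum to 1")
})

test_that("oxygenation model evaluates the decaying exponential", {
  m <- decay_params(A = 0.9, y0 = 0.55, lambda_um = 51.8, x0_um = 5)
  expect_equal(true_inverse_ratio(5, m), 0.55 + 0.9)
  # one decay constant past x0 the exponential term is at 1/e (~37%)
  expect_equal(true_inverse_ratio(5 + 51.8, m), 0.55 + 0.9 * exp(-1))
  expect_equal(round(100 * exp(-1)), 37)
  expect_equal(true_inverse_ratio(5 + 50 * 51.8, m), 0.55, tolerance = 1e-9)
  expect_error(true_inverse_ratio(1, decay_params(1, 0, -2)), "lambda")
  # strictly decreasing for positive amplitude
  d <- seq(0, 120, by = 1)
  expect_true(all(diff(true_inverse_ratio(d, m)) < 0))
})

test_that("tracheal tree respects per-compartment density targets", {
  cfg <- phantom_config(volume_shape = c(48, 96, 96), seed = 11)
  tr <- generate_tracheal_tree(cfg)
  sh <- cfg$volume_shape
  xs <- round(tr$coords_um[, 3] / cfg$voxel_size[3])
  split_idx <- cfg$compartment_split * sh[3]
  n_cb <- sum(xs < split_idx)
  n_ol <- nrow(tr$coords_um) - n_cb
  half <- prod(sh) / 2
  expect_lt(abs(n_cb / half - cfg$tracheal_density_cb),
            0.3 * cfg$tracheal_density_cb)
  expect_lt(abs(n_ol / half - cfg$tracheal_density_ol),
            0.3 * cfg$tracheal_density_ol)
  # dense central brain vs sparse optic lobe: >= 10x voxel fraction
  expect_gt(n_cb / n_ol, 10)
  # analytic skeleton bookkeeping is self-consistent
  expect_equal(tr$total_length_um,
               sum(tr$length_by_compartment), tolerance = 1e-9)
})

test_that("zero density targets give an empty map and impossible ones error", {
  cfg <- phantom_config(tracheal_density_cb = 0, tracheal_density_ol = 0)
  tr <- generate_tracheal_tree(cfg)
  expect_equal(nrow(tr$coords_um), 0)
  expect_equal(tr$total_length_um, 0)
  cfg2 <- phantom_config(tracheal_density_cb = 0.9)
  expect_error(generate_tracheal_tree(cfg2), "unreachable.*central_brain")
})

test_that("straight tube rasterization has exact analytic length", {
  sh <- c(40, 120, 120); vs <- c(1, 0.5, 0.5)
  pl <- rbind(c(20, 5, 30), c(20, 55, 30))
  tm <- tracheal_map(matrix(numeric(0), 0, 3), vs, sh,
                     skeleton = list(pl))
  expect_equal(tm$total_length_um, 50)
})

test_that("nucleus placement produces valid, separable ground truth", {
  cfg <- small_config(seed = 5)
  tr <- generate_tracheal_tree(cfg)
  nuc <- place_nuclei(cfg, tr)
  expect_equal(nrow(nuc), cfg$n_nuclei)
  extent <- cfg$volume_shape * cfg$voxel_size
  expect_true(all(nuc$z_um > 0 & nuc$z_um < extent[1]))
  expect_true(all(nuc$true_ratio > 0))
  # pairwise non-overlap with the configured gap
  ctr <- as.matrix(nuc[, c("z_um", "y_um", "x_um")])
  dm <- as.matrix(stats::dist(ctr))
  diag(dm) <- Inf
  gaps <- dm - outer(nuc$radius_um, nuc$radius_um, "+")
  expect_gte(min(gaps), cfg$min_gap_um - 1e-9)
  # distances equal brute force over tracheal voxels
  expect_equal(nuc$dist_um, brute_min_dist(ctr, tr$coords_um),
               tolerance = 1e-12)
  expect_equal(nrow(place_nuclei(small_config(n_nuclei = 0), tr)), 0)
})

test_that("noiseless distance-model ratios obey the exact identity", {
  cfg <- small_config(noise_cv = 0, seed = 8)
  tr <- generate_tracheal_tree(cfg)
  nuc <- place_nuclei(cfg, tr)
  expect_equal(nuc$true_ratio,
               1 / true_inverse_ratio(nuc$dist_um, cfg$ratio_model),
               tolerance = 1e-12)
})

test_that("per-type configured means are recovered in large samples", {
  cfg <- phantom_config(volume_shape = c(96, 224, 224), n_nuclei = 2000,
                        celltype_ratio_means = celltype_reference_means(),
                        ratio_sd = 0.15, marker_channels = FALSE, seed = 9)
  tr <- generate_tracheal_tree(cfg)
  nuc <- place_nuclei(cfg, tr)
  ref <- celltype_reference_means()
  for (i in seq_len(nrow(ref))) {
    sel <- nuc$cell_type == ref$cell_type[i] &
      nuc$compartment == ref$compartment[i]
    if (sum(sel) < 30) next
    tol <- 3 * 0.15 / sqrt(sum(sel))
    expect_lt(abs(mean(nuc$true_ratio[sel]) - ref$mean_ratio[i]), tol)
  }
})

test_that("rendered channels encode the true ratio by construction", {
  cfg <- phantom_config(volume_shape = c(24, 48, 48), n_nuclei = 1,
                        noise_cv = 0, read_noise_sd = 0, background = 0,
                        celltype_ratio_means = compartment_ratio_means(2, 2),
                        ratio_sd = 0, seed = 4)
  ph <- generate_phantom(cfg)
  lab <- ground_truth_labels(ph)
  idx <- which(lab$labels > 0)
  gfp <- get_channel(ph$stack, "gfp")[idx]
  rfp <- get_channel(ph$stack, "rfp")[idx]
  expect_equal(mean(gfp) / mean(rfp), 2.0, tolerance = 1e-6)
})

test_that("marker channels light only their own cell type", {
  cfg <- phantom_config(volume_shape = c(32, 64, 64), n_nuclei = 30,
                        read_noise_sd = 0, background = 0, seed = 6,
                        marker_channels = TRUE)
  ph <- generate_phantom(cfg)
  lab <- ground_truth_labels(ph)
  truth <- ph$truth$nuclei
  mk <- get_channel(ph$stack, "marker_neuroblast")
  lit <- unique(lab$labels[mk > 0.5 & lab$labels > 0])
  nb_ids <- truth$id[truth$cell_type == "neuroblast"]
  expect_setequal(lit, nb_ids)
  # no marker signal outside nuclei
  expect_equal(sum(mk[lab$labels == 0]), 0)
})

test_that("identical config and seed give bit-identical phantoms", {
  cfg <- small_config(seed = 12)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$stack$data, p2$stack$data)
  expect_identical(p1$truth$nuclei, p2$truth$nuclei)
})

test_that("condition presets order mean ratios hyperoxia < normoxia < hypoxia", {
  for (cc in c("central_brain", "optic_lobe")) {
    m_nor <- condition_preset("normoxia")$compartment_means[[cc]]
    m_hyp <- condition_preset("hyperoxia")$compartment_means[[cc]]
    m_hpo <- condition_preset("hypoxia")$compartment_means[[cc]]
    expect_lt(m_hyp, m_nor)
    expect_gt(m_hpo, m_nor)
  }
  # same ordering holds for the distance models at any distance
  d <- c(0, 25, 80)
  r <- function(cond) 1 / true_inverse_ratio(d, condition_preset(cond)$ratio_model)
  expect_true(all(r("hyperoxia") < r("normoxia")))
  expect_true(all(r("hypoxia") > r("normoxia")))
})
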