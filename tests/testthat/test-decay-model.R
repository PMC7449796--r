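test_that("noiseless model data are recovered essentially exactly", {
  m <- decay_params(A = 0.9, y0 = 0.55, lambda_um = 51.8, x0_um = 0)
  d <- simulate_decay_data(400, m, c(0, 150), noise_cv = 0, seed = 1)
  f <- fit_decay(d$dist_um, d$inv_ratio, x0_policy = 0)
  expect_true(f$converged)
  expect_equal(f$params$A, 0.9, tolerance = 1e-6)
  expect_equal(f$params$y0, 0.55, tolerance = 1e-6)
  expect_equal(f$params$lambda_um, 51.8, tolerance = 1e-6)
})

test_that("constant oxygenation flags the decay constant unidentifiable", {
  set.seed(2)
  f <- fit_decay(runif(50, 0, 100), rep(0.7, 50))
  expect_true(f$converged)
  expect_lt(f$params$A, 1e-6)
  expect_equal(f$params$y0, 0.7, tolerance = 1e-6)
  expect_false(f$lambda_identifiable)
})

test_that("noisy decay data recover lambda within five percent", {
  m <- condition_preset("normoxia")$ratio_model
  d <- simulate_decay_data(5000, m, c(0, 150), noise_cv = 0.08,
                           noise = "gaussian", seed = 42)
  f <- fit_decay(d$dist_um, d$inv_ratio)
  expect_lt(abs(f$params$lambda_um / m$lambda_um - 1), 0.05)
})

test_that("lambda recovery is accurate and unbiased over replicates", {
  m <- condition_preset("normoxia")$ratio_model
  set.seed(10)
  lam <- replicate(50, {
    d <- simulate_decay_data(3000, m, c(0, 150), noise_cv = 0.10,
                             noise = "lognormal")
    fit_decay(d$dist_um, d$inv_ratio)$params$lambda_um
  })
  rel_err <- abs(lam / m$lambda_um - 1)
  expect_lt(median(rel_err), 0.05)
  expect_lt(abs(mean(lam) / m$lambda_um - 1), 0.03)
})

test_that("least-squares and orthogonal fits agree without x-noise", {
  m <- condition_preset("normoxia")$ratio_model
  d <- simulate_decay_data(2000, m, c(0, 150), noise_cv = 0.05, seed = 1)
  f1 <- fit_decay(d$dist_um, d$inv_ratio, method = "least_squares")
  f2 <- fit_decay(d$dist_um, d$inv_ratio, method = "odr")
  expect_lt(abs(f2$params$A / f1$params$A - 1), 0.02)
  expect_lt(abs(f2$params$y0 / f1$params$y0 - 1), 0.02)
  expect_lt(abs(f2$params$lambda_um / f1$params$lambda_um - 1), 0.02)
})

test_that("hyperoxia-like data refit with a slower decay than normoxia", {
  nor <- condition_preset("normoxia")$ratio_model
  hyp <- condition_preset("hyperoxia")$ratio_model
  d_n <- simulate_decay_data(4000, nor, c(0, 150), 0.08, seed = 31)
  d_h <- simulate_decay_data(4000, hyp, c(0, 150), 0.08, seed = 32)
  l_n <- fit_decay(d_n$dist_um, d_n$inv_ratio)$params$lambda_um
  l_h <- fit_decay(d_h$dist_um, d_h$inv_ratio)$params$lambda_um
  expect_gt(l_h, l_n)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_decay(1:5, rep(1, 5)), "at least 10")
  expect_error(fit_decay(1:20, c(rep(1, 19), -0.1)), "> 0")
})

test_that("curve averaging is exact for analytic cases", {
  m1 <- decay_params(0.9, 0.5, 50, 0)
  m2 <- decay_params(0.9, 0.7, 50, 0)
  mk <- function(p) hypoxiamap:::new_decay_fit(
    p, se = c(A = 0, y0 = 0, lambda = 0), residual_rms = 0, n = 100,
    method = "least_squares", converged = TRUE)
  # identical fits average to themselves
  av1 <- average_fit(list(mk(m1), mk(m1)))
  expect_equal(av1$mean_inv_ratio,
               true_inverse_ratio(av1$distance_grid, m1), tolerance = 1e-9)
  # fits differing only in y0 average the offset
  av <- average_fit(list(mk(m1), mk(m2)))
  expect_equal(av$params$y0, 0.6, tolerance = 1e-6)
  expect_equal(av$params$A, 0.9, tolerance = 1e-6)
  expect_error(average_fit(list()), "no fits")
  bad <- mk(m1); bad$converged <- FALSE
  expect_error(average_fit(list(bad)), "converged")
})

test_that("ratio prediction inverts the model and is monotone", {
  m <- decay_params(0.9, 0.55, 51.8, 0)
  f <- hypoxiamap:::new_decay_fit(m, c(A = 0, y0 = 0, lambda = 0), 0, 100,
                                  "least_squares", TRUE)
  expect_equal(predict_ratio(f, 0), 1 / (0.55 + 0.9))
  # remaining exponential fraction one decay constant out: 37%
  frac <- (true_inverse_ratio(51.8, m) - m$y0) /
    (true_inverse_ratio(0, m) - m$y0)
  expect_equal(round(100 * frac), 37)
  d <- seq(0, 140, by = 0.5)
  expect_true(all(diff(predict_ratio(f, d)) > 0))
  f$converged <- FALSE
  expect_error(predict_ratio(f, 10), "non-converged")
})

test_that("prediction maps paint each nucleus with its predicted ratio", {
  # hemisphere-like geometry: tracheoles confined to one end so nucleus
  # distances span the full decay range (~0-130 um)
  cfg <- phantom_config(volume_shape = c(96, 320, 320), n_nuclei = 400,
                        compartment_split = 0.3,
                        tracheal_density_cb = 0.006,
                        tracheal_density_ol = 0,
                        marker_channels = FALSE, seed = 23)
  ph <- generate_phantom(cfg)
  labs <- ground_truth_labels(ph)
  tab <- ph$truth$nuclei
  tab$inv_ratio <- 1 / tab$true_ratio
  f <- fit_decay(tab$dist_um, tab$inv_ratio)
  pm <- render_prediction_map(f, labs, tab, cfg$voxel_size)
  vol <- get_channel(pm, 1)
  # per-label map values equal predict_ratio exactly
  for (id in c(1, 150, 400)) {
    vox <- vol[labs$labels == id]
    expect_equal(unique(vox), predict_ratio(f, tab$dist_um[tab$id == id]))
  }
  # voxelwise correlation with the true-ratio map under default noise
  truth_vol <- array(0, dim(labs$labels))
  idx <- which(labs$labels > 0)
  truth_vol[idx] <- tab$true_ratio[labs$labels[idx]]
  expect_gt(cor(vol[idx], truth_vol[idx]), 0.9)
  # missing distances are reported by label id
  tab2 <- tab[tab$id != 3, ]
  expect_error(render_prediction_map(f, labs, tab2, cfg$voxel_size), "3")
})
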