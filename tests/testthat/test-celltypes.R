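# fixture: labelled nuclei with hand-set marker channels
marker_fixture <- function(marker_values) {
  sh <- c(8, 16, 16); vs <- c(1, 1, 1)
  lab <- array(0L, sh)
  centers <- list(c(3, 4, 4), c(3, 4, 12), c(3, 12, 4), c(3, 12, 12))
  for (i in seq_along(centers)) {
    sv <- hypoxiamap:::sphere_voxels(centers[[i]], 1.6, sh, vs)
    lab[sv$idx] <- i
  }
  chans <- c("rfp", "gfp", "marker_neuroblast", "marker_GMC",
             "marker_neuron", "marker_glia")
  arr <- array(0, c(length(chans), sh))
  arr[1, , , ] <- 1
  arr[2, , , ] <- 1
  for (ch in names(marker_values)) {
    k <- match(ch, chans)
    v <- array(0, sh)
    for (i in marker_values[[ch]]) v[lab == i] <- 1
    arr[k, , , ] <- v
  }
  tab <- data.frame(id = 1:4,
                    z_um = sapply(centers, `[`, 1) - 1,
                    y_um = sapply(centers, `[`, 2) - 1,
                    x_um = sapply(centers, `[`, 3) - 1)
  list(stack = image_stack(arr, vs, chans),
       labels = label_volume(lab, 4L), table = tab)
}

test_that("single-positive nuclei get their marker's type", {
  fx <- marker_fixture(list(marker_neuroblast = 1, marker_GMC = 2,
                            marker_neuron = 3, marker_glia = 4))
  out <- assign_cell_types(fx$stack, fx$labels, fx$table,
                           cell_type_rules(threshold = 0.5))
  expect_equal(out$cell_type, c("neuroblast", "GMC", "neuron", "glia"))
})

test_that("marker-negative nuclei are unknown", {
  fx <- marker_fixture(list())
  out <- assign_cell_types(fx$stack, fx$labels, fx$table,
                           cell_type_rules(threshold = 0.5))
  expect_equal(out$cell_type, rep("unknown", 4))
})

test_that("multi-positive nuclei resolve by the priority order", {
  # nucleus 1 positive for both the GMC and neuron markers (the Prospero /
  # Elav overlap case): GMC outranks neuron by default
  fx <- marker_fixture(list(marker_GMC = 1, marker_neuron = 1))
  out <- assign_cell_types(fx$stack, fx$labels, fx$table,
                           cell_type_rules(threshold = 0.5))
  expect_equal(out$cell_type[1], "GMC")
  # neuroblast outranks everything
  fx2 <- marker_fixture(list(marker_neuroblast = 1, marker_GMC = 1,
                             marker_glia = 1))
  out2 <- assign_cell_types(fx2$stack, fx2$labels, fx2$table,
                            cell_type_rules(threshold = 0.5))
  expect_equal(out2$cell_type[1], "neuroblast")
})

test_that("a neuroepithelium mask overrides marker calls", {
  fx <- marker_fixture(list(marker_neuroblast = 1))
  ne <- array(FALSE, c(8, 16, 16))
  ne[, , 9:16] <- TRUE  # right half holds nuclei 2 and 4
  out <- assign_cell_types(fx$stack, fx$labels, fx$table,
                           cell_type_rules(threshold = 0.5), ne_mask = ne)
  expect_equal(out$cell_type,
               c("neuroblast", "neuroepithelium", "unknown",
                 "neuroepithelium"))
})

test_that("rules referencing missing channels error", {
  fx <- marker_fixture(list())
  rules <- cell_type_rules(markers = c(glia = "marker_missing"),
                           priority = "glia")
  expect_error(assign_cell_types(fx$stack, fx$labels, fx$table, rules),
               "missing channel")
})

test_that("type assignment is perfect on noiseless disjoint-marker phantoms", {
  cfg <- phantom_config(volume_shape = c(48, 96, 96), n_nuclei = 120,
                        noise_cv = 0, read_noise_sd = 0, background = 0,
                        celltype_proportions = c(neuroblast = 0.2, GMC = 0.2,
                                                 neuron = 0.2, glia = 0.2,
                                                 neuroepithelium = 0.2),
                        seed = 19)
  ph <- generate_phantom(cfg)
  seg <- segment_nuclei(ph$stack)
  tab <- measure_ratios(ph$stack, seg$labels, nuclei = seg$nuclei)
  tab <- assign_cell_types(ph$stack, seg$labels, tab, cell_type_rules(),
                           ne_mask = get_channel(ph$stack,
                                                 "marker_neuroepithelium") > 0.5)
  m <- match_detections(tab, ph$truth$nuclei)
  good <- m$dist < max(cfg$voxel_size)
  expect_equal(mean(tab$cell_type[good] ==
                      ph$truth$nuclei$cell_type[m$nearest[good]]), 1)
})

test_that("group summaries compute n, mean, sd and sem correctly", {
  tab <- data.frame(id = 1:3, ratio = c(1, 2, 5), inv_ratio = 1 / c(1, 2, 5),
                    dist_um = c(1, 3, 10), grp = c("a", "a", "b"),
                    flagged = FALSE)
  sm <- summarize_groups(tab, "grp")
  expect_equal(sm$n, c(2L, 1L))
  expect_equal(sm$mean_ratio, c(1.5, 5))
  expect_equal(sm$sem_ratio[1], 0.5)
  expect_true(is.na(sm$sd_ratio[2]))
  expect_false(sm$sd_defined[2])
  empty <- summarize_groups(tab[0, ], "grp")
  expect_equal(nrow(empty), 0)
})

test_that("flat groups flag lambda while graded groups order correctly", {
  set.seed(33)
  n <- 600
  d1 <- runif(n, 0, 120)
  d2 <- runif(n, 0, 120)
  flat <- runif(n, 0, 120)
  mk <- function(d, lam) (0.5 + 0.9 * exp(-d / lam)) * (1 + 0.05 * rnorm(n))
  tab <- data.frame(
    dist_um = c(d1, d2, flat),
    inv_ratio = c(mk(d1, 30), mk(d2, 60), 0.8 * (1 + 0.05 * rnorm(n))),
    cell_type = rep(c("neuron", "glia", "neuroepithelium"), each = n))
  fits <- fit_decay_by_group(tab, "cell_type")
  expect_false(fits$neuroepithelium$lambda_identifiable)
  expect_true(fits$neuron$lambda_identifiable)
  expect_lt(fits$neuron$params$lambda_um, fits$glia$params$lambda_um)
  # single group equals the ungrouped fit
  one <- tab[tab$cell_type == "neuron", ]
  f_grp <- fit_decay_by_group(one, "cell_type")$neuron
  f_all <- fit_decay(one$dist_um, one$inv_ratio)
  expect_equal(f_grp$params, f_all$params)
})

test_that("stratified means recover configured truths on noisy phantoms", {
  cfg <- phantom_config(volume_shape = c(64, 160, 160), n_nuclei = 600,
                        celltype_proportions = c(neuroblast = 0.2, GMC = 0.2,
                                                 neuron = 0.2, glia = 0.2,
                                                 neuroepithelium = 0.2),
                        celltype_ratio_means = celltype_reference_means(),
                        ratio_sd = 0.15, noise_cv = 0.10, seed = 11)
  ph <- generate_phantom(cfg)
  seg <- segment_nuclei(ph$stack)
  tab <- measure_ratios(ph$stack, seg$labels, nuclei = seg$nuclei)
  tab <- assign_compartment(tab, compartment_mask(cfg), ph$stack$voxel_size)
  tab <- assign_cell_types(ph$stack, seg$labels, tab, cell_type_rules(),
                           ne_mask = get_channel(ph$stack,
                                                 "marker_neuroepithelium") > 0.5)
  sm <- summarize_groups(tab)
  ref <- celltype_reference_means()
  for (i in seq_len(nrow(ref))) {
    row <- sm[sm$cell_type == ref$cell_type[i] &
                sm$compartment == ref$compartment[i], ]
    if (nrow(row) == 0 || row$n < 30) next
    expect_lt(abs(row$mean_ratio - ref$mean_ratio[i]), 3 * row$sem_ratio)
  }
})
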