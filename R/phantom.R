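#' Condition presets for the oxygenation model
#'
#' Returns the default decaying-exponential model and reference compartment
#' mean ratios for a rearing condition. Decay constants are the average-fit
#' values measured in the larval brain under ambient normoxia (~21 percent
#' oxygen), hyperoxia (60 percent) and hypoxia (5 percent); amplitude and
#' offset are package defaults chosen to produce ratios spanning roughly
#' 0.7 near a tracheole to 1.8 far from one under normoxia, with the offset
#' shifted so that hyperoxia lowers and hypoxia raises ratios throughout.
#'
#' @param condition one of `"normoxia"`, `"hyperoxia"`, `"hypoxia"`.
#' @return list with `ratio_model` (a [decay_params()]) and
#'   `compartment_means` (reference mean GFP-ODD/RFP ratios for the central
#'   brain and optic lobe under that condition).
#' @export
condition_preset <- function(condition = c("normoxia", "hyperoxia", "hypoxia")) {
  condition <- match.arg(condition)
  switch(condition,
    normoxia = list(
      ratio_model = decay_params(A = 0.9, y0 = 0.55, lambda_um = 51.8, x0_um = 0),
      compartment_means = c(central_brain = 0.89, optic_lobe = 1.32)),
    hyperoxia = list(
      ratio_model = decay_params(A = 0.9, y0 = 0.90, lambda_um = 65.8, x0_um = 0),
      compartment_means = c(central_brain = 0.55, optic_lobe = 0.61)),
    hypoxia = list(
      ratio_model = decay_params(A = 0.9, y0 = 0.35, lambda_um = 53.4, x0_um = 0),
      compartment_means = c(central_brain = 1.25, optic_lobe = 1.86)))
}

#' Cell types recognised by the pipeline
#' @export
CELL_TYPES <- c("neuroblast", "GMC", "neuron", "glia", "neuroepithelium")

#' Reference per-type mean ratios at 84 h after larval hatching
#'
#' Mean GFP-ODD/RFP ratios per cell type and compartment measured in the
#' larval brain under normoxia, used as default calibration for cell-type
#' phantoms. The central-brain neuroblast and the (distance-insensitive)
#' neuroepithelium values are package defaults chosen consistent with
#' neuroblasts being the most hypoxic type in each compartment; the others
#' are measured values.
#'
#' @return data frame with columns `cell_type`, `compartment`, `mean_ratio`.
#' @export
celltype_reference_means <- function() {
  data.frame(
    cell_type = rep(CELL_TYPES, each = 2),
    compartment = rep(c("central_brain", "optic_lobe"), times = 5),
    mean_ratio = c(1.05, 1.51,   # neuroblast (CB value is a package default)
                   0.75, 1.17,   # GMC
                   0.81, 1.24,   # neuron
                   0.92, 1.16,   # glia
                   1.20, 1.20),  # neuroepithelium (flat; package default)
    stringsAsFactors = FALSE)
}

#' Build a per-type mean-ratio table with one value per compartment
#'
#' Convenience for phantoms whose true compartment mean ratio should be a
#' single value for all cell types, e.g. to emulate a whole-compartment
#' measurement.
#'
#' @param central_brain,optic_lobe mean ratio per compartment.
#' @return data frame usable as `celltype_ratio_means` in [phantom_config()].
#' @export
compartment_ratio_means <- function(central_brain, optic_lobe) {
  data.frame(cell_type = rep(CELL_TYPES, each = 2),
             compartment = rep(c("central_brain", "optic_lobe"), times = 5),
             mean_ratio = rep(c(central_brain, optic_lobe), times = 5),
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic brain phantom
#'
#' Defines the geometry, tracheal densities, nuclear population, true
#' oxygenation model and noise levels of a 3D brain phantom. The volume is
#' split along x into a densely tracheolated "central brain" (low x) and a
#' sparsely tracheolated "optic lobe" (high x).
#'
#' @param volume_shape integer length-3, voxels per axis (z, y, x).
#' @param voxel_size numeric length-3, um per voxel (z, y, x).
#' @param compartment_split fraction of the x extent belonging to the
#'   central brain.
#' @param tracheal_density_cb,tracheal_density_ol target tracheal voxel
#'   fraction per compartment, in `[0, 1]`.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um numeric length-2 `(mean, sd)` of nucleus radius.
#' @param celltype_proportions named fractions over
#'   neuroblast/GMC/neuron/glia/neuroepithelium; must sum to 1.
#' @param ratio_model a [decay_params()] giving the true
#'   oxygenation-versus-distance model; defaults to the preset for
#'   `condition`.
#' @param celltype_ratio_means optional data frame (`cell_type`,
#'   `compartment`, `mean_ratio`); when set, true ratios are drawn from a
#'   truncated normal around these means (sd `ratio_sd`) instead of the
#'   distance model.
#' @param ratio_sd standard deviation of the truncated normal used with
#'   `celltype_ratio_means`.
#' @param noise_cv coefficient of variation of the multiplicative
#'   (log-normal, mean 1) noise applied to distance-model true ratios.
#' @param condition rearing-condition preset selecting `ratio_model`
#'   defaults.
#' @param tube_radius_um tracheal tube radius; default one voxel
#'   (`max(voxel_size)`).
#' @param min_gap_um minimum surface-to-surface gap enforced between nuclei.
#' @param peak_intensity nuclear reporter peak intensity.
#' @param background additive background level on imaging channels.
#' @param read_noise_sd additive Gaussian read-noise sd on imaging channels.
#' @param marker_channels logical; render one binary marker channel per cell
#'   type.
#' @param seed RNG seed for the phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(64L, 128L, 128L),
                           voxel_size = c(1.0, 0.5, 0.5),
                           compartment_split = 0.5,
                           tracheal_density_cb = 0.02,
                           tracheal_density_ol = 0.001,
                           n_nuclei = 400L,
                           nucleus_radius_um = c(2.2, 0.2),
                           celltype_proportions = c(neuroblast = 0.06,
                                                    GMC = 0.14, neuron = 0.50,
                                                    glia = 0.12,
                                                    neuroepithelium = 0.18),
                           ratio_model = NULL,
                           celltype_ratio_means = NULL,
                           ratio_sd = 0.15,
                           noise_cv = 0.10,
                           condition = c("normoxia", "hyperoxia", "hypoxia"),
                           tube_radius_um = NULL,
                           min_gap_um = 1.0,
                           peak_intensity = 1.0,
                           background = 0.005,
                           read_noise_sd = 0.01,
                           marker_channels = TRUE,
                           seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(ratio_model)) ratio_model <- condition_preset(condition)$ratio_model
  if (is.null(tube_radius_um)) tube_radius_um <- max(voxel_size)
  volume_shape <- as.integer(volume_shape)
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive")
  for (d in c(tracheal_density_cb, tracheal_density_ol)) {
    if (d < 0 || d > 1) stop("tracheal densities must lie in [0, 1]")
  }
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (abs(sum(celltype_proportions) - 1) > 1e-9) {
    stop("celltype_proportions must sum to 1")
  }
  if (!all(names(celltype_proportions) %in% CELL_TYPES)) {
    stop("unknown cell type in celltype_proportions")
  }
  if (!is.null(celltype_ratio_means)) {
    stopifnot(all(c("cell_type", "compartment", "mean_ratio") %in%
                    names(celltype_ratio_means)))
  }
  structure(list(volume_shape = volume_shape, voxel_size = voxel_size,
                 compartment_split = compartment_split,
                 tracheal_density_cb = tracheal_density_cb,
                 tracheal_density_ol = tracheal_density_ol,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_um = nucleus_radius_um,
                 celltype_proportions = celltype_proportions,
                 ratio_model = ratio_model,
                 celltype_ratio_means = celltype_ratio_means,
                 ratio_sd = ratio_sd, noise_cv = noise_cv,
                 condition = condition, tube_radius_um = tube_radius_um,
                 min_gap_um = min_gap_um, peak_intensity = peak_intensity,
                 background = background, read_noise_sd = read_noise_sd,
                 marker_channels = isTRUE(marker_channels),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# x-axis voxel-centre coordinates (um) and the compartment of each x index
compartment_of_x <- function(config) {
  nx <- config$volume_shape[3]
  x_um <- (seq_len(nx) - 1) * config$voxel_size[3]
  extent <- nx * config$voxel_size[3]
  ifelse(x_um < config$compartment_split * extent, "central_brain", "optic_lobe")
}

#' Compartment mask volume for a phantom configuration
#'
#' @param config a `phantom_config`.
#' @return integer 3D array `[z, y, x]` with 1 = central brain, 2 = optic
#'   lobe (the coding used by [assign_compartment()]).
#' @export
compartment_mask <- function(config) {
  comp_x <- compartment_of_x(config)
  code <- ifelse(comp_x == "central_brain", 1L, 2L)
  sh <- config$volume_shape
  arr <- array(rep(code, each = sh[1] * sh[2]), dim = sh)
  arr
}

#' Oxygenation (ratio^-1) as a function of tracheole distance
#'
#' Evaluates the decaying-exponential oxygenation model
#' `y0 + A * exp(-(d - x0) / lambda)`. This is the true model used by the
#' phantom generator and the functional form fitted by [fit_decay()].
#'
#' @param d distance(s) to the nearest tracheole, um.
#' @param model a [decay_params()].
#' @return oxygenation proxy value(s) (ratio^-1, dimensionless).
#' @export
true_inverse_ratio <- function(d, model) {
  stopifnot(inherits(model, "decay_params"))
  if (model$lambda_um <= 0) stop("lambda must be > 0")
  model$y0 + model$A * exp(-(d - model$x0_um) / model$lambda_um)
}

#' Rasterize a polyline into tube voxels
#'
#' Marks every voxel whose centre lies within `radius_um` of the polyline.
#'
#' @param points_um matrix n x 3 of (z, y, x) um points.
#' @param shape integer length-3 volume shape (z, y, x).
#' @param voxel_size um per voxel (z, y, x).
#' @param radius_um tube radius, um.
#' @return integer vector of linear voxel indices (1-based, column-major).
#' @export
rasterize_tube <- function(points_um, shape, voxel_size, radius_um) {
  idx_all <- integer(0)
  if (nrow(points_um) < 2) return(idx_all)
  for (s in seq_len(nrow(points_um) - 1)) {
    p0 <- points_um[s, ]; p1 <- points_um[s + 1, ]
    lo <- pmax(floor(pmin(p0, p1) - radius_um) / voxel_size, 0)
    hi <- (pmax(p0, p1) + radius_um) / voxel_size
    i0 <- pmax(1L, as.integer(floor(lo)) + 1L)
    i1 <- pmin(shape, as.integer(ceiling(hi)) + 1L)
    if (any(i0 > i1)) next
    gz <- (i0[1]:i1[1] - 1) * voxel_size[1]
    gy <- (i0[2]:i1[2] - 1) * voxel_size[2]
    gx <- (i0[3]:i1[3] - 1) * voxel_size[3]
    g <- expand.grid(z = gz, y = gy, x = gx, KEEP.OUT.ATTRS = FALSE)
    d <- point_segment_dist(as.matrix(g), p0, p1)
    keep <- which(d <= radius_um)
    if (length(keep) == 0) next
    iz <- expand.grid(z = i0[1]:i1[1], y = i0[2]:i1[2], x = i0[3]:i1[3],
                      KEEP.OUT.ATTRS = FALSE)[keep, ]
    lin <- iz$z + shape[1] * (iz$y - 1L + shape[2] * (iz$x - 1L))
    idx_all <- c(idx_all, lin)
  }
  unique(idx_all)
}

# distance from points (n x 3) to the segment p0--p1, all in um
point_segment_dist <- function(pts, p0, p1) {
  v <- p1 - p0
  l2 <- sum(v^2)
  if (l2 == 0) {
    return(sqrt(rowSums(sweep(pts, 2, p0)^2)))
  }
  w <- sweep(pts, 2, p0)
  t <- pmin(1, pmax(0, as.vector(w %*% v) / l2))
  proj <- outer(t, v) + rep(p0, each = nrow(pts))
  sqrt(rowSums((pts - proj)^2))
}

# split the length of segment p0--p1 at the compartment boundary plane
segment_length_by_compartment <- function(p0, p1, split_x_um) {
  len <- sqrt(sum((p1 - p0)^2))
  x0 <- p0[3]; x1 <- p1[3]
  if (x0 > x1) { tmp <- x0; x0 <- x1; x1 <- tmp }
  if (x1 <= split_x_um) return(c(central_brain = len, optic_lobe = 0))
  if (x0 >= split_x_um) return(c(central_brain = 0, optic_lobe = len))
  f <- (split_x_um - x0) / (x1 - x0)
  c(central_brain = f * len, optic_lobe = (1 - f) * len)
}

#' Tracheal map
#'
#' Set of tracheal voxel coordinates (voxel centres, um) with an optional
#' analytic skeleton (list of polylines) and total length.
#'
#' @param coords_um matrix n x 3 of (z, y, x) um voxel-centre coordinates.
#' @param voxel_size um per voxel (z, y, x).
#' @param dim volume shape (z, y, x) in voxels.
#' @param skeleton optional list of polylines (matrices of um points).
#' @param length_by_compartment optional named numeric
#'   (central_brain, optic_lobe) of analytic skeleton length.
#' @param voxel_idx optional linear voxel indices matching `coords_um`.
#' @return Object of class `tracheal_map`. `total_length_um` is the sum of
#'   all skeleton segment lengths (0 when no skeleton).
#' @export
tracheal_map <- function(coords_um, voxel_size, dim, skeleton = NULL,
                         length_by_compartment = NULL, voxel_idx = NULL) {
  coords_um <- as.matrix(coords_um)
  if (ncol(coords_um) != 3 && nrow(coords_um) > 0) {
    stop("coords_um must have 3 columns (z, y, x)")
  }
  total <- 0
  if (!is.null(skeleton)) {
    total <- sum(vapply(skeleton, polyline_length, numeric(1)))
  }
  structure(list(coords_um = coords_um, voxel_size = as.numeric(voxel_size),
                 dim = as.integer(dim), skeleton = skeleton,
                 total_length_um = total,
                 length_by_compartment = length_by_compartment,
                 voxel_idx = voxel_idx),
            class = "tracheal_map")
}

polyline_length <- function(pl) {
  if (nrow(pl) < 2) return(0)
  sum(sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2)))
}

#' @export
print.tracheal_map <- function(x, ...) {
  cat("tracheal_map:", nrow(x$coords_um), "voxels, total skeleton length",
      round(x$total_length_um, 2), "um\n")
  invisible(x)
}

#' Generate a branching tracheal tree
#'
#' Grows a single connected tree of straight tubular segments by stochastic
#' branching from existing nodes, rasterized at the configured tube radius,
#' until the tracheal voxel fraction in each compartment reaches its target
#' (within the generator's +/-30 percent contract). The root is placed in
#' the central brain near the compartment boundary so the tree can reach
#' both compartments; when one compartment's budget is filled, growth is
#' steered toward the other.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @return A [tracheal_map()] whose skeleton holds one 2-point polyline per
#'   segment and whose `length_by_compartment` is the exact analytic length
#'   of the skeleton in each compartment.
#' @export
generate_tracheal_tree <- function(config, seed = config$seed) {
  sh <- config$volume_shape
  vs <- config$voxel_size
  comp_x <- compartment_of_x(config)
  n_slice <- sh[1] * sh[2]
  nvox_comp <- c(central_brain = sum(comp_x == "central_brain") * n_slice,
                 optic_lobe = sum(comp_x == "optic_lobe") * n_slice)
  targets <- c(central_brain = config$tracheal_density_cb * nvox_comp[[1]],
               optic_lobe = config$tracheal_density_ol * nvox_comp[[2]])
  for (cc in names(targets)) {
    dens <- if (cc == "central_brain") config$tracheal_density_cb
            else config$tracheal_density_ol
    if (dens > 0.2) {
      stop("tracheal density target ", dens, " unreachable at tube radius ",
           config$tube_radius_um, " um in compartment ", cc)
    }
  }
  empty <- tracheal_map(matrix(numeric(0), 0, 3), vs, sh,
                        skeleton = list(),
                        length_by_compartment = c(central_brain = 0,
                                                  optic_lobe = 0))
  if (all(targets == 0)) return(empty)

  set.seed(seed)
  extent <- sh * vs
  split_x_um <- config$compartment_split * extent[3]
  margin <- config$tube_radius_um + max(vs)
  root_x <- if (targets[["central_brain"]] > 0) {
    max(margin, min(split_x_um * 0.8, extent[3] - margin))
  } else {
    min(extent[3] - margin, split_x_um * 1.2)
  }
  root <- c(stats::runif(1, margin, extent[1] - margin),
            stats::runif(1, margin, extent[2] - margin), root_x)
  nodes <- matrix(root, 1, 3)
  occ <- array(FALSE, dim = sh)
  counts <- c(central_brain = 0, optic_lobe = 0)
  lengths <- c(central_brain = 0, optic_lobe = 0)
  skeleton <- list()
  done <- function() all(counts >= targets)
  max_iter <- max(6000L, as.integer(120 * ceiling(sum(targets) / 100)))
  iter <- 0L
  while (!done() && iter < max_iter) {
    iter <- iter + 1L
    # steer: which compartment still needs voxels?
    need_cb <- counts[["central_brain"]] < targets[["central_brain"]]
    need_ol <- counts[["optic_lobe"]] < targets[["optic_lobe"]]
    n_nodes <- nrow(nodes)
    dir <- stats::rnorm(3)
    if (need_cb && need_ol) {
      from <- nodes[sample.int(n_nodes, 1, prob = seq_len(n_nodes)), ]
    } else {
      # grow only inside the compartment that still needs voxels: prefer
      # nodes safely inside it, else steer from the closest node toward it
      buffer <- 5
      inside <- if (need_ol) nodes[, 3] > split_x_um + buffer
                else nodes[, 3] < split_x_um - buffer
      if (any(inside)) {
        cand <- which(inside)
        from <- nodes[cand[sample.int(length(cand), 1,
                                      prob = seq_along(cand))], ]
      } else {
        from <- nodes[if (need_ol) which.max(nodes[, 3])
                      else which.min(nodes[, 3]), ]
        if (need_ol && dir[3] < 0) dir[3] <- -dir[3]
        if (need_cb && dir[3] > 0) dir[3] <- -dir[3]
      }
    }
    dir <- dir / sqrt(sum(dir^2))
    # size proposals from the remaining voxel budget so the final segments
    # of a compartment fit without overshooting the density contract
    vpu <- if (sum(lengths) > 0) sum(counts) / sum(lengths) else 12
    rem_vox <- min(if (need_cb) targets[["central_brain"]] -
                     counts[["central_brain"]] else Inf,
                   if (need_ol) targets[["optic_lobe"]] -
                     counts[["optic_lobe"]] else Inf)
    len <- stats::runif(1, 12, 30)
    if (rem_vox / vpu < len) {
      len <- max(6, rem_vox / vpu * stats::runif(1, 0.85, 1.0))
    }
    to <- from + dir * len
    to <- pmin(pmax(to, margin), extent - margin)
    if (sqrt(sum((to - from)^2)) < 2) next
    lc <- segment_length_by_compartment(from, to, split_x_um)
    # reject growth into a compartment whose budget is already filled
    if (!need_cb && lc[["central_brain"]] > 1) next
    if (!need_ol && lc[["optic_lobe"]] > 1) next
    idx <- rasterize_tube(rbind(from, to), sh, vs, config$tube_radius_um)
    fresh <- !occ[idx]
    # reject mostly-overlapping segments so the analytic skeleton length
    # stays consistent with the rasterized tube set; the attachment ball
    # around the parent node necessarily overlaps and is not held against
    # the segment
    co <- linear_to_um(idx, sh, vs)
    core <- sqrt((co[, 1] - from[1])^2 + (co[, 2] - from[2])^2 +
                   (co[, 3] - from[3])^2) >
      config$tube_radius_um + max(vs)
    if (sum(fresh & core) < 0.85 * max(sum(core), 1)) next
    idx <- idx[fresh]
    if (length(idx) == 0) next
    xi <- ((idx - 1L) %/% n_slice) + 1L  # x index of each new voxel
    new_cb <- sum(comp_x[xi] == "central_brain")
    new_ol <- length(idx) - new_cb
    # keep each compartment within the density contract: no spill into a
    # filled compartment, no overshoot past ~20% of the target
    if (!need_cb && new_cb > 0.02 * max(targets[["central_brain"]], 50)) next
    if (!need_ol && new_ol > 0.02 * max(targets[["optic_lobe"]], 50)) next
    if (need_cb && counts[["central_brain"]] + new_cb >
          max(1.2 * targets[["central_brain"]],
              targets[["central_brain"]] + 80)) next
    if (need_ol && counts[["optic_lobe"]] + new_ol >
          max(1.2 * targets[["optic_lobe"]],
              targets[["optic_lobe"]] + 80)) next
    occ[idx] <- TRUE
    counts[["central_brain"]] <- counts[["central_brain"]] + new_cb
    counts[["optic_lobe"]] <- counts[["optic_lobe"]] + new_ol
    lengths <- lengths + lc
    skeleton[[length(skeleton) + 1L]] <- rbind(from, to)
    nodes <- rbind(nodes, to)
  }
  if (!done()) {
    short <- names(targets)[counts < 0.7 * targets]
    if (length(short) > 0) {
      stop("could not reach tracheal density target in compartment ",
           paste(short, collapse = ", "))
    }
  }
  lin <- which(occ)
  coords <- linear_to_um(lin, sh, vs)
  tracheal_map(coords, vs, sh, skeleton = skeleton,
               length_by_compartment = lengths, voxel_idx = lin)
}

# linear (1-based, column-major z,y,x) voxel indices -> centre um coordinates
linear_to_um <- function(lin, shape, voxel_size) {
  lin0 <- lin - 1L
  z <- lin0 %% shape[1]
  rem <- lin0 %/% shape[1]
  y <- rem %% shape[2]
  x <- rem %/% shape[2]
  cbind(z * voxel_size[1], y * voxel_size[2], x * voxel_size[3])
}

# truncated-normal sampler by rejection (lower bound only)
rtrunc_norm <- function(n, mean, sd, lower = 0.05) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Place ground-truth nuclei in a phantom
#'
#' Samples non-overlapping spherical nuclei uniformly over the volume,
#' assigns each a cell type by the configured proportions, its exact minimum
#' Euclidean distance to the tracheal voxel set, and its true
#' GFP-ODD/RFP ratio: either `1 / true_inverse_ratio(distance)` with
#' multiplicative log-normal noise (mean 1, CV `noise_cv`), or a truncated
#' normal draw around the configured per-type/per-compartment mean when
#' `celltype_ratio_means` is set.
#'
#' @param config a [phantom_config()].
#' @param trachea a [tracheal_map()].
#' @param seed RNG seed.
#' @return Data frame with columns `id`, `z_um`, `y_um`, `x_um`,
#'   `radius_um`, `cell_type`, `compartment`, `dist_um`, `true_ratio`.
#' @export
place_nuclei <- function(config, trachea, seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n_nuclei
  cols <- c("id", "z_um", "y_um", "x_um", "radius_um", "cell_type",
            "compartment", "dist_um", "true_ratio")
  if (n == 0) {
    df <- data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
                     x_um = numeric(0), radius_um = numeric(0),
                     cell_type = character(0), compartment = character(0),
                     dist_um = numeric(0), true_ratio = numeric(0))
    return(df[cols])
  }
  extent <- config$volume_shape * config$voxel_size
  rm_ <- config$nucleus_radius_um
  radii <- pmax(0.8, rtrunc_norm(n, rm_[1], rm_[2], lower = rm_[1] - 3 * rm_[2]))
  centers <- matrix(NA_real_, n, 3)
  max_tries <- 2000L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (tr in seq_len(max_tries)) {
      m <- radii[i] + max(config$voxel_size)
      p <- c(stats::runif(1, m, extent[1] - m),
             stats::runif(1, m, extent[2] - m),
             stats::runif(1, m, extent[3] - m))
      if (i > 1) {
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        dmin <- sqrt(rowSums(sweep(prev, 2, p)^2)) -
          radii[seq_len(i - 1)] - radii[i]
        if (min(dmin) < config$min_gap_um) next
      }
      centers[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("failed to place nucleus ", i, " of ", n,
           " without overlap after ", max_tries, " tries; ",
           "reduce n_nuclei or nucleus radius")
    }
  }
  types <- sample(names(config$celltype_proportions), n, replace = TRUE,
                  prob = config$celltype_proportions)
  split_x_um <- config$compartment_split * extent[3]
  comp <- ifelse(centers[, 3] < split_x_um, "central_brain", "optic_lobe")
  if (nrow(trachea$coords_um) > 0) {
    dist <- cpp_min_dist(centers, trachea$coords_um)$dist_um
  } else {
    dist <- rep(NA_real_, n)
  }
  if (!is.null(config$celltype_ratio_means)) {
    key <- paste(types, comp)
    tab <- config$celltype_ratio_means
    mu <- tab$mean_ratio[match(key, paste(tab$cell_type, tab$compartment))]
    if (any(is.na(mu))) {
      stop("celltype_ratio_means is missing entries for: ",
           paste(unique(key[is.na(mu)]), collapse = ", "))
    }
    ratio <- rtrunc_norm(n, mu, config$ratio_sd)
  } else {
    if (any(is.na(dist))) {
      stop("distance-model ratios require a non-empty tracheal map")
    }
    ratio <- 1 / true_inverse_ratio(dist, config$ratio_model)
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      ratio <- ratio * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  }
  data.frame(id = seq_len(n), z_um = centers[, 1], y_um = centers[, 2],
             x_um = centers[, 3], radius_um = radii, cell_type = types,
             compartment = comp, dist_um = dist, true_ratio = ratio,
             stringsAsFactors = FALSE)
}

# linear indices of voxels within radius of a centre (um), plus the radial
# Gaussian profile value at each voxel
sphere_voxels <- function(center, radius, shape, voxel_size) {
  i0 <- pmax(1L, as.integer(floor((center - radius) / voxel_size)) + 1L)
  i1 <- pmin(shape, as.integer(ceiling((center + radius) / voxel_size)) + 1L)
  if (any(i0 > i1)) return(list(idx = integer(0), d = numeric(0)))
  gz <- (i0[1]:i1[1] - 1) * voxel_size[1] - center[1]
  gy <- (i0[2]:i1[2] - 1) * voxel_size[2] - center[2]
  gx <- (i0[3]:i1[3] - 1) * voxel_size[3] - center[3]
  g <- expand.grid(z = gz, y = gy, x = gx, KEEP.OUT.ATTRS = FALSE)
  d <- sqrt(g$z^2 + g$y^2 + g$x^2)
  keep <- which(d <= radius)
  iz <- expand.grid(z = i0[1]:i1[1], y = i0[2]:i1[2], x = i0[3]:i1[3],
                    KEEP.OUT.ATTRS = FALSE)[keep, ]
  lin <- iz$z + shape[1] * (iz$y - 1L + shape[2] * (iz$x - 1L))
  list(idx = lin, d = d[keep])
}

#' Render a phantom image stack from ground truth
#'
#' Builds the multi-channel stack: the `rfp` channel contains
#' Gaussian-profile spheres at each nucleus; the `gfp` channel is the RFP
#' profile multiplied voxelwise by the nucleus's true ratio (so the
#' nucleus-mean GFP/RFP equals the true ratio exactly before noise); the
#' `trachea` channel is the rasterized tube set; one binary `marker_<type>`
#' channel per cell type lights only that type's nuclei. Imaging channels
#' get an additive background plus Gaussian read noise, clamped at zero.
#'
#' @param truth nucleus table from [place_nuclei()].
#' @param trachea a [tracheal_map()].
#' @param config a [phantom_config()].
#' @param seed RNG seed for the read noise.
#' @return An [image_stack()].
#' @export
render_stack <- function(truth, trachea, config, seed = config$seed + 2L) {
  set.seed(seed)
  sh <- config$volume_shape
  vs <- config$voxel_size
  nvox <- prod(sh)
  rfp <- numeric(nvox)
  gfp <- numeric(nvox)
  markers <- if (config$marker_channels) {
    stats::setNames(lapply(CELL_TYPES, function(t) numeric(nvox)), CELL_TYPES)
  } else NULL
  for (i in seq_len(nrow(truth))) {
    ctr <- c(truth$z_um[i], truth$y_um[i], truth$x_um[i])
    r <- truth$radius_um[i]
    sv <- sphere_voxels(ctr, r, sh, vs)
    if (length(sv$idx) == 0) next
    prof <- config$peak_intensity * exp(-sv$d^2 / (2 * (r / 2)^2))
    rfp[sv$idx] <- rfp[sv$idx] + prof
    gfp[sv$idx] <- gfp[sv$idx] + prof * truth$true_ratio[i]
    if (!is.null(markers)) {
      markers[[truth$cell_type[i]]][sv$idx] <- 1.0
    }
  }
  tra <- numeric(nvox)
  if (!is.null(trachea$voxel_idx) && length(trachea$voxel_idx) > 0) {
    tra[trachea$voxel_idx] <- config$peak_intensity
  } else if (nrow(trachea$coords_um) > 0) {
    ijk <- round(sweep(trachea$coords_um, 2, vs, "/")) + 1
    lin <- ijk[, 1] + sh[1] * (ijk[, 2] - 1 + sh[2] * (ijk[, 3] - 1))
    tra[lin] <- config$peak_intensity
  }
  noisy <- function(v) {
    v <- v + config$background
    if (config$read_noise_sd > 0) {
      v <- v + stats::rnorm(length(v), 0, config$read_noise_sd)
    }
    pmax(v, 0)
  }
  chans <- c(list(rfp = noisy(rfp), gfp = noisy(gfp), trachea = noisy(tra)),
             if (!is.null(markers)) {
               stats::setNames(markers, paste0("marker_", names(markers)))
             })
  arr <- array(0, dim = c(length(chans), sh))
  for (k in seq_along(chans)) {
    arr[k, , , ] <- array(chans[[k]], dim = sh)
  }
  image_stack(arr, vs, names(chans))
}

#' Generate a complete brain phantom
#'
#' Runs [generate_tracheal_tree()], [place_nuclei()] and [render_stack()]
#' with seeds derived from `config$seed`, returning the stack together with
#' full ground truth for parameter-recovery experiments.
#'
#' @param config a [phantom_config()].
#' @return A `brain_phantom`: list with `stack` (an [image_stack()]) and
#'   `truth` (nucleus table, `trachea`, true `model`,
#'   `total_tracheal_length_um` per compartment, and the `config`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  trachea <- generate_tracheal_tree(config, seed = config$seed)
  nuclei <- place_nuclei(config, trachea, seed = config$seed + 1L)
  stack <- render_stack(nuclei, trachea, config, seed = config$seed + 2L)
  structure(list(stack = stack,
                 truth = list(nuclei = nuclei, trachea = trachea,
                              model = config$ratio_model,
                              total_tracheal_length_um =
                                trachea$length_by_compartment,
                              config = config)),
            class = "brain_phantom")
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat("brain_phantom:", nrow(x$truth$nuclei), "nuclei,",
      nrow(x$truth$trachea$coords_um), "tracheal voxels, condition",
      x$truth$config$condition, "\n")
  invisible(x)
}

#' Ground-truth label volume of a phantom
#'
#' Rasterizes the true nuclei as labelled spheres, bypassing segmentation;
#' used for closure tests of the ratiometric measurements.
#'
#' @param phantom a `brain_phantom`.
#' @return A [label_volume()] whose label ids equal the truth-table `id`s.
#' @export
ground_truth_labels <- function(phantom) {
  config <- phantom$truth$config
  sh <- config$volume_shape
  lab <- array(0L, dim = sh)
  truth <- phantom$truth$nuclei
  for (i in seq_len(nrow(truth))) {
    sv <- sphere_voxels(c(truth$z_um[i], truth$y_um[i], truth$x_um[i]),
                        truth$radius_um[i], sh, config$voxel_size)
    lab[sv$idx] <- truth$id[i]
  }
  label_volume(lab, n_labels = nrow(truth),
               provenance = list(source = "ground_truth"))
}
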