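#' Labelled voxel volume
#'
#' @param labels integer 3D array `[z, y, x]`, 0 = background, nuclei
#'   labelled 1..N (26-connected components).
#' @param n_labels number of labels.
#' @param provenance list recording the source channel and parameters.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(labels, n_labels = max(labels), provenance = list()) {
  stopifnot(length(dim(labels)) == 3L)
  structure(list(labels = labels, n_labels = as.integer(n_labels),
                 provenance = provenance),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", x$n_labels, "labels in",
      paste(dim(x$labels), collapse = " x "), "voxels\n")
  invisible(x)
}

gaussian_kernel1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

smooth3d <- function(vol, voxel_size, sigma_um) {
  if (sigma_um <= 0) return(vol)
  kernels <- lapply(1:3, function(a) gaussian_kernel1d(sigma_um / voxel_size[a]))
  cpp_sep_conv3(vol, dim(vol), kernels)
}

# greyscale opening with a box structuring element (um half-widths),
# the background estimate for rolling-ball-style background subtraction
background_open <- function(vol, voxel_size, radius_um) {
  r <- as.integer(pmax(0, round(radius_um / voxel_size)))
  if (all(r == 0)) return(vol * 0)
  er <- cpp_box_filter3(vol, dim(vol), r, TRUE)
  cpp_box_filter3(er, dim(vol), r, FALSE)
}

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment nuclei from the baseline-reporter channel
#'
#' Processing order: background subtraction (greyscale opening with a box of
#' `background_radius` um) -> Gaussian smoothing (`smooth_sigma` um) ->
#' threshold (Otsu by default) -> 26-connected component labelling ->
#' physical volume filter -> optional watershed splitting of touching
#' nuclei seeded at smoothed distance-transform maxima. All geometric
#' quantities are computed in micrometres, respecting anisotropic voxels.
#'
#' @param stack an [image_stack()].
#' @param channel nuclear reporter channel (name or index).
#' @param background_radius background-opening half-width, um.
#' @param smooth_sigma Gaussian smoothing sigma, um.
#' @param threshold_method `"otsu"` or a fixed numeric threshold.
#' @param min_volume_um3,max_volume_um3 nucleus volume filter, um^3.
#' @param split_touching split merged objects by seeded watershed.
#' @param seed_sigma_um smoothing applied to the distance transform before
#'   maxima detection.
#' @param min_seed_sep_um watershed seeds closer than this are merged
#'   (lowest seed id wins).
#' @return list with `labels` (a [label_volume()]) and `nuclei`, a data
#'   frame of intensity-weighted centroids (`id`, `z_um`, `y_um`, `x_um`,
#'   `volume_um3`, `n_voxels`).
#' @export
segment_nuclei <- function(stack, channel = "rfp",
                           background_radius = 10, smooth_sigma = 0.5,
                           threshold_method = "otsu",
                           min_volume_um3 = 15, max_volume_um3 = 600,
                           split_touching = FALSE,
                           seed_sigma_um = 1.0, min_seed_sep_um = 2.0) {
  vol <- get_channel(stack, channel)
  vs <- stack$voxel_size
  vox_vol <- prod(vs)
  if (background_radius > 0) {
    vol <- pmax(vol - background_open(vol, vs, background_radius), 0)
    dim(vol) <- dim(stack$data)[2:4]
  }
  sm <- smooth3d(vol, vs, smooth_sigma)
  thr <- if (identical(threshold_method, "otsu")) otsu_threshold(sm)
         else as.numeric(threshold_method)
  mask <- sm > thr
  if (!any(mask)) {
    warning("no voxels above threshold; returning empty nucleus table")
    return(list(labels = label_volume(array(0L, dim(sm)), 0L),
                nuclei = empty_nucleus_centroids()))
  }
  lab <- cpp_label3(mask, dim(sm))
  if (split_touching) {
    edt <- cpp_edt3(mask, dim(sm), vs)
    sedt <- smooth3d(edt, vs, seed_sigma_um)
    mx <- cpp_local_maxima3(sedt, dim(sm), mask)
    seeds <- seed_labels(mx, dim(sm), vs, min_seed_sep_um)
    if (max(seeds) > 0) {
      lab <- cpp_watershed3(edt, seeds, mask, dim(sm))
    }
  }
  res <- relabel_and_measure(lab, sm, vs)
  keep <- res$nuclei$volume_um3 >= min_volume_um3 &
    res$nuclei$volume_um3 <= max_volume_um3
  res <- filter_labels(res, keep)
  res$labels$provenance <- list(channel = channel,
                                background_radius = background_radius,
                                smooth_sigma = smooth_sigma,
                                threshold = thr,
                                split_touching = split_touching)
  res
}

empty_nucleus_centroids <- function() {
  data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
             x_um = numeric(0), volume_um3 = numeric(0), n_voxels = integer(0))
}

# convert local-maxima mask to integer seed labels, merging maxima closer
# than min_sep_um (kept seed = lowest linear index, i.e. lowest label id)
seed_labels <- function(mx, dims, voxel_size, min_sep_um) {
  idx <- which(mx)
  seeds <- integer(length(mx))
  dim(seeds) <- dims
  if (length(idx) == 0) return(seeds)
  pts <- linear_to_um(idx, dims, voxel_size)
  keep <- rep(TRUE, length(idx))
  for (i in seq_along(idx)[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    if (length(prev) > 0) {
      d <- sqrt(colSums((t(pts[prev, , drop = FALSE]) - pts[i, ])^2))
      if (min(d) < min_sep_um) keep[i] <- FALSE
    }
  }
  kept <- idx[keep]
  seeds[kept] <- seq_along(kept)
  seeds
}

# relabel to contiguous 1..N and compute intensity-weighted centroids
relabel_and_measure <- function(lab, intensity, voxel_size) {
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(list(labels = label_volume(array(0L, dim(lab)), 0L),
                nuclei = empty_nucleus_centroids()))
  }
  l <- lab[idx]
  ul <- sort(unique(l))
  l <- match(l, ul)
  newlab <- array(0L, dim(lab))
  newlab[idx] <- l
  w <- intensity[idx]
  co <- linear_to_um(idx, dim(lab), voxel_size)
  sw <- rowsum(w, l)
  cz <- rowsum(w * co[, 1], l) / sw
  cy <- rowsum(w * co[, 2], l) / sw
  cx <- rowsum(w * co[, 3], l) / sw
  nvox <- as.integer(rowsum(rep(1L, length(l)), l))
  nuclei <- data.frame(id = seq_along(ul), z_um = as.vector(cz),
                       y_um = as.vector(cy), x_um = as.vector(cx),
                       volume_um3 = nvox * prod(voxel_size),
                       n_voxels = nvox)
  list(labels = label_volume(newlab, length(ul)), nuclei = nuclei)
}

filter_labels <- function(res, keep) {
  if (all(keep)) return(res)
  old_ids <- res$nuclei$id[keep]
  lab <- res$labels$labels
  map <- integer(res$labels$n_labels)
  map[old_ids] <- seq_along(old_ids)
  idx <- which(lab > 0)
  lab[idx] <- map[lab[idx]]
  nuclei <- res$nuclei[keep, , drop = FALSE]
  nuclei$id <- seq_len(nrow(nuclei))
  rownames(nuclei) <- NULL
  list(labels = label_volume(lab, nrow(nuclei)), nuclei = nuclei)
}

#' Extract the voxel-level tracheal map from the tracheal channel
#'
#' Background subtraction, Gaussian smoothing and a global threshold; the
#' coordinates of every above-threshold voxel form the digital tracheal
#' map used for nucleus-to-tracheole distances.
#'
#' @param stack an [image_stack()].
#' @param channel tracheal channel (name or index).
#' @param background_radius background-opening half-width, um (0 disables).
#' @param smooth_sigma Gaussian sigma, um (0 disables).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @return A [tracheal_map()] (possibly empty, with a warning).
#' @export
extract_tracheal_map <- function(stack, channel = "trachea",
                                 background_radius = 0, smooth_sigma = 0,
                                 threshold = "otsu") {
  vol <- get_channel(stack, channel)
  vs <- stack$voxel_size
  if (background_radius > 0) {
    vol <- pmax(vol - background_open(vol, vs, background_radius), 0)
    dim(vol) <- dim(stack$data)[2:4]
  }
  sm <- smooth3d(vol, vs, smooth_sigma)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(sm)
         else as.numeric(threshold)
  idx <- which(sm > thr)
  if (length(idx) == 0) {
    warning("tracheal channel produced an empty map")
    return(tracheal_map(matrix(numeric(0), 0, 3), vs, dim(sm)))
  }
  coords <- linear_to_um(idx, dim(sm), vs)
  tracheal_map(coords, vs, dim(sm), voxel_idx = idx)
}

#' Total skeleton length of a tracheal map
#'
#' Reduces the tracheal voxel set to centreline polylines and sums their
#' Euclidean segment lengths in micrometres. The centreline is traced on
#' the 26-connectivity voxel adjacency graph: for each connected component
#' a root is chosen as the graph-farthest voxel from an arbitrary start,
#' then branches are peeled off by repeatedly walking the shortest-path
#' tree from the farthest uncaptured voxel down to the existing skeleton,
#' capturing voxels within `capture_radius_um` of the new branch. Polylines
#' are smoothed with a short moving average to remove voxel-lattice zigzag
#' before lengths are summed.
#'
#' @param map a [tracheal_map()].
#' @param roi_mask optional logical 3D array; only polyline segments whose
#'   midpoint falls in the mask contribute to the total.
#' @param capture_radius_um capture radius around a traced branch.
#' @param min_branch_um hard floor on counted branch length; branches that
#'   additionally never leave the immediate neighbourhood of the existing
#'   centreline are discarded as tube-thickness artefacts whatever their
#'   length.
#' @param spur_tol_um a branch whose every point lies within this distance
#'   of the already-traced centreline counts as a thickness spur; defaults
#'   to 1.25x the capture radius (calibrated on rasterized tubes of known
#'   length).
#' @return total length in um (0 for an empty map).
#' @export
skeleton_total_length <- function(map, roi_mask = NULL,
                                  capture_radius_um = NULL,
                                  min_branch_um = 1.5,
                                  spur_tol_um = NULL) {
  stopifnot(inherits(map, "tracheal_map"))
  n <- nrow(map$coords_um)
  if (n == 0) return(0)
  if (is.null(capture_radius_um)) {
    capture_radius_um <- 1.6 * max(map$voxel_size)
  }
  if (is.null(spur_tol_um)) spur_tol_um <- 1.25 * capture_radius_um
  pts <- map$coords_um
  vs <- map$voxel_size
  ijk <- round(sweep(pts, 2, vs, "/"))
  # adjacency: voxel pairs whose index offsets are all within 1 (26-conn)
  key <- (ijk[, 1] + 2) + 1e4 * ((ijk[, 2] + 2) + 1e4 * (ijk[, 3] + 2))
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nk <- (ijk[, 1] + offs$dz[o] + 2) +
      1e4 * ((ijk[, 2] + offs$dy[o] + 2) + 1e4 * (ijk[, 3] + offs$dx[o] + 2))
    j <- match(nk, key)
    hit <- which(!is.na(j) & j > seq_len(n))
    if (length(hit) > 0) edges[[length(edges) + 1L]] <- cbind(hit, j[hit])
  }
  if (length(edges) == 0) return(0)
  em <- do.call(rbind, edges)
  w <- sqrt(rowSums((pts[em[, 1], , drop = FALSE] -
                       pts[em[, 2], , drop = FALSE])^2))
  # medial-axis penalty: weight edges by how far they run from the tube
  # centre (distance-from-background transform), so shortest paths hug the
  # centreline and parallel lanes merge onto a single skeleton
  mask <- array(FALSE, dim = map$dim)
  lin <- ijk[, 1] + 1L + map$dim[1] * (ijk[, 2] + map$dim[2] * ijk[, 3])
  mask[lin] <- TRUE
  edt <- cpp_edt3(mask, map$dim, vs)[lin]
  cent <- (edt[em[, 1]] + edt[em[, 2]]) / 2
  wpen <- w * (1 + 5 * (1 - cent / max(edt))^2)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::E(g)$weight <- wpen
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  total <- 0
  for (ci in seq_len(comp$no)) {
    vset <- which(comp$membership == ci)
    if (length(vset) < 2) next
    total <- total + trace_component_length(g, vset, em, wpen, pts, roi_mask,
                                            vs, map$dim, capture_radius_um,
                                            min_branch_um, spur_tol_um)
  }
  total
}

trace_component_length <- function(g, vset, em, w, pts, roi_mask, voxel_size,
                                   dims, capture_radius_um, min_branch_um,
                                   spur_tol_um) {
  n_all <- nrow(pts)
  d0 <- igraph::distances(g, v = vset[1], to = vset)[1, ]
  root <- vset[which.max(d0)]
  droot_v <- igraph::distances(g, v = root, to = vset)[1, ]
  droot <- rep(Inf, n_all)
  droot[vset] <- droot_v
  # predecessor on the shortest-path tree, derived from distances:
  # pred[b] = a for any edge (a, b) lying on a shortest path to b
  pred <- integer(n_all)
  eps <- 1e-9
  fwd <- which(abs(droot[em[, 1]] + w - droot[em[, 2]]) < eps)
  pred[em[fwd, 2]] <- em[fwd, 1]
  bwd <- which(abs(droot[em[, 2]] + w - droot[em[, 1]]) < eps)
  pred[em[bwd, 1]] <- em[bwd, 2]
  pred[root] <- 0L
  captured <- rep(FALSE, n_all)
  on_skel <- rep(FALSE, n_all)
  first <- TRUE
  total <- 0
  repeat {
    rem <- vset[!captured[vset]]
    if (length(rem) == 0) break
    target <- rem[which.max(droot[rem])]
    path <- integer(0)
    cur <- target
    while (cur != 0L) {
      path <- c(path, cur)
      # branches join the skeleton at an exact previously-traced vertex
      if (!first && on_skel[cur]) break
      cur <- pred[cur]
    }
    branch <- pts[path, , drop = FALSE]
    dmin <- cpp_min_dist(pts[rem, , drop = FALSE], branch)$dist_um
    captured[rem[dmin <= capture_radius_um]] <- TRUE
    captured[path] <- TRUE
    sm <- smooth_polyline(branch, window = 5L)
    blen <- polyline_roi_length(sm, roi_mask, voxel_size, dims)
    keep <- first || polyline_length(sm) >= min_branch_um
    if (!first && keep) {
      # tube-wall spur check: a branch that never leaves the immediate
      # neighbourhood of the existing centreline is thickness artefact,
      # not a real side branch
      dsk <- cpp_min_dist(branch, pts[which(on_skel), , drop = FALSE])$dist_um
      if (max(dsk) <= spur_tol_um) keep <- FALSE
    }
    on_skel[path] <- TRUE
    if (keep) total <- total + blen
    first <- FALSE
  }
  total
}

# moving-average smoothing preserving endpoints
smooth_polyline <- function(pl, window = 5L) {
  n <- nrow(pl)
  if (n <= 2 || window < 3) return(pl)
  half <- window %/% 2
  out <- pl
  for (i in 2:(n - 1)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i, ] <- colMeans(pl[lo:hi, , drop = FALSE])
  }
  out
}

polyline_roi_length <- function(pl, roi_mask, voxel_size, dims) {
  if (nrow(pl) < 2) return(0)
  seg <- sqrt(rowSums((pl[-1, , drop = FALSE] - pl[-nrow(pl), , drop = FALSE])^2))
  if (is.null(roi_mask)) return(sum(seg))
  mid <- (pl[-1, , drop = FALSE] + pl[-nrow(pl), , drop = FALSE]) / 2
  ijk <- pmin(pmax(round(sweep(mid, 2, voxel_size, "/")) + 1, 1),
              matrix(dims, nrow(mid), 3, byrow = TRUE))
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1 + dims[2] * (ijk[, 3] - 1))
  sum(seg[roi_mask[lin]])
}

#' Tracheolation index: skeleton length per tissue volume
#'
#' The ratio of total tracheolar length within a region to the region's
#' volume, the standard summary of how densely a compartment is supplied
#' with tracheoles.
#'
#' @param total_length_um total tracheolar length, um.
#' @param volume_um3 region volume, um^3.
#' @return index in um^-2.
#' @export
tracheolation_index <- function(total_length_um, volume_um3) {
  if (volume_um3 <= 0) stop("volume must be > 0")
  total_length_um / volume_um3
}
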