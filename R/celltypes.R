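#' Cell-type assignment rules
#'
#' Maps marker names to stack channels, with an intensity threshold policy
#' and a priority order that resolves multi-positive nuclei (markers such
#' as Prospero overlap partially between cell types). Neuroepithelium is
#' not marker-called: it is assigned from a region mask covering the
#' proliferation centres, supplied separately to [assign_cell_types()].
#'
#' @param markers named character/integer vector: cell type -> channel.
#' @param threshold `"otsu"` (computed on the per-nucleus mean marker
#'   intensities of each channel) or a fixed numeric threshold applied to
#'   all channels.
#' @param priority total order over configured types; the highest-priority
#'   positive marker wins.
#' @return Object of class `cell_type_rules`.
#' @export
cell_type_rules <- function(markers = c(neuroblast = "marker_neuroblast",
                                        GMC = "marker_GMC",
                                        neuron = "marker_neuron",
                                        glia = "marker_glia"),
                            threshold = "otsu",
                            priority = c("neuroblast", "GMC", "glia",
                                         "neuron")) {
  if (!all(names(markers) %in% setdiff(CELL_TYPES, "neuroepithelium"))) {
    stop("unknown marker cell type")
  }
  if (!setequal(priority, names(markers))) {
    stop("priority must be a total order over the configured marker types")
  }
  structure(list(markers = markers, threshold = threshold,
                 priority = priority),
            class = "cell_type_rules")
}

#' Assign cell types to nuclei from marker channels
#'
#' Computes the mean intensity of each marker channel over each nucleus's
#' voxels; a nucleus is positive for a marker when that mean exceeds the
#' channel threshold, and receives the highest-priority positive type.
#' Nuclei with no positive marker are `"unknown"`. When `ne_mask` is given,
#' nuclei whose centroid lies in the mask are assigned
#' `"neuroepithelium"` first, mirroring the region-based identification of
#' the proliferation centres.
#'
#' @param stack an [image_stack()] containing the marker channels.
#' @param labels a [label_volume()].
#' @param table nucleus table with `id` (and centroids if `ne_mask` used).
#' @param rules a [cell_type_rules()].
#' @param ne_mask optional logical 3D array marking the neuroepithelium
#'   region.
#' @return the table with a `cell_type` column.
#' @export
assign_cell_types <- function(stack, labels, table, rules = cell_type_rules(),
                              ne_mask = NULL) {
  stopifnot(inherits(rules, "cell_type_rules"))
  for (ch in rules$markers) {
    if (is.character(ch) && !(ch %in% stack$channel_names)) {
      stop("marker rule references missing channel '", ch, "'")
    }
  }
  lab <- labels$labels
  idx <- which(lab > 0)
  l <- lab[idx]
  ids <- sort(unique(l))
  nvox <- as.vector(rowsum(rep(1, length(l)), l))
  means <- sapply(rules$markers, function(ch) {
    v <- get_channel(stack, ch)
    as.vector(rowsum(v[idx], l)) / nvox
  })
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(NULL, names(rules$markers)))
  }
  thr <- if (identical(rules$threshold, "otsu")) {
    apply(means, 2, otsu_threshold)
  } else {
    rep(as.numeric(rules$threshold), ncol(means))
  }
  positive <- sweep(means, 2, thr, ">")
  type <- rep("unknown", length(ids))
  for (tp in rev(rules$priority)) {
    type[positive[, tp]] <- tp
  }
  out <- rep(NA_character_, nrow(table))
  out[match(ids, table$id)] <- type
  out[is.na(out)] <- "unknown"
  table$cell_type <- out
  if (!is.null(ne_mask)) {
    dims <- dim(ne_mask)
    ctr <- as.matrix(table[, c("z_um", "y_um", "x_um")])
    ijk <- round(sweep(ctr, 2, stack$voxel_size, "/")) + 1
    lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1 + dims[2] * (ijk[, 3] - 1))
    table$cell_type[ne_mask[lin]] <- "neuroepithelium"
  }
  table
}

#' Group-wise ratiometric summaries
#'
#' One row per group with the sample size and the mean, sd and sem of the
#' ratio, plus mean ratio^-1 and mean tracheole distance where available.
#' Flagged nuclei are excluded. Rows are ordered deterministically by the
#' grouping keys; groups of size 1 have `sd`/`sem` set to `NA` and are
#' flagged in `sd_defined`.
#'
#' @param table nucleus table.
#' @param group_keys character vector of grouping columns
#'   (e.g. `c("cell_type", "compartment")`).
#' @return summary data frame.
#' @export
summarize_groups <- function(table, group_keys = c("cell_type",
                                                   "compartment")) {
  stopifnot(all(group_keys %in% names(table)))
  if ("flagged" %in% names(table)) table <- table[!table$flagged, ]
  if (nrow(table) == 0) {
    out <- stats::setNames(
      data.frame(matrix(ncol = length(group_keys) + 7, nrow = 0)),
      c(group_keys, "n", "mean_ratio", "sd_ratio", "sem_ratio",
        "mean_inv_ratio", "mean_dist_um", "sd_defined"))
    return(out)
  }
  key <- interaction(table[group_keys], drop = TRUE, lex.order = TRUE)
  sp <- split(table, key)
  rows <- lapply(sp, function(d) {
    r <- d$ratio
    out <- d[1, group_keys, drop = FALSE]
    out$n <- nrow(d)
    out$mean_ratio <- mean(r)
    out$sd_ratio <- if (nrow(d) > 1) stats::sd(r) else NA_real_
    out$sem_ratio <- out$sd_ratio / sqrt(nrow(d))
    out$mean_inv_ratio <- if ("inv_ratio" %in% names(d)) mean(d$inv_ratio)
                          else mean(1 / r)
    out$mean_dist_um <- if ("dist_um" %in% names(d)) mean(d$dist_um)
                        else NA_real_
    out$sd_defined <- nrow(d) > 1
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[group_keys]), , drop = FALSE]
}

#' Fit the oxygenation decay model per group
#'
#' Runs [fit_decay()] on `(dist_um, inv_ratio)` within each group. Groups
#' failing the fit preconditions (fewer than 10 points, non-positive
#' values) are skipped with a warning. Groups whose true oxygenation is
#' distance-independent come back with `lambda_identifiable = FALSE`, the
#' behaviour observed for neuroepithelial cells.
#'
#' @param table nucleus table with `dist_um` and `inv_ratio`.
#' @param group_keys grouping columns.
#' @param method passed to [fit_decay()].
#' @return named list of `decay_fit` objects.
#' @export
fit_decay_by_group <- function(table, group_keys = "cell_type",
                               method = "least_squares") {
  stopifnot(all(c("dist_um", "inv_ratio") %in% names(table)))
  if ("flagged" %in% names(table)) table <- table[!table$flagged, ]
  key <- interaction(table[group_keys], drop = TRUE, lex.order = TRUE)
  sp <- split(table, key)
  fits <- list()
  for (nm in names(sp)) {
    d <- sp[[nm]]
    f <- tryCatch(fit_decay(d$dist_um, d$inv_ratio, method = method),
                  error = function(e) {
                    warning("skipping group '", nm, "': ",
                            conditionMessage(e))
                    NULL
                  })
    if (!is.null(f)) fits[[nm]] <- f
  }
  fits
}
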