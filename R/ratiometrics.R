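#' Per-nucleus ratiometric biosensor measurements
#'
#' For every label, computes the mean degradation-sensor (GFP-ODD) and
#' baseline-reporter (RFP) intensity over the label's voxels and their
#' ratio, the per-nucleus hypoxia-response readout. The ratio is the ratio
#' of channel means, `mean(GFP) / mean(RFP)`, which is robust to dim voxels
#' at the nuclear rim. Nuclei whose mean RFP falls below `rfp_floor` are
#' flagged and excluded from downstream statistics; the default floor is
#' the background mean plus twice the background standard deviation,
#' estimated from voxels outside all labels.
#'
#' @param stack an [image_stack()].
#' @param labels a [label_volume()] aligned with the stack.
#' @param gfp_channel,rfp_channel channel names or indices.
#' @param rfp_floor numeric floor on mean RFP, or `NULL` for the automatic
#'   background-based floor.
#' @param nuclei optional centroid table from [segment_nuclei()] to merge
#'   (by `id`) into the result.
#' @return Nucleus table: `id`, centroid columns (when `nuclei` given),
#'   `mean_gfp`, `mean_rfp`, `ratio`, `inv_ratio`, `flagged`.
#' @export
measure_ratios <- function(stack, labels, gfp_channel = "gfp",
                           rfp_channel = "rfp", rfp_floor = NULL,
                           nuclei = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (!identical(dim(labels$labels), dim(stack$data)[2:4])) {
    stop("label volume shape does not match stack shape")
  }
  gfp <- get_channel(stack, gfp_channel)
  rfp <- get_channel(stack, rfp_channel)
  lab <- labels$labels
  idx <- which(lab > 0)
  l <- lab[idx]
  if (length(idx) == 0) {
    out <- data.frame(id = integer(0), mean_gfp = numeric(0),
                      mean_rfp = numeric(0), ratio = numeric(0),
                      inv_ratio = numeric(0), flagged = logical(0))
    return(out)
  }
  nvox <- as.vector(rowsum(rep(1, length(l)), l))
  ids <- sort(unique(l))
  mean_gfp <- as.vector(rowsum(gfp[idx], l)) / nvox
  mean_rfp <- as.vector(rowsum(rfp[idx], l)) / nvox
  if (is.null(rfp_floor)) {
    bg <- rfp[-idx]
    rfp_floor <- if (length(bg) > 0) mean(bg) + 2 * stats::sd(bg) else 0
    if (is.na(rfp_floor)) rfp_floor <- 0
  }
  flagged <- mean_rfp <= rfp_floor | mean_rfp <= 0
  ratio <- ifelse(flagged & mean_rfp <= 0, NA_real_, mean_gfp / mean_rfp)
  out <- data.frame(id = ids, mean_gfp = mean_gfp, mean_rfp = mean_rfp,
                    ratio = ratio, inv_ratio = 1 / ratio, flagged = flagged)
  if (!is.null(nuclei)) {
    out <- merge(nuclei, out, by = "id", sort = TRUE)
  }
  out
}

#' Normalise ratios to the whole-hemisphere mean
#'
#' Adds `ratio_norm = ratio / mean(ratio)` where the mean is taken over all
#' unflagged nuclei, so that the mean normalised ratio over the hemisphere
#' is exactly 1. Used for frequency-distribution comparisons across brains
#' of different overall intensity.
#'
#' @param table nucleus table from [measure_ratios()].
#' @return the table with a `ratio_norm` column.
#' @export
normalize_to_hemisphere <- function(table) {
  ok <- !table$flagged & !is.na(table$ratio)
  if (!any(ok)) stop("no unflagged nuclei to normalise against")
  m <- mean(table$ratio[ok])
  table$ratio_norm <- table$ratio / m
  table
}

COMPARTMENT_CODES <- c(central_brain = 1L, optic_lobe = 2L)

#' Assign brain compartments from a mask volume
#'
#' Each nucleus receives the compartment of the voxel containing its
#' centroid: 1 = central brain, 2 = optic lobe, 0 = none.
#'
#' @param table nucleus table with centroid columns `z_um`, `y_um`, `x_um`.
#' @param mask integer 3D array `[z, y, x]` with values in {0, 1, 2}.
#' @param voxel_size um per voxel (z, y, x).
#' @return the table with a `compartment` column
#'   (`"central_brain"`, `"optic_lobe"` or `"none"`).
#' @export
assign_compartment <- function(table, mask, voxel_size) {
  stopifnot(length(dim(mask)) == 3L)
  dims <- dim(mask)
  if (nrow(table) == 0) {
    table$compartment <- character(0)
    return(table)
  }
  ctr <- as.matrix(table[, c("z_um", "y_um", "x_um")])
  ijk <- round(sweep(ctr, 2, voxel_size, "/")) + 1
  if (any(ijk < 1) || any(sweep(ijk, 2, dims, ">") != 0)) {
    stop("nucleus centroid outside mask volume; shape mismatch?")
  }
  lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1 + dims[2] * (ijk[, 3] - 1))
  code <- mask[lin]
  table$compartment <- c("none", names(COMPARTMENT_CODES))[code + 1L]
  table
}
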