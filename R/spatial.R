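#' Minimum Euclidean distance from nuclei to the tracheal map
#'
#' For each nucleus centroid, the exact minimum over all tracheal voxel
#' centres of the 3D Euclidean distance in micrometres, computed by
#' exhaustive search (the distances are exact, not approximated by a
#' spatial index). Optionally the nuclear radius can be subtracted to
#' obtain a surface-to-tracheole distance, floored at zero.
#'
#' @param centroids_um numeric matrix n x 3 of (z, y, x) um centroids, or a
#'   nucleus table with `z_um`, `y_um`, `x_um` columns.
#' @param trachea a [tracheal_map()]; must be non-empty.
#' @param radius_um optional per-nucleus radii to subtract (surface
#'   distance).
#' @return data frame: `id`, `dist_um`, and nearest tracheal point
#'   (`near_z_um`, `near_y_um`, `near_x_um`).
#' @export
min_distance_to_trachea <- function(centroids_um, trachea, radius_um = NULL) {
  stopifnot(inherits(trachea, "tracheal_map"))
  if (nrow(trachea$coords_um) == 0) {
    stop("tracheal map is empty; an untracheolated volume has no ",
         "distance-to-trachea -- handle this case in the caller")
  }
  if (is.data.frame(centroids_um)) {
    ids <- if ("id" %in% names(centroids_um)) centroids_um$id
           else seq_len(nrow(centroids_um))
    ctr <- as.matrix(centroids_um[, c("z_um", "y_um", "x_um")])
  } else {
    ctr <- as.matrix(centroids_um)
    ids <- seq_len(nrow(ctr))
  }
  res <- cpp_min_dist(ctr, trachea$coords_um)
  d <- res$dist_um
  if (!is.null(radius_um)) d <- pmax(d - radius_um, 0)
  np <- trachea$coords_um[res$nearest, , drop = FALSE]
  data.frame(id = ids, dist_um = d, near_z_um = np[, 1], near_y_um = np[, 2],
             near_x_um = np[, 3])
}

#' Append tracheole distances to a nucleus table
#'
#' @param table nucleus table with centroid columns.
#' @param trachea a [tracheal_map()].
#' @param surface subtract the nuclear radius (`radius_um` column) to
#'   report surface rather than centroid distance.
#' @return the table with a `dist_um` column.
#' @export
add_distances <- function(table, trachea, surface = FALSE) {
  r <- if (surface) {
    if (!"radius_um" %in% names(table)) {
      stop("surface distance requested but table has no radius_um column")
    }
    table$radius_um
  } else NULL
  d <- min_distance_to_trachea(table, trachea, radius_um = r)
  table$dist_um <- d$dist_um
  table
}
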