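#' Multi-channel 3D image stack
#'
#' Container for a multi-channel voxel grid with explicit physical voxel
#' sizes. Voxels are indexed `[channel, z, y, x]`; physical coordinates are
#' in micrometres with the centre of voxel `(i, j, k)` (1-based) at
#' `(i - 1) * voxel_size`, i.e. 0-based index times voxel size.
#'
#' @param data numeric array, either 4D `[channel, z, y, x]` or 3D
#'   `[z, y, x]` (promoted to a single channel).
#' @param voxel_size numeric length-3, micrometres per voxel along (z, y, x).
#' @param channel_names character vector, one name per channel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channel_names = NULL) {
  if (length(dim(data)) == 3L) {
    dim(data) <- c(1L, dim(data))
  }
  stopifnot(length(dim(data)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive values (z, y, x) in um")
  }
  nc <- dim(data)[1]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nc, ")")
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("stack intensities must be finite and >= 0")
  }
  structure(list(data = data, voxel_size = voxel_size,
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("image_stack:", d[1], "channel(s),", d[2], "x", d[3], "x", d[4],
      "voxels (z,y,x)\n")
  cat("  voxel size (um):", paste(signif(x$voxel_size, 4), collapse = " x "), "\n")
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @return 3D numeric array `[z, y, x]`.
#' @export
get_channel <- function(stack, channel) {
  i <- resolve_channel(stack, channel)
  arr <- stack$data[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$data)[2:4]
  arr
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop("channel '", channel, "' not found; available: ",
                       paste(stack$channel_names, collapse = ", "))
    return(i)
  }
  i <- as.integer(channel)
  if (i < 1L || i > dim(stack$data)[1]) stop("channel index out of range: ", i)
  i
}

#' Write an image stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are written channel-major (all z-planes of channel 1, then channel
#' 2, ...). Intensities are stored as 32-bit floats scaled to `[0, 1]`; the
#' scale factor, voxel sizes and channel names go into `<path>.json` so that
#' [read_stack()] restores physical units and metadata.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pl <- stack$data[ch, z, , ] / scale
      dim(pl) <- d[3:4]
      pages[[p]] <- pl
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(voxel_size_um = stack$voxel_size,
               channel_names = stack$channel_names,
               shape_czyx = d, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Reads the metadata sidecar written by [write_stack()] when present.
#' Without a sidecar the file is treated as a single-channel z-stack and
#' `voxel_size_override` must be supplied, otherwise an error is raised:
#' physical voxel sizes are required for all downstream distance and length
#' computations.
#'
#' @param path TIFF path.
#' @param voxel_size_override optional numeric length-3 (z, y, x) in um,
#'   used when the file carries no voxel-size metadata (and overriding it
#'   when it does).
#' @return An `image_stack`.
#' @export
read_stack <- function(path, voxel_size_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  if (is.null(meta) && is.null(voxel_size_override)) {
    stop("no voxel-size metadata found for '", path,
         "' and no voxel_size_override given")
  }
  if (!is.null(meta)) {
    d <- as.integer(meta$shape_czyx)
    scale <- meta$intensity_scale
    vs <- if (is.null(voxel_size_override)) as.numeric(meta$voxel_size_um)
          else voxel_size_override
    cn <- meta$channel_names
  } else {
    d <- c(1L, length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2])
    scale <- 1
    vs <- voxel_size_override
    cn <- NULL
  }
  arr <- array(0, dim = d)
  p <- 1L
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pl <- pages[[p]]
      if (length(dim(pl)) == 3L) pl <- pl[, , 1]  # tolerate grey written as RGB
      arr[ch, z, , ] <- pl * scale
      p <- p + 1L
    }
  }
  image_stack(arr, vs, cn)
}

#' Write analysis tables and fits with a checksum manifest
#'
#' Writes each table as CSV and each fit/summary object as JSON into
#' `out_dir`, then writes `manifest.csv` listing every file with its MD5
#' checksum.
#'
#' @param tables named list of data frames (written as `<name>.csv`).
#' @param fits named list of JSON-serialisable objects (written as
#'   `<name>.json`); may be `NULL`.
#' @param out_dir output directory (created if missing).
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_results <- function(tables = list(), fits = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(fits)) {
    f <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(unclass_deep(fits[[nm]]), f, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Export a skeleton as an SWC file
#'
#' Writes the polylines of a tracheal skeleton in SWC format (id, type,
#' x, y, z, radius, parent), one connected path per polyline, coordinates
#' in micrometres.
#'
#' @param map a `tracheal_map` with a non-null skeleton.
#' @param path output file.
#' @param radius_um radius written for every node.
#' @return `path`, invisibly.
#' @export
write_swc <- function(map, path, radius_um = 0.5) {
  stopifnot(inherits(map, "tracheal_map"))
  if (is.null(map$skeleton) || length(map$skeleton) == 0) {
    stop("tracheal map has no skeleton to export")
  }
  rows <- list()
  id <- 0L
  for (pl in map$skeleton) {
    parent <- -1L
    for (i in seq_len(nrow(pl))) {
      id <- id + 1L
      # SWC columns are x, y, z; our points are (z, y, x) um
      rows[[id]] <- c(id, 0L, pl[i, 3], pl[i, 2], pl[i, 1], radius_um, parent)
      parent <- id
    }
  }
  m <- do.call(rbind, rows)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
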