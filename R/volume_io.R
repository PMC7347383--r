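# Disk round-trip for synthetic volumes: multi-page TIFF (channel-interleaved
# per z-plane) with a JSON sidecar carrying the physical calibration, SWC for
# centerlines, JSON for ground truth.

#' Write an `exm_volume` as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z-major, channel-interleaved (z1/ch1, z1/ch2, z2/ch1,
#' ...). Intensities are rescaled to the unit interval for 32-bit float TIFF
#' storage; the scale factor is recorded in the sidecar and undone on read.
#'
#' @param volume An `exm_volume`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_exm_volume <- function(volume, path) {
  stopifnot(inherits(volume, "exm_volume"))
  d <- dim(volume$data)
  scale <- max(volume$data, 1e-12)
  pages <- vector("list", d[3] * d[4])
  n <- 0L
  for (k in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      n <- n + 1L
      # TIFF pages are row-major images: rows = y, columns = x.
      pages[[n]] <- t(volume$data[, , k, ch]) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(voxel_xy = volume$voxel_xy, voxel_z = volume$voxel_z,
                  expansion_factor = volume$expansion_factor,
                  channel_names = volume$channel_names,
                  n_z = d[3], n_channels = d[4], intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an `exm_volume` written by [write_exm_volume()]
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return An `exm_volume`.
#' @export
read_exm_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z; nc <- meta$n_channels
  stopifnot(length(pages) == nz * nc)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(nx, ny, nz, nc))
  n <- 0L
  for (k in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      n <- n + 1L
      data[, , k, ch] <- t(pages[[n]]) * meta$intensity_scale
    }
  }
  structure(list(data = data, voxel_xy = meta$voxel_xy, voxel_z = meta$voxel_z,
                 expansion_factor = meta$expansion_factor,
                 channel_names = meta$channel_names),
            class = "exm_volume")
}

#' Write a centerline as SWC
#'
#' Nodes are 1-based, type 3 (dendrite), each parented to its predecessor;
#' coordinates are um post-expansion.
#'
#' @param centerline n x 3 matrix (um post-expansion).
#' @param path Output path.
#' @param radius Node radius column, um post-expansion.
#' @return `path`, invisibly.
#' @export
write_swc <- function(centerline, path, radius = 1) {
  n <- nrow(centerline)
  df <- data.frame(id = seq_len(n), type = 3L,
                   x = centerline[, 1], y = centerline[, 2],
                   z = centerline[, 3], radius = radius,
                   parent = c(-1L, seq_len(n - 1L)))
  utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an SWC centerline
#' @param path SWC file path.
#' @return n x 3 coordinate matrix (um, same frame the file was written in).
#' @export
read_swc <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  as.matrix(df[order(df$id), c("x", "y", "z")])
}

#' Write / read generator ground truth as JSON
#' @param truth An `exm_truth`.
#' @param path JSON path.
#' @return `path` invisibly (write); an `exm_truth` (read).
#' @export
write_exm_truth <- function(truth, path) {
  stopifnot(inherits(truth, "exm_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_exm_truth
#' @export
read_exm_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$synapse_positions <- as.numeric(x$synapse_positions)
  x$decoy_positions <- as.numeric(x$decoy_positions)
  rec <- as.data.frame(x$punctum_records)
  if (!nrow(rec)) {
    rec <- data.frame(arc_length_pre = numeric(), azimuth = numeric(),
                      diameter = numeric(), label = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  }
  x$punctum_records <- rec
  structure(x, class = "exm_truth")
}
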