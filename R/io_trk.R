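# TrackVis .trk tractogram I/O.
#
# The .trk format stores points in "voxmm" coordinates (0-based voxel index
# scaled by voxel size) with a 1000-byte header; header version 2 carries the
# voxel-to-world affine, which lets the reader recover world mm exactly (to
# float32 precision). One per-track property slot holds each streamline's
# mean FA.

trk_pad <- function(x, n) {
  r <- as.raw(rep(0L, n))
  b <- charToRaw(x)
  r[seq_along(b)] <- b
  r
}

#' Write a tractogram to TrackVis .trk
#'
#' @param tract a `tractogram`.
#' @param path output path.
#' @param vol the `tensor_volume` the tracks live in (supplies grid dims,
#'   voxel size and the voxel-to-world affine stored in the header).
#' @return the path, invisibly.
#' @export
write_trk <- function(tract, path, vol) {
  con <- file(path, "wb")
  on.exit(close(con))
  inv <- solve(vol$affine)
  vs <- vol$voxel_size
  writeBin(trk_pad("TRACK", 6L), con)
  writeBin(as.integer(vol$dim), con, size = 2L)                 # dim[3]
  writeBin(as.numeric(vs), con, size = 4L)                      # voxel_size
  writeBin(numeric(3), con, size = 4L)                          # origin
  writeBin(0L, con, size = 2L)                                  # n_scalars
  writeBin(as.raw(rep(0L, 200L)), con)                          # scalar names
  writeBin(1L, con, size = 2L)                                  # n_properties
  writeBin(trk_pad("mean_fa", 20L), con)
  writeBin(as.raw(rep(0L, 180L)), con)                          # rest of names
  writeBin(as.numeric(t(vol$affine)), con, size = 4L)           # vox_to_ras
  writeBin(as.raw(rep(0L, 444L)), con)                          # reserved
  writeBin(trk_pad("RAS", 4L), con)                             # voxel_order
  writeBin(as.raw(rep(0L, 4L)), con)                            # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4L)     # orientation
  writeBin(as.raw(rep(0L, 2L)), con)                            # pad1
  writeBin(as.raw(rep(0L, 6L)), con)                            # invert/swap
  writeBin(length(tract$streamlines), con, size = 4L)           # n_count
  writeBin(2L, con, size = 4L)                                  # version
  writeBin(1000L, con, size = 4L)                               # hdr_size
  for (s in tract$streamlines) {
    vox <- t(inv %*% rbind(t(s$points), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(vox, 2, vs, `*`)
    writeBin(nrow(voxmm), con, size = 4L)
    writeBin(as.numeric(t(voxmm)), con, size = 4L)
    writeBin(as.numeric(s$mean_fa), con, size = 4L)
  }
  invisible(path)
}

#' Read a TrackVis .trk tractogram
#'
#' @param path a `.trk` file written by [write_trk()] (header version 2).
#' @return a `tractogram` with points converted back to world mm via the
#'   header affine; the `mean_fa` property is restored per streamline.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (magic != "TRACK") stop("not a TrackVis file: ", path)
  dims <- readBin(con, "integer", 3L, size = 2L)
  vs <- readBin(con, "numeric", 3L, size = 4L)
  readBin(con, "numeric", 3L, size = 4L)          # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  n_props <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "raw", 200L)
  affine <- matrix(readBin(con, "numeric", 16L, size = 4L), 4L, 4L,
                   byrow = TRUE)
  readBin(con, "raw", 444L + 4L + 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L)
  version <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 4L)          # hdr_size
  streamlines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1L, size = 4L)
    pts <- matrix(readBin(con, "numeric", np * (3L + n_scalars), size = 4L),
                  ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    props <- readBin(con, "numeric", n_props, size = 4L)
    vox <- sweep(pts, 2, vs, `/`)
    world <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    seg <- diff(world)
    streamlines[[i]] <- list(
      points = world,
      mean_fa = if (n_props >= 1L) props[1] else NA_real_,
      length = sum(sqrt(rowSums(seg^2))))
  }
  structure(list(streamlines = streamlines, params = NULL),
            class = "tractogram")
}
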