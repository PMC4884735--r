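#' Deterministic tracking parameters
#'
#' Defaults follow the standard deterministic streamline configuration for
#' this mapping framework: FA threshold 0.14, turning-angle threshold 45
#' degrees, 0.5 mm steps, momentum smoothing 0.5, one seed per voxel, and a
#' 30--300 mm fiber length constraint to exclude misidentified fibers.
#'
#' `smoothing` is a momentum weight s in [0, 1): each new step direction is
#' `normalize((1 - s) * v_field + s * v_previous)`.
#'
#' @param fa_threshold terminate when interpolated FA falls below this.
#' @param turning_angle_deg terminate when the field direction turns by more
#'   than this from the previous step direction.
#' @param step_mm integration step in mm.
#' @param smoothing momentum weight in [0, 1).
#' @param seeds_per_voxel seeds placed per mask voxel (at the voxel center;
#'   additional seeds are uniformly jittered inside the voxel).
#' @param min_len_mm,max_len_mm retained fiber length range, inclusive.
#' @param rng_seed seed for jittered seeding (unused at 1 seed/voxel).
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(fa_threshold = 0.14, turning_angle_deg = 45,
                            step_mm = 0.5, smoothing = 0.5,
                            seeds_per_voxel = 1L, min_len_mm = 30,
                            max_len_mm = 300, rng_seed = 1L) {
  stopifnot(fa_threshold >= 0, fa_threshold <= 1,
            turning_angle_deg > 0, turning_angle_deg <= 90,
            step_mm > 0, smoothing >= 0, smoothing < 1,
            seeds_per_voxel >= 1L)
  if (min_len_mm > max_len_mm)
    stop("min_len_mm must not exceed max_len_mm")
  structure(list(fa_threshold = fa_threshold,
                 turning_angle_deg = turning_angle_deg, step_mm = step_mm,
                 smoothing = smoothing,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 min_len_mm = min_len_mm, max_len_mm = max_len_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Sample FA and principal diffusion direction at world points
#'
#' Trilinearly interpolates the six tensor components, then
#' eigen-decomposes the interpolated tensor. The eigenvector sign is chosen
#' to align with `reference` (tensors are sign-symmetric).
#'
#' @param vol a `tensor_volume` carrying a tensor grid.
#' @param points n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @param reference n x 3 matrix (or length-3 vector) of reference
#'   directions for the sign choice; default +x.
#' @return list with `fa` (NA outside the grid), `dir` (n x 3) and `inside`.
#' @export
sample_field <- function(vol, points, reference = c(1, 0, 0)) {
  if (is.null(vol$tensor)) stop("volume carries no tensor grid")
  points <- matrix(as.numeric(points), ncol = 3L)
  reference <- matrix(as.numeric(reference), ncol = 3L)
  if (nrow(reference) == 1L)
    reference <- reference[rep(1L, nrow(points)), , drop = FALSE]
  res <- cpp_sample_field(vol$tensor, vol$dim, solve(vol$affine), points,
                          reference)
  list(fa = as.numeric(res$fa), dir = res$dir, inside = res$inside)
}

streamline_from_cpp <- function(raw, params, seed_voxel = NA_integer_) {
  if (is.null(raw)) return(NULL)
  seg <- diff(raw$points)
  structure(list(points = raw$points, fa = raw$fa,
                 length = sum(sqrt(rowSums(seg^2))),
                 mean_fa = mean(raw$fa),
                 seed_voxel = seed_voxel),
            class = "streamline")
}

#' Track one streamline from a seed point
#'
#' Integrates bidirectionally along the principal eigenvector field from the
#' seed, momentum-blending directions, and terminates a branch when the FA
#' falls below threshold, the field turns more than the angle threshold, or
#' the track leaves the grid. The two branches are concatenated. No length
#' filter is applied here (that belongs to mask-seeded tracking).
#'
#' @param vol a `tensor_volume`.
#' @param seed length-3 world mm point.
#' @param params a `tracking_params`.
#' @return a `streamline` (points, per-point FA, length mm, mean FA), or
#'   `NULL` if the seed itself fails the FA threshold or lies outside the
#'   grid.
#' @export
track_streamline <- function(vol, seed, params = tracking_params()) {
  res <- cpp_track(vol$tensor, vol$dim, solve(vol$affine),
                   matrix(as.numeric(seed), 1L, 3L),
                   params$fa_threshold, params$turning_angle_deg,
                   params$step_mm, params$smoothing, params$max_len_mm)
  streamline_from_cpp(res[[1]], params)
}

#' Track all streamlines from a voxel seed mask
#'
#' One seed per mask voxel at the voxel center (additional seeds per voxel,
#' if requested, are uniformly jittered using `params$rng_seed`). Resulting
#' streamlines are filtered to the closed length interval
#' `[min_len_mm, max_len_mm]`.
#'
#' @param vol a `tensor_volume`.
#' @param mask integer vector of 1-based linear voxel ids, or an n x 3 matrix
#'   of 0-based voxel ijk indices.
#' @param params a `tracking_params`.
#' @return a `tractogram`: list of retained `streamline`s plus the params as
#'   provenance.
#' @export
track_from_mask <- function(vol, mask, params = tracking_params()) {
  if (is.matrix(mask)) ijk <- mask
  else ijk <- voxel_id_to_ijk(vol$dim, mask)
  if (nrow(ijk) == 0L)
    return(structure(list(streamlines = list(), params = params),
                     class = "tractogram"))
  seeds <- voxel_to_world(vol, ijk)
  seed_vox <- voxel_linear_id(vol$dim, ijk)
  if (params$seeds_per_voxel > 1L) {
    extra <- with_seed(params$rng_seed, {
      k <- params$seeds_per_voxel - 1L
      jit <- matrix(stats::runif(nrow(ijk) * k * 3L, -0.5, 0.5),
                    ncol = 3L)
      base <- ijk[rep(seq_len(nrow(ijk)), each = k), , drop = FALSE]
      voxel_to_world(vol, base + jit)
    })
    seeds <- rbind(seeds, extra)
    seed_vox <- c(seed_vox, rep(seed_vox, each = params$seeds_per_voxel - 1L))
  }
  res <- cpp_track(vol$tensor, vol$dim, solve(vol$affine), seeds,
                   params$fa_threshold, params$turning_angle_deg,
                   params$step_mm, params$smoothing, params$max_len_mm)
  eps <- 1e-9
  out <- list()
  for (i in seq_along(res)) {
    s <- streamline_from_cpp(res[[i]], params, seed_vox[i])
    if (is.null(s)) next
    if (s$length >= params$min_len_mm - eps &&
        s$length <= params$max_len_mm + eps)
      out[[length(out) + 1L]] <- s
  }
  structure(list(streamlines = out, params = params), class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  if (n) {
    lens <- vapply(x$streamlines, `[[`, 0, "length")
    fas <- vapply(x$streamlines, `[[`, 0, "mean_fa")
    cat(sprintf(
      "tractogram: %d streamlines, length %.1f-%.1f mm, mean FA %.3f\n",
      n, min(lens), max(lens), mean(fas)))
  } else cat("tractogram: 0 streamlines\n")
  invisible(x)
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, %.1f mm, mean FA %.3f\n",
              nrow(x$points), x$length, x$mean_fa))
  invisible(x)
}

#' Number of streamlines in a tractogram
#' @param tract a `tractogram`.
#' @return integer count.
#' @export
n_streamlines <- function(tract) length(tract$streamlines)
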