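#' The FiCD statistic for one cortical unit
#'
#' Fiber connectivity density: the per-fiber mean FA values of all fibers
#' seeded from the unit are summed and divided by the unit's seed volume
#' (mm^3), correcting for inhomogeneity in unit size. An empty fiber set
#' gives 0.
#'
#' @param tracks a `tractogram` of the unit's seeded, length-filtered
#'   streamlines, or a numeric vector of per-fiber mean FA values.
#' @param seed_volume the unit's seed-mask volume in mm^3 (> 0).
#' @return the FiCD value (>= 0), or `NA` if `seed_volume` is 0 (undefined;
#'   such units are excluded from statistics).
#' @export
compute_ficd <- function(tracks, seed_volume) {
  if (inherits(tracks, "tractogram"))
    fas <- vapply(tracks$streamlines, `[[`, 0, "mean_fa")
  else fas <- as.numeric(tracks)
  if (seed_volume <= 0) return(NA_real_)
  sum(fas) / seed_volume
}

#' Project per-CU values to a per-vertex map
#'
#' Every vertex carries the value of its owning CU (face-majority ownership,
#' ties to the lower CU id), giving a piecewise-constant vertex map.
#'
#' @param parc a `parcellation`.
#' @param ficd_per_cu numeric vector of length K; `NA` marks undefined CUs.
#' @return numeric vertex map of length V (NA where the owning CU is
#'   undefined).
#' @export
project_to_vertices <- function(parc, ficd_per_cu) {
  if (length(ficd_per_cu) != parc$K)
    stop(sprintf("expected %d CU values, got %d", parc$K,
                 length(ficd_per_cu)))
  as.numeric(ficd_per_cu)[parc$vertex_cu]
}

#' Compute a subject's whole-surface FiCD map
#'
#' Runs the per-CU pipeline: seed-layer extraction, mask-seeded deterministic
#' tracking with length filtering, the FiCD statistic, and projection back to
#' vertices.
#'
#' @param vol the subject's `tensor_volume`.
#' @param parc the `parcellation` of the subject's GM-WM interface.
#' @param params a `tracking_params`.
#' @param thickness seed-layer thickness in mm (default one voxel).
#' @return an object of class `ficd_map`: per-vertex values, per-CU values,
#'   per-CU fiber counts and seed volumes, and provenance.
#' @export
ficd_map <- function(vol, parc, params = tracking_params(),
                     thickness = NULL) {
  masks <- seed_layers(parc, vol, thickness)
  vv <- voxel_volume(vol)
  cu_vals <- numeric(parc$K)
  cu_fn <- integer(parc$K)
  for (cu in seq_len(parc$K)) {
    mask <- masks[[cu]]
    if (!length(mask)) {
      cu_vals[cu] <- NA_real_
      next
    }
    tracks <- track_from_mask(vol, mask, params)
    cu_fn[cu] <- n_streamlines(tracks)
    cu_vals[cu] <- compute_ficd(tracks, length(mask) * vv)
  }
  structure(list(mesh = parc$mesh, values = project_to_vertices(parc, cu_vals),
                 cu_values = cu_vals, cu_fiber_count = cu_fn,
                 cu_seed_volume = vapply(masks, length, 1L) * vv,
                 provenance = list(params = params, thickness = thickness,
                                   K = parc$K)),
            class = "ficd_map")
}

#' @export
print.ficd_map <- function(x, ...) {
  ok <- is.finite(x$cu_values)
  cat(sprintf("ficd_map: %d vertices, %d/%d CUs defined, FiCD %.3g-%.3g\n",
              length(x$values), sum(ok), length(ok),
              min(x$cu_values[ok]), max(x$cu_values[ok])))
  invisible(x)
}

#' Z-transform a vertex map over the hemisphere
#'
#' Subtracts the mean and divides by the sample standard deviation of the
#' whole-hemisphere map (computed over defined vertices), improving normality
#' ahead of the inter-group comparison.
#'
#' @param values numeric vertex map (NA allowed for undefined vertices).
#' @return the transformed map: mean 0, SD 1 over defined vertices.
#' @export
z_transform_hemisphere <- function(values) {
  ok <- is.finite(values)
  if (!any(ok)) stop("no defined vertices")
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) stop("constant map: Z-transform undefined")
  (values - mean(values[ok])) / s
}
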