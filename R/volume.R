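#' Diffusion tensor volume
#'
#' Gridded symmetric diffusion tensors with a voxel-to-world affine, plus the
#' derived fractional anisotropy (FA) and principal-eigenvector grids used by
#' the tracker. Voxel indexing is 0-based and a voxel's world position is the
#' position of its center: `world = affine %*% c(i, j, k, 1)`.
#'
#' @param tensor numeric array `c(dim, 6)` with the unique tensor components in
#'   the order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz; or `NULL` if `fa`/`v1` are given
#'   directly.
#' @param affine 4 x 4 voxel-to-world matrix (mm); must be invertible.
#' @param fa optional precomputed FA array (same spatial grid).
#' @param v1 optional precomputed principal-eigenvector array `c(dim, 3)`.
#' @param provenance optional list recording how the volume was built.
#' @return An object of class `tensor_volume`.
#' @export
tensor_volume <- function(tensor = NULL, affine, fa = NULL, v1 = NULL,
                          provenance = list()) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4 x 4")
  deta <- det(affine[1:3, 1:3])
  if (!is.finite(deta) || abs(deta) < 1e-12)
    stop("affine is not invertible (singular spatial 3 x 3 block)")
  if (is.null(tensor) && (is.null(fa) || is.null(v1)))
    stop("either `tensor` or both `fa` and `v1` must be supplied")
  if (!is.null(tensor)) {
    d <- dim(tensor)
    if (length(d) != 4L || d[4] != 6L)
      stop("tensor must be a 4-D array with 6 components on axis 4, got [",
           paste(d, collapse = ", "), "]")
    dims <- d[1:3]
  } else dims <- dim(fa)
  if (is.null(fa) || is.null(v1)) {
    dv <- tensor_principal(matrix(tensor, ncol = 6L))
    fa <- array(dv$fa, dims)
    v1 <- array(dv$v1, c(dims, 3L))
  }
  stopifnot(all(dim(fa) == dims), all(dim(v1) == c(dims, 3L)))
  structure(list(tensor = tensor, fa = fa, v1 = v1, dim = as.integer(dims),
                 affine = affine, voxel_size = sqrt(colSums(affine[1:3, 1:3]^2)),
                 provenance = provenance),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("tensor_volume: %s grid, voxel %s mm, FA range [%.3f, %.3f]\n",
              paste(x$dim, collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x "),
              min(x$fa), max(x$fa)))
  invisible(x)
}

# FA and principal eigenvector for a matrix of tensor rows
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). Thin wrapper over the compiled routine.
tensor_principal <- function(tensor6) {
  res <- cpp_tensor_principal(tensor6)
  list(fa = res$fa, v1 = res$v1)
}

#' Map voxel indices to world coordinates
#'
#' @param vol a `tensor_volume` (or any object with an `$affine`).
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates (voxel centers).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(vol$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#' @param vol a `tensor_volume`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of fractional voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(solve(vol$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# Linear (column-major) voxel ids <-> 0-based ijk triplets.
voxel_linear_id <- function(dim, ijk) {
  as.integer(ijk[, 1] + dim[1] * (ijk[, 2] + dim[2] * ijk[, 3]) + 1)
}

voxel_id_to_ijk <- function(dim, id) {
  id0 <- as.integer(id) - 1L
  i <- id0 %% dim[1]
  j <- (id0 %/% dim[1]) %% dim[2]
  k <- id0 %/% (dim[1] * dim[2])
  cbind(i, j, k)
}

#' Volume of one voxel in mm^3
#' @param vol a `tensor_volume`.
#' @return scalar mm^3.
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))
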