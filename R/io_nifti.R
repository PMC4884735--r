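# NIfTI-1 volume I/O (via RNifti).
#
# World convention: NIfTI's own, world = affine %*% c(i, j, k, 1) with
# 0-based voxel indices and voxel centers at integer coordinates — the same
# convention used throughout the package.

nifti_with_affine <- function(data, affine) {
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(sqrt(colSums(affine[1:3, 1:3]^2)),
                           rep(1, max(0L, nd - 3L)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img
}

#' Write a tensor volume (or one of its derived grids) to NIfTI
#'
#' @param vol a `tensor_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param what `"tensor"` (4-D, 6 components: Dxx, Dxy, Dxz, Dyy, Dyz, Dzz),
#'   `"fa"` (3-D) or `"v1"` (4-D, 3 components).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, what = c("tensor", "fa", "v1")) {
  what <- match.arg(what)
  data <- switch(what,
    tensor = {
      if (is.null(vol$tensor)) stop("volume carries no tensor grid")
      vol$tensor
    },
    fa = vol$fa,
    v1 = vol$v1)
  RNifti::writeNifti(nifti_with_affine(data, vol$affine), path)
  invisible(path)
}

#' Read a tensor volume from NIfTI
#'
#' Accepts either a 4-D tensor volume with 6 components on the 4th axis, or
#' (with `fa_path`/`v1_path`) a precomputed FA + principal-eigenvector pair.
#'
#' @param path NIfTI file with the 6 tensor components, or `NULL`.
#' @param fa_path,v1_path alternative inputs: 3-D FA plus 4-D eigenvector
#'   volumes (3 components).
#' @return a `tensor_volume`.
#' @export
read_volume <- function(path = NULL, fa_path = NULL, v1_path = NULL) {
  if (!is.null(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L || d[4] != 6L)
      stop(sprintf(
        "expected a 4-D tensor volume with 6 components on axis 4, got [%s]",
        paste(d, collapse = ", ")))
    return(tensor_volume(tensor = array(as.numeric(img), d),
                         affine = unclass(RNifti::xform(img))[1:4, 1:4]))
  }
  if (is.null(fa_path) || is.null(v1_path))
    stop("supply `path`, or both `fa_path` and `v1_path`")
  fa_img <- RNifti::readNifti(fa_path)
  v1_img <- RNifti::readNifti(v1_path)
  if (length(dim(fa_img)) != 3L)
    stop("FA volume must be 3-D, got ", length(dim(fa_img)), " dims")
  if (length(dim(v1_img)) != 4L || dim(v1_img)[4] != 3L)
    stop(sprintf(
      "eigenvector volume must have 3 components on axis 4, got [%s]",
      paste(dim(v1_img), collapse = ", ")))
  tensor_volume(affine = unclass(RNifti::xform(fa_img))[1:4, 1:4],
                fa = array(as.numeric(fa_img), dim(fa_img)),
                v1 = array(as.numeric(v1_img), dim(v1_img)))
}
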