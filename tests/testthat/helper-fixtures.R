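# Shared fixtures, built once per test session and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) assign(key, fn(), envir = .fixtures)
  .fixtures[[key]]
}

# spheres at the package's standard phantom radius
sphere_mesh <- function(subdiv, radius = 50) {
  fixture(sprintf("sphere_%d_%g", subdiv, radius), function()
    make_cortex_mesh(phantom_spec(mesh_subdiv = subdiv,
                                  mesh_radius = radius)))
}

# straight +x bundle through a 60 mm box, 2 mm voxels
straight_bundle_volume <- function() {
  fixture("straight_bundle", function()
    make_tensor_phantom(phantom_spec(
      grid_shape = c(30, 30, 30), voxel_size = 2,
      bundles = list(list(points = cbind(c(-10, 70), 29, 29),
                          radius = 6, fa = 0.8)),
      fa_background = 0.05)))
}

# quarter-circle arc bundle of radius 20 mm in the xy-plane; 1 mm voxels so
# the rasterized tangent field follows the arc closely
arc_bundle_volume <- function() {
  fixture("arc_bundle", function() {
    theta <- seq(0, pi / 2, length.out = 128)
    pts <- cbind(14 + 20 * cos(theta), 14 + 20 * sin(theta), 24)
    make_tensor_phantom(phantom_spec(
      grid_shape = c(48, 48, 48), voxel_size = 1,
      bundles = list(list(points = pts, radius = 5, fa = 0.8)),
      fa_background = 0.05))
  })
}

# flat z = 0 plane mesh spanning [0, n] x [0, n], outward normal +z
plane_mesh <- function(n = 9) {
  g <- expand.grid(x = 0:n, y = 0:n)
  verts <- cbind(g$x, g$y, 0)
  id <- function(i, j) i + (n + 1L) * j + 1L
  faces <- NULL
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    faces <- rbind(faces,
                   c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                   c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(verts, faces)
}

# volume whose voxel centers sit at z in {-1.5, -0.5, 0.5, 1.5} under the
# plane mesh footprint (1 mm voxels)
plane_volume <- function(n = 9) {
  affine <- diag(4)
  affine[3, 4] <- -1.5
  dm <- c(n + 1L, n + 1L, 4L)
  fa <- array(0.05, dm)
  v1 <- array(0, c(dm, 3L)); v1[, , , 1] <- 1
  tensor <- array(0, c(dm, 6L))
  bg <- ficdmap:::tensor_from_fa_dir(0.05, c(1, 0, 0))
  for (c in 1:6) tensor[, , , c] <- bg[c]
  tensor_volume(tensor = tensor, affine = affine, fa = fa, v1 = v1)
}
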