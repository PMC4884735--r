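test_that("straight bundle voxels carry the bundle FA and tangent direction", {
  vol <- straight_bundle_volume()
  # voxel centers on the bundle axis
  on_axis <- which(vol$fa > 0.5)
  expect_gt(length(on_axis), 0)
  expect_true(all(abs(vol$fa[on_axis] - 0.8) < 1e-12))
  ijk <- ficdmap:::voxel_id_to_ijk(vol$dim, on_axis)
  dirs <- matrix(vol$v1[cbind(rep(ijk[, 1] + 1L, 3), rep(ijk[, 2] + 1L, 3),
                              rep(ijk[, 3] + 1L, 3), rep(1:3, each = nrow(ijk)))],
                 ncol = 3)
  # eigenvector is +-x everywhere inside the bundle
  expect_true(all(abs(abs(dirs[, 1]) - 1) < 1e-9))
  expect_true(all(abs(vol$fa[-on_axis] - 0.05) < 1e-12))
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- phantom_spec(grid_shape = c(12, 12, 12), voxel_size = 2,
                     bundles = list(list(points = cbind(c(-5, 30), 11, 11),
                                         radius = 4, fa = 0.7)),
                     rng_seed = 42)
  v1 <- make_tensor_phantom(sp)
  v2 <- make_tensor_phantom(sp)
  expect_identical(v1$tensor, v2$tensor)
  expect_identical(v1$fa, v2$fa)
})

test_that("curved-arc bundle tangent matches the analytic circle tangent", {
  vol <- arc_bundle_volume()
  # arc midpoint at 45 degrees: center (14,14,24) + 20*(cos45, sin45, 0)
  mid <- c(14 + 20 * cos(pi / 4), 14 + 20 * sin(pi / 4), 24)
  ijk <- round(world_to_voxel(vol, matrix(mid, 1)))
  d <- vol$v1[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1, ]
  tangent <- c(-sin(pi / 4), cos(pi / 4), 0)
  ang <- acos(min(1, abs(sum(d * tangent)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("overlapping bundles with conflicting directions are recorded", {
  sp <- phantom_spec(grid_shape = c(20, 20, 20), voxel_size = 2,
    bundles = list(
      list(points = cbind(c(-5, 45), 19, 19), radius = 4, fa = 0.8),
      list(points = cbind(19, c(-5, 45), 19), radius = 4, fa = 0.8)))
  vol <- make_tensor_phantom(sp)
  expect_gt(length(vol$provenance$overlap_voxels), 0)
  # last writer wins: crossing voxel points along +-y
  ctr <- round(world_to_voxel(vol, matrix(c(19, 19, 19), 1)))
  d <- vol$v1[ctr[1] + 1, ctr[2] + 1, ctr[3] + 1, ]
  expect_lt(abs(d[1]), 1e-9)
  expect_equal(abs(d[2]), 1, tolerance = 1e-9)
})

test_that("sphere meshes are closed genus-0 surfaces with the right area", {
  m <- sphere_mesh(4)
  expect_true(is_closed_mesh(m))
  expect_identical(euler_characteristic(m), 2L)
  expect_equal(mesh_area(m), 4 * pi * 50^2, tolerance = 0.01)
  # vertices on the requested radius
  r <- sqrt(rowSums(sweep(m$vertices, 2, colMeans(m$vertices))^2))
  expect_true(all(abs(r - 50) < 1e-6))
})

test_that("folded meshes remain closed and manifold", {
  m <- make_cortex_mesh(phantom_spec(mesh_kind = "folded", mesh_subdiv = 3,
                                     mesh_radius = 40, mesh_amplitude = 6))
  expect_true(is_closed_mesh(m))
  expect_identical(euler_characteristic(m), 2L)
  expect_gt(mesh_area(m), 0)
})

test_that("per-vertex areas partition the total surface area", {
  m <- sphere_mesh(3, 25)
  expect_equal(sum(vertex_areas(m)), mesh_area(m), tolerance = 1e-12)
})

test_that("null cohorts show no systematic group difference", {
  m <- sphere_mesh(3, 25)
  # white vertex noise: vertex t values are essentially independent draws
  co <- make_cohort(m, cohort_spec(effect_size = 0, noise_fwhm = 0,
                                   rng_seed = 9))
  stat <- glm_group_contrast(co)
  expect_gt(mean(abs(stat$t) < 3), 0.99)
  # spatially smooth noise: same property, looser because vertex t values
  # are correlated within one draw
  co2 <- make_cohort(m, cohort_spec(effect_size = 0, rng_seed = 9))
  expect_gt(mean(abs(glm_group_contrast(co2)$t) < 3), 0.95)
})

test_that("an injected effect appears at the patch with the right size", {
  m <- sphere_mesh(3, 25)
  patch <- geodesic_patch(m, 50, 60)
  co <- make_cohort(m, cohort_spec(effect_vertices = patch,
                                   effect_size = -0.5, rng_seed = 5))
  grp <- co$covariates$group
  centroid <- patch[which.min(colMeans((t(m$vertices[patch, ]) -
                                        colMeans(m$vertices[patch, ]))^2))]
  a <- co$ficd[centroid, grp == "A"]
  b <- co$ficd[centroid, grp == "B"]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - (-0.5)), 2 * se + 0.05)
})

test_that("cohort generation is deterministic and validates its inputs", {
  m <- sphere_mesh(3, 25)
  c1 <- make_cohort(m, cohort_spec(rng_seed = 77))
  c2 <- make_cohort(m, cohort_spec(rng_seed = 77))
  expect_identical(c1$ficd, c2$ficd)
  expect_identical(c1$covariates, c2$covariates)
  expect_error(cohort_spec(effect_size = -1, effect_vertices = integer(0)),
               "effect_vertices")
  expect_error(make_cohort(m, cohort_spec(effect_vertices = 10^6,
                                          effect_size = 1)),
               "outside")
})

test_that("severity couples to the realized effect with the requested sign", {
  m <- sphere_mesh(3, 25)
  patch <- geodesic_patch(m, 100, 80)
  co <- make_cohort(m, cohort_spec(effect_vertices = patch, effect_size = -0.5,
                                   severity_coupling = -20,
                                   severity_noise_sd = 0.5, rng_seed = 21))
  # negative coupling: severity rises as the (negative) effect deepens
  expect_lt(cor(co$covariates$severity, co$covariates$realized_effect), -0.8)
})
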