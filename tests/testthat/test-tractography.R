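test_that("field sampling interpolates constants and voxel centers exactly", {
  vol <- straight_bundle_volume()
  # voxel center: exactly that voxel's FA
  s <- sample_field(vol, c(29, 29, 29))
  ijk <- round(world_to_voxel(vol, matrix(c(29, 29, 29), 1)))
  expect_equal(s$fa, vol$fa[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1],
               tolerance = 1e-12)
  # inside the uniform bundle interior, any off-grid point gives the same
  # constant tensor
  s2 <- sample_field(vol, c(29.37, 29.21, 28.77))
  expect_equal(s2$fa, 0.8, tolerance = 1e-9)
  expect_equal(abs(s2$dir[1]), 1, tolerance = 1e-9)
  # outside the grid: NA sentinel
  expect_true(is.na(sample_field(vol, c(-50, 0, 0))$fa))
})

test_that("midpoint FA equals the FA of the averaged tensor", {
  # two diagonal tensors sharing eigenvectors, FA 0.2 and 0.8
  t_lo <- ficdmap:::tensor_from_fa_dir(0.2, c(1, 0, 0))
  t_hi <- ficdmap:::tensor_from_fa_dir(0.8, c(1, 0, 0))
  dm <- c(2, 2, 2)
  tens <- array(rep(t_lo, each = 8), c(dm, 6))
  tens[2, , , ] <- rep(t_hi, each = 4)  # x = 1 plane carries the high-FA tensor
  vol <- tensor_volume(tensor = tens, affine = diag(4))
  s <- sample_field(vol, c(0.5, 0, 0))
  tm <- (t_lo + t_hi) / 2
  D <- matrix(c(tm[1], tm[2], tm[3], tm[2], tm[4], tm[5], tm[3], tm[5], tm[6]),
              3, 3)
  ev <- eigen(D, symmetric = TRUE)$values
  fa_oracle <- sqrt(1.5 * sum((ev - mean(ev))^2) / sum(ev^2))
  expect_equal(s$fa, fa_oracle, tolerance = 1e-12)
})

test_that("uniform-field streamlines are straight and span the box", {
  vol <- straight_bundle_volume()
  st <- track_streamline(vol, c(29, 29, 29), tracking_params())
  # straight: all points on the y = z = 29 line within 2 steps
  expect_lt(max(abs(st$points[, 2] - 29)), 2 * 0.5)
  expect_lt(max(abs(st$points[, 3] - 29)), 2 * 0.5)
  # length matches the box extent (58 mm of voxel centers) within 2 steps
  expect_lt(abs(st$length - 58), 2 * 0.5 + 1e-9)
})

test_that("a seed below the FA threshold yields no streamline", {
  sp <- phantom_spec(grid_shape = c(20, 20, 20), voxel_size = 2,
                     fa_background = 0.10)
  vol <- make_tensor_phantom(sp)
  expect_null(track_streamline(vol, c(19, 19, 19), tracking_params()))
  # background 0.15 is above the 0.14 threshold: tracking proceeds
  sp2 <- phantom_spec(grid_shape = c(20, 20, 20), voxel_size = 2,
                      fa_background = 0.15)
  expect_false(is.null(track_streamline(make_tensor_phantom(sp2),
                                        c(19, 19, 19), tracking_params())))
})

test_that("a 90-degree field flip terminates the track at the interface", {
  # +x field for x < 30, +y field for x >= 30
  dm <- c(30, 30, 30)
  tx <- ficdmap:::tensor_from_fa_dir(0.8, c(1, 0, 0))
  ty <- ficdmap:::tensor_from_fa_dir(0.8, c(0, 1, 0))
  tens <- array(0, c(dm, 6))
  for (c in 1:6) {
    tens[, , , c] <- tx[c]
    tens[16:30, , , c] <- ty[c]
  }
  vol <- tensor_volume(tensor = tens, affine = diag(c(2, 2, 2, 1)))
  st <- track_streamline(vol, c(10, 29, 29), tracking_params())
  # the +x branch terminates near the x = 30 interface instead of turning
  expect_lt(max(st$points[, 1]), 32)
  expect_lt(max(abs(st$points[, 2] - 29)), 1e-6)
})

test_that("length filtering respects the closed 30-300 mm interval", {
  # 20 mm bundle: everything dies under the 30 mm minimum
  sp <- phantom_spec(grid_shape = c(30, 30, 30), voxel_size = 2,
    bundles = list(list(points = cbind(c(20, 40), 29, 29),
                        radius = 4, fa = 0.8)),
    fa_background = 0.05)
  vol <- make_tensor_phantom(sp)
  mask <- which(vol$fa > 0.5)
  expect_identical(n_streamlines(track_from_mask(vol, mask,
                                                 tracking_params())), 0L)

  # uniform 30 mm grid: every track has length exactly 30.0 and is retained
  dm <- c(31, 31, 31)
  tu <- ficdmap:::tensor_from_fa_dir(0.8, c(1, 0, 0))
  tens <- array(rep(tu, each = prod(dm)), c(dm, 6))
  vol30 <- tensor_volume(tensor = tens, affine = diag(4))
  ctr <- matrix(c(15, 15, 15), 1)
  tr <- track_from_mask(vol30, round(world_to_voxel(vol30, ctr)),
                        tracking_params())
  expect_identical(n_streamlines(tr), 1L)
  expect_equal(tr$streamlines[[1]]$length, 30, tolerance = 1e-9)
  # raising the minimum just past 30 excludes it
  tr2 <- track_from_mask(vol30, round(world_to_voxel(vol30, ctr)),
                         tracking_params(min_len_mm = 30.01))
  expect_identical(n_streamlines(tr2), 0L)
})

test_that("every mask voxel in a long bundle yields a surviving streamline", {
  vol <- straight_bundle_volume()
  mask <- which(vol$fa > 0.5)
  mask <- mask[seq(1, length(mask), by = 3)][1:100]
  tr <- track_from_mask(vol, mask, tracking_params())
  expect_identical(n_streamlines(tr), 100L)
  lens <- vapply(tr$streamlines, `[[`, 0, "length")
  expect_true(all(lens >= 30 & lens <= 300))
})

test_that("emitted streamlines satisfy their own invariants on re-walking", {
  vol <- arc_bundle_volume()
  mask <- which(vol$fa > 0.5)
  p <- tracking_params()
  tr <- track_from_mask(vol, mask[seq(1, length(mask), 7)], p)
  expect_gt(n_streamlines(tr), 0)
  for (s in tr$streamlines) {
    seg <- diff(s$points)
    seg <- seg / sqrt(rowSums(seg^2))
    if (nrow(seg) > 1) {
      cosang <- rowSums(seg[-nrow(seg), , drop = FALSE] *
                        seg[-1, , drop = FALSE])
      expect_true(all(cosang >= cos(p$turning_angle_deg * pi / 180) - 1e-9))
    }
    fa <- sample_field(vol, s$points)$fa
    expect_true(all(fa >= p$fa_threshold - 1e-9))
  }
})

test_that("streamline points stay within 2 steps of the analytic arc", {
  vol <- arc_bundle_volume()
  seed <- c(14 + 20 * cos(pi / 4), 14 + 20 * sin(pi / 4), 24)
  # momentum off isolates integration fidelity: the momentum blend lags the
  # rotating tangent and adds a known drift of (total turn) * s/(1-s) * step
  # compare against the arc over its angular span; past the arc's endpoints
  # the tube's rounded caps extend straight and leave the circle by design
  on_arc <- function(p) {
    th <- atan2(p[, 2] - 14, p[, 1] - 14)
    th >= 0 & th <= pi / 2
  }
  st0 <- track_streamline(vol, seed,
                          tracking_params(smoothing = 0, min_len_mm = 0))
  r0 <- sqrt((st0$points[, 1] - 14)^2 + (st0$points[, 2] - 14)^2)
  expect_lt(max(abs(r0[on_arc(st0$points)] - 20)), 2 * 0.5)
  # with the default momentum the track must still hug the bundle: analytic
  # lag drift bound plus two steps
  st <- track_streamline(vol, seed, tracking_params(min_len_mm = 0))
  r <- sqrt((st$points[, 1] - 14)^2 + (st$points[, 2] - 14)^2)
  expect_lt(max(abs(r[on_arc(st$points)] - 20)), (pi / 2) * 0.5 + 2 * 0.5)
})

test_that("tracked length in a uniform field is step-size invariant", {
  vol <- straight_bundle_volume()
  l1 <- track_streamline(vol, c(29, 29, 29), tracking_params())$length
  l2 <- track_streamline(vol, c(29, 29, 29),
                         tracking_params(step_mm = 0.25))$length
  expect_lt(abs(l1 - l2), 0.5 + 1e-9)
})

test_that("tensor sign symmetry: reversed bundle orientation tracks identically", {
  fwd <- make_tensor_phantom(phantom_spec(grid_shape = c(30, 30, 30),
    voxel_size = 2,
    bundles = list(list(points = cbind(c(-10, 70), 29, 29), radius = 6,
                        fa = 0.8)), fa_background = 0.05))
  rev <- make_tensor_phantom(phantom_spec(grid_shape = c(30, 30, 30),
    voxel_size = 2,
    bundles = list(list(points = cbind(c(70, -10), 29, 29), radius = 6,
                        fa = 0.8)), fa_background = 0.05))
  expect_identical(fwd$tensor, rev$tensor)
  s1 <- track_streamline(fwd, c(29, 29, 29), tracking_params())
  s2 <- track_streamline(rev, c(29, 29, 29), tracking_params())
  expect_equal(s1$length, s2$length, tolerance = 1e-12)
})

test_that("tracking parameter invariants are enforced", {
  expect_error(tracking_params(min_len_mm = 300, max_len_mm = 30), "min_len")
  expect_error(tracking_params(fa_threshold = 1.2))
  expect_error(tracking_params(smoothing = 1))
  expect_error(tracking_params(turning_angle_deg = 0))
})
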