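test_that("two-sample t and U match brute-force oracles", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  rt <- two_sample_t(a, b)
  # direct formula
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(rt$t, t_oracle, tolerance = 1e-12)
  ru <- mann_whitney_u(a, b)
  # exhaustive pair count: #{(i, j): a_i > b_j} (+ half ties)
  u_oracle <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(ru$U), u_oracle)      # 0 here
  # antisymmetry
  expect_equal(two_sample_t(b, a)$t, -rt$t, tolerance = 1e-12)
  expect_equal(unname(mann_whitney_u(b, a)$U), 9 - u_oracle)
})

test_that("degenerate group comparisons are handled", {
  a <- c(1, 2, 3)
  rt <- two_sample_t(a, a)
  expect_equal(rt$t, 0)
  expect_equal(rt$p, 1)
  r0 <- two_sample_t(c(1, 1), c(1, 1))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  rinf <- two_sample_t(c(2, 2), c(1, 1))
  expect_true(is.infinite(rinf$t) && rinf$t > 0)
  expect_equal(rinf$p, 0)
})

test_that("random inputs reproduce stats oracles to 1e-8", {
  set.seed(19)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(7, 0.5)
    ht <- t.test(a, b, var.equal = TRUE)
    expect_equal(two_sample_t(a, b)$t, unname(ht$statistic),
                 tolerance = 1e-8)
    expect_equal(two_sample_t(a, b)$p, ht$p.value, tolerance = 1e-8)
    hu <- wilcox.test(a, b)
    expect_equal(mann_whitney_u(a, b)$U, unname(hu$statistic),
                 tolerance = 1e-12)
    u_brute <- sum(outer(a, b, ">"))
    expect_equal(unname(mann_whitney_u(a, b)$U), u_brute)
  }
})

test_that("partial correlation: identities and the three-correlation form", {
  set.seed(20)
  z <- rnorm(20)
  x <- rnorm(20)
  # y = x: perfect dependence survives partialling
  expect_equal(partial_correlation(x, x + 0 * z, z)$r, 1, tolerance = 1e-12)
  # y = z: dependence fully explained by the control
  expect_equal(partial_correlation(x, z, z)$r, 0)
  expect_equal(partial_correlation(z, x, z)$r, 0)
  # closed-form identity on a random dataset
  y <- 0.6 * x + 0.3 * z + rnorm(20)
  pc <- partial_correlation(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  r_oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(pc$r, r_oracle, tolerance = 1e-8)
  tt <- r_oracle * sqrt(17 / (1 - r_oracle^2))
  expect_equal(pc$p, 2 * pt(-abs(tt), 17), tolerance = 1e-10)
  expect_error(partial_correlation(rep(1, 20), y, z), "non-constant")
})

test_that("the normality gate switches to the U test for skewed data", {
  set.seed(21)
  a <- rnorm(15)
  b <- rnorm(15)
  expect_identical(group_compare(a, b)$method, "t")
  expect_identical(group_compare(exp(rnorm(30, 0, 2)), b)$method, "u")
  expect_identical(group_compare(a, b, method = "u")$method, "u")
})

test_that("cluster metric extraction matches constant-map expectations", {
  m <- sphere_mesh(2, 25)
  co <- make_cohort(m, cohort_spec(n_group_a = 3, n_group_b = 3,
                                   rng_seed = 2))
  vids <- geodesic_patch(m, 1, 20)
  co$ficd[] <- 0.6
  met <- extract_cluster_metrics(list(vertices = vids), co)
  expect_true(all(abs(met$mean_ficd - 0.6) < 1e-12))
  expect_equal(met$gm_volume,
               unname(colSums(co$gmvol[vids, , drop = FALSE])),
               tolerance = 1e-12)
  # scaling linearity
  co2 <- co
  co2$ficd <- 3 * co$ficd
  met2 <- extract_cluster_metrics(list(vertices = vids), co2)
  expect_equal(met2$mean_ficd, 3 * met$mean_ficd, tolerance = 1e-12)
})

test_that("cluster-seeded tracking returns the bundle's fiber count and FA", {
  sp <- phantom_spec(grid_shape = c(30, 30, 30), voxel_size = 2,
    bundles = list(list(points = cbind(c(-10, 70), 29, 29), radius = 8,
                        fa = 0.8)),
    fa_background = 0.05, mesh_subdiv = 3, mesh_radius = 20)
  vol <- make_tensor_phantom(sp)
  mesh <- make_cortex_mesh(sp)
  co <- make_cohort(mesh, cohort_spec(n_group_a = 2, n_group_b = 2,
                                      rng_seed = 1))
  # cluster at the sphere's +x pole, where the bundle crosses the surface
  ctr <- colMeans(mesh$vertices)
  pole <- which.max(mesh$vertices[, 1])
  vids <- geodesic_patch(mesh, pole, 30)
  met <- extract_cluster_metrics(list(vertices = vids), co, vol = vol)
  expect_true(all(met$fn > 0))
  expect_true(all(met$fn == met$fn[1]))  # shared phantom volume
  expect_equal(met$mean_fiber_fa[1], 0.8, tolerance = 1e-6)
  # oracle: the same mask tracked directly
  f <- mesh$faces
  inc <- matrix(f %in% vids, nrow(f), 3)
  mask <- extract_seed_layer(mesh, vol, as.integer(rowSums(inc) >= 2))[["1"]]
  expect_identical(met$fn[1], n_streamlines(track_from_mask(vol, mask)))
})

test_that("roi_report recovers the generator's severity coupling", {
  m <- sphere_mesh(3, 25)
  patch <- geodesic_patch(m, 100, 80)
  co <- make_cohort(m, cohort_spec(effect_vertices = patch,
                                   effect_size = -0.5, effect_sd = 0.15,
                                   severity_coupling = -20,
                                   severity_noise_sd = 0.5, rng_seed = 31))
  rep <- roi_report(co, list(list(vertices = patch)))
  row <- rep[rep$analysis == "pcor_severity_ficd" & rep$group == "A", ]
  expect_lt(row$statistic, 0)
  expect_lt(row$p, 0.05)
  expect_identical(nrow(rep), 2L + 6L)  # 2 group tests + 3 pcor x 2 groups
})

test_that("null cohorts give small ROI correlations", {
  m <- sphere_mesh(3, 25)
  patch <- geodesic_patch(m, 100, 80)
  set.seed(40)
  rs <- sapply(1:20, function(i) {
    co <- make_cohort(m, cohort_spec(rng_seed = 100 + i))
    rep <- roi_report(co, list(list(vertices = patch)))
    rep[rep$analysis == "pcor_severity_ficd" & rep$group == "A",
        "statistic"]
  })
  expect_lt(abs(mean(rs)), 0.2)
  expect_lt(max(abs(rs)), 0.8)
})
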