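test_that("vertex GLM reproduces the pooled two-sample t everywhere", {
  m <- sphere_mesh(3, 25)
  co <- make_cohort(m, cohort_spec(rng_seed = 8))
  stat <- glm_group_contrast(co)
  grp <- co$covariates$group
  expect_identical(stat$df, nrow(co$covariates) - 2L)
  # closed-form oracle at every vertex
  na <- sum(grp == "A"); nb <- sum(grp == "B")
  ma <- rowMeans(co$ficd[, grp == "A"])
  mb <- rowMeans(co$ficd[, grp == "B"])
  va <- apply(co$ficd[, grp == "A"], 1, var)
  vb <- apply(co$ficd[, grp == "B"], 1, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t_oracle <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  expect_lt(max(abs(stat$t - t_oracle)), 1e-8)
  expect_lt(max(abs(stat$p - 2 * pt(-abs(t_oracle), na + nb - 2))), 1e-10)
})

test_that("identical groups with zero noise give t = 0, p = 1", {
  m <- sphere_mesh(2, 25)
  co <- make_cohort(m, cohort_spec(n_group_a = 3, n_group_b = 3,
                                   between_subject_sd = 0, noise_fwhm = 0,
                                   effect_sd = 0, rng_seed = 1))
  stat <- glm_group_contrast(co)
  expect_true(all(stat$t == 0))
  expect_true(all(stat$p == 1))
})

test_that("nuisance covariates change the degrees of freedom and design", {
  m <- sphere_mesh(2, 25)
  co <- make_cohort(m, cohort_spec(rng_seed = 3))
  s0 <- glm_group_contrast(co)
  s1 <- glm_group_contrast(co, nuisance = "tbv")
  expect_identical(s1$df, s0$df - 1L)
  # oracle via lm() at a single vertex
  v <- 17
  fit <- lm(co$ficd[v, ] ~ I(co$covariates$group == "A") +
              scale(co$covariates$tbv, scale = FALSE))
  expect_equal(unname(s1$t[v]), unname(summary(fit)$coefficients[2, "t value"]),
               tolerance = 1e-8)
  # collinear design errors
  co$covariates$dup <- as.numeric(co$covariates$group == "A")
  expect_error(glm_group_contrast(co, nuisance = "dup"), "collinear")
})

test_that("permuted null labels give the nominal vertex-wise false positive rate", {
  m <- sphere_mesh(3, 25)
  co <- make_cohort(m, cohort_spec(rng_seed = 10))
  set.seed(33)
  frac <- replicate(100, {
    co2 <- co
    co2$covariates$group <- sample(co$covariates$group)
    mean(glm_group_contrast(co2)$p < 0.05)
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("cluster correction handles empty and extreme threshold sets", {
  m <- sphere_mesh(3, 25)
  nv <- nrow(m$vertices)
  # no vertex below the cluster-forming threshold: zero clusters
  stat <- list(t = rep(0.1, nv), p = rep(0.9, nv), sign = rep(1, nv), df = 30)
  cl <- monte_carlo_cluster_correct(m, stat, 8, n_iter = 200, rng_seed = 1)
  expect_length(cl$clusters, 0)
  # an observed cluster larger than every simulated maximum: plus-one floor
  z <- numeric(nv)
  patch <- geodesic_patch(m, 1, 300)
  z[patch] <- 10
  stat2 <- list(t = z, p = 2 * pnorm(-abs(z)), sign = sign(z + 0.1), df = 30)
  cl2 <- monte_carlo_cluster_correct(m, stat2, 6, n_iter = 200, rng_seed = 1)
  expect_equal(cl2$clusters[[1]]$p_corrected, 1 / 201, tolerance = 1e-12)
  expect_warning(monte_carlo_cluster_correct(m, stat, 8, n_iter = 50,
                                             rng_seed = 1), "unstable")
})

test_that("corrected p is monotone nonincreasing in observed cluster area", {
  m <- sphere_mesh(3, 25)
  nv <- nrow(m$vertices)
  z <- numeric(nv)
  z[geodesic_patch(m, 1, 40)] <- 5
  z[geodesic_patch(m, 300, 15)] <- 5
  z[geodesic_patch(m, 600, 5)] <- -5
  stat <- list(t = z, p = 2 * pnorm(-abs(z)),
               sign = ifelse(z >= 0, 1, -1), df = 30)
  cl <- monte_carlo_cluster_correct(m, stat, 8, n_iter = 300, rng_seed = 2)
  ar <- vapply(cl$clusters, `[[`, 0, "area")
  pc <- vapply(cl$clusters, `[[`, 0, "p_corrected")
  o <- order(ar)
  expect_true(all(diff(pc[o]) <= 1e-12))
})

test_that("shrinking the cluster-forming threshold never adds clusters", {
  m <- sphere_mesh(3, 25)
  co <- make_cohort(m, cohort_spec(rng_seed = 14))
  stat <- glm_group_contrast(co)
  n_at <- function(cfp) {
    cl <- monte_carlo_cluster_correct(m, stat, 8, n_iter = 100,
                                      cf_p = cfp, rng_seed = 3)
    length(cl$clusters)
  }
  counts <- vapply(c(0.05, 0.01, 0.001), n_at, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("negating every subject map swaps cluster signs and nothing else", {
  m <- sphere_mesh(3, 25)
  patch <- geodesic_patch(m, 200, 80)
  co <- make_cohort(m, cohort_spec(effect_vertices = patch,
                                   effect_size = -0.4, rng_seed = 6))
  stat <- glm_group_contrast(co)
  co2 <- co
  co2$ficd <- -co$ficd
  stat2 <- glm_group_contrast(co2)
  expect_equal(stat2$t, -stat$t, tolerance = 1e-10)
  fw <- estimate_map_fwhm(m, stat$residuals)
  cl1 <- monte_carlo_cluster_correct(m, stat, fw, n_iter = 200, rng_seed = 4)
  cl2 <- monte_carlo_cluster_correct(m, stat2, fw, n_iter = 200, rng_seed = 4)
  expect_identical(length(cl1$clusters), length(cl2$clusters))
  for (i in seq_along(cl1$clusters)) {
    expect_identical(cl1$clusters[[i]]$vertices, cl2$clusters[[i]]$vertices)
    expect_identical(cl1$clusters[[i]]$sign, -cl2$clusters[[i]]$sign)
    expect_equal(cl1$clusters[[i]]$p_corrected,
                 cl2$clusters[[i]]$p_corrected, tolerance = 1e-12)
  }
})

test_that("dice overlap behaves on edge cases", {
  expect_equal(dice_overlap(1:10, 1:10), 1)
  expect_equal(dice_overlap(1:10, 11:20), 0)
  expect_equal(dice_overlap(1:10, 6:15), 0.5)
})
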