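# Post-hoc ROI analyses on significant clusters: per-subject metric
# extraction, group comparisons (t or Mann-Whitney U after a normality
# gate), partial correlations controlling for total brain volume, and the
# cluster-seeded fiber-count / mean-FA comparison.

#' Pooled-variance two-sample t test
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `p` (two-sided) and `df`. Zero pooled variance
#'   gives t = 0, p = 1 for equal means and |t| = Inf, p = 0 otherwise.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = df)
}

#' Mann-Whitney U test
#'
#' Exact when samples are small and untied, otherwise the normal
#' approximation with tie correction (via [stats::wilcox.test()]; its W
#' statistic is the U of the first sample).
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `U` and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Compare two samples, switching tests on a normality gate
#'
#' Uses the pooled two-sample t test when both samples pass a Shapiro-Wilk
#' normality check at p >= 0.05, and the Mann-Whitney U test otherwise.
#'
#' @param a,b numeric samples.
#' @param method "auto" (normality gate), "t", or "u".
#' @return list with `method`, `statistic`, `p`.
#' @export
group_compare <- function(a, b, method = c("auto", "t", "u")) {
  method <- match.arg(method)
  if (method == "auto") {
    normal <- function(x) length(unique(x)) < 3L ||
      stats::shapiro.test(x)$p.value >= 0.05
    method <- if (normal(a) && normal(b)) "t" else "u"
  }
  if (method == "t") {
    r <- two_sample_t(a, b)
    list(method = "t", statistic = r$t, p = r$p)
  } else {
    r <- mann_whitney_u(a, b)
    list(method = "u", statistic = r$U, p = r$p)
  }
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of x and y after least-squares
#' regression on the control variable; p from the t transform with n - 3
#' degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param z control covariate.
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(n >= 4L, length(y) == n, length(z) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must be non-constant")
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  # a variable collinear with the control leaves numerically-zero residuals:
  # the dependence is fully explained, r = 0 by convention
  tol <- 1e-10
  if (stats::sd(rx) < tol * stats::sd(x) ||
      stats::sd(ry) < tol * stats::sd(y))
    return(list(r = 0, p = 1, df = n - 3L))
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Per-subject metrics of a significant cluster
#'
#' Mean FiCD = unweighted mean of the subject's FiCD map over the cluster
#' vertices; GM volume = sum of the subject's per-vertex GM-volume map over
#' the cluster. If a tensor volume is supplied, the subcortical voxel layer
#' beneath the cluster is extracted and used as a tracking seed, giving the
#' fiber number FN (retained streamlines) and the mean FA of those fibers.
#'
#' @param cluster a cluster (list with `vertices`) from
#'   [monte_carlo_cluster_correct()], or an integer vertex id vector.
#' @param cohort a `cohort_table`.
#' @param vol optional `tensor_volume` shared by the cohort (phantom
#'   studies); per-subject volumes may be given as a list of length n.
#' @param params a `tracking_params` for the cluster-seeded tracking.
#' @param thickness seed-layer thickness mm (default one voxel).
#' @return data.frame with one row per subject: id, group, mean_ficd,
#'   gm_volume, and (when tracking was run) fn and mean_fiber_fa.
#' @export
extract_cluster_metrics <- function(cluster, cohort, vol = NULL,
                                    params = tracking_params(),
                                    thickness = NULL) {
  vids <- if (is.list(cluster)) cluster$vertices else as.integer(cluster)
  mesh <- cohort$mesh
  if (min(vids) < 1L || max(vids) > n_vertices(mesh))
    stop("cluster vertices outside the mesh")
  cov <- cohort$covariates
  out <- data.frame(id = cov$id, group = cov$group,
                    mean_ficd = colMeans(cohort$ficd[vids, , drop = FALSE]),
                    gm_volume = colSums(cohort$gmvol[vids, , drop = FALSE]),
                    stringsAsFactors = FALSE)
  if (!is.null(vol)) {
    vols <- if (inherits(vol, "tensor_volume"))
      rep(list(vol), nrow(cov)) else vol
    # cluster faces: majority of face vertices inside the cluster
    f <- mesh$faces
    inc <- matrix(f %in% vids, nrow(f), 3L)
    face_label <- as.integer(rowSums(inc) >= 2L)
    fn <- integer(nrow(cov))
    mfa <- rep(NA_real_, nrow(cov))
    for (i in seq_len(nrow(cov))) {
      mask <- extract_seed_layer(mesh, vols[[i]], face_label,
                                 thickness)[["1"]]
      if (is.null(mask) || !length(mask)) {
        fn[i] <- NA_integer_
        warning("cluster seed layer is empty; FN undefined for subject ",
                cov$id[i])
        next
      }
      tracks <- track_from_mask(vols[[i]], mask, params)
      fn[i] <- n_streamlines(tracks)
      if (fn[i] > 0L)
        mfa[i] <- mean(vapply(tracks$streamlines, `[[`, 0, "mean_fa"))
    }
    out$fn <- fn
    out$mean_fiber_fa <- mfa
  }
  rownames(out) <- NULL
  out
}

#' ROI report over significant clusters
#'
#' For each cluster: between-group comparisons of mean FiCD, GM volume and
#' (when tracking is available) fiber number and mean fiber FA, plus partial
#' correlations (controlling for total brain volume) between severity score
#' and FiCD, severity and GM volume, and FiCD and GM volume within each
#' group.
#'
#' @param cohort a `cohort_table` whose covariates include `severity` and
#'   `tbv`.
#' @param clusters a `cluster_results`, or a list of clusters / vertex id
#'   vectors.
#' @param vol optional `tensor_volume` enabling the fiber metrics.
#' @param params,thickness passed to [extract_cluster_metrics()].
#' @param method group-comparison method passed to [group_compare()].
#' @return data.frame with one row per cluster x analysis: columns cluster,
#'   analysis, group (for correlations), statistic name, value, p.
#' @export
roi_report <- function(cohort, clusters, vol = NULL,
                       params = tracking_params(), thickness = NULL,
                       method = "auto") {
  if (inherits(clusters, "cluster_results"))
    clusters <- significant_clusters(clusters)
  cov <- cohort$covariates
  ga <- levels(factor(cov$group))[1]
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (ci in seq_along(clusters)) {
    met <- extract_cluster_metrics(clusters[[ci]], cohort, vol, params,
                                   thickness)
    ina <- met$group == ga
    for (v in intersect(c("mean_ficd", "gm_volume", "fn", "mean_fiber_fa"),
                        names(met))) {
      x <- met[[v]][ina]; y <- met[[v]][!ina]
      ok <- is.finite(x) & !is.na(x)
      okb <- is.finite(y) & !is.na(y)
      if (sum(ok) < 2L || sum(okb) < 2L) {
        add(cluster = ci, analysis = paste0("group_", v), group = "A-B",
            statistic = NA_real_, p = NA_real_, method = NA_character_)
        next
      }
      gc <- group_compare(x[ok], y[okb], method)
      add(cluster = ci, analysis = paste0("group_", v), group = "A-B",
          statistic = gc$statistic, p = gc$p, method = gc$method)
    }
    for (g in levels(factor(cov$group))) {
      sel <- met$group == g
      pc1 <- partial_correlation(cov$severity[sel], met$mean_ficd[sel],
                                 cov$tbv[sel])
      pc2 <- partial_correlation(cov$severity[sel], met$gm_volume[sel],
                                 cov$tbv[sel])
      pc3 <- partial_correlation(met$mean_ficd[sel], met$gm_volume[sel],
                                 cov$tbv[sel])
      add(cluster = ci, analysis = "pcor_severity_ficd", group = g,
          statistic = pc1$r, p = pc1$p, method = "partial_r")
      add(cluster = ci, analysis = "pcor_severity_gm", group = g,
          statistic = pc2$r, p = pc2$p, method = "partial_r")
      add(cluster = ci, analysis = "pcor_ficd_gm", group = g,
          statistic = pc3$r, p = pc3$p, method = "partial_r")
    }
  }
  do.call(rbind, rows)
}
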