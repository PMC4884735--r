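#' Pipeline configuration
#'
#' Collects every stage parameter into one validated object. Unknown keys
#' are rejected; the tracking block is validated through
#' [tracking_params()] before any compute runs.
#'
#' @param rng_seed master seed; per-stage child seeds are derived from it by
#'   a stable hash, so stages are reproducible in isolation.
#' @param phantom named list of [phantom_spec()] arguments (used when the
#'   "simulate" stage is on).
#' @param cohort named list of [cohort_spec()] arguments.
#' @param inputs named list of file paths (`tensor`, `surface`,
#'   `cohort_tsv`) used when "simulate" is off.
#' @param K cortical unit count for parcellation.
#' @param thickness seed-layer thickness mm (`NULL` = one voxel).
#' @param tracking named list of [tracking_params()] arguments.
#' @param fwhm surface smoothing kernel FWHM in mm.
#' @param n_iter,cf_p,alpha Monte Carlo cluster-correction settings.
#' @param nuisance GLM nuisance covariate names.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "parcellate", "ficd", "smooth", "zscore", "glm", "mcz",
#'   "roi")`, honored in pipeline order.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(rng_seed = 1L, phantom = list(),
                            cohort = list(), inputs = list(), K = 2000L,
                            thickness = NULL, tracking = list(), fwhm = 10,
                            n_iter = 10000L, cf_p = 0.05, alpha = 0.05,
                            nuisance = NULL,
                            stages = c("simulate", "parcellate", "ficd",
                                       "smooth", "zscore", "glm", "mcz",
                                       "roi")) {
  known <- c("simulate", "parcellate", "ficd", "smooth", "zscore", "glm",
             "mcz", "roi")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stopifnot(fwhm >= 0, n_iter >= 1, cf_p > 0, cf_p < 1, alpha > 0, alpha < 1)
  tp <- do.call(tracking_params, tracking)      # validates before compute
  structure(list(rng_seed = as.integer(rng_seed), phantom = phantom,
                 cohort = cohort, inputs = inputs, K = as.integer(K),
                 thickness = thickness, tracking = tp, fwhm = fwhm,
                 n_iter = as.integer(n_iter), cf_p = cf_p, alpha = alpha,
                 nuisance = nuisance, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path a YAML file whose top-level keys are [pipeline_config()]
#'   arguments; unknown keys are rejected.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

config_for_json <- function(config) {
  cf <- unclass(config)
  cf$tracking <- unclass(cf$tracking)
  cf$phantom$bundles <- lapply(cf$phantom$bundles, function(b) {
    b$points <- as.numeric(unlist(b$points))
    b
  })
  cf
}

#' Run the full FiCD mapping pipeline
#'
#' Executes, in order and honoring the configured stage toggles:
#' phantom/cohort simulation (or file loading), surface parcellation,
#' per-CU tractography + FiCD mapping of the tensor volume, surface
#' smoothing, Z-transform, the vertex-wise group GLM, Monte Carlo
#' cluster-wise correction, and the ROI report. Every written artifact is
#' digested (MD5) into a provenance record; identical config + seed gives
#' byte-identical digests.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @return invisible list with the stage results (`vol`, `mesh`, `cohort`,
#'   `parc`, `ficd`, `stat`, `clusters`, `roi`) and the `provenance` record.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  seeds <- list()
  res <- list()
  on_stage <- function(s) s %in% config$stages
  emit <- function(path) artifacts <<- c(artifacts, path)
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  # --- simulate / load ----------------------------------------------------
  stage <- "simulate"
  tryCatch({
    if (on_stage("simulate")) {
      seeds$phantom <- derive_seed(config$rng_seed, "phantom")
      seeds$cohort <- derive_seed(config$rng_seed, "cohort")
      pspec <- do.call(phantom_spec,
                       c(config$phantom, list(rng_seed = seeds$phantom)))
      res$vol <- make_tensor_phantom(pspec)
      res$mesh <- make_cortex_mesh(pspec)
      cargs <- config$cohort
      cargs$rng_seed <- seeds$cohort
      res$cohort <- make_cohort(res$mesh, do.call(cohort_spec, cargs))
      emit(write_volume(res$vol, file.path(out_dir, "tensor.nii.gz")))
      emit(write_volume(res$vol, file.path(out_dir, "fa.nii.gz"), "fa"))
      emit(write_surface(res$mesh, file.path(out_dir, "surface.gii")))
      emit(write_cohort_tsv(res$cohort, file.path(out_dir, "cohort")))
    } else {
      if (!is.null(config$inputs$tensor))
        res$vol <- read_volume(config$inputs$tensor)
      if (!is.null(config$inputs$surface))
        res$mesh <- read_surface(config$inputs$surface)
      if (!is.null(config$inputs$cohort_tsv))
        res$cohort <- read_cohort_tsv(config$inputs$cohort_tsv, res$mesh)
      if (!is.null(res$cohort)) res$mesh <- res$cohort$mesh
    }
  }, error = function(e) fail(stage, e))

  # --- parcellate ---------------------------------------------------------
  if (on_stage("parcellate")) {
    stage <- "parcellate"
    tryCatch({
      seeds$parcellate <- derive_seed(config$rng_seed, "parcellate")
      res$parc <- parcellate_surface(res$mesh, config$K, seeds$parcellate)
      pj <- file.path(out_dir, "parcellation.json")
      jsonlite::write_json(list(K = res$parc$K, face_cu = res$parc$face_cu,
                                vertex_cu = res$parc$vertex_cu,
                                seeds = res$parc$seeds),
                           pj, auto_unbox = TRUE)
      emit(pj)
      emit(write_vertex_map(res$parc$vertex_cu,
                            file.path(out_dir, "cu_labels.gii")))
    }, error = function(e) fail(stage, e))
  }

  # --- per-CU tractography + FiCD map of the tensor volume ----------------
  if (on_stage("ficd")) {
    stage <- "ficd"
    tryCatch({
      res$ficd <- ficd_map(res$vol, res$parc, config$tracking,
                           config$thickness)
      emit(write_vertex_map(res$ficd$values,
                            file.path(out_dir, "ficd.gii")))
    }, error = function(e) fail(stage, e))
  }

  # --- smooth + z-transform the cohort maps -------------------------------
  maps <- res$cohort$ficd
  if (on_stage("smooth")) {
    stage <- "smooth"
    tryCatch({
      maps <- smooth_surface_map(res$mesh, maps, config$fwhm)
    }, error = function(e) fail(stage, e))
  }
  if (on_stage("zscore")) {
    stage <- "zscore"
    tryCatch({
      maps <- apply(maps, 2, z_transform_hemisphere)
    }, error = function(e) fail(stage, e))
  }
  res$analysis_maps <- maps

  # --- GLM ----------------------------------------------------------------
  if (on_stage("glm")) {
    stage <- "glm"
    tryCatch({
      res$stat <- glm_group_contrast(res$cohort, maps = maps,
                                     nuisance = config$nuisance)
      emit(write_vertex_map(res$stat$t, file.path(out_dir, "tmap.gii")))
      emit(write_vertex_map(res$stat$p, file.path(out_dir, "pmap.gii")))
    }, error = function(e) fail(stage, e))
  }

  # --- Monte Carlo cluster correction -------------------------------------
  if (on_stage("mcz")) {
    stage <- "mcz"
    tryCatch({
      seeds$mcz <- derive_seed(config$rng_seed, "mcz")
      fwhm_est <- estimate_map_fwhm(res$mesh, res$stat$residuals)
      res$clusters <- monte_carlo_cluster_correct(
        res$mesh, res$stat, fwhm_est, config$n_iter, config$cf_p,
        config$alpha, seeds$mcz)
      cj <- file.path(out_dir, "clusters.json")
      jsonlite::write_json(lapply(res$clusters$clusters, function(cl)
        list(vertices = cl$vertices, area = cl$area, sign = cl$sign,
             p_corrected = cl$p_corrected, significant = cl$significant)),
        cj, auto_unbox = TRUE, digits = NA)
      emit(cj)
      lab <- numeric(n_vertices(res$mesh))
      for (i in seq_along(res$clusters$clusters))
        if (res$clusters$clusters[[i]]$significant)
          lab[res$clusters$clusters[[i]]$vertices] <- i
      emit(write_vertex_map(lab, file.path(out_dir, "cluster_labels.gii")))
    }, error = function(e) fail(stage, e))
  }

  # --- ROI report ---------------------------------------------------------
  if (on_stage("roi")) {
    stage <- "roi"
    tryCatch({
      sig <- significant_clusters(res$clusters)
      if (length(sig)) {
        res$roi <- roi_report(res$cohort, sig, vol = res$vol,
                              params = config$tracking,
                              thickness = config$thickness)
        rp <- file.path(out_dir, "roi_report.tsv")
        utils::write.table(res$roi, rp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(rp)
      }
    }, error = function(e) fail(stage, e))
  }

  # --- provenance ---------------------------------------------------------
  digests <- tools::md5sum(artifacts)
  names(digests) <- basename(names(digests))
  prov <- list(
    package = "ficdmap",
    version = as.character(utils::packageVersion("ficdmap")),
    config = config_for_json(config),
    seeds = seeds,
    digests = as.list(digests))
  pv <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, pv, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$provenance <- prov
  invisible(res)
}
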