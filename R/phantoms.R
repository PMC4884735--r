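#' Specification of a synthetic tensor-field / cortical-mesh phantom
#'
#' Describes a gridded diffusion-tensor phantom containing hard-edged fiber
#' bundles (tube cross-sections: a voxel is either fully inside a bundle or
#' background, which keeps analytic expectations exact) plus a closed
#' cortical-style mesh used as the gray--white matter interface.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size numeric length-3 (or scalar), mm per axis.
#' @param bundles list of bundles, each a list with `points` (n x 3 matrix of
#'   centerline control points in world mm), `radius` (mm), `fa` (FA inside).
#' @param fa_background background FA (isotropic-ish tensor), in [0, 1).
#' @param mesh_kind "sphere" or "folded".
#' @param mesh_radius sphere radius mm (also the base radius of the folded
#'   mesh).
#' @param mesh_amplitude radial fold amplitude mm (folded kind only).
#' @param mesh_subdiv icosphere subdivision level (4 gives 2562 vertices /
#'   5120 faces; 5 gives 10242 / 20480).
#' @param mesh_center center of the mesh in world mm.
#' @param rng_seed integer seed making every derived artifact reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 40), voxel_size = 2,
                         bundles = list(), fa_background = 0.05,
                         mesh_kind = c("sphere", "folded"), mesh_radius = 50,
                         mesh_amplitude = 5, mesh_subdiv = 4,
                         mesh_center = NULL, rng_seed = 1L) {
  mesh_kind <- match.arg(mesh_kind)
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L),
            all(voxel_size > 0), fa_background >= 0, fa_background < 1,
            mesh_radius > 0, mesh_subdiv >= 0)
  bundles <- lapply(bundles, function(b) {
    if (is.null(b$points) || is.null(b$radius) || is.null(b$fa))
      stop("each bundle needs `points`, `radius`, `fa`")
    if (is.list(b$points))  # e.g. rows parsed from a YAML config
      b$points <- do.call(rbind, lapply(b$points, as.numeric))
    b$points <- as.matrix(b$points)
    if (ncol(b$points) != 3L || nrow(b$points) < 2L)
      stop("bundle `points` must be an n x 3 matrix with n >= 2")
    if (b$radius <= 0) stop("bundle radius must be > 0")
    if (b$fa < 0 || b$fa > 1) stop("bundle FA must be in [0, 1]")
    b
  })
  if (is.null(mesh_center)) mesh_center <- grid_shape * voxel_size / 2
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 bundles = bundles, fa_background = fa_background,
                 mesh_kind = mesh_kind, mesh_radius = mesh_radius,
                 mesh_amplitude = mesh_amplitude, mesh_subdiv = mesh_subdiv,
                 mesh_center = mesh_center, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Axially symmetric tensor components for a given FA and unit direction.
# Mean diffusivity is held fixed (arbitrary units; FA is scale invariant):
# eigenvalues md*(1 + 2*delta), md*(1 - delta) x2 with
# delta = FA * sqrt(3 / (9 - 6 FA^2)).
tensor_from_fa_dir <- function(fa, dir, md = 0.7e-3) {
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  l1 <- md * (1 + 2 * delta)
  l23 <- md * (1 - delta)
  d <- dir / sqrt(sum(dir^2))
  # D = l23 * I + (l1 - l23) * d d'
  dd <- (l1 - l23) * tcrossprod(d)
  c(l23 + dd[1, 1], dd[1, 2], dd[1, 3], l23 + dd[2, 2], dd[2, 3], l23 + dd[3, 3])
}

# Resample a polyline to (approximately) uniform arc-length spacing, returning
# points and unit tangents.
resample_polyline <- function(points, spacing) {
  seg <- diff(points)
  seglen <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  ns <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = ns)
  out <- sapply(1:3, function(d) stats::approx(s, points[, d], xout = si)$y)
  tg <- rbind(out[2, ] - out[1, ],
              (out[-(1:2), , drop = FALSE] - out[seq_len(ns - 2), , drop = FALSE])[, , drop = FALSE],
              out[ns, ] - out[ns - 1, ])
  # central differences in the interior
  if (ns > 2) tg[2:(ns - 1), ] <- out[3:ns, , drop = FALSE] - out[1:(ns - 2), , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = out, tangents = tg, arc = si)
}

#' Build a synthetic diffusion-tensor volume from a phantom specification
#'
#' Voxels whose centers lie within a bundle's tube radius get an axially
#' symmetric tensor whose principal eigenvector is tangent to the centerline
#' at the nearest centerline point; all other voxels get an isotropic-leaning
#' tensor at the background FA with a fixed arbitrary axis. When bundles
#' overlap, the last bundle in the list wins and the conflicting voxels are
#' recorded in the provenance.
#'
#' @param spec a `phantom_spec`.
#' @return a `tensor_volume` with provenance fields `spec` and
#'   `overlap_voxels` (0-based linear voxel ids overwritten by a later bundle
#'   with a direction differing by more than 5 degrees).
#' @export
make_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  affine <- diag(c(vs, 1))
  nvox <- prod(dm)

  # voxel centers
  ijk <- voxel_id_to_ijk(dm, seq_len(nvox))
  centers <- cbind(ijk[, 1] * vs[1], ijk[, 2] * vs[2], ijk[, 3] * vs[3])

  fa <- rep(spec$fa_background, nvox)
  dirs <- matrix(rep(c(1, 0, 0), each = nvox), nvox, 3)  # background axis
  owner <- integer(nvox)  # 0 = background
  overlap <- integer(0)

  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    rp <- resample_polyline(as.matrix(b$points), min(vs) / 2)
    # candidate voxels: inside the bundle bounding box inflated by radius
    lo <- apply(rp$points, 2, min) - b$radius - max(vs)
    hi <- apply(rp$points, 2, max) + b$radius + max(vs)
    cand <- which(centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
                  centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
                  centers[, 3] >= lo[3] & centers[, 3] <= hi[3])
    if (!length(cand)) next
    # nearest centerline sample per candidate voxel (chunked)
    nsamp <- nrow(rp$points)
    best_d2 <- rep(Inf, length(cand))
    best_s <- integer(length(cand))
    chunk <- max(1L, floor(2e6 / length(cand)))
    for (s0 in seq(1L, nsamp, by = chunk)) {
      s1 <- min(nsamp, s0 + chunk - 1L)
      for (s in s0:s1) {
        d2 <- (centers[cand, 1] - rp$points[s, 1])^2 +
              (centers[cand, 2] - rp$points[s, 2])^2 +
              (centers[cand, 3] - rp$points[s, 3])^2
        upd <- d2 < best_d2
        best_d2[upd] <- d2[upd]
        best_s[upd] <- s
      }
    }
    inside <- best_d2 <= b$radius^2
    vin <- cand[inside]
    if (!length(vin)) next
    newdir <- rp$tangents[best_s[inside], , drop = FALSE]
    prev <- owner[vin] > 0L
    if (any(prev)) {
      cosang <- abs(rowSums(newdir[prev, , drop = FALSE] *
                            dirs[vin[prev], , drop = FALSE]))
      overlap <- c(overlap, vin[prev][cosang < cos(5 * pi / 180)])
    }
    fa[vin] <- b$fa
    dirs[vin, ] <- newdir
    owner[vin] <- bi
  }

  tens <- matrix(0, nvox, 6)
  # background tensor is shared; compute one and recycle
  bg <- tensor_from_fa_dir(spec$fa_background, c(1, 0, 0))
  tens[] <- rep(bg, each = nvox)
  inb <- which(owner > 0L)
  for (v in inb) tens[v, ] <- tensor_from_fa_dir(fa[v], dirs[v, ])

  tensor_volume(
    tensor = array(tens, c(dm, 6L)), affine = affine,
    fa = array(fa, dm),
    v1 = array(dirs, c(dm, 3L)),
    provenance = list(spec = spec, bundle_owner = owner,
                      overlap_voxels = sort(unique(overlap))))
}

# Unit icosahedron vertices/faces, consistently outward-oriented.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# One loop of Loop-style 1-to-4 subdivision with vertex deduplication,
# projecting new vertices back to the unit sphere.
subdivide_sphere <- function(v, f) {
  key_of <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- key_of(f[, 1], f[, 2]); e2 <- key_of(f[, 2], f[, 3]); e3 <- key_of(f[, 3], f[, 1])
  keys <- unique(c(e1, e2, e3))
  idx <- stats::setNames(seq_along(keys) + nrow(v), keys)
  parts <- do.call(rbind, strsplit(keys, " "))
  a <- as.integer(parts[, 1]); b <- as.integer(parts[, 2])
  mid <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  v2 <- rbind(v, mid)
  m1 <- idx[e1]; m2 <- idx[e2]; m3 <- idx[e3]
  f2 <- rbind(cbind(f[, 1], m1, m3),
              cbind(f[, 2], m2, m1),
              cbind(f[, 3], m3, m2),
              cbind(m1, m2, m3))
  list(vertices = v2, faces = unname(f2))
}

#' Generate a closed cortical-style surface mesh
#'
#' `sphere` gives a geodesic icosphere of the requested radius; `folded`
#' modulates the radius with smooth angular harmonics to mimic gyral folding
#' while staying closed, manifold and star-shaped (so outward orientation is
#' preserved).
#'
#' @param spec a `phantom_spec`.
#' @return a `surface_mesh` centered on `spec$mesh_center`.
#' @export
make_cortex_mesh <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$faces
  for (i in seq_len(spec$mesh_subdiv)) {
    s <- subdivide_sphere(v, f)
    v <- s$vertices; f <- s$faces
  }
  r <- spec$mesh_radius
  if (spec$mesh_kind == "folded") {
    theta <- acos(pmin(1, pmax(-1, v[, 3])))
    phi <- atan2(v[, 2], v[, 1])
    bump <- sin(6 * theta) * cos(5 * phi) + 0.6 * sin(4 * phi + 2 * theta)
    r <- r + spec$mesh_amplitude * bump / 1.6
  }
  verts <- v * r + matrix(spec$mesh_center, nrow(v), 3, byrow = TRUE)
  surface_mesh(verts, f)
}

#' Specification of a synthetic two-group cohort
#'
#' Each subject receives a vertex-wise FiCD map equal to a smooth base pattern
#' plus a group effect on a chosen vertex patch plus i.i.d. vertex noise, a
#' per-vertex gray-matter volume map, a total brain volume, and an SPQ-like
#' severity score coupled to the subject's realized effect.
#'
#' @param n_group_a,n_group_b subject counts (study default 20 and 18).
#' @param effect_vertices integer vertex ids carrying the group effect.
#' @param effect_size additive FiCD shift applied to group A at
#'   `effect_vertices` (signed, FiCD units).
#' @param between_subject_sd per-vertex SD of the subject noise fields.
#' @param noise_fwhm spatial smoothness (FWHM, mm) of each subject's noise
#'   field; noise is independent across subjects. 0 gives white vertex
#'   noise. The default 12 mm reflects the spatial coherence of
#'   between-subject variability in cortical maps.
#' @param effect_sd SD of the per-subject realized effect magnitude around its
#'   group mean.
#' @param severity_coupling slope `a` of severity = a * realized effect +
#'   noise; negative values emulate severity rising as FiCD falls.
#' @param severity_noise_sd SD of the severity noise.
#' @param rng_seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 20L, n_group_b = 18L,
                        effect_vertices = integer(0), effect_size = 0,
                        between_subject_sd = 0.1, noise_fwhm = 12,
                        effect_sd = 0.05, severity_coupling = 0,
                        severity_noise_sd = 1, rng_seed = 1L) {
  stopifnot(n_group_a >= 2L, n_group_b >= 2L, between_subject_sd >= 0,
            noise_fwhm >= 0, effect_sd >= 0, severity_noise_sd >= 0)
  if (effect_size != 0 && length(effect_vertices) == 0L)
    stop("nonzero effect_size requires a nonempty effect_vertices set")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 effect_vertices = as.integer(effect_vertices),
                 effect_size = effect_size,
                 between_subject_sd = between_subject_sd,
                 noise_fwhm = noise_fwhm,
                 effect_sd = effect_sd,
                 severity_coupling = severity_coupling,
                 severity_noise_sd = severity_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort on a shared mesh
#'
#' All subjects share the mesh topology, which is the synthetic stand-in for
#' inter-subject surface registration: vertex i corresponds across subjects.
#'
#' @param mesh the common `surface_mesh`.
#' @param spec a `cohort_spec`; `effect_vertices` must index mesh vertices.
#' @return An object of class `cohort_table`: list with `mesh`, `ficd` and
#'   `gmvol` (V x n matrices, one column per subject) and `covariates`
#'   (data.frame: id, group, severity, tbv mm^3, realized_effect).
#' @export
make_cohort <- function(mesh, spec) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(spec, "cohort_spec"))
  nv <- n_vertices(mesh)
  if (length(spec$effect_vertices) &&
      (min(spec$effect_vertices) < 1L || max(spec$effect_vertices) > nv))
    stop("effect_vertices outside 1..V")
  n <- spec$n_group_a + spec$n_group_b
  group <- factor(rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)),
                  levels = c("A", "B"))

  # smooth base FiCD pattern over the mesh (low angular frequency)
  ctr <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, ctr)
  scale <- max(sqrt(rowSums(rel^2)))
  base <- 1 + 0.2 * rel[, 1] / scale + 0.1 * sin(pi * rel[, 3] / scale)

  with_seed(spec$rng_seed, {
    mu <- ifelse(group == "A", spec$effect_size, 0)
    realized <- stats::rnorm(n, mu, spec$effect_sd)
    ficd <- matrix(base, nv, n)
    if (length(spec$effect_vertices))
      ficd[spec$effect_vertices, ] <- ficd[spec$effect_vertices, ] +
        rep(realized, each = length(spec$effect_vertices))
    noise <- matrix(stats::rnorm(nv * n), nv, n)
    if (spec$noise_fwhm > 0) {
      noise <- smooth_surface_map(mesh, noise, spec$noise_fwhm)
      # rescale so each subject's noise field has the requested vertex SD
      noise <- sweep(noise, 2, apply(noise, 2, stats::sd), `/`)
    }
    ficd <- ficd + spec$between_subject_sd * noise

    # GM volume per vertex ~ vertex area x 2.5 mm cortical thickness + noise
    gm_base <- 2.5 * vertex_areas(mesh)
    gmvol <- matrix(gm_base, nv, n) *
      (1 + matrix(stats::rnorm(nv * n, 0, 0.1), nv, n))
    gmvol[gmvol < 0] <- 0

    tbv <- stats::rnorm(n, 1.4e6, 7e4)
    severity <- 30 + spec$severity_coupling * realized +
      stats::rnorm(n, 0, spec$severity_noise_sd)

    ids <- sprintf("sub-%03d", seq_len(n))
    colnames(ficd) <- ids
    colnames(gmvol) <- ids
    structure(list(mesh = mesh, ficd = ficd, gmvol = gmvol,
                   covariates = data.frame(id = ids, group = group,
                                           severity = severity, tbv = tbv,
                                           realized_effect = realized,
                                           stringsAsFactors = FALSE),
                   spec = spec),
              class = "cohort_table")
  })
}

#' @export
print.cohort_table <- function(x, ...) {
  tab <- table(x$covariates$group)
  cat(sprintf("cohort_table: %d subjects (A: %d, B: %d), %d vertices\n",
              nrow(x$covariates), tab[["A"]], tab[["B"]], nrow(x$ficd)))
  invisible(x)
}
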