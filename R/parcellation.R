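#' Parcellate a surface into K approximately equal-area cortical units
#'
#' Seeds K vertices by farthest-point sampling over the weighted vertex
#' graph, then grows all K regions simultaneously over the face-adjacency
#' graph with area balancing: at each step the region with the smallest
#' accumulated area claims the unclaimed frontier face nearest its seed.
#' This yields exactly K edge-connected, non-empty, face-disjoint patches
#' covering the mesh with near-equal areas, deterministically for a given
#' seed.
#'
#' @param mesh a `surface_mesh` (manifold).
#' @param K number of cortical units; the framework's default whole-surface
#'   count is 2000. Must satisfy `K <= n_faces(mesh)`.
#' @param rng_seed seed choosing the initial farthest-point sample.
#' @return an object of class `parcellation`: the mesh, `K`, `face_cu`
#'   (length-F CU id per face), `vertex_cu` (face-majority vertex ownership,
#'   ties to the lower CU id) and the seed vertices.
#' @export
parcellate_surface <- function(mesh, K, rng_seed = 1L) {
  nf <- n_faces(mesh)
  nv <- n_vertices(mesh)
  if (K > nf) stop(sprintf("K = %d exceeds the face count %d", K, nf))
  if (K < 1L) stop("K must be >= 1")

  # farthest-point sampling of K seed vertices
  first <- with_seed(rng_seed, sample.int(nv, 1L))
  seeds <- integer(K)
  seeds[1L] <- first
  if (K > 1L) {
    g <- mesh_graph(mesh)
    dist <- as.numeric(igraph::distances(g, v = first))
    for (k in 2L:K) {
      s <- which.max(dist)
      seeds[k] <- s
      ds <- as.numeric(igraph::distances(g, v = s))
      dist <- pmin(dist, ds)
    }
  }

  face_cu <- grow_balanced(mesh, seeds)
  vertex_cu <- vertex_ownership(mesh, face_cu)
  structure(list(mesh = mesh, K = as.integer(K), face_cu = face_cu,
                 vertex_cu = vertex_cu, seeds = seeds,
                 rng_seed = as.integer(rng_seed)),
            class = "parcellation")
}

# Area-balanced simultaneous region growing over the face graph.
grow_balanced <- function(mesh, seeds) {
  K <- length(seeds)
  nf <- n_faces(mesh)
  fadj <- face_adjacency(mesh)
  farea <- face_areas(mesh)
  f <- mesh$faces
  cent <- (mesh$vertices[f[, 1], , drop = FALSE] +
           mesh$vertices[f[, 2], , drop = FALSE] +
           mesh$vertices[f[, 3], , drop = FALSE]) / 3

  # faces incident to each vertex
  vf_v <- c(f[, 1], f[, 2], f[, 3])
  vf_f <- rep(seq_len(nf), 3L)
  o <- order(vf_v, vf_f)
  vf_v <- vf_v[o]; vf_f <- vf_f[o]
  vstart <- c(match(seq_len(n_vertices(mesh)), vf_v), length(vf_v) + 1L)

  incident_faces <- function(v) {
    a <- vstart[v]
    if (is.na(a)) return(integer(0))
    b <- a
    while (b <= length(vf_v) && vf_v[b] == v) b <- b + 1L
    vf_f[a:(b - 1L)]
  }

  face_cu <- integer(nf)
  cu_area <- numeric(K)
  frontier <- vector("list", K)
  seed_xyz <- mesh$vertices[seeds, , drop = FALSE]

  claim <- function(fid, k) {
    face_cu[fid] <<- k
    cu_area[k] <<- cu_area[k] + farea[fid]
    nb <- fadj[[fid]]
    frontier[[k]] <<- c(frontier[[k]], nb[face_cu[nb] == 0L])
  }

  for (k in seq_len(K)) {
    cand <- incident_faces(seeds[k])
    cand <- cand[face_cu[cand] == 0L]
    if (!length(cand)) {
      # seed's faces already taken (only possible at extreme K): take the
      # globally nearest unclaimed face
      un <- which(face_cu == 0L)
      d2 <- rowSums(sweep(cent[un, , drop = FALSE], 2, seed_xyz[k, ])^2)
      cand <- un[which.min(d2)]
    }
    claim(cand[1L], k)
  }

  n_claimed <- K
  active <- rep(TRUE, K)
  area_rank <- cu_area
  while (n_claimed < nf) {
    area_rank[!active] <- Inf
    k <- which.min(area_rank)
    if (!is.finite(area_rank[k])) break  # disconnected remainder (no-op on
                                         # manifold meshes)
    fr <- frontier[[k]]
    fr <- fr[face_cu[fr] == 0L]
    if (!length(fr)) {
      frontier[[k]] <- integer(0)
      active[k] <- FALSE
      next
    }
    fr <- unique(fr)
    d2 <- rowSums(sweep(cent[fr, , drop = FALSE], 2, seed_xyz[k, ])^2)
    fid <- fr[which.min(d2)]
    frontier[[k]] <- fr[fr != fid]
    claim(fid, k)
    area_rank[k] <- cu_area[k]
    n_claimed <- n_claimed + 1L
  }
  face_cu
}

# Vertex ownership: the CU owning the majority of a vertex's incident faces,
# ties broken by the lower CU id.
vertex_ownership <- function(mesh, face_cu) {
  f <- mesh$faces
  v <- c(f[, 1], f[, 2], f[, 3])
  cu <- rep(face_cu, 3L)
  o <- order(v, cu)
  v <- v[o]; cu <- cu[o]
  own <- integer(n_vertices(mesh))
  i <- 1L
  n <- length(v)
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    tab <- table(cu[i:j])
    own[v[i]] <- as.integer(names(tab)[which.max(tab)])  # first max = lower id
    i <- j + 1L
  }
  own
}

#' @export
print.parcellation <- function(x, ...) {
  ar <- cu_areas(x)
  cat(sprintf("parcellation: %d cortical units, area %.1f-%.1f mm^2 (median %.1f)\n",
              x$K, min(ar), max(ar), stats::median(ar)))
  invisible(x)
}

#' Per-CU surface areas
#' @param parc a `parcellation`.
#' @return numeric vector of K areas in mm^2; sums exactly to the mesh area.
#' @export
cu_areas <- function(parc) {
  as.numeric(tapply(face_areas(parc$mesh), factor(parc$face_cu,
                    levels = seq_len(parc$K)), sum, default = 0))
}

#' Vertex ids of one cortical unit
#' @param parc a `parcellation`.
#' @param cu CU id.
#' @return integer vertex ids owned by the CU.
#' @export
cu_vertices <- function(parc, cu) which(parc$vertex_cu == cu)

# Are all K units edge-connected face sets?
parcellation_connected <- function(parc) {
  fadj <- face_adjacency(parc$mesh)
  for (cu in seq_len(parc$K)) {
    fids <- which(parc$face_cu == cu)
    if (!length(fids)) return(FALSE)
    inset <- logical(n_faces(parc$mesh))
    inset[fids] <- TRUE
    seen <- logical(n_faces(parc$mesh))
    queue <- fids[1]
    seen[fids[1]] <- TRUE
    cnt <- 0L
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      cnt <- cnt + 1L
      nb <- fadj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (cnt != length(fids)) return(FALSE)
  }
  TRUE
}

#' Extract the subcortical seed-voxel layer beneath labelled faces
#'
#' Finds every voxel whose center lies within `thickness` mm of the surface
#' on the inward-normal (white matter) side, assigns it to the label of the
#' face holding the nearest surface point (so masks of competing labels are
#' disjoint), and returns the per-label voxel sets.
#'
#' @param mesh a `surface_mesh` with outward-oriented faces.
#' @param vol a `tensor_volume` supplying the voxel grid and affine.
#' @param face_label integer label per face (e.g. CU ids); label 0 = ignore.
#' @param thickness layer thickness in mm; default one voxel
#'   (`mean(vol$voxel_size)`). `thickness = 0` gives empty masks.
#' @return named list mapping label to an integer vector of 1-based linear
#'   voxel ids (possibly empty).
#' @export
extract_seed_layer <- function(mesh, vol, face_label, thickness = NULL) {
  stopifnot(length(face_label) == n_faces(mesh))
  if (is.null(thickness)) thickness <- mean(vol$voxel_size)
  labels <- sort(unique(face_label[face_label > 0L]))
  out <- stats::setNames(rep(list(integer(0)), length(labels)),
                         as.character(labels))
  if (thickness <= 0) return(out)
  res <- cpp_seed_layer(mesh$vertices, mesh$faces, as.integer(face_label),
                        vol$affine, vol$dim, thickness)
  keep <- res$label > 0L
  if (!any(keep)) return(out)
  ids <- voxel_linear_id(vol$dim, cbind(res$i, res$j, res$k)[keep, , drop = FALSE])
  lab <- res$label[keep]
  for (l in labels)
    out[[as.character(l)]] <- sort(ids[lab == l])
  out
}

#' Seed-voxel masks for every cortical unit of a parcellation
#'
#' @param parc a `parcellation`.
#' @param vol a `tensor_volume`.
#' @param thickness seed-layer thickness in mm (default one voxel).
#' @return list of K integer vectors of linear voxel ids (element k for CU
#'   k); CUs with empty masks trigger a warning and are later excluded from
#'   FiCD statistics.
#' @export
seed_layers <- function(parc, vol, thickness = NULL) {
  masks <- extract_seed_layer(parc$mesh, vol, parc$face_cu, thickness)
  out <- rep(list(integer(0)), parc$K)
  idx <- as.integer(names(masks))
  out[idx] <- masks
  empty <- sum(vapply(out, length, 1L) == 0L)
  if (empty > 0L)
    warning(sprintf("%d cortical unit(s) have empty seed masks; their FiCD is undefined",
                    empty))
  out
}
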