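#' Triangulated cortical surface mesh
#'
#' Container for a triangle mesh of the gray--white matter interface in world
#' coordinates (mm), together with optional named per-vertex scalar maps
#' (FiCD, gray-matter volume, ...). Per-vertex area is defined as one third of
#' the area of the incident triangles, so that vertex areas sum exactly to the
#' total surface area.
#'
#' @param vertices numeric matrix, V x 3, world mm.
#' @param faces integer matrix, F x 3, 1-based vertex indices.
#' @param maps named list of length-V numeric vectors (optional).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, maps = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("faces index vertices outside 1..V")
  for (nm in names(maps)) {
    if (length(maps[[nm]]) != nrow(vertices))
      stop(sprintf("map '%s' has %d values but mesh has %d vertices",
                   nm, length(maps[[nm]]), nrow(vertices)))
  }
  structure(list(vertices = vertices, faces = faces, maps = maps,
                 cache = new.env(parent = emptyenv())),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  if (length(x$maps))
    cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)
n_faces <- function(mesh) nrow(mesh$faces)

mesh_cached <- function(mesh, key, fn) {
  if (!is.null(mesh$cache[[key]])) return(mesh$cache[[key]])
  val <- fn()
  assign(key, val, envir = mesh$cache)
  val
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Triangle areas of a mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector of length F (mm^2).
#' @export
face_areas <- function(mesh) {
  mesh_cached(mesh, "face_areas", function() {
    cr <- face_cross(mesh)
    0.5 * sqrt(rowSums(cr^2))
  })
}

#' Per-vertex areas (one third of incident triangle areas)
#' @param mesh a `surface_mesh`.
#' @return numeric vector of length V (mm^2); sums to the total surface area.
#' @export
vertex_areas <- function(mesh) {
  mesh_cached(mesh, "vertex_areas", function() {
    fa <- face_areas(mesh) / 3
    va <- numeric(n_vertices(mesh))
    for (k in 1:3) {
      s <- tapply(fa, mesh$faces[, k], sum)
      idx <- as.integer(names(s))
      va[idx] <- va[idx] + as.numeric(s)
    }
    va
  })
}

#' Total surface area
#' @param mesh a `surface_mesh`.
#' @return total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Outward vertex normals (area-weighted average of incident face normals)
#' @param mesh a `surface_mesh` whose faces are consistently oriented
#'   counter-clockwise seen from outside.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  mesh_cached(mesh, "vertex_normals", function() {
    cr <- face_cross(mesh)  # per-face normal scaled by 2*area
    vn <- matrix(0, n_vertices(mesh), 3)
    for (k in 1:3) {
      for (d in 1:3) {
        s <- tapply(cr[, d], mesh$faces[, k], sum)
        idx <- as.integer(names(s))
        vn[idx, d] <- vn[idx, d] + as.numeric(s)
      }
    }
    nrm <- sqrt(rowSums(vn^2))
    nrm[nrm == 0] <- 1
    vn / nrm
  })
}

# Unique undirected edges as a 2-column matrix (i < j), with a count of the
# number of faces sharing each edge and the edge lengths in mm.
mesh_edges <- function(mesh) {
  mesh_cached(mesh, "edges", function() {
    f <- mesh$faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    tb <- table(key)
    first <- !duplicated(key)
    eu <- e[first, , drop = FALSE]
    cnt <- as.integer(tb[paste(eu[, 1], eu[, 2])])
    d <- mesh$vertices[eu[, 1], , drop = FALSE] - mesh$vertices[eu[, 2], , drop = FALSE]
    list(edges = eu, count = cnt, length = sqrt(rowSums(d^2)))
  })
}

#' Is the mesh a closed manifold surface?
#'
#' Checks that every edge is shared by exactly two faces.
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
is_closed_mesh <- function(mesh) all(mesh_edges(mesh)$count == 2L)

#' Euler characteristic V - E + F
#' @param mesh a `surface_mesh`.
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(mesh_edges(mesh)$edges) + n_faces(mesh)
}

# Vertex adjacency as a list of integer vectors.
mesh_adjacency <- function(mesh) {
  mesh_cached(mesh, "adjacency", function() {
    ed <- mesh_edges(mesh)$edges
    adj <- vector("list", n_vertices(mesh))
    src <- c(ed[, 1], ed[, 2])
    dst <- c(ed[, 2], ed[, 1])
    o <- order(src)
    src <- src[o]; dst <- dst[o]
    runs <- rle(src)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$values))
      adj[[runs$values[i]]] <- dst[starts[i]:ends[i]]
    adj
  })
}

# Weighted igraph of the vertex graph (edge weights = Euclidean lengths).
mesh_graph <- function(mesh) {
  mesh_cached(mesh, "graph", function() {
    ed <- mesh_edges(mesh)
    g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
    igraph::E(g)$weight <- ed$length
    g
  })
}

# Face adjacency over shared edges: list mapping face -> neighbouring faces.
face_adjacency <- function(mesh) {
  mesh_cached(mesh, "face_adjacency", function() {
    f <- mesh$faces
    nf <- nrow(f)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    fid <- rep(seq_len(nf), 3L)
    key <- e[, 1] * (n_vertices(mesh) + 1) + e[, 2]
    o <- order(key)
    key <- key[o]; fid <- fid[o]
    adj <- vector("list", nf)
    i <- 1L
    n <- length(key)
    while (i < n) {
      j <- i
      while (j < n && key[j + 1L] == key[i]) j <- j + 1L
      if (j > i) {
        grp <- fid[i:j]
        for (a in grp) adj[[a]] <- c(adj[[a]], grp[grp != a])
      }
      i <- j + 1L
    }
    adj
  })
}

# Connected components of a vertex subset under mesh edge connectivity.
# Returns a list of integer vectors (vertex ids), largest first.
vertex_components <- function(mesh, vids) {
  if (length(vids) == 0L) return(list())
  adj <- mesh_adjacency(mesh)
  inset <- logical(n_vertices(mesh))
  inset[vids] <- TRUE
  seen <- logical(n_vertices(mesh))
  comps <- list()
  for (v in vids) {
    if (seen[v]) next
    comp <- integer(0)
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adj[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(-vapply(comps, length, 1L))]
}

# Geodesic disk: the n vertices nearest (graph-geodesic) to a centre vertex.
# Used to place spatially compact effect patches and cluster seeds.
#' Select a connected patch of n vertices around a centre vertex
#'
#' Vertices are ranked by graph-geodesic distance from the centre, giving an
#' approximately circular, edge-connected patch.
#' @param mesh a `surface_mesh`.
#' @param center vertex id (1-based).
#' @param n patch size in vertices.
#' @return integer vector of n vertex ids including `center`.
#' @export
geodesic_patch <- function(mesh, center, n) {
  stopifnot(n >= 1L, n <= n_vertices(mesh))
  d <- as.numeric(igraph::distances(mesh_graph(mesh), v = center))
  sort(order(d)[seq_len(n)])
}
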