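#' Triangular surface mesh
#'
#' Constructs a triangle mesh from vertex coordinates and faces. This is the
#' discretised cortical sheet that all statistics in the package live on.
#' Synthetic sheets generated by [make_folded_sheet()] are periodic in the
#' x/y plane (a torus), which makes the spatial shift permutation test exact;
#' for such meshes `periodic_domain` holds the two period lengths in mm and
#' edge lengths are measured with the minimal-image convention.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param periodic_domain optional numeric length-2, x/y period lengths (mm).
#' @param grid_dim optional integer length-2; present when vertices form a
#'   regular grid (row-major over y, x fastest), enabling cyclic shifts.
#' @return an object of class `fb_mesh` with elements `vertices`, `faces`,
#'   `periodic_domain`, `grid_dim`, and a cached symmetric adjacency list.
#' @export
fb_mesh <- function(vertices, faces, periodic_domain = NULL, grid_dim = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("face references out-of-range vertex")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
          faces[, 1] == faces[, 3]))
    stop("degenerate face (repeated vertex index)")
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         periodic_domain = periodic_domain, grid_dim = grid_dim),
    class = "fb_mesh")
  mesh$adjacency <- .build_adjacency(mesh)
  if (any(lengths(mesh$adjacency) == 0L))
    stop("mesh contains isolated vertices")
  mesh
}

#' @export
print.fb_mesh <- function(x, ...) {
  cat(sprintf("fb_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$periodic_domain))
                sprintf(", periodic domain %g x %g mm",
                        x$periodic_domain[1], x$periodic_domain[2]) else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

.build_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  e <- unique(e)
  unname(split(e[, 2], factor(e[, 1], levels = seq_len(nrow(mesh$vertices)))))
}

#' Mesh-edge neighbours
#'
#' Vertex pairs directly joined by a mesh edge are "neighbours". Returns the
#' symmetric adjacency as a list of integer vectors, one per vertex.
#'
#' @param mesh an [fb_mesh()].
#' @return list of length n_vertices; element v holds the sorted neighbour
#'   indices of vertex v (no self-adjacency).
#' @export
neighbours <- function(mesh) {
  stopifnot(inherits(mesh, "fb_mesh"))
  lapply(mesh$adjacency, function(v) sort(unname(v)))
}

# displacement vectors u -> v respecting the periodic minimal-image rule
.edge_vectors <- function(mesh, from, to) {
  d <- mesh$vertices[to, , drop = FALSE] - mesh$vertices[from, , drop = FALSE]
  if (!is.null(mesh$periodic_domain)) {
    L <- mesh$periodic_domain
    d[, 1] <- d[, 1] - L[1] * round(d[, 1] / L[1])
    d[, 2] <- d[, 2] - L[2] * round(d[, 2] / L[2])
  }
  d
}

# unique undirected edge list with Euclidean lengths
.edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2, 1)]
  e <- unique(e)
  d <- .edge_vectors(mesh, e[, 1], e[, 2])
  list(edges = e, lengths = sqrt(rowSums(d^2)))
}

# 0-based CSR of the weighted edge graph, for the compiled Dijkstra
.adjacency_csr <- function(mesh) {
  et <- .edge_table(mesh)
  e2 <- rbind(et$edges, et$edges[, c(2, 1)])
  w2 <- c(et$lengths, et$lengths)
  o <- order(e2[, 1], e2[, 2])
  e2 <- e2[o, , drop = FALSE]
  w2 <- w2[o]
  n <- n_vertices(mesh)
  cnt <- tabulate(e2[, 1], nbins = n)
  list(ptr = as.integer(c(0L, cumsum(cnt))),
       idx = as.integer(e2[, 2] - 1L), w = as.double(w2))
}

#' Inter-vertex distance map
#'
#' The spatial-sampling-density measure: for each vertex, the mean (or
#' minimum) Euclidean edge length to its mesh neighbours, in mm. On folded
#' cortical meshes this distance is larger on gyral crests than in sulci.
#'
#' @param mesh an [fb_mesh()].
#' @param mode `"mean_neighbour"` (default) or `"nearest_neighbour"`.
#' @return numeric vector, one value (mm) per vertex.
#' @export
inter_vertex_distance <- function(mesh,
                                  mode = c("mean_neighbour",
                                           "nearest_neighbour")) {
  mode <- match.arg(mode)
  et <- .edge_table(mesh)
  n <- n_vertices(mesh)
  from <- c(et$edges[, 1], et$edges[, 2])
  len <- c(et$lengths, et$lengths)
  if (mode == "mean_neighbour") {
    s <- rowsum(len, from)
    out <- rep(NA_real_, n)
    out[as.integer(rownames(s))] <- s[, 1]
    out / tabulate(from, nbins = n)
  } else {
    out <- rep(Inf, n)
    for (i in seq_along(from))
      if (len[i] < out[from[i]]) out[from[i]] <- len[i]
    out
  }
}

#' Vertex areas
#'
#' Allots 1/3 of each triangle's area to each of its three vertices; a
#' vertex's area is the sum of allotments over all incident triangles. The
#' total vertex area equals the total surface area exactly.
#'
#' @param mesh an [fb_mesh()].
#' @return numeric vector of areas (mm^2), one per vertex.
#' @export
vertex_areas <- function(mesh) {
  f <- mesh$faces
  ab <- .edge_vectors(mesh, f[, 1], f[, 2])
  ac <- .edge_vectors(mesh, f[, 1], f[, 3])
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  if (any(fa == 0)) warning("zero-area face(s); contribute 0 to vertex areas")
  share <- rep(fa / 3, 3L)
  idx <- c(f[, 1], f[, 2], f[, 3])
  out <- numeric(n_vertices(mesh))
  acc <- rowsum(share, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Truncated geodesic distances
#'
#' Shortest-path distances along the mesh edge graph (edges weighted by
#' Euclidean length), computed by truncated Dijkstra from each source with
#' early termination at `max_radius`. Pairs farther apart than the radius are
#' simply absent. This edge-graph geodesic slightly overestimates the exact
#' polyhedral geodesic but is accurate at the 2-15 mm scales used here.
#'
#' @param mesh an [fb_mesh()].
#' @param sources integer vertex indices (default: all vertices).
#' @param max_radius radius in mm (> 0).
#' @return data.frame with columns `from`, `to`, `d` (mm); includes each
#'   source at distance 0 to itself.
#' @export
geodesic_distances <- function(mesh, sources = seq_len(n_vertices(mesh)),
                               max_radius) {
  stopifnot(max_radius > 0)
  csr <- .adjacency_csr(mesh)
  res <- .dijkstra_radius(n_vertices(mesh), csr$ptr, csr$idx, csr$w,
                          as.integer(sources - 1L), as.double(max_radius))
  data.frame(from = res$i + 1L, to = res$j + 1L, d = res$d)
}
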