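#' Construct a triangulated surface mesh
#'
#' Validates vertex and face arrays, precomputes the vertex adjacency list
#' and the unique edge set with Euclidean edge lengths. Vertices are
#' 1-indexed throughout the package (file formats that index from 0, such
#' as GIFTI, are converted on read/write); coordinates are in mm in a
#' right-handed RAS-like frame matching the MNI convention.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, three vertex indices
#'   (1-based).
#' @return Object of class `surface_mesh`: list with `vertices`, `faces`,
#'   `adjacency` (list of sorted neighbor indices), `edges` (2-column
#'   matrix), `edge_lengths`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  nv <- nrow(vertices)
  if (any(faces < 1L) || any(faces > nv))
    stop("face indices out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
          faces[, 2] == faces[, 3]))
    stop("degenerate face (repeated vertex)")
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  lens <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                        vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", nv)
  nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adj[as.integer(names(nb))] <- lapply(nb, function(v) sort(unique(v)))
  for (i in seq_len(nv)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  structure(list(vertices = vertices, faces = faces, adjacency = adj,
                 edges = e, edge_lengths = lens),
            class = "surface_mesh")
}

#' @method print surface_mesh
#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces, %d edges (mean edge %.2f mm)\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges),
              mean(x$edge_lengths)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
}

#' Build a geodesic icosphere mesh
#'
#' Starts from a regular icosahedron and subdivides each triangle into four
#' `subdivisions` times, projecting new vertices back to the sphere. Vertex
#' count is `10 * 4^s + 2`. Useful as a closed, nearly regular test surface
#' standing in for a registered cortical template.
#'
#' @param subdivisions nonnegative integer.
#' @param radius_mm sphere radius in mm.
#' @return A [surface_mesh()].
#' @examples
#' build_icosphere(2, 80)  # 162 vertices
#' @export
build_icosphere <- function(subdivisions = 2, radius_mm = 80) {
  stopifnot(subdivisions >= 0, radius_mm > 0)
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
  for (s in seq_len(subdivisions)) {
    midpoint_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midpoint_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      midpoint_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  surface_mesh(v * radius_mm, f)
}

#' Connected components of a masked vertex set
#'
#' Maximal edge-connected sets of vertices within a logical mask. Component
#' labels are deterministic: components are numbered 1, 2, ... in order of
#' their smallest vertex index.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_mask logical vector, one per vertex.
#' @return Integer vector, one per vertex: 0 outside the mask, otherwise
#'   the component label.
#' @export
connected_components <- function(mesh, vertex_mask) {
  nv <- n_vertices(mesh)
  if (length(vertex_mask) != nv) stop("mask length must equal vertex count")
  vertex_mask <- as.logical(vertex_mask)
  labels <- integer(nv)
  if (!any(vertex_mask)) return(labels)
  keep <- mesh$edges[vertex_mask[mesh$edges[, 1]] &
                     vertex_mask[mesh$edges[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  masked <- which(vertex_mask)
  # renumber by smallest member index
  first_seen <- comp[masked][!duplicated(comp[masked])]
  relabel <- integer(max(comp))
  relabel[first_seen] <- seq_along(first_seen)
  labels[masked] <- relabel[comp[masked]]
  labels
}

# Smoothing operator internals: one iteration of the symmetric neighbor
# exchange x <- x + (lambda/maxdeg) * (A x - d x). Because the update matrix
# is symmetric with unit row sums, the total sum of x is preserved exactly on
# any mesh, and positivity is preserved whenever lambda <= 1.
smoothing_plan <- function(mesh, fwhm_mm, lambda_max = 0.9) {
  deg <- lengths(mesh$adjacency)
  maxdeg <- max(deg)
  h2 <- mean(mesh$edge_lengths^2)
  sigma2 <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  # per-iteration per-dimension variance of the lazy neighbor walk:
  # q * h^2 / 2 with move probability q = lambda * mean(deg) / maxdeg
  gain_max <- lambda_max * mean(deg) / maxdeg * h2 / 2
  m <- max(1L, ceiling(sigma2 / gain_max))
  lambda <- sigma2 / (m * mean(deg) / maxdeg * h2 / 2)
  list(iterations = m, lambda = min(lambda, lambda_max), maxdeg = maxdeg)
}

#' Smooth per-vertex values on a mesh with an FWHM-calibrated kernel
#'
#' Iterated symmetric neighbor averaging (a lazy diffusion / umbrella
#' operator) whose iteration count and step size are calibrated so the
#' effective kernel matches a Gaussian of the requested full width at half
#' maximum, using the random-walk variance relation
#' `sigma^2 = m * q * hbar^2 / 2` for mean-squared edge length `hbar^2`.
#' The operator is symmetric with unit row sums, so the vertex-sum of the
#' input is preserved exactly and nonnegative inputs stay nonnegative.
#'
#' @param mesh a [surface_mesh()].
#' @param vertex_values numeric vector (length = vertex count) or matrix
#'   with one map per row (subjects x vertices).
#' @param fwhm_mm requested kernel FWHM in mm; 0 returns the input
#'   unchanged.
#' @return Smoothed values, same shape as the input.
#' @export
smooth_metric <- function(mesh, vertex_values, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1 || fwhm_mm < 0)
    stop("fwhm_mm must be a single nonnegative number")
  vec_in <- is.null(dim(vertex_values))
  x <- if (vec_in) matrix(vertex_values, nrow = 1) else as.matrix(vertex_values)
  nv <- n_vertices(mesh)
  if (ncol(x) != nv) stop("vertex_values must have one value per vertex")
  if (fwhm_mm == 0) return(vertex_values)
  plan <- smoothing_plan(mesh, fwhm_mm)
  W <- Matrix::sparseMatrix(i = c(mesh$edges[, 1], mesh$edges[, 2]),
                            j = c(mesh$edges[, 2], mesh$edges[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- lengths(mesh$adjacency)
  xt <- Matrix::t(Matrix::Matrix(x, sparse = FALSE))  # vertices x maps
  step <- plan$lambda / plan$maxdeg
  for (i in seq_len(plan$iterations)) {
    xt <- xt + step * (W %*% xt - deg * xt)
  }
  out <- t(as.matrix(xt))
  if (vec_in) drop(out) else out
}

#' Spherical ROI mask by Euclidean distance
#'
#' Marks every vertex whose Euclidean distance to a center point (mm) is at
#' most the radius — the standard "sphere at an MNI coordinate" region
#' definition.
#'
#' @param mesh a [surface_mesh()].
#' @param center_mm numeric length-3 center coordinate.
#' @param radius_mm sphere radius (> 0).
#' @return Logical vertex mask.
#' @export
sphere_roi <- function(mesh, center_mm, radius_mm) {
  stopifnot(length(center_mm) == 3, radius_mm > 0)
  d2 <- colSums((t(mesh$vertices) - center_mm)^2)
  d2 <= radius_mm^2
}

#' Geodesic disc around a seed vertex
#'
#' All vertices whose graph-geodesic distance (edge-length-weighted shortest
#' path along mesh edges) to the seed is at most the radius.
#'
#' @param mesh a [surface_mesh()].
#' @param seed_vertex 1-based vertex index.
#' @param radius_mm geodesic radius in mm (>= 0; 0 selects only the seed).
#' @return Logical vertex mask (always edge-connected).
#' @export
geodesic_disc <- function(mesh, seed_vertex, radius_mm) {
  nv <- n_vertices(mesh)
  if (seed_vertex < 1 || seed_vertex > nv) stop("seed_vertex outside mesh")
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, v = seed_vertex, weights = mesh$edge_lengths)
  as.vector(d) <= radius_mm
}

#' Geodesic distances from a seed vertex
#'
#' @param mesh a [surface_mesh()].
#' @param seed_vertex 1-based vertex index.
#' @return Numeric vector of edge-weighted shortest-path distances (mm).
#' @export
geodesic_distances <- function(mesh, seed_vertex) {
  g <- mesh_graph(mesh)
  as.vector(igraph::distances(g, v = seed_vertex,
                              weights = mesh$edge_lengths))
}
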