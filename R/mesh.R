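#' Construct a triangle mesh
#'
#' A triangle mesh is the raw representation of a structure surface: a matrix
#' of 3-D vertex positions (in mm) and a matrix of oriented vertex-index
#' triples. Construction validates index ranges and rejects degenerate
#' (zero-area) faces.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices;
#'   rows are counter-clockwise when seen from outside.
#' @param validate if `TRUE` (default), check index ranges, degenerate faces
#'   and isolated vertices.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh",
                    edge_cache = new.env(parent = emptyenv()))
  if (validate) {
    if (nrow(faces) > 0L) {
      rng <- range(faces)
      if (rng[1] < 1L || rng[2] > nrow(vertices))
        stop("face vertex index out of range [1, ", nrow(vertices), "]")
      a <- face_areas(mesh)
      if (any(a <= .Machine$double.eps * max(a, 1)))
        stop("degenerate (zero-area) faces: ",
             paste(utils::head(which(a <= .Machine$double.eps * max(a, 1)), 5),
                   collapse = ", "))
      used <- tabulate(faces, nbins = nrow(vertices))
      if (any(used == 0L))
        stop("isolated vertices (not referenced by any face): ",
             paste(utils::head(which(used == 0L), 5), collapse = ", "))
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<%s> %d vertices, %d faces\n",
              class(x)[1], nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected edge table. Returns list with:
#   edges   : e x 2 matrix, each row sorted (i < j)
#   count   : number of incident faces per undirected edge
#   he      : 3m x 2 matrix of directed (half) edges in face order
#   he_edge : index into `edges` for every half edge
mesh_edge_table <- function(mesh) {
  cache <- attr(mesh, "edge_cache")
  if (!is.null(cache) && !is.null(cache$et)) return(cache$et)
  f <- mesh$faces
  he <- rbind(f[, c(1, 2), drop = FALSE],
              f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  lo <- pmin(he[, 1], he[, 2])
  hi <- pmax(he[, 1], he[, 2])
  key <- lo * (nrow(mesh$vertices) + 1) + hi
  uk <- sort(unique(key))
  idx <- match(key, uk)
  count <- tabulate(idx, nbins = length(uk))
  first <- match(uk, key)
  edges <- cbind(lo[first], hi[first])
  et <- list(edges = edges, count = count, he = he, he_edge = idx)
  if (!is.null(cache)) cache$et <- et
  et
}

# Ordered boundary loops as lists of vertex index cycles.  A boundary half
# edge is a directed edge whose reverse does not occur; loops follow the
# induced orientation.
boundary_loops <- function(mesh) {
  et <- mesh_edge_table(mesh)
  n <- nrow(mesh$vertices)
  dir_key <- et$he[, 1] * (n + 1) + et$he[, 2]
  rev_key <- et$he[, 2] * (n + 1) + et$he[, 1]
  is_bnd <- !(rev_key %in% dir_key)
  bnd <- et$he[is_bnd, , drop = FALSE]
  if (nrow(bnd) == 0L) return(list())
  # boundary of an oriented manifold: each boundary vertex has exactly one
  # outgoing boundary half edge (reverse orientation of face half edges)
  nxt <- rep(NA_integer_, n)
  # traverse opposite to the face half-edge direction so loops are oriented
  nxt[bnd[, 2]] <- bnd[, 1]
  loops <- list()
  visited <- rep(FALSE, n)
  starts <- sort(unique(bnd[, 2]))
  for (s in starts) {
    if (visited[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      loop <- c(loop, v)
      visited[v] <- TRUE
      v <- nxt[v]
      if (is.na(v)) stop("open boundary chain: mesh is not edge-manifold")
      if (v == s) break
      if (visited[v]) stop("boundary traversal revisited vertex ", v)
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Topology report for a triangle mesh
#'
#' Counts vertices, edges and faces, enumerates boundary loops, and derives
#' the genus from the Euler formula V - E + F = 2 - 2g - b. Non-manifold
#' edges (shared by more than two faces) or inconsistently oriented faces
#' (a directed edge appearing twice) raise an error listing the offenders.
#'
#' @param mesh a `triangle_mesh`.
#' @return A list with `n_vertices`, `n_edges`, `n_faces`, `euler`,
#'   `n_boundaries`, `boundary_loops` (list of vertex cycles), `genus` and
#'   `manifold`.
#' @export
validate_topology <- function(mesh) {
  et <- mesh_edge_table(mesh)
  bad <- which(et$count > 2L)
  if (length(bad))
    stop("non-manifold edges (more than 2 incident faces): ",
         paste(apply(et$edges[utils::head(bad, 5), , drop = FALSE], 1,
                     paste, collapse = "-"), collapse = ", "))
  n <- nrow(mesh$vertices)
  dir_key <- et$he[, 1] * (n + 1) + et$he[, 2]
  if (anyDuplicated(dir_key))
    stop("inconsistent face orientation: directed edge used twice (e.g. ",
         paste(et$he[which(duplicated(dir_key))[1], ], collapse = "->"), ")")
  loops <- boundary_loops(mesh)
  V <- n; E <- nrow(et$edges); F <- nrow(mesh$faces)
  chi <- V - E + F
  b <- length(loops)
  g2 <- 2 - b - chi
  if (g2 %% 2 != 0) stop("non-integer genus: surface is not a 2-manifold")
  list(n_vertices = V, n_edges = E, n_faces = F, euler = chi,
       n_boundaries = b, boundary_loops = loops, genus = g2 %/% 2,
       manifold = TRUE)
}

# vertex indices lying on any boundary loop
boundary_vertices <- function(mesh) {
  sort(unique(unlist(boundary_loops(mesh))))
}
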