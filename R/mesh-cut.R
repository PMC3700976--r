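# Topology optimization: open a closed genus-zero surface into a topological
# cylinder by removing two small vertex patches at geometrically extreme
# positions along the first principal axis.  The two resulting boundary
# loops serve as consistent landmarks across subjects.

# first principal axis of the vertex cloud with a deterministic fallback
# when the top eigenvalues are (numerically) tied: use the coordinate axis
# with the largest vertex range, ties broken in x < y < z order.
principal_axes <- function(vertices) {
  c0 <- sweep(vertices, 2, colMeans(vertices))
  ev <- eigen(crossprod(c0) / nrow(c0), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) <=
      1e-8 * max(ev$values[1], .Machine$double.eps)) {
    # degenerate (sphere-like) cloud: fall back to coordinate axes ranked
    # by vertex range, ties broken in x < y < z order
    rng <- apply(vertices, 2, function(x) diff(range(x)))
    ord <- order(-rng, seq_len(3))
    return(diag(3)[, ord, drop = FALSE])
  }
  ax <- ev$vectors
  # fix signs so results do not depend on eigensolver conventions
  for (k in 1:3) {
    j <- which.max(abs(ax[, k]))
    if (ax[j, k] < 0) ax[, k] <- -ax[, k]
  }
  ax
}

principal_axis <- function(vertices) principal_axes(vertices)[, 1]

# vertex indices within k graph hops of `seed`
k_ring <- function(mesh, seed, k, adj = vertex_adjacency(mesh)) {
  ring <- seed
  frontier <- seed
  for (step in seq_len(k)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), ring)
    ring <- c(ring, frontier)
  }
  sort(ring)
}

# adjacency lists for all vertices (list of integer vectors)
vertex_adjacency <- function(mesh) {
  et <- mesh_edge_table(mesh)
  n <- nrow(mesh$vertices)
  src <- c(et$edges[, 1], et$edges[, 2])
  dst <- c(et$edges[, 2], et$edges[, 1])
  adj <- vector("list", n)
  s <- split(dst, src)
  adj[as.integer(names(s))] <- s
  adj
}

#' Cut a closed surface into a topological cylinder
#'
#' Removes the faces incident to a k-ring vertex patch around each of the
#' two extreme vertices along the first principal axis of the vertex cloud,
#' producing a genus-zero surface with two open boundaries. The boundary
#' loop on the larger-projection side is labeled *anterior*, the other
#' *posterior*; the anterior loop is loop A of the parameterization (u = 0).
#'
#' @param mesh closed genus-zero [triangle_mesh()].
#' @param k ring depth of the removed patches (default 2).
#' @return A `cylinder_mesh`: a `triangle_mesh` with extra elements
#'   `loop_anterior` and `loop_posterior` (ordered vertex cycles),
#'   `orig_index` (index of each kept vertex in the input mesh) and `axis`
#'   (the principal axis used).
#' @export
cut_extremities <- function(mesh, k = 2) {
  top <- validate_topology(mesh)
  if (top$genus != 0 || top$n_boundaries != 0)
    stop("cut_extremities needs a closed genus-zero mesh (got genus ",
         top$genus, ", ", top$n_boundaries, " boundaries)")
  axes <- principal_axes(mesh$vertices)
  ax <- axes[, 1]
  proj <- drop(mesh$vertices %*% ax)
  v_max <- which.max(proj)[1]   # anterior extreme
  v_min <- which.min(proj)[1]   # posterior extreme
  adj <- vertex_adjacency(mesh)
  patch_a <- k_ring(mesh, v_max, k, adj)
  patch_p <- k_ring(mesh, v_min, k, adj)
  if (length(intersect(patch_a, patch_p)))
    stop("cut patches overlap: structure too small for k = ", k)
  drop_v <- c(patch_a, patch_p)
  keep_face <- !apply(matrix(mesh$faces %in% drop_v, ncol = 3), 1, any)
  f <- mesh$faces[keep_face, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  cyl <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(remap[f], ncol = 3))
  top2 <- validate_topology(cyl)
  if (top2$genus != 0 || top2$n_boundaries != 2)
    stop("cut did not produce a topological cylinder (genus ", top2$genus,
         ", ", top2$n_boundaries, " boundaries); increase mesh resolution ",
         "or decrease k")
  # label loops by mean projection of their vertices onto the axis
  loop_proj <- vapply(top2$boundary_loops,
                      function(l) mean(proj[used[l]]), 0)
  ord <- order(loop_proj, decreasing = TRUE)
  cyl$loop_anterior <- top2$boundary_loops[[ord[1]]]
  cyl$loop_posterior <- top2$boundary_loops[[ord[2]]]
  cyl$orig_index <- used
  cyl$axis <- ax
  # the second principal axis anchors the circular coordinate's origin
  # consistently across subjects (see seam_path)
  cyl$axis2 <- axes[, 2]
  class(cyl) <- c("cylinder_mesh", class(cyl))
  cyl
}
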