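# Conformal rectangle parameterization of a topological cylinder via
# holomorphic 1-forms: a harmonic function between the two boundary loops
# gives the harmonic 1-form; its conjugate is found by rotating the face
# gradients by 90 degrees in each tangent plane and re-integrating in the
# least-squares sense on the seam-cut mesh.  Integrating the pair maps the
# surface onto a rectangle [0,1] x [0,h), h the conformal modulus.

#' Harmonic function between the boundary loops of a cylinder mesh
#'
#' Solves the discrete (cotangent) Laplace equation with Dirichlet data 0 on
#' the anterior loop and 1 on the posterior loop.
#'
#' @param cyl a `cylinder_mesh` from [cut_extremities()] (or any
#'   `triangle_mesh` carrying `loop_anterior`/`loop_posterior`).
#' @return numeric vector, one value per vertex, in `[0, 1]` up to the
#'   discrete maximum principle.
#' @export
harmonic_function <- function(cyl) {
  n <- nrow(cyl$vertices)
  L <- cotan_laplacian(cyl)
  f <- numeric(n)
  fixed <- c(cyl$loop_anterior, cyl$loop_posterior)
  f[cyl$loop_posterior] <- 1
  free <- setdiff(seq_len(n), fixed)
  if (!length(free)) return(f)
  rhs <- -L[free, fixed, drop = FALSE] %*% f[fixed]
  sol <- tryCatch(
    Matrix::solve(L[free, free], rhs),
    error = function(e) stop("harmonic system is singular (disconnected ",
                             "mesh?): ", conditionMessage(e)))
  f[free] <- as.numeric(sol)
  f
}

#' Exterior derivative of a vertex function as a discrete 1-form
#'
#' The harmonic 1-form of the parameterization is `d` of the harmonic
#' function: omega(i -> j) = f_j - f_i.  Values are stored on undirected
#' edges with the convention "from lower to higher vertex index".
#'
#' @param cyl the mesh the function lives on.
#' @param f per-vertex values.
#' @return an object of class `oneform` with elements `edges` (e x 2,
#'   lo < hi) and `values`.
#' @export
harmonic_oneform <- function(cyl, f) {
  et <- mesh_edge_table(cyl)
  omega <- structure(list(edges = et$edges,
                          values = f[et$edges[, 2]] - f[et$edges[, 1]]),
                     class = "oneform")
  attr(omega, "potential") <- f
  omega
}

# directed value of a 1-form on edges given as (from, to) index vectors
oneform_directed <- function(omega, from, to, n_vertices) {
  key <- pmin(from, to) * (n_vertices + 1) + pmax(from, to)
  ekey <- omega$edges[, 1] * (n_vertices + 1) + omega$edges[, 2]
  idx <- match(key, ekey)
  if (anyNA(idx)) stop("edge not present in 1-form")
  omega$values[idx] * ifelse(from < to, 1, -1)
}

#' Sum of a 1-form around every face
#'
#' Exact closedness (zero within rounding) holds for exterior derivatives of
#' vertex functions; the conjugate form is closed on its cut mesh by
#' construction.
#'
#' @param mesh mesh carrying the faces.
#' @param omega a `oneform` on that mesh.
#' @return numeric vector of face circulation values.
#' @export
oneform_face_sums <- function(mesh, omega) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  oneform_directed(omega, f[, 1], f[, 2], n) +
    oneform_directed(omega, f[, 2], f[, 3], n) +
    oneform_directed(omega, f[, 3], f[, 1], n)
}

# discrete L2 inner product of two 1-forms via cotangent edge weights
oneform_inner <- function(mesh, omega1, omega2) {
  f <- mesh$faces
  ct <- face_cotans(mesh)
  n <- nrow(mesh$vertices)
  i <- c(f[, 2], f[, 3], f[, 1])
  j <- c(f[, 3], f[, 1], f[, 2])
  w <- c(ct[, 1], ct[, 2], ct[, 3]) / 2
  v1 <- oneform_directed(omega1, i, j, n)
  v2 <- oneform_directed(omega2, i, j, n)
  sum(w * v1 * v2)
}

# ---- seam ------------------------------------------------------------------

# Seam between the two boundary loops, anchoring the circular coordinate's
# origin: it starts at the anterior-loop vertex with the largest projection
# onto the second principal axis (a geometrically consistent landmark
# across subjects) and follows the shortest weighted graph path to the
# posterior loop, ties broken by lowest vertex index.
seam_path <- function(cyl) {
  et <- mesh_edge_table(cyl)
  len <- row_norm(cyl$vertices[et$edges[, 1], , drop = FALSE] -
                  cyl$vertices[et$edges[, 2], , drop = FALSE])
  # heavily penalize edges touching the boundary so the seam leaves the
  # loops immediately and never runs along or through them
  bnd <- c(cyl$loop_anterior, cyl$loop_posterior)
  touches <- (et$edges[, 1] %in% bnd) + (et$edges[, 2] %in% bnd)
  w <- len * 1000^touches
  g <- igraph::graph_from_edgelist(et$edges, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = w)
  a <- cyl$loop_anterior
  b <- sort(cyl$loop_posterior)
  ref <- cyl$axis2
  if (is.null(ref)) ref <- principal_axes(cyl$vertices)[, 2]
  pr <- drop(cyl$vertices[a, , drop = FALSE] %*% ref)
  a0 <- a[which.max(pr)]
  d <- igraph::distances(g, v = a0, to = b)
  b0 <- b[order(drop(d), b)[1]]
  p <- igraph::shortest_paths(g, from = a0, to = b0,
                              output = "vpath")$vpath[[1]]
  as.integer(p)
}

# Cut the cylinder mesh open along a seam path running from loop A to
# loop B.  Faces on the left of the path (those containing the forward
# directed half edge) reference duplicated seam vertices, which opens the
# cylinder into a topological disk.  Returns the cut mesh, the map from cut
# vertices to original vertices, and the (original, duplicate) seam pairs.
cut_along_path <- function(cyl, path) {
  n <- nrow(cyl$vertices)
  f <- cyl$faces
  m <- nrow(f)
  he_face <- rep(seq_len(m), 3)
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  he_key <- he_from * (n + 1) + he_to
  seam_edges <- cbind(path[-length(path)], path[-1])
  seam_key_und <- pmin(seam_edges[, 1], seam_edges[, 2]) * (n + 1) +
    pmax(seam_edges[, 1], seam_edges[, 2])
  faces_new <- f
  vmap <- seq_len(n)         # cut vertex -> original vertex
  pairs <- NULL
  for (pi in seq_along(path)) {
    v <- path[pi]
    inc <- which(f[, 1] == v | f[, 2] == v | f[, 3] == v)
    # ring graph: faces incident to v, connected when sharing a non-seam
    # edge through v
    nb <- lapply(inc, function(fi) {
      vs <- f[fi, ]
      setdiff(vs, v)
    })
    comp <- seq_along(inc)     # union-find over local face list
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (ia in seq_along(inc)) {
      for (ib in seq_along(inc)) {
        if (ib <= ia) next
        shared <- intersect(nb[[ia]], nb[[ib]])
        for (w in shared) {
          ekey <- min(v, w) * (n + 1) + max(v, w)
          if (!(ekey %in% seam_key_und)) {
            ra <- find(ia); rb <- find(ib)
            if (ra != rb) comp[ra] <- rb
          }
        }
      }
    }
    roots <- vapply(seq_along(inc), find, 1L)
    # component on the left of the path: the one holding the face with the
    # forward directed half edge
    if (pi < length(path)) {
      fwd <- he_face[match(v * (n + 1) + path[pi + 1], he_key)]
    } else {
      fwd <- he_face[match(path[pi - 1] * (n + 1) + v, he_key)]
    }
    if (is.na(fwd)) stop("seam edge has no incident face")
    left_root <- roots[match(fwd, inc)]
    left_faces <- inc[roots == left_root]
    if (length(left_faces) == length(inc))
      stop("seam does not separate the one-ring at vertex ", v)
    new_id <- length(vmap) + 1L
    vmap <- c(vmap, v)
    fl <- faces_new[left_faces, , drop = FALSE]
    fl[f[left_faces, , drop = FALSE] == v] <- new_id
    faces_new[left_faces, ] <- fl
    pairs <- rbind(pairs, c(v, new_id))
  }
  cut <- structure(list(vertices = cyl$vertices[vmap, , drop = FALSE],
                        faces = faces_new),
                   class = "triangle_mesh",
                   edge_cache = new.env(parent = emptyenv()))
  list(mesh = cut, vmap = vmap, pairs = pairs)
}

# ---- conjugate 1-form ------------------------------------------------------

# per-face gradient of a vertex function (rows = faces)
face_gradients <- function(mesh, f) {
  cc <- face_corner_coords(mesh)
  nrm <- row_cross(cc$p2 - cc$p1, cc$p3 - cc$p1)
  A2 <- pmax(row_norm(nrm), .Machine$double.xmin)
  nhat <- nrm / A2
  e1 <- cc$p3 - cc$p2   # opposite corner 1
  e2 <- cc$p1 - cc$p3
  e3 <- cc$p2 - cc$p1
  g <- (f[mesh$faces[, 1]] * row_cross(nhat, e1) +
        f[mesh$faces[, 2]] * row_cross(nhat, e2) +
        f[mesh$faces[, 3]] * row_cross(nhat, e3)) / A2
  g
}

#' Conjugate harmonic 1-form on the seam-cut cylinder
#'
#' Rotates the face-wise gradient of the harmonic function by 90 degrees
#' about each face normal and re-integrates it, in the least-squares sense,
#' to a vertex function v on the mesh cut open along a seam path between the
#' two boundary loops. The conjugate form is d v on the cut mesh; the jump
#' of v across the seam is the conformal modulus h (the circular period).
#'
#' @param cyl a `cylinder_mesh`.
#' @param omega harmonic 1-form from [harmonic_oneform()].
#' @return a `oneform` on the cut mesh, with attributes `cut` (cut mesh,
#'   vertex map, seam pairs), `v` (the conjugate potential), `h` (conformal
#'   modulus) and `seam` (the seam path in original indices).
#' @export
conjugate_oneform <- function(cyl, omega) {
  f <- attr(omega, "potential")
  if (is.null(f)) {
    # recover the potential by integrating omega along a spanning tree
    f <- integrate_tree(cyl, omega, root = 1L)
  }
  seam <- seam_path(cyl)
  cut <- cut_along_path(cyl, seam)
  f_cut <- f[cut$vmap]
  w <- face_gradients(cut$mesh, f_cut)
  nhat <- face_normals(cut$mesh)
  rot <- row_cross(nhat, w)
  # FEM right-hand side: b_i = sum_T A_T grad(phi_i) . rot_T
  cc <- face_corner_coords(cut$mesh)
  nrm <- row_cross(cc$p2 - cc$p1, cc$p3 - cc$p1)
  A2 <- pmax(row_norm(nrm), .Machine$double.xmin)
  nunit <- nrm / A2
  contrib <- function(eopp) row_dot(row_cross(nunit, eopp), rot) / 2
  b_contrib <- cbind(contrib(cc$p3 - cc$p2),
                     contrib(cc$p1 - cc$p3),
                     contrib(cc$p2 - cc$p1))
  nc <- nrow(cut$mesh$vertices)
  b <- numeric(nc)
  for (k in 1:3) {
    s <- rowsum(b_contrib[, k], cut$mesh$faces[, k], reorder = FALSE)
    b[as.integer(rownames(s))] <- b[as.integer(rownames(s))] + s
  }
  L <- cotan_laplacian(cut$mesh)
  # Constrain the seam jump to a single unknown period h: v_cut = P v0 + h e
  # with P folding duplicates onto their originals and e the duplicate
  # indicator.  The joint least-squares system in (v0, h) keeps the
  # conjugate potential single-valued up to an exact h-jump across the
  # seam, so the parameter domain tiles the strip without gaps.
  n0 <- nrow(cyl$vertices)
  P <- Matrix::sparseMatrix(i = seq_len(nc), j = cut$vmap, x = 1,
                            dims = c(nc, n0))
  e <- numeric(nc); e[cut$pairs[, 2]] <- 1
  PtLP <- Matrix::t(P) %*% L %*% P
  PtLe <- Matrix::t(P) %*% (L %*% e)
  A <- rbind(cbind(PtLP, PtLe),
             cbind(Matrix::t(PtLe), sum(e * (L %*% e))))
  rhs <- c(as.numeric(Matrix::t(P) %*% b), sum(e * b))
  # pin v0[1] = 0 (the potential is defined up to a constant)
  keep <- c(2:n0, n0 + 1L)
  sol <- as.numeric(Matrix::solve(A[keep, keep], rhs[keep]))
  v0 <- c(0, sol[seq_len(n0 - 1)])
  h <- sol[n0]
  v <- as.numeric(P %*% v0 + h * e)
  if (abs(h) < 1e-12 * max(abs(v), 1))
    stop("zero circular period: degenerate cylinder geometry")
  if (h < 0) { v <- -v; h <- -h }
  et <- mesh_edge_table(cut$mesh)
  ostar <- structure(list(edges = et$edges,
                          values = v[et$edges[, 2]] - v[et$edges[, 1]]),
                     class = "oneform")
  attr(ostar, "cut") <- cut
  attr(ostar, "v") <- v
  attr(ostar, "h") <- h
  attr(ostar, "seam") <- seam
  ostar
}

# integrate a closed 1-form along a BFS spanning tree from `root`
integrate_tree <- function(mesh, omega, root = 1L) {
  g <- igraph::graph_from_edgelist(
    mesh_edge_table(mesh)$edges, directed = FALSE)
  bfs <- igraph::bfs(g, root = root, father = TRUE, order = TRUE,
                     unreachable = FALSE)
  ord <- as.integer(bfs$order)
  father <- as.integer(bfs$father)
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  ord <- ord[!is.na(ord)]
  kids <- ord[ord != root]
  vals <- oneform_directed(omega, father[kids], kids, n)
  for (i in seq_along(kids)) out[kids[i]] <- out[father[kids[i]]] + vals[i]
  out
}

#' Integrate the holomorphic 1-form pair to rectangle coordinates
#'
#' Integrates `(omega, omega_star)` along a spanning tree of the seam-cut
#' mesh from the seam's anterior endpoint, normalizes the axial coordinate u
#' to `[0, 1]` (anterior loop at 0) and reduces the circular coordinate v
#' modulo the conformal modulus h, with the v origin anchored at the seam.
#' The resulting parameter triangles must all be positively oriented; flipped
#' triangles raise an error reporting their count and indices.
#'
#' @param cyl a `cylinder_mesh`.
#' @param omega harmonic 1-form.
#' @param omega_star conjugate 1-form from [conjugate_oneform()].
#' @return a `param_mesh`: the cylinder mesh plus `u`, `v` (per vertex),
#'   `h`, `corner_u`/`corner_v` (per face corner, v unwrapped across the
#'   seam), and the cut/seam bookkeeping.
#' @export
integrate_to_rectangle <- function(cyl, omega, omega_star) {
  cut <- attr(omega_star, "cut")
  seam <- attr(omega_star, "seam")
  h <- attr(omega_star, "h")
  if (is.null(cut)) stop("omega_star must come from conjugate_oneform()")
  # omega lives on the original mesh; lift to the cut mesh edges
  n <- nrow(cyl$vertices)
  et_cut <- mesh_edge_table(cut$mesh)
  lift <- structure(list(
    edges = et_cut$edges,
    values = oneform_directed(omega, cut$vmap[et_cut$edges[, 1]],
                              cut$vmap[et_cut$edges[, 2]], n)),
    class = "oneform")
  root <- seam[1]                      # anterior seam endpoint, original copy
  u_cut <- integrate_tree(cut$mesh, lift, root = root)
  v_cut <- integrate_tree(cut$mesh, omega_star, root = root)
  # normalize u to [0,1] with the anterior loop at 0
  u_cut <- u_cut - min(u_cut)
  ru <- max(u_cut)
  if (ru <= 0) stop("degenerate axial coordinate")
  u_cut <- u_cut / ru
  if (mean(u_cut[cut$vmap %in% cyl$loop_anterior]) > 0.5)
    u_cut <- 1 - u_cut
  # orientation: require positive parameter areas for the majority, else
  # flip the circular direction
  fc <- cut$mesh$faces
  area2 <- (u_cut[fc[, 2]] - u_cut[fc[, 1]]) *
    (v_cut[fc[, 3]] - v_cut[fc[, 1]]) -
    (u_cut[fc[, 3]] - u_cut[fc[, 1]]) *
    (v_cut[fc[, 2]] - v_cut[fc[, 1]])
  if (stats::median(sign(area2)) < 0) {
    v_cut <- -v_cut
    area2 <- -area2
  }
  flipped <- which(area2 <= 0)
  if (length(flipped))
    stop("parameterization is not locally injective: ", length(flipped),
         " flipped parameter triangles (faces ",
         paste(utils::head(flipped, 10), collapse = ", "), ")")
  # per-vertex coordinates from the original-copy values (cut vertices
  # 1..n are the originals, duplicates are appended after)
  u <- u_cut[seq_len(n)]
  v <- ((v_cut[seq_len(n)] %% h) + h) %% h
  param <- list(mesh = cyl, u = u, v = v, h = h,
                corner_u = matrix(u_cut[fc], ncol = 3),
                corner_v = matrix(v_cut[fc], ncol = 3),
                cut = cut, seam = seam,
                cache = new.env(parent = emptyenv()))
  class(param) <- "param_mesh"
  param
}

#' @export
print.param_mesh <- function(x, ...) {
  cat(sprintf("<param_mesh> %d vertices, %d faces, conformal modulus h = %.4f\n",
              nrow(x$mesh$vertices), nrow(x$mesh$faces), x$h))
  invisible(x)
}

#' Conformal factor of a parameterization
#'
#' Per face, the ratio of the 3-D face area to its parameter-domain area;
#' per vertex, the area-weighted average over incident faces.  Under a
#' conformal map the factor equals the local metric scaling (area ratio).
#'
#' @param param a `param_mesh`.
#' @return numeric vector of per-vertex conformal factors (> 0).
#' @export
conformal_factor <- function(param) {
  A3 <- face_areas(param$mesh)
  cu <- param$corner_u; cv <- param$corner_v
  A2 <- 0.5 * ((cu[, 2] - cu[, 1]) * (cv[, 3] - cv[, 1]) -
               (cu[, 3] - cu[, 1]) * (cv[, 2] - cv[, 1]))
  if (any(A2 <= 0)) stop("non-positive parameter-domain face area")
  lam_face <- A3 / A2
  n <- nrow(param$mesh$vertices)
  num <- numeric(n); den <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(lam_face * A3, param$mesh$faces[, k], reorder = FALSE)
    w <- rowsum(A3, param$mesh$faces[, k], reorder = FALSE)
    ids <- as.integer(rownames(s))
    num[ids] <- num[ids] + s
    den[ids] <- den[ids] + w
  }
  num / den
}

#' Full conformal parameterization of a cylinder mesh
#'
#' Convenience wrapper: harmonic function, harmonic 1-form, conjugate
#' 1-form, rectangle integration, conformal factor and mean curvature.
#'
#' @param cyl a `cylinder_mesh` from [cut_extremities()].
#' @return a `param_mesh` with `lambda` and `H` filled in.
#' @export
conformal_parameterize <- function(cyl) {
  f <- harmonic_function(cyl)
  omega <- harmonic_oneform(cyl, f)
  ostar <- conjugate_oneform(cyl, omega)
  param <- integrate_to_rectangle(cyl, omega, ostar)
  param$lambda <- conformal_factor(param)
  param$H <- mean_curvature(cyl)
  param
}
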