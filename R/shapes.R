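# Analytic test shapes.  The sphere, tube and planar patch have known mean
# curvature, conformal modulus and parameterization, so they serve as
# oracles for the geometry stack.

#' Icosphere
#'
#' Subdivided icosahedron projected to a sphere of radius `r`.
#'
#' @param subdiv number of 1-to-4 subdivision rounds (0 = icosahedron).
#' @param r radius (mm).
#' @return closed genus-zero [triangle_mesh()].
#' @export
icosphere <- function(subdiv = 3, r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    res <- subdivide_mesh(v, f)
    v <- res$v; f <- res$f
  }
  v <- v / sqrt(rowSums(v^2)) * r
  triangle_mesh(v, f)
}

# one round of loop-style 1-to-4 topological subdivision (midpoint insertion)
subdivide_mesh <- function(v, f) {
  n <- nrow(v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- lo * (n + 1) + hi
  uk <- unique(key)
  mid_idx <- n + match(key, uk)
  first <- match(uk, key)
  mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
  m <- nrow(f)
  m12 <- mid_idx[seq_len(m)]
  m23 <- mid_idx[m + seq_len(m)]
  m31 <- mid_idx[2 * m + seq_len(m)]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = f2)
}

#' Structured open tube mesh
#'
#' A right circular cylinder (no caps) of radius `r` and length `len` along
#' the x axis, with `n_axial` rings of `n_circ` vertices.  Its conformal
#' modulus is 2*pi*r/len and its intrinsic geometry is flat, so the
#' rectangle parameterization is known analytically.
#'
#' @param r radius (mm).
#' @param len length (mm).
#' @param n_axial,n_circ grid resolution.
#' @return a `triangle_mesh` with two boundary loops.
#' @export
tube_mesh <- function(r = 1, len = 4, n_axial = 20, n_circ = 24) {
  x <- seq(0, len, length.out = n_axial)
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  v <- cbind(rep(x, each = n_circ),
             r * cos(rep(th, n_axial)),
             r * sin(rep(th, n_axial)))
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  f <- NULL
  for (i in seq_len(n_axial - 1)) {
    j <- seq_len(n_circ)
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)),
               cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)))
  }
  triangle_mesh(v, f)
}

#' Flat rectangular patch mesh in the z = 0 plane
#' @param nx,ny grid resolution.
#' @param lx,ly side lengths (mm).
#' @return a `triangle_mesh` (open, one boundary).
#' @export
planar_patch <- function(nx = 15, ny = 15, lx = 1, ly = 1) {
  xs <- seq(0, lx, length.out = nx)
  ys <- seq(0, ly, length.out = ny)
  v <- cbind(rep(xs, each = ny), rep(ys, nx), 0)
  idx <- function(i, j) (i - 1L) * ny + j
  f <- NULL
  for (i in seq_len(nx - 1)) {
    j <- seq_len(ny - 1)
    f <- rbind(f,
               cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  triangle_mesh(v, f)
}

#' Ellipsoid mesh
#' @param semi_axes numeric length-3 (mm).
#' @param subdiv icosphere subdivision level.
#' @return closed `triangle_mesh`.
#' @export
ellipsoid_mesh <- function(semi_axes = c(3, 1.5, 1), subdiv = 3) {
  s <- icosphere(subdiv, 1)
  s$vertices <- sweep(s$vertices, 2, semi_axes, `*`)
  s
}
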