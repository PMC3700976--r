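# Per-vertex morphometry from a registration-induced correspondence:
# surface Jacobians in local orthonormal tangent frames, areal ratio det J,
# log deformation tensors for multivariate tensor-based morphometry, and
# the medial-axis radial distance.

# per-face orthonormal tangent frames aligned with the parameter u
# direction, so frames vary smoothly across the surface and are gauge-
# consistent between template and corresponded geometry
face_frames <- function(faces, coords, corner_u, corner_v) {
  p1 <- coords[faces[, 1], , drop = FALSE]
  p2 <- coords[faces[, 2], , drop = FALSE]
  p3 <- coords[faces[, 3], , drop = FALSE]
  e2 <- p2 - p1; e3 <- p3 - p1
  nrm <- row_cross(e2, e3)
  a2 <- row_norm(nrm)
  nhat <- nrm / pmax(a2, .Machine$double.xmin)
  du2 <- corner_u[, 2] - corner_u[, 1]; du3 <- corner_u[, 3] - corner_u[, 1]
  dv2 <- corner_v[, 2] - corner_v[, 1]; dv3 <- corner_v[, 3] - corner_v[, 1]
  det2 <- du2 * dv3 - du3 * dv2
  # dx/du = (e2 * dv3 - e3 * dv2) / det2
  xu <- (e2 * dv3 - e3 * dv2) / det2
  t1 <- xu / pmax(row_norm(xu), .Machine$double.xmin)
  t2 <- row_cross(nhat, t1)
  list(t1 = t1, t2 = t2, area = a2 / 2, e2 = e2, e3 = e3)
}

#' Surface Jacobian of a correspondence at each template vertex
#'
#' Per template face, the 2x2 linear map taking the template face edges to
#' the corresponded face edges, both expressed in their own orthonormal
#' tangent frame (aligned with the parameter u direction so the frame field
#' is smooth and the map is invariant to rigid motions of either surface).
#' Per vertex, the area-weighted average of the incident face Jacobians.
#'
#' @param template a `param_mesh`.
#' @param corresponded numeric matrix (template vertices x 3): the 3-D point
#'   on the subject surface corresponding to each template vertex.
#' @return list with `J` (vertices x 4 matrix, columns J11, J12, J21, J22)
#'   and `J_face` (faces x 4).
#' @export
face_jacobian <- function(template, corresponded) {
  f <- template$mesh$faces
  ft <- face_frames(f, template$mesh$vertices,
                    template$corner_u, template$corner_v)
  fs <- face_frames(f, corresponded, template$corner_u, template$corner_v)
  if (any(fs$area <= .Machine$double.eps * max(fs$area)))
    stop("degenerate corresponded faces (zero area): ",
         paste(utils::head(which(fs$area <= .Machine$double.eps *
                                   max(fs$area)), 10), collapse = ", "))
  # edge matrices in local 2-D frames
  a1 <- row_dot(ft$t1, ft$e2); a2 <- row_dot(ft$t1, ft$e3)
  b1 <- row_dot(ft$t2, ft$e2); b2 <- row_dot(ft$t2, ft$e3)
  c1 <- row_dot(fs$t1, fs$e2); c2 <- row_dot(fs$t1, fs$e3)
  d1 <- row_dot(fs$t2, fs$e2); d2 <- row_dot(fs$t2, fs$e3)
  det_t <- a1 * b2 - a2 * b1
  # J = E' E^{-1} with E = [[a1 a2],[b1 b2]], E' = [[c1 c2],[d1 d2]]
  J11 <- (c1 * b2 - c2 * b1) / det_t
  J12 <- (c2 * a1 - c1 * a2) / det_t
  J21 <- (d1 * b2 - d2 * b1) / det_t
  J22 <- (d2 * a1 - d1 * a2) / det_t
  J_face <- cbind(J11, J12, J21, J22)
  n <- nrow(template$mesh$vertices)
  Jv <- matrix(0, n, 4)
  wsum <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(J_face * ft$area, f[, k], reorder = FALSE)
    w <- rowsum(ft$area, f[, k], reorder = FALSE)
    ids <- as.integer(rownames(s))
    Jv[ids, ] <- Jv[ids, ] + s
    wsum[ids] <- wsum[ids] + w
  }
  Jv <- Jv / wsum
  colnames(Jv) <- c("J11", "J12", "J21", "J22")
  list(J = Jv, J_face = J_face)
}

# matrix logarithm of (J^T J)^{1/2} for rows of 2x2 Jacobians:
# log S = (1/2) log(J^T J), computed with the analytic-function formula for
# symmetric 2x2 matrices
log_deformation <- function(J) {
  C11 <- J[, 1]^2 + J[, 3]^2
  C12 <- J[, 1] * J[, 2] + J[, 3] * J[, 4]
  C22 <- J[, 2]^2 + J[, 4]^2
  tr2 <- (C11 + C22) / 2
  disc <- sqrt(pmax(((C11 - C22) / 2)^2 + C12^2, 0))
  l1 <- tr2 + disc; l2 <- pmax(tr2 - disc, .Machine$double.xmin)
  fmean <- (log(l1) + log(l2)) / 2
  fslope <- ifelse(disc > 1e-14 * tr2, (log(l1) - log(l2)) / (2 * disc),
                   1 / pmax(tr2, .Machine$double.xmin))
  # log C = fmean I + fslope (C - tr2 I); log S = log C / 2
  L11 <- (fmean + fslope * (C11 - tr2)) / 2
  L12 <- (fslope * C12) / 2
  L22 <- (fmean + fslope * (C22 - tr2)) / 2
  cbind(L11, L12, L22)
}

#' Deformation features from per-vertex Jacobians
#'
#' det J (areal ratio) and the log deformation tensor log S,
#' S = (J^T J)^(1/2), vectorized as (l11, sqrt(2) l12, l22) so the
#' Euclidean norm of the 3-vector equals the Frobenius norm of log S.
#' Vertices with det J <= 0 are flagged and excluded (their rows are NA).
#'
#' @param J vertices x 4 Jacobian matrix from [face_jacobian()].
#' @return list with `detJ` (vector), `logS` (vertices x 3 matrix,
#'   sqrt(2)-weighted off-diagonal), `excluded` (indices with det J <= 0).
#' @export
deformation_features <- function(J) {
  detJ <- J[, 1] * J[, 4] - J[, 2] * J[, 3]
  bad <- which(!(detJ > 0) | !is.finite(detJ))
  ok <- setdiff(seq_len(nrow(J)), bad)
  logS <- matrix(NA_real_, nrow(J), 3)
  if (length(ok)) {
    L <- log_deformation(J[ok, , drop = FALSE])
    logS[ok, ] <- cbind(L[, 1], sqrt(2) * L[, 2], L[, 3])
  }
  colnames(logS) <- c("logS1", "logS2", "logS3")
  if (length(bad))
    warning(length(bad), " vertices with det J <= 0 excluded")
  list(detJ = detJ, logS = logS, excluded = bad)
}

#' Medial axis of a parameterized surface
#'
#' The centroid of each iso-parametric curve u = const, sampled at the
#' circular grid positions of the conformal grid.
#'
#' @param param a `param_mesh` (or the template mesh with a substituted
#'   vertex field via `coords`).
#' @param n_levels number of iso-u levels (default 32).
#' @param n_circ circular samples per level (default 32).
#' @param coords optional replacement vertex coordinates (e.g. corresponded
#'   points) to compute a subject-side axis on the template grid.
#' @return a `medial_axis`: list with `points` (n_levels x 3) and
#'   `u_levels`.
#' @export
medial_axis <- function(param, n_levels = 32, n_circ = 32, coords = NULL) {
  coords <- coords %||% param$mesh$vertices
  g <- sample_grid(param, coords, resolution = c(n_levels, n_circ))
  pts <- apply(g$values, c(1, 3), mean)
  if (any(!is.finite(pts))) stop("empty iso-parametric level")
  structure(list(points = pts, u_levels = g$u), class = "medial_axis")
}

# linear interpolation of axis points at arbitrary u
axis_at_u <- function(axis, u) {
  lev <- axis$u_levels
  k <- findInterval(u, lev, all.inside = TRUE)
  t <- (u - lev[k]) / (lev[k + 1] - lev[k])
  axis$points[k, , drop = FALSE] * (1 - t) +
    axis$points[k + 1, , drop = FALSE] * t
}

#' Medial-axis radial distance per template vertex
#'
#' Euclidean distance from each corresponded point to the medial-axis point
#' at the same axial coordinate.  By default the axis is recomputed from the
#' corresponded points (subject-side axis), so the distance measures the
#' subject's own local thickness at corresponding locations; set
#' `side = "template"` to measure against the template axis instead.
#'
#' @param template a `param_mesh`.
#' @param corresponded matrix (vertices x 3) of corresponded points.
#' @param side `"subject"` (default) or `"template"`.
#' @param n_levels axis resolution.
#' @return numeric vector of radial distances (mm).
#' @export
radial_distance <- function(template, corresponded,
                            side = c("subject", "template"),
                            n_levels = 32) {
  side <- match.arg(side)
  axis <- if (side == "subject")
    medial_axis(template, n_levels = n_levels, coords = corresponded)
  else medial_axis(template, n_levels = n_levels)
  ctr <- axis_at_u(axis, template$u)
  row_norm(corresponded - ctr)
}

#' All four morphometry statistics for one subject
#'
#' @param template a `param_mesh`.
#' @param corresponded matrix of corresponded 3-D points.
#' @param axis_side side for [radial_distance()].
#' @return list with `detJ`, `logS`, `R`, `combined` (vertices x 4),
#'   `excluded`.
#' @export
vertex_morphometry <- function(template, corresponded,
                               axis_side = "subject") {
  fj <- face_jacobian(template, corresponded)
  df <- deformation_features(fj$J)
  R <- radial_distance(template, corresponded, side = axis_side)
  combined <- cbind(df$logS, R = R)
  list(detJ = df$detJ, logS = df$logS, R = R, combined = combined,
       excluded = df$excluded)
}
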