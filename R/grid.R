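# Resampling of per-vertex surface fields onto a regular grid over the
# parameter rectangle [0,1] x [0,h).  The v direction is periodic; faces
# crossing the seam are handled by testing v-shifted copies.

grid_axes <- function(h, n_u, n_v) {
  list(u = seq(0, 1, length.out = n_u),
       v = seq(0, h, length.out = n_v + 1)[seq_len(n_v)])
}

# Uniform-bucket index over the parameter rectangle: every face (with its
# -h/0/+h shifted copies that intersect [0, h)) is registered in the
# buckets its bounding box touches.  Built once per param mesh and cached.
bucket_index <- function(param, nb = 24L) {
  if (!is.null(param$cache) && !is.null(param$cache$buckets))
    return(param$cache$buckets)
  cu <- param$corner_u; cv <- param$corner_v
  h <- param$h
  m <- nrow(cu)
  ids <- integer(0); shifts <- numeric(0)
  for (shift in c(0, -h, h)) {
    lo_v <- pmin(cv[, 1], cv[, 2], cv[, 3]) + shift
    hi_v <- pmax(cv[, 1], cv[, 2], cv[, 3]) + shift
    keep <- which(hi_v >= 0 & lo_v <= h)
    ids <- c(ids, keep); shifts <- c(shifts, rep(shift, length(keep)))
  }
  lo_u <- pmin(cu[ids, 1], cu[ids, 2], cu[ids, 3])
  hi_u <- pmax(cu[ids, 1], cu[ids, 2], cu[ids, 3])
  lo_v <- pmin(cv[ids, 1], cv[ids, 2], cv[ids, 3]) + shifts
  hi_v <- pmax(cv[ids, 1], cv[ids, 2], cv[ids, 3]) + shifts
  eps <- 1e-12
  bu0 <- pmax(pmin(floor(lo_u * nb / (1 + eps)), nb - 1L), 0L)
  bu1 <- pmax(pmin(floor(hi_u * nb / (1 + eps)), nb - 1L), 0L)
  bv0 <- pmax(pmin(floor(lo_v * nb / (h * (1 + eps))), nb - 1L), 0L)
  bv1 <- pmax(pmin(floor(hi_v * nb / (h * (1 + eps))), nb - 1L), 0L)
  # expand (entry x bucket-range) pairs without an R loop
  ncell_u <- bu1 - bu0 + 1L
  e1 <- rep(seq_along(ids), ncell_u)
  uu <- sequence(ncell_u) - 1L + rep(bu0, ncell_u)
  ncell_v <- (bv1 - bv0 + 1L)[e1]
  e2 <- rep(e1, ncell_v)
  uu2 <- rep(uu, ncell_v)
  vv2 <- sequence(ncell_v) - 1L + rep(bv0[e1], ncell_v)
  cell <- uu2 + nb * vv2 + 1L
  sp <- split(e2, cell)
  cellmap <- integer(nb * nb)
  cellmap[as.integer(names(sp))] <- seq_along(sp)
  sp[[length(sp) + 1L]] <- integer(0)   # shared empty-cell entry
  idx <- list(nb = nb, entry_face = ids, entry_shift = shifts,
              cells = sp, cellmap = cellmap, empty = length(sp))
  if (!is.null(param$cache)) param$cache$buckets <- idx
  idx
}

# Locate arbitrary (u, v) query points in the parameter triangulation.
# Returns face index, shift and barycentric coordinates per point; points
# are wrapped into [0, h) and faces are tested with v shifts of -h, 0, +h.
# Points in genuine coverage gaps (rounding at the seam) fall back to the
# face with the largest minimum barycentric coordinate, extrapolating
# linearly so nearby queries stay distinct.
locate_param_points <- function(param, pts, tol = 1e-9) {
  cu <- param$corner_u; cv <- param$corner_v
  h <- param$h
  P <- nrow(pts)
  qu <- pmin(pmax(pts[, 1], 0), 1)
  qv <- ((pts[, 2] %% h) + h) %% h
  qv[qv >= h] <- 0
  bx <- bucket_index(param)
  nb <- bx$nb
  qcell <- pmin(floor(qu * nb), nb - 1L) +
    nb * pmin(floor(qv * nb / h), nb - 1L) + 1L
  slot <- bx$cellmap[qcell]
  slot[slot == 0L] <- bx$empty
  cand_per_q <- bx$cells[slot]
  nc <- lengths(cand_per_q)
  qid <- rep(seq_len(P), nc)
  entry <- unlist(cand_per_q, use.names = FALSE)
  fid <- bx$entry_face[entry]
  b <- tri_barycentric3(cu[fid, 1], cu[fid, 2], cu[fid, 3],
                        cv[fid, 1] + bx$entry_shift[entry],
                        cv[fid, 2] + bx$entry_shift[entry],
                        cv[fid, 3] + bx$entry_shift[entry],
                        qu[qid], qv[qid])
  minb <- pmin(b[, 1], b[, 2], b[, 3])
  inside <- minb >= -tol
  ord <- order(qid, -inside, -minb)
  first <- ord[!duplicated(qid[ord])]
  face <- rep(NA_integer_, P)
  bary <- matrix(NA_real_, P, 3)
  face[qid[first]] <- fid[first]
  bary[qid[first], ] <- b[first, , drop = FALSE]
  # snap just-outside points onto their best face; keep genuine-gap points
  # as linear extrapolations
  mb <- pmin(bary[, 1], bary[, 2], bary[, 3])
  snap <- which(!is.na(mb) & mb < 0 & mb > -1e-6)
  if (length(snap)) {
    bs <- pmax(bary[snap, , drop = FALSE], 0)
    bary[snap, ] <- bs / rowSums(bs)
  }
  miss <- which(is.na(face))
  for (p in miss) {
    # empty bucket (should be rare): scan all faces and shifts
    best <- -Inf; bf <- NA_integer_; bb <- NULL
    for (shift in c(0, -h, h)) {
      bm <- tri_barycentric_all(cu, cv + shift, qu[p], qv[p])
      mbm <- pmin(bm[, 1], bm[, 2], bm[, 3])
      k <- which.max(mbm)
      if (mbm[k] > best) { best <- mbm[k]; bf <- k; bb <- bm[k, ] }
    }
    face[p] <- bf
    bary[p, ] <- if (best > -1e-6) pmax(bb, 0) / sum(pmax(bb, 0)) else bb
  }
  list(face = face, bary = bary)
}

# barycentric coordinates for paired (face, query) pairs given corner
# coordinate vectors
tri_barycentric3 <- function(u1, u2, u3, v1, v2, v3, qu, qv) {
  d <- (v2 - v3) * (u1 - u3) + (u3 - u2) * (v1 - v3)
  b1 <- ((v2 - v3) * (qu - u3) + (u3 - u2) * (qv - v3)) / d
  b2 <- ((v3 - v1) * (qu - u3) + (u1 - u3) * (qv - v3)) / d
  cbind(b1, b2, 1 - b1 - b2)
}

# barycentric coordinates of query points wrt one parameter triangle
tri_barycentric <- function(tu, tv, qu, qv) {
  d <- (tv[2] - tv[3]) * (tu[1] - tu[3]) + (tu[3] - tu[2]) * (tv[1] - tv[3])
  b1 <- ((tv[2] - tv[3]) * (qu - tu[3]) + (tu[3] - tu[2]) * (qv - tv[3])) / d
  b2 <- ((tv[3] - tv[1]) * (qu - tu[3]) + (tu[1] - tu[3]) * (qv - tv[3])) / d
  cbind(b1, b2, 1 - b1 - b2)
}

# barycentric coordinates of one point wrt all faces (vectorized over faces)
tri_barycentric_all <- function(cu, cv, qu, qv) {
  d <- (cv[, 2] - cv[, 3]) * (cu[, 1] - cu[, 3]) +
    (cu[, 3] - cu[, 2]) * (cv[, 1] - cv[, 3])
  b1 <- ((cv[, 2] - cv[, 3]) * (qu - cu[, 3]) +
           (cu[, 3] - cu[, 2]) * (qv - cv[, 3])) / d
  b2 <- ((cv[, 3] - cv[, 1]) * (qu - cu[, 3]) +
           (cu[, 1] - cu[, 3]) * (qv - cv[, 3])) / d
  cbind(b1, b2, 1 - b1 - b2)
}

# interpolate per-vertex fields (matrix n x C) at located points
interp_vertex_fields <- function(param, loc, values) {
  values <- as.matrix(values)
  f <- param$mesh$faces
  i1 <- f[loc$face, 1]; i2 <- f[loc$face, 2]; i3 <- f[loc$face, 3]
  loc$bary[, 1] * values[i1, , drop = FALSE] +
    loc$bary[, 2] * values[i2, , drop = FALSE] +
    loc$bary[, 3] * values[i3, , drop = FALSE]
}

#' Sample per-vertex fields onto a regular parameter-domain grid
#'
#' Barycentric interpolation of per-vertex values at the nodes of a regular
#' n_u x n_v grid over the rectangle (u inclusive of both boundaries, v
#' periodic).  Gaps at the seam are filled by the periodic wrap / nearest
#' face, never with NaN.
#'
#' @param param a `param_mesh`.
#' @param values numeric matrix (vertices x channels) or vector.
#' @param resolution length-2 integer (n_u, n_v), default `c(64, 64)`.
#' @param normalize z-score each channel over the grid (default `FALSE`).
#' @param channels optional channel names.
#' @return a `feature_grid`: list with `values` (array n_u x n_v x C), `h`,
#'   `u`, `v`, `channels`.
#' @export
sample_grid <- function(param, values, resolution = c(64, 64),
                        normalize = FALSE, channels = NULL) {
  values <- as.matrix(values)
  n_u <- resolution[1]; n_v <- resolution[2]
  ax <- grid_axes(param$h, n_u, n_v)
  pts <- cbind(rep(ax$u, times = n_v), rep(ax$v, each = n_u))
  # grid-node location depends only on the parameterization and the
  # resolution, so it is cached on the param mesh
  key <- paste0("loc", n_u, "x", n_v)
  if (!is.null(param$cache) && !is.null(param$cache[[key]])) {
    loc <- param$cache[[key]]
  } else {
    loc <- locate_param_points(param, pts)
    if (!is.null(param$cache)) param$cache[[key]] <- loc
  }
  out <- interp_vertex_fields(param, loc, values)
  arr <- array(out, dim = c(n_u, n_v, ncol(values)))
  if (normalize) {
    for (c in seq_len(dim(arr)[3])) {
      ch <- arr[, , c]
      s <- stats::sd(ch)
      # near-constant channels carry no alignment information; zero them
      # instead of amplifying rounding noise
      arr[, , c] <- if (s < 1e-9 * max(abs(mean(ch)), 1)) ch * 0
                    else (ch - mean(ch)) / s
    }
  }
  structure(list(values = arr, h = param$h, u = ax$u, v = ax$v,
                 channels = channels %||%
                   colnames(values) %||%
                   paste0("ch", seq_len(ncol(values)))),
            class = "feature_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surface feature image for registration
#'
#' The 2-channel feature image driving the registration: conformal
#' factor and mean curvature resampled on the parameter grid and z-scored
#' per channel so both contribute comparably to the intensity difference.
#'
#' @param param a `param_mesh` with `lambda` and `H`.
#' @param resolution grid size, default `c(64, 64)`.
#' @return a `feature_grid` with channels `lambda` and `H`.
#' @export
sample_feature_grid <- function(param, resolution = c(64, 64)) {
  if (is.null(param$lambda) || is.null(param$H))
    stop("param mesh lacks lambda/H; run conformal_parameterize()")
  sample_grid(param, cbind(lambda = param$lambda, H = param$H),
              resolution = resolution, normalize = TRUE)
}
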