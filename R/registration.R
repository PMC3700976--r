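# Inverse-consistent fluid registration of surface feature images in the
# parameter domain.  The viscous-flow PDE (mu Lap v + (mu+lambda) grad div v
# = -force) is discretized with finite differences on the rectangle grid,
# periodic in the circular direction and with the boundary loops held as
# hard landmarks (no axial motion across them).  Displacements are stored in
# grid-node units on the template (fixed) grid for the forward map g and on
# the subject (moving) grid for the backward map h.

#' Registration parameters
#'
#' @param mu shear viscosity of the flow (default 1).
#' @param lambda_visc second viscosity (default 0: decoupled components).
#' @param max_iter iteration cap (default 200).
#' @param tol relative SSD decrease below which iterations stop (default 1e-5).
#' @param step_max largest displacement update per iteration, in grid nodes
#'   (a CFL-style bound; default 0.4).
#' @param regrid_threshold regrid when the minimum Jacobian determinant of
#'   the incremental map falls below this (default 0.5).
#' @param ic_weight step size of the inverse-consistency correction
#'   (default 0.2).
#' @param patience iterations of stagnation tolerated before stopping
#'   (default 5).
#' @param init_shift search all global circular shifts before the flow and
#'   start from the best one (default `TRUE`); this restores the rigid
#'   rotation mode that the boundary conditions exclude.
#' @return list of class `registration_params`.
#' @export
registration_params <- function(mu = 1, lambda_visc = 0, max_iter = 200,
                                tol = 1e-5, step_max = 0.4,
                                regrid_threshold = 0.5, ic_weight = 0.2,
                                patience = 5, init_shift = TRUE) {
  stopifnot(mu > 0, lambda_visc >= 0, max_iter >= 1, tol > 0,
            step_max > 0, regrid_threshold > 0, regrid_threshold < 1,
            ic_weight >= 0)
  structure(list(mu = mu, lambda_visc = lambda_visc, max_iter = max_iter,
                 tol = tol, step_max = step_max,
                 regrid_threshold = regrid_threshold,
                 ic_weight = ic_weight, patience = patience,
                 init_shift = isTRUE(init_shift)),
            class = "registration_params")
}

# Sparse operator -(mu Lap + (mu+lambda) grad div) for a 2-vector field on
# the n_u x n_v grid: periodic circumferentially, displacement pinned to 0
# on the two boundary rows (the boundary loops are hard landmarks).  The
# factorization is cached per (n_u, n_v, mu, lambda_visc).
.op_cache <- new.env(parent = emptyenv())

viscous_operator <- function(n_u, n_v, mu, lambda_visc) {
  key <- paste(n_u, n_v, mu, lambda_visc, sep = "|")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  N <- n_u * n_v
  id <- function(i, j, c) (c - 1L) * N + ((j - 1L) %% n_v) * n_u + i
  i_all <- rep(seq_len(n_u), n_v)
  j_all <- rep(seq_len(n_v), each = n_u)
  int <- i_all > 1 & i_all < n_u
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  emit <- function(r, c, v) {
    ii <<- c(ii, r); jj <<- c(jj, c); xx <<- c(xx, v)
  }
  for (comp in 1:2) {
    i <- i_all[int]; j <- j_all[int]
    r <- id(i, j, comp)
    emit(r, r, rep(4 * mu, length(r)))
    emit(r, id(i - 1, j, comp), rep(-mu, length(r)))
    emit(r, id(i + 1, j, comp), rep(-mu, length(r)))
    emit(r, id(i, j + 1, comp), rep(-mu, length(r)))
    emit(r, id(i, j - 1, comp), rep(-mu, length(r)))
    w <- mu + lambda_visc
    if (w > 0) {
      if (comp == 1) {
        emit(r, r, rep(2 * w, length(r)))
        emit(r, id(i - 1, j, 1), rep(-w, length(r)))
        emit(r, id(i + 1, j, 1), rep(-w, length(r)))
        emit(r, id(i + 1, j + 1, 2), rep(-w / 4, length(r)))
        emit(r, id(i + 1, j - 1, 2), rep(w / 4, length(r)))
        emit(r, id(i - 1, j + 1, 2), rep(w / 4, length(r)))
        emit(r, id(i - 1, j - 1, 2), rep(-w / 4, length(r)))
      } else {
        emit(r, r, rep(2 * w, length(r)))
        emit(r, id(i, j + 1, 2), rep(-w, length(r)))
        emit(r, id(i, j - 1, 2), rep(-w, length(r)))
        emit(r, id(i + 1, j + 1, 1), rep(-w / 4, length(r)))
        emit(r, id(i - 1, j + 1, 1), rep(w / 4, length(r)))
        emit(r, id(i + 1, j - 1, 1), rep(w / 4, length(r)))
        emit(r, id(i - 1, j - 1, 1), rep(-w / 4, length(r)))
      }
    }
    bi <- i_all[!int]; bj <- j_all[!int]
    br <- id(bi, bj, comp)
    emit(br, br, rep(1, length(br)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * N, 2 * N))
  fac <- Matrix::lu(A)
  .op_cache[[key]] <- fac
  fac
}

# circular resampling of the columns of a (n_u x n_v x C) array by a
# (possibly fractional) shift: out[, j, ] = arr[, j + s, ] with periodic
# wrap and linear interpolation
shift_columns <- function(arr, s) {
  n_v <- dim(arr)[2]
  pj <- ((seq_len(n_v) + s - 1) %% n_v)
  j0 <- floor(pj); w <- pj - j0
  i0 <- j0 + 1L
  i1 <- (i0 %% n_v) + 1L
  out <- arr
  for (c in seq_len(dim(arr)[3]))
    out[, , c] <- arr[, i0, c] * (1 - w)[col(out[, , c])] +
      arr[, i1, c] * w[col(out[, , c])]
  out
}

# bilinear sampling of a (n_u x n_v x C) array at fractional node
# coordinates; i clamped to [1, n_u], j periodic
bilinear_sample <- function(arr, pi, pj) {
  d <- dim(arr)
  n_u <- d[1]; n_v <- d[2]; C <- if (length(d) == 3) d[3] else 1L
  pi <- pmin(pmax(pi, 1), n_u)
  i0 <- pmin(floor(pi), n_u - 1); fi <- pi - i0
  pj <- ((pj - 1) %% n_v) + 1
  pj[pj >= n_v + 1] <- 1        # fp edge: (x %% n) can round up to n
  j0 <- floor(pj); fj <- pj - j0
  j1 <- (j0 %% n_v) + 1
  N <- n_u * n_v
  k00 <- i0 + (j0 - 1) * n_u
  k10 <- k00 + 1
  k01 <- i0 + (j1 - 1) * n_u
  k11 <- k01 + 1
  w00 <- (1 - fi) * (1 - fj); w10 <- fi * (1 - fj)
  w01 <- (1 - fi) * fj;       w11 <- fi * fj
  out <- matrix(0, length(pi), C)
  off <- 0L
  for (c in seq_len(C)) {
    out[, c] <- w00 * arr[k00 + off] + w10 * arr[k10 + off] +
      w01 * arr[k01 + off] + w11 * arr[k11 + off]
    off <- off + N
  }
  out
}

# finite-difference gradient of a scalar grid: central in both directions,
# one-sided at the axial boundaries, periodic circumferentially
grid_gradient <- function(g) {
  n_u <- nrow(g); n_v <- ncol(g)
  du <- (g[c(2:n_u, n_u), ] - g[c(1, 1:(n_u - 1)), ]) /
    matrix(c(1, rep(2, n_u - 2), 1), n_u, n_v)
  dv <- (g[, c(2:n_v, 1)] - g[, c(n_v, 1:(n_v - 1))]) / 2
  list(du = du, dv = dv)
}

# Jacobian determinant of the map id + disp (disp in node units)
disp_jacobian_det <- function(disp) {
  g1 <- grid_gradient(disp[, , 1])
  g2 <- grid_gradient(disp[, , 2])
  (1 + g1$du) * (1 + g2$dv) - g1$dv * g2$du
}

# compose displacement fields: result(x) = inner(x) + outer(x + inner(x))
compose_disp <- function(outer, inner) {
  if (is.null(outer)) return(inner)
  d <- dim(inner)
  ii <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  jj <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  s <- bilinear_sample(outer, as.vector(ii + inner[, , 1]),
                       as.vector(jj + inner[, , 2]))
  out <- inner
  out[, , 1] <- inner[, , 1] + matrix(s[, 1], d[1], d[2])
  out[, , 2] <- inner[, , 2] + matrix(s[, 2], d[1], d[2])
  out
}

# numerical inverse of a displacement field by fixed-point iteration
invert_disp <- function(disp, iters = 30) {
  d <- dim(disp)
  inv <- array(0, d)
  ii <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  jj <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  for (k in seq_len(iters)) {
    s <- bilinear_sample(disp, as.vector(ii + inv[, , 1]),
                         as.vector(jj + inv[, , 2]))
    inv[, , 1] <- -matrix(s[, 1], d[1], d[2])
    inv[, , 2] <- -matrix(s[, 2], d[1], d[2])
  }
  inv
}

# warp a multi-channel image by a displacement field
warp_image <- function(img, disp) {
  d <- dim(img)
  ii <- rep(seq_len(d[1]), d[2])
  jj <- rep(seq_len(d[2]), each = d[1])
  s <- bilinear_sample(img, ii + as.vector(disp[, , 1]),
                       jj + as.vector(disp[, , 2]))
  array(s, d)
}

ssd_value <- function(a, b) sum((a - b)^2)

# demons-style body force from an already-warped image; optional per-node
# weight
grad_force <- function(warped, fixed, weight = NULL) {
  d <- dim(fixed)
  f1 <- matrix(0, d[1], d[2]); f2 <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) {
    gr <- grid_gradient(warped[, , c])
    resid <- warped[, , c] - fixed[, , c]
    f1 <- f1 - resid * gr$du
    f2 <- f2 - resid * gr$dv
  }
  if (!is.null(weight)) { f1 <- f1 * weight; f2 <- f2 * weight }
  if (any(!is.finite(f1)) || any(!is.finite(f2)))
    stop("NaN in registration body force")
  list(f1 = f1, f2 = f2)
}

# body force for warping `moving` toward `fixed` given the current
# displacement (used directly by tests; the main loop reuses its warps)
ssd_force <- function(moving, fixed, disp, weight = NULL) {
  warped <- warp_image(moving, disp)
  c(grad_force(warped, fixed, weight), list(warped = warped))
}

solve_velocity <- function(op, f1, f2) {
  n_u <- nrow(f1); n_v <- ncol(f1)
  f1[c(1, n_u), ] <- 0   # boundary loops are hard landmarks
  f2[c(1, n_u), ] <- 0
  rhs <- c(as.vector(f1), as.vector(f2))
  sol <- as.numeric(Matrix::solve(op, rhs))
  array(sol, c(n_u, n_v, 2))
}

# one fluid advection update: dt * (v - (v . grad) u)
fluid_update <- function(disp, vel, step_max) {
  g1 <- grid_gradient(disp[, , 1])
  g2 <- grid_gradient(disp[, , 2])
  p1 <- vel[, , 1] - (vel[, , 1] * g1$du + vel[, , 2] * g1$dv)
  p2 <- vel[, , 2] - (vel[, , 1] * g2$du + vel[, , 2] * g2$dv)
  mx <- max(abs(p1), abs(p2))
  if (mx < 1e-14) return(NULL)
  dt <- step_max / mx
  upd <- disp
  upd[, , 1] <- p1 * dt
  upd[, , 2] <- p2 * dt
  upd
}

#' Inverse-consistent fluid registration of two feature grids
#'
#' Alternating symmetric scheme: at each iteration the multi-channel SSD
#' body force is computed for the forward map g (moving onto fixed) and the
#' backward map h (fixed onto moving), the viscous-flow PDE is solved for
#' each velocity, displacements are advanced with the material-transport
#' term, and an inverse-consistency correction pulls g and h toward each
#' other's inverse.  Regridding keeps the incremental maps diffeomorphic.
#'
#' @param moving,fixed `feature_grid`s of equal resolution.
#' @param params a [registration_params()] list.
#' @param weight optional per-node force weight on the fixed grid (e.g. the
#'   template conformal factor); `NULL` for none.
#' @return a `disp_field2d`: `forward` (g, on the fixed grid), `backward`
#'   (h, on the moving grid), per-iteration `ssd` log, `iterations`,
#'   `converged`, and the final inverse-consistency residual `ic_rms`
#'   (grid nodes).
#' @export
fluid_register <- function(moving, fixed, params = registration_params(),
                           weight = NULL) {
  M <- moving$values; F <- fixed$values
  if (!all(dim(M) == dim(F))) stop("grids must share resolution")
  n_u <- dim(F)[1]; n_v <- dim(F)[2]
  # global circular alignment: the viscous flow keeps the boundary loops
  # fixed, so a whole-surface rotation about the cylinder axis must be
  # found up front
  s0 <- 0
  if (params$init_shift && n_v > 1) {
    ssd_s <- vapply(0:(n_v - 1), function(s) {
      idx <- ((seq_len(n_v) + s - 1L) %% n_v) + 1L
      sum((M[, idx, , drop = FALSE] - F)^2)
    }, 0)
    k <- which.min(ssd_s)
    s0 <- k - 1
    # parabolic refinement to a fractional shift, kept only if it actually
    # lowers the SSD
    e0 <- ssd_s[k]
    em <- ssd_s[((k - 2) %% n_v) + 1]
    ep <- ssd_s[(k %% n_v) + 1]
    denom <- em - 2 * e0 + ep
    if (e0 > 0 && denom > 0) {
      frac <- max(min(0.5 * (em - ep) / denom, 0.5), -0.5)
      if (abs(frac) > 1e-9 &&
          sum((shift_columns(M, s0 + frac) - F)^2) < e0)
        s0 <- s0 + frac
    }
    if (abs(s0) > 1e-12) M <- shift_columns(M, s0)
    else s0 <- 0
  }
  op <- viscous_operator(n_u, n_v, params$mu, params$lambda_visc)
  g_base <- NULL; g_inc <- array(0, c(n_u, n_v, 2))
  h_base <- NULL; h_inc <- array(0, c(n_u, n_v, 2))
  total <- function(base, inc) compose_disp(base, inc)
  eval_state <- function(g, h) {
    wg <- warp_image(M, g); wh <- warp_image(F, h)
    list(ssd = ssd_value(wg, F) + ssd_value(wh, M), wg = wg, wh = wh)
  }
  ssd_log <- numeric(0)
  step <- params$step_max
  stall <- 0; rejected <- 0
  g <- total(g_base, g_inc); h <- total(h_base, h_inc)
  st <- eval_state(g, h)
  ssd_cur <- st$ssd
  for (it in seq_len(params$max_iter)) {
    ssd_log <- c(ssd_log, ssd_cur)
    if (ssd_cur < 1e-12) break
    fg <- grad_force(st$wg, F, weight)
    fh <- grad_force(st$wh, M, weight)
    vg <- solve_velocity(op, fg$f1, fg$f2)
    vh <- solve_velocity(op, fh$f1, fh$f2)
    ug <- fluid_update(g_inc, vg, step)
    uh <- fluid_update(h_inc, vh, step)
    if (is.null(ug) && is.null(uh)) break
    g_try <- if (is.null(ug)) g_inc else g_inc + ug
    h_try <- if (is.null(uh)) h_inc else h_inc + uh
    # inverse-consistency correction toward each other's inverse
    if (params$ic_weight > 0) {
      g_t <- total(g_base, g_try); h_t <- total(h_base, h_try)
      r_g <- compose_disp(h_t, g_t)   # g(x) + h(x + g(x))
      r_h <- compose_disp(g_t, h_t)
      g_try[, , 1] <- g_try[, , 1] - params$ic_weight * r_g[, , 1]
      g_try[, , 2] <- g_try[, , 2] - params$ic_weight * r_g[, , 2]
      h_try[, , 1] <- h_try[, , 1] - params$ic_weight * r_h[, , 1]
      h_try[, , 2] <- h_try[, , 2] - params$ic_weight * r_h[, , 2]
      g_try[c(1, n_u), , ] <- 0
      h_try[c(1, n_u), , ] <- 0
    }
    g_new <- total(g_base, g_try)
    h_new <- total(h_base, h_try)
    st_new <- eval_state(g_new, h_new)
    ssd_new <- st_new$ssd
    if (!is.finite(ssd_new)) stop("NaN in registration objective")
    if (ssd_new > ssd_cur * (1 + 1e-12)) {
      # reject: shrink the step and retry from the accepted state
      step <- step / 2
      rejected <- rejected + 1
      if (rejected > 4 * params$patience)
        stop("fluid registration diverging: ", rejected,
             " rejected steps (SSD ", signif(ssd_cur, 6), ")")
      if (step < 1e-3 * params$step_max) break
      next
    }
    rel_gain <- (ssd_cur - ssd_new) / max(ssd_log[1], 1e-300)
    g_inc <- g_try; h_inc <- h_try
    g <- g_new; h <- h_new
    st <- st_new
    ssd_cur <- ssd_new
    if (min(disp_jacobian_det(g_inc)) < params$regrid_threshold) {
      g_base <- compose_disp(g_base, g_inc); g_inc[] <- 0
    }
    if (min(disp_jacobian_det(h_inc)) < params$regrid_threshold) {
      h_base <- compose_disp(h_base, h_inc); h_inc[] <- 0
    }
    if (rel_gain < params$tol) {
      stall <- stall + 1
      if (stall >= params$patience) break
    } else stall <- 0
  }
  g <- total(g_base, g_inc); h <- total(h_base, h_inc)
  r_g <- compose_disp(h, g)
  if (s0 != 0) {
    # fold the global shift back into the fields: the forward map gains a
    # constant circular offset; the backward map is re-indexed to the
    # unshifted moving frame
    g[, , 2] <- g[, , 2] + s0
    h <- shift_columns(h, -s0)
    h[, , 2] <- h[, , 2] - s0
  }
  structure(list(forward = g, backward = h, ssd = ssd_log,
                 iterations = length(ssd_log),
                 converged = length(ssd_log) < params$max_iter,
                 ic_rms = sqrt(mean(r_g^2)),
                 min_jac = min(disp_jacobian_det(g),
                               disp_jacobian_det(h)),
                 params = params),
            class = "disp_field2d")
}

#' Constrained harmonic map between two parameter rectangles
#'
#' Solves the Laplace equation for the map components on the template
#' rectangle with the boundary correspondence fixed: the u = 0 loop maps to
#' the u = 0 loop, u = 1 to u = 1, and the circular coordinate is aligned
#' proportionally starting from the common seam anchor.  This is the
#' feature-blind registration baseline: the interior is filled harmonically
#' from the boundary data alone.
#'
#' @param moving,fixed `param_mesh`es (their grids define the rectangle).
#' @param resolution grid size (n_u, n_v), default `c(64, 64)`.
#' @return a `disp_field2d` whose `forward` field is the harmonic map (in
#'   grid-node units) and whose `backward` field is its numerical inverse;
#'   `residual` reports the interior Laplacian residual.
#' @export
harmonic_register <- function(moving, fixed, resolution = c(64, 64)) {
  n_u <- resolution[1]; n_v <- resolution[2]
  N <- n_u * n_v
  i_all <- rep(seq_len(n_u), n_v); j_all <- rep(seq_len(n_v), each = n_u)
  idx <- function(i, j) ((j - 1L) %% n_v) * n_u + i
  int <- i_all > 1 & i_all < n_u
  i <- i_all[int]; j <- j_all[int]
  r <- idx(i, j)
  ii <- c(r, r, r, r, r, which(!int))
  jj <- c(r, idx(i - 1, j), idx(i + 1, j), idx(i, j + 1), idx(i, j - 1),
          which(!int))
  xx <- c(rep(4, length(r)), rep(-1, 4 * length(r)), rep(1, sum(!int)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  lu <- Matrix::lu(A)
  # boundary correspondence: loops map to loops with proportional,
  # seam-anchored circular alignment, i.e. zero displacement in node units;
  # the interior displacement components are harmonic with that data
  solve_comp <- function(bnd_lo, bnd_hi) {
    b <- numeric(N)
    b[i_all == 1] <- bnd_lo
    b[i_all == n_u] <- bnd_hi
    matrix(as.numeric(Matrix::solve(lu, b)), n_u, n_v)
  }
  d1 <- solve_comp(0, 0)
  d2 <- solve_comp(0, 0)
  disp <- array(0, c(n_u, n_v, 2))
  disp[, , 1] <- d1; disp[, , 2] <- d2
  lap <- function(mp) {
    mp[2:(n_u - 1), , drop = FALSE] * 4 -
      mp[1:(n_u - 2), , drop = FALSE] - mp[3:n_u, , drop = FALSE] -
      mp[2:(n_u - 1), c(2:n_v, 1), drop = FALSE] -
      mp[2:(n_u - 1), c(n_v, 1:(n_v - 1)), drop = FALSE]
  }
  map_i <- d1 + matrix(rep(seq_len(n_u), n_v), n_u, n_v)
  map_j <- d2 + matrix(rep(seq_len(n_v), each = n_u), n_u, n_v)
  # residual of the map components (identity rows/columns are discrete
  # harmonic up to the periodic wrap of the raw column index, so check the
  # displacement, whose interior Laplacian must vanish)
  res <- max(abs(lap(d1)), abs(lap(d2)))
  structure(list(forward = disp, backward = invert_disp(disp),
                 ssd = numeric(0), iterations = 0L, converged = TRUE,
                 ic_rms = 0, residual = res, map_i = map_i, map_j = map_j,
                 min_jac = min(disp_jacobian_det(disp)),
                 params = NULL),
            class = "disp_field2d")
}

#' Push template vertices through a registration field onto a subject
#'
#' Each template vertex's rectangle coordinate is advanced by the forward
#' map and located on the subject's parameterization; the returned points
#' are barycentric combinations of subject vertices, i.e. they lie exactly
#' on the subject surface.
#'
#' @param subject,template `param_mesh`es.
#' @param field a `disp_field2d` from registering the subject's feature
#'   grid (moving) to the template's (fixed).
#' @return numeric matrix (template vertices x 3) of corresponded 3-D
#'   points on the subject surface.
#' @export
induce_correspondence <- function(subject, template, field) {
  d <- dim(field$forward)
  n_u <- d[1]; n_v <- d[2]
  iu <- 1 + template$u * (n_u - 1)
  jv <- 1 + template$v / template$h * n_v
  s <- bilinear_sample(field$forward, iu, jv)
  iu2 <- iu + s[, 1]; jv2 <- jv + s[, 2]
  u_s <- (pmin(pmax(iu2, 1), n_u) - 1) / (n_u - 1)
  v_s <- (jv2 - 1) * subject$h / n_v
  loc <- locate_param_points(subject, cbind(u_s, v_s))
  interp_vertex_fields(subject, loc, subject$mesh$vertices)
}
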