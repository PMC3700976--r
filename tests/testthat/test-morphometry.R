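test_that("identity correspondence gives J = I, detJ = 1, logS = 0", {
  par <- base_param_fixture()
  fj <- face_jacobian(par, par$mesh$vertices)
  expect_lt(max(abs(fj$J[, c(1, 4)] - 1)), 1e-12)
  expect_lt(max(abs(fj$J[, c(2, 3)])), 1e-12)
  df <- deformation_features(fj$J)
  expect_equal(df$detJ, rep(1, nrow(fj$J)))
  expect_lt(max(abs(df$logS)), 1e-12)
  expect_length(df$excluded, 0)
})

test_that("uniform scaling gives J = sI and the expected areal ratio", {
  par <- base_param_fixture()
  fj <- face_jacobian(par, par$mesh$vertices * 2)
  df <- deformation_features(fj$J)
  expect_lt(max(abs(df$detJ - 4)), 1e-10)
  expect_lt(max(abs(df$logS[, 1] - log(2))), 1e-10)
  expect_lt(max(abs(df$logS[, 2])), 1e-10)
  expect_lt(max(abs(df$logS[, 3] - log(2))), 1e-10)
})

test_that("logS is invariant to rigid motion of the subject surface", {
  par <- base_param_fixture()
  th <- 1.1
  Rm <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- matrix(c(5, -3, 2), nrow(par$mesh$vertices), 3, byrow = TRUE)
  corr0 <- par$mesh$vertices * 1.3           # a non-trivial correspondence
  corr1 <- corr0 %*% Rm + shift
  d0 <- deformation_features(face_jacobian(par, corr0)$J)
  d1 <- deformation_features(face_jacobian(par, corr1)$J)
  expect_lt(max(abs(d0$logS - d1$logS)), 1e-9)
  expect_lt(max(abs(d0$detJ - d1$detJ)), 1e-9)
})

test_that("a planted in-plane affine map of a flat patch is recovered
           exactly up to the tangent-frame gauge", {
  # flat patch parameterized by itself: build a param_mesh by hand
  pp <- planar_patch(12, 12, 1, 1)
  f <- pp$faces
  par <- structure(list(
    mesh = pp,
    u = pp$vertices[, 1], v = pp$vertices[, 2], h = 1,
    corner_u = matrix(pp$vertices[f, 1], ncol = 3),
    corner_v = matrix(pp$vertices[f, 2], ncol = 3),
    cache = new.env(parent = emptyenv())), class = "param_mesh")
  A <- rbind(c(1.4, 0.3), c(-0.2, 0.8))
  corr <- cbind(pp$vertices[, 1:2] %*% t(A), 0)
  fj <- face_jacobian(par, corr)
  df <- deformation_features(fj$J)
  # the gauge leaves det and the deformation tensor invariant
  expect_lt(max(abs(df$detJ - det(A))), 1e-6)
  SA <- eigen(t(A) %*% A, symmetric = TRUE)
  logSA <- SA$vectors %*% diag(log(SA$values) / 2) %*% t(SA$vectors)
  want <- c(logSA[1, 1], sqrt(2) * logSA[1, 2], logSA[2, 2])
  expect_lt(max(abs(sweep(df$logS, 2, want))), 1e-6)
})

test_that("detJ equals the product of the singular values of J", {
  par <- base_param_fixture()
  set.seed(9)
  corr <- par$mesh$vertices * 1.2 +
    matrix(rnorm(length(par$mesh$vertices), 0, 0.05), ncol = 3)
  fj <- face_jacobian(par, corr)
  sv_prod <- vapply(seq_len(nrow(fj$J)), function(i) {
    J <- matrix(fj$J[i, ], 2, 2, byrow = TRUE)
    prod(svd(J)$d) * sign(det(J))
  }, 0)
  expect_lt(max(abs(fj$J[, 1] * fj$J[, 4] - fj$J[, 2] * fj$J[, 3] -
                      sv_prod)), 1e-10)
})

test_that("detJ-weighted template areas conserve the subject's total area", {
  par <- base_param_fixture()
  corr <- par$mesh$vertices * 1.7
  fj <- face_jacobian(par, corr)
  detJ_face <- fj$J_face[, 1] * fj$J_face[, 4] -
    fj$J_face[, 2] * fj$J_face[, 3]
  a_t <- face_areas(par$mesh)
  a_s <- face_areas(list(vertices = corr, faces = par$mesh$faces))
  expect_lt(abs(sum(detJ_face * a_t) - sum(a_s)) / sum(a_s), 0.01)
})

test_that("the medial axis of a straight tube is its centerline", {
  tb <- mk_tube_cyl(r = 2, len = 10, n_axial = 25, n_circ = 30)
  par <- conformal_parameterize(tb)
  ax <- medial_axis(par)
  expect_equal(nrow(ax$points), 32)
  expect_lt(max(abs(ax$points[, 2])), 0.02 * 2)
  expect_lt(max(abs(ax$points[, 3])), 0.02 * 2)
})

test_that("the medial axis follows a bent tube with monotone arc length", {
  tb <- mk_tube_cyl(r = 1, len = 10, n_axial = 30, n_circ = 24)
  bent <- tb
  t <- tb$vertices[, 1] / 10
  bent$vertices <- cbind(tb$vertices[, 1],
                         tb$vertices[, 2] + 3 * sin(pi * t),
                         tb$vertices[, 3])
  attr(bent, "edge_cache") <- new.env(parent = emptyenv())
  par <- conformal_parameterize(bent)
  ax <- medial_axis(par)
  # centerline of the bent tube: y = 3 sin(pi x / 10), z = 0.  The conformal
  # iso-u curves tilt relative to the x = const cross-sections (the outer
  # side of the bend is metrically longer), so the centroid curve follows
  # the bend with a tolerance of a quarter of the bend amplitude.
  pred_y <- 3 * sin(pi * ax$points[, 1] / 10)
  expect_lt(max(abs(ax$points[, 2] - pred_y)), 0.75)
  expect_gt(max(ax$points[, 2]), 2)
  # the bend is in the x-y plane; the axis stays near z = 0 relative to
  # the bend amplitude of 3
  expect_lt(max(abs(ax$points[, 3])), 0.5)
  steps <- diff(ax$points[, 1])
  expect_true(all(steps > 0) || all(steps < 0))
})

test_that("radial distance recovers the tube radius and scales linearly", {
  tb <- mk_tube_cyl(r = 3, len = 12, n_axial = 25, n_circ = 30)
  par <- conformal_parameterize(tb)
  R <- radial_distance(par, par$mesh$vertices)
  expect_lt(max(abs(R - 3) / 3), 0.02)
  R2 <- radial_distance(par, par$mesh$vertices * 2.5)
  expect_lt(max(abs(R2 - 7.5) / 7.5), 0.02)
})

test_that("radial distance matches the analytic elliptical cross-section", {
  tb <- mk_tube_cyl(r = 1, len = 10, n_axial = 25, n_circ = 36)
  ell <- tb$vertices
  ell[, 2] <- ell[, 2] * 3
  ell[, 3] <- ell[, 3] * 2
  par <- conformal_parameterize(tb)
  R <- radial_distance(par, ell)
  expect_lt(max(abs(R - sqrt(ell[, 2]^2 + ell[, 3]^2)) /
                  sqrt(ell[, 2]^2 + ell[, 3]^2)), 0.03)
})
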