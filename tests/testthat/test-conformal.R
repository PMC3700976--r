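test_that("harmonic function on a right tube is linear in the axial
           coordinate and satisfies the solver contract", {
  tb <- mk_tube_cyl(r = 2, len = 10)
  f <- harmonic_function(tb)
  expect_true(all(f >= -1e-12 & f <= 1 + 1e-12))
  # anterior loop (x = len) is f = 0, so f = 1 - x/len on a flat cylinder
  expect_lt(max(abs(f - (1 - tb$vertices[, 1] / 10))), 1e-6)
  L <- cotan_laplacian(tb)
  interior <- setdiff(seq_len(nrow(tb$vertices)),
                      c(tb$loop_anterior, tb$loop_posterior))
  expect_lt(max(abs((L %*% f)[interior])), 1e-8)
})

test_that("harmonic 1-form is exact: closed around every face, zero for
           constant potentials, analytic on the tube", {
  tb <- mk_tube_cyl(r = 2, len = 10)
  f <- harmonic_function(tb)
  om <- harmonic_oneform(tb, f)
  expect_lt(max(abs(oneform_face_sums(tb, om))), 1e-12)
  om0 <- harmonic_oneform(tb, rep(3.7, nrow(tb$vertices)))
  expect_true(all(om0$values == 0))
  # axial edges carry df = edge length / tube length
  axial <- abs(tb$vertices[om$edges[, 1], 1] -
                 tb$vertices[om$edges[, 2], 1]) > 1e-9
  elen <- abs(tb$vertices[om$edges[axial, 1], 1] -
                tb$vertices[om$edges[axial, 2], 1])
  expect_lt(max(abs(abs(om$values[axial]) - elen / 10)), 1e-6)
})

test_that("conjugate 1-form has the analytic conformal modulus and is
           L2-orthogonal to the harmonic form", {
  tb <- mk_tube_cyl(r = 2, len = 10, n_axial = 25, n_circ = 30)
  f <- harmonic_function(tb)
  om <- harmonic_oneform(tb, f)
  os <- conjugate_oneform(tb, om)
  h <- attr(os, "h")
  expect_lt(abs(h - 2 * pi * 2 / 10) / (2 * pi * 2 / 10), 0.02)
  # closed on the cut mesh (it is d of the conjugate potential)
  cut <- attr(os, "cut")
  expect_lt(max(abs(oneform_face_sums(cut$mesh, os))), 1e-10)
  # orthogonality under the cotangent inner product, via the lifted omega
  lift <- harmonic_oneform(cut$mesh, f[cut$vmap])
  ip <- surfmorph:::oneform_inner(cut$mesh, lift, os)
  scale <- sqrt(abs(surfmorph:::oneform_inner(cut$mesh, lift, lift) *
                      surfmorph:::oneform_inner(cut$mesh, os, os)))
  expect_lt(abs(ip) / scale, 1e-8)
})

test_that("zero harmonic form yields a degenerate-period error", {
  tb <- mk_tube_cyl(r = 2, len = 10)
  om0 <- harmonic_oneform(tb, rep(0, nrow(tb$vertices)))
  expect_error(conjugate_oneform(tb, om0), "period|degenerate")
})

test_that("rectangle integration reproduces the analytic tube chart", {
  tb <- mk_tube_cyl(r = 2, len = 10, n_axial = 25, n_circ = 30)
  par <- conformal_parameterize(tb)
  # u equals the axial fraction (anterior loop at u = 0)
  expect_lt(sqrt(mean((par$u - (1 - tb$vertices[, 1] / 10))^2)), 1e-2)
  expect_true(all(abs(par$u[tb$loop_anterior]) < 1e-9))
  expect_true(all(abs(par$u[tb$loop_posterior] - 1) < 1e-9))
  # v is the scaled arc-length angle up to a global rotation/reflection
  theta <- atan2(tb$vertices[, 3], tb$vertices[, 2])
  v_an <- (theta %% (2 * pi)) * 2 / 10
  dv <- (par$v - v_an) %% par$h
  err1 <- min(sapply(seq(0, par$h, length.out = 100), function(o)
    sqrt(mean(pmin(abs(dv - o), par$h - abs(dv - o))^2))))
  dv2 <- (par$v + v_an) %% par$h
  err2 <- min(sapply(seq(0, par$h, length.out = 100), function(o)
    sqrt(mean(pmin(abs(dv2 - o), par$h - abs(dv2 - o))^2))))
  expect_lt(min(err1, err2), 1e-2)
})

test_that("parameter triangles are positively oriented on cohort meshes", {
  co <- generate_cohort(cohort_spec(n_group0 = 3, n_group1 = 3,
                                    delta = 0.1, seed = 5))
  for (s in co$subjects) {
    par <- conformal_parameterize(cut_extremities(s$mesh, 2))
    areas <- (par$corner_u[, 2] - par$corner_u[, 1]) *
      (par$corner_v[, 3] - par$corner_v[, 1]) -
      (par$corner_u[, 3] - par$corner_u[, 1]) *
      (par$corner_v[, 2] - par$corner_v[, 1])
    expect_true(all(areas > 0))
  }
})

test_that("conformal factor is near-constant on the tube and scales as s^2", {
  tb <- mk_tube_cyl(r = 2, len = 10, n_axial = 25, n_circ = 30)
  par <- conformal_parameterize(tb)
  lam <- par$lambda
  expect_lt(stats::sd(lam) / mean(lam), 0.05)
  tb2 <- tb
  tb2$vertices <- tb$vertices * 3
  attr(tb2, "edge_cache") <- new.env(parent = emptyenv())
  par2 <- conformal_parameterize(tb2)
  expect_lt(abs(mean(par2$lambda) / mean(lam) - 9) / 9, 0.02)
})

test_that("feature-grid sampling is exact at vertices, z-normalizes
           channels and zeroes constant ones", {
  par <- base_param_fixture()
  g <- sample_feature_grid(par, resolution = c(24, 24))
  expect_true(all(is.finite(g$values)))
  expect_lt(abs(mean(g$values[, , 1])), 1e-9)
  expect_equal(stats::sd(g$values[, , 1]), 1, tolerance = 1e-9)
  cg <- sample_grid(par, rep(4.2, nrow(par$mesh$vertices)),
                    resolution = c(12, 12), normalize = TRUE)
  expect_true(all(cg$values == 0))
  # interpolating a vertex field at the vertices reproduces it
  loc <- surfmorph:::locate_param_points(par, cbind(par$u, par$v))
  vals <- surfmorph:::interp_vertex_fields(par, loc, par$mesh$vertices)
  expect_lt(max(abs(vals - par$mesh$vertices)), 1e-9)
})

test_that("doubling the grid resolution only changes smooth fields by
           interpolation error", {
  par <- base_param_fixture()
  smooth_field <- sin(2 * pi * par$u) + cos(2 * pi * par$v / par$h)
  g1 <- sample_grid(par, smooth_field, resolution = c(16, 16))
  g2 <- sample_grid(par, smooth_field, resolution = c(31, 32))
  coarse_from_fine <- g2$values[seq(1, 31, by = 2), seq(1, 32, by = 2), 1]
  expect_lt(sqrt(mean((coarse_from_fine - g1$values[, , 1])^2)), 1e-2)
})

test_that("quasi-conformal dilatation approaches 1 under refinement", {
  med_dil <- vapply(c(16, 24), function(nc) {
    tb <- mk_tube_cyl(r = 1, len = 4, n_axial = round(nc * 2 / 3),
                      n_circ = nc)
    par <- conformal_parameterize(tb)
    fj <- face_jacobian(par, par$mesh$vertices)
    # dilatation of the chart itself: singular values of the face map from
    # parameters to 3-D, via the first fundamental form of the chart
    cu <- par$corner_u; cv <- par$corner_v
    v3 <- par$mesh$vertices
    f <- par$mesh$faces
    dil <- vapply(seq_len(nrow(f)), function(t) {
      P2 <- rbind(c(cu[t, 2] - cu[t, 1], cu[t, 3] - cu[t, 1]),
                  c(cv[t, 2] - cv[t, 1], cv[t, 3] - cv[t, 1]))
      E <- cbind(v3[f[t, 2], ] - v3[f[t, 1], ],
                 v3[f[t, 3], ] - v3[f[t, 1], ])
      J <- E %*% solve(P2)
      sv <- sqrt(eigen(crossprod(J), symmetric = TRUE,
                       only.values = TRUE)$values)
      sv[1] / sv[2]
    }, 0)
    stats::median(dil)
  }, 0)
  expect_true(all(med_dil >= 1))
  expect_lt(med_dil[2] - 1, med_dil[1] - 1 + 1e-12)
  expect_lt(med_dil[2], 1.05)
})

test_that("the full parameterization is deterministic", {
  cyl <- cut_extremities(base_shape(3), 2)
  p1 <- conformal_parameterize(cyl)
  p2 <- conformal_parameterize(cyl)
  expect_identical(p1$u, p2$u)
  expect_identical(p1$v, p2$v)
  expect_identical(p1$h, p2$h)
})
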