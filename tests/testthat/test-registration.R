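# Fixtures: smooth band-limited 2-channel images on the periodic rectangle
# grid; ground-truth warps are applied by resampling, so the registration
# target is the numerical inverse of the applied field.

test_that("registering an image to itself returns zero displacement", {
  img <- mk_feature_image(24, 24, seed = 3)
  r <- fluid_register(img, img)
  expect_equal(max(abs(r$forward)), 0)
  expect_equal(max(abs(r$backward)), 0)
  expect_lt(utils::tail(r$ssd, 1), 1e-12)
})

test_that("a circular shift in v is recovered", {
  n <- 32
  img <- mk_feature_image(n, n, seed = 7)
  shifted <- as_feature_grid(img$values[, c((n - 3):n, 1:(n - 4)), ,
                                        drop = FALSE])
  r <- fluid_register(shifted, img, registration_params(max_iter = 100))
  expect_lt(abs(mean(r$forward[2:(n - 1), , 2]) - 4), 0.5)
})

test_that("a smooth synthetic diffeomorphism is recovered with sub-node
           accuracy and inverse consistency", {
  n <- 32
  img <- mk_feature_image(n, n, seed = 11)
  u <- seq(0, 1, length.out = n)
  v <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  gstar <- array(0, c(n, n, 2))
  gstar[, , 1] <- 1.2 * outer(sin(pi * u), cos(v))
  gstar[, , 2] <- 1.5 * outer(sin(pi * u), sin(2 * v + 1))
  gstar[c(1, n), , ] <- 0
  moved <- as_feature_grid(surfmorph:::warp_image(img$values, gstar))
  r <- fluid_register(moved, img, registration_params(max_iter = 300))
  true_fwd <- surfmorph:::invert_disp(gstar)
  expect_lt(sqrt(mean((r$forward - true_fwd)^2)), 0.5)
  expect_lt(r$ic_rms, 0.25)
  # SSD strictly reduced vs. the unregistered start
  expect_lt(utils::tail(r$ssd, 1), 0.2 * r$ssd[1])
  # diffeomorphism guard
  expect_gt(r$min_jac, 0)
})

test_that("the constrained harmonic map is the identity for matching
           boundary data and satisfies the solver contract", {
  hr <- harmonic_register(NULL, NULL, resolution = c(24, 24))
  expect_equal(max(abs(hr$forward)), 0)
  expect_lt(hr$residual, 1e-8)
})

test_that("the harmonic baseline recovers the simulated warp no better
           than the fluid method", {
  n <- 32
  img <- mk_feature_image(n, n, seed = 11)
  u <- seq(0, 1, length.out = n)
  v <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  gstar <- array(0, c(n, n, 2))
  gstar[, , 1] <- 1.2 * outer(sin(pi * u), cos(v))
  gstar[, , 2] <- 1.5 * outer(sin(pi * u), sin(2 * v + 1))
  gstar[c(1, n), , ] <- 0
  moved <- as_feature_grid(surfmorph:::warp_image(img$values, gstar))
  rf <- fluid_register(moved, img, registration_params(max_iter = 300))
  rh <- harmonic_register(NULL, NULL, resolution = c(n, n))
  true_fwd <- surfmorph:::invert_disp(gstar)
  err_f <- sqrt(mean((rf$forward - true_fwd)^2))
  err_h <- sqrt(mean((rh$forward - true_fwd)^2))
  expect_gte(err_h, err_f)
})

test_that("induced correspondence with a zero field on the template is the
           template itself, and points lie on the subject surface", {
  par <- base_param_fixture()
  zero <- structure(list(forward = array(0, c(24, 24, 2)),
                         backward = array(0, c(24, 24, 2))),
                    class = "disp_field2d")
  corr <- induce_correspondence(par, par, zero)
  expect_lt(max(abs(corr - par$mesh$vertices)), 1e-8)
})

test_that("a rigidly rotated subject is corresponded onto the rotated
           vertices", {
  par <- base_param_fixture()
  th <- 0.6
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh2 <- triangle_mesh(par$mesh$vertices %*% Rm, par$mesh$faces)
  cyl2 <- par$mesh
  cyl2$vertices <- mesh2$vertices
  attr(cyl2, "edge_cache") <- new.env(parent = emptyenv())
  par2 <- conformal_parameterize(cyl2)
  g1 <- sample_feature_grid(par2, resolution = c(24, 24))
  g0 <- sample_feature_grid(par, resolution = c(24, 24))
  field <- fluid_register(g1, g0, registration_params(max_iter = 60))
  corr <- induce_correspondence(par2, par, field)
  rmse <- sqrt(mean((corr - par$mesh$vertices %*% Rm)^2))
  expect_lt(rmse, 0.01 * mesh_diameter(par$mesh))
})
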