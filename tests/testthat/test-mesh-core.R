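test_that("mesh IO round-trips OFF, PLY and VTK and flags malformed files", {
  tet <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                             c(0, 0, 1)),
                       rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4),
                             c(1, 4, 3)))
  tmp <- withr::local_tempdir()
  # tetrahedron OFF written by hand: smallest closed mesh
  off <- file.path(tmp, "tet.off")
  writeLines(c("OFF", "4 4 0",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 1 2 3", "3 0 3 2"), off)
  m <- read_mesh(off)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 4)

  set.seed(7)
  rnd <- icosphere(1, r = 2)
  rnd$vertices <- rnd$vertices + matrix(rnorm(length(rnd$vertices), 0, 0.01),
                                        ncol = 3)
  for (fmt in c("off", "ply", "vtk")) {
    p <- file.path(tmp, paste0("m.", fmt))
    write_mesh(rnd, p)
    back <- read_mesh(p)
    expect_identical(back$faces, rnd$faces)
    expect_equal(back$vertices, rnd$vertices, tolerance = 1e-15)
  }

  bad <- file.path(tmp, "bad.off")
  writeLines(c("OFF", "3 1 0", "0 0 0", "1 0 0", "0 1 0",
               "5 0 1 2 0 1"), bad)
  expect_error(read_mesh(bad), "triangular")
})

test_that("topology report gets genus and boundary counts right", {
  s <- icosphere(2)
  top <- validate_topology(s)
  expect_equal(top$genus, 0)
  expect_equal(top$n_boundaries, 0)
  expect_equal(top$euler, 2)

  one_gone <- triangle_mesh(s$vertices, s$faces[-1, , drop = FALSE],
                            validate = FALSE)
  top1 <- validate_topology(one_gone)
  expect_equal(top1$genus, 0)
  expect_equal(top1$n_boundaries, 1)

  # remove two antipodal caps (faces touching the extreme +/- z vertices),
  # dropping the now-unreferenced apex vertices
  zext <- c(which.max(s$vertices[, 3]), which.min(s$vertices[, 3]))
  keep <- !apply(matrix(s$faces %in% zext, ncol = 3), 1, any)
  f2 <- s$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(s$vertices)); remap[used] <- seq_along(used)
  two_caps <- triangle_mesh(s$vertices[used, , drop = FALSE],
                            matrix(remap[f2], ncol = 3), validate = FALSE)
  top2 <- validate_topology(two_caps)
  expect_equal(top2$genus, 0)
  expect_equal(top2$n_boundaries, 2)

  # non-manifold: duplicate one face with flipped orientation
  nm <- triangle_mesh(s$vertices, rbind(s$faces, s$faces[1, c(1, 3, 2)]),
                      validate = FALSE)
  expect_error(validate_topology(nm), "non-manifold|orientation")
})

test_that("Euler bookkeeping is an exact integer identity on fixtures", {
  for (m in list(icosphere(2), tube_mesh(), planar_patch(),
                 base_shape(3))) {
    top <- validate_topology(m)
    expect_identical(top$euler,
                     2L - 2L * as.integer(top$genus) -
                       as.integer(top$n_boundaries))
  }
})

test_that("mean curvature matches analytic values on sphere, tube, plane", {
  H2 <- mean_curvature(icosphere(4, r = 2))
  expect_lt(max(abs(H2 - 0.5) / 0.5), 0.02)

  tb <- tube_mesh(r = 2, len = 10, n_axial = 25, n_circ = 30)
  Ht <- mean_curvature(tb)
  interior <- setdiff(seq_len(nrow(tb$vertices)),
                      unlist(validate_topology(tb)$boundary_loops))
  expect_lt(max(abs(Ht[interior] - 0.25) / 0.25), 0.02)

  pp <- planar_patch()
  Hp <- mean_curvature(pp)
  int_p <- setdiff(seq_len(nrow(pp$vertices)),
                   unlist(validate_topology(pp)$boundary_loops))
  expect_lt(max(abs(Hp[int_p])), 1e-8)
})

test_that("sphere curvature error decreases monotonically under refinement", {
  errs <- vapply(2:4, function(k) {
    H <- mean_curvature(icosphere(k, r = 1))
    max(abs(H - 1))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("cut_extremities opens a cylinder at the long-axis poles", {
  e <- ellipsoid_mesh(c(3, 1.5, 1), 3)
  cyl <- cut_extremities(e, k = 2)
  top <- validate_topology(cyl)
  expect_equal(top$genus, 0)
  expect_equal(top$n_boundaries, 2)
  # loops sit at the +/- x poles
  expect_gt(mean(cyl$vertices[cyl$loop_anterior, 1]), 2)
  expect_lt(mean(cyl$vertices[cyl$loop_posterior, 1]), -2)
})

test_that("cut_extremities is deterministic, also for a sphere", {
  s <- icosphere(3)
  c1 <- cut_extremities(s, k = 2)
  c2 <- cut_extremities(s, k = 2)
  expect_identical(c1$faces, c2$faces)
  expect_identical(c1$loop_anterior, c2$loop_anterior)
  b1 <- cut_extremities(base_shape(3), k = 2)
  b2 <- cut_extremities(base_shape(3), k = 2)
  expect_identical(b1$faces, b2$faces)
})

test_that("cut loops are geodesically well separated on the base shape", {
  mesh <- base_shape(3)
  cyl <- cut_extremities(mesh, k = 2)
  g <- surfmorph:::mesh_graph(cyl)
  d <- igraph::distances(g, v = cyl$loop_anterior,
                         to = cyl$loop_posterior)
  expect_gt(min(d), 0.5 * mesh_diameter(mesh))
})

test_that("cut patches that would overlap raise an error", {
  expect_error(cut_extremities(icosphere(1), k = 4), "overlap|cylinder")
})
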