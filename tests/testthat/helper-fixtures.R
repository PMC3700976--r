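# Shared fixtures: all built in code, no data files.

# open tube as a cylinder_mesh with labeled loops (anterior = +x side)
mk_tube_cyl <- function(r = 2, len = 10, n_axial = 25, n_circ = 30) {
  tb <- tube_mesh(r = r, len = len, n_axial = n_axial, n_circ = n_circ)
  top <- validate_topology(tb)
  side <- vapply(top$boundary_loops,
                 function(l) mean(tb$vertices[l, 1]), 0)
  tb$loop_anterior <- top$boundary_loops[[which.max(side)]]
  tb$loop_posterior <- top$boundary_loops[[which.min(side)]]
  tb$axis2 <- c(0, 1, 0)
  class(tb) <- c("cylinder_mesh", class(tb))
  tb
}

# smooth band-limited 2-channel test image, periodic in the v direction
mk_feature_image <- function(n_u, n_v, seed) {
  set.seed(seed)
  z <- array(0, c(n_u, n_v, 2))
  u <- seq(0, 1, length.out = n_u)
  v <- seq(0, 2 * pi, length.out = n_v + 1)[seq_len(n_v)]
  for (c in 1:2) {
    g <- matrix(0, n_u, n_v)
    for (k in 1:8) {
      g <- g + stats::rnorm(1) *
        outer(sin(pi * u * sample(1:4, 1) + stats::rnorm(1)),
              sin(sample(1:4, 1) * v + stats::rnorm(1)))
    }
    z[, , c] <- (g - mean(g)) / stats::sd(g)
  }
  structure(list(values = z, h = 1, channels = c("a", "b")),
            class = "feature_grid")
}

as_feature_grid <- function(values) {
  structure(list(values = values, h = 1), class = "feature_grid")
}

# exhaustive two-sample permutation p-values (brute force oracle)
brute_force_perm_p <- function(values, labels, stat_fn) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  sets <- utils::combn(n, n1)
  obs <- stat_fn(values, labels)
  counts <- 0
  for (k in seq_len(ncol(sets))) {
    lab <- integer(n); lab[sets[, k]] <- 1L
    counts <- counts + (stat_fn(values, lab) >= obs)
  }
  counts / ncol(sets)
}

# a small closed mesh parameterized end to end (shared across tests)
base_param_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      mesh <- base_shape(3)
      cyl <- cut_extremities(mesh, k = 2)
      val <<- conformal_parameterize(cyl)
    }
    val
  }
})
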