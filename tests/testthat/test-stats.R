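mk_cohort <- function(n0, n1, seed = 1) {
  set.seed(seed)
  cohort_table(id = sprintf("S%02d", seq_len(n0 + n1)),
               group = c(rep(0, n0), rep(1, n1)),
               age = c(rnorm(n0, 45.1, 5.1), rnorm(n1, 41.1, 5.0)))
}

test_that("age adjustment removes a pure age effect and preserves a group
           shift", {
  co <- mk_cohort(10, 10, seed = 2)
  # values exactly 2 * age: adjustment leaves a constant across subjects
  vals <- outer(co$age * 2, rep(1, 50))
  adj <- adjust_for_age(vals, co)
  expect_lt(max(abs(sweep(adj, 2, colMeans(adj)))), 1e-9)
  # no age effect at all: adjustment changes values by at most the
  # estimated-slope noise times the age spread
  set.seed(3)
  noise <- matrix(rnorm(20 * 50), 20, 50)
  adj2 <- adjust_for_age(noise, co)
  X <- cbind(1, co$age, co$group)
  b1 <- solve(crossprod(X), crossprod(X, noise))[2, ]
  bound <- max(abs(b1)) * max(abs(co$age - mean(co$age)))
  expect_lte(max(abs(adj2 - noise)), bound + 1e-12)
  expect_lt(bound, 2)
  # age slope 0.5 plus group shift 1: slope recovered, shift preserved
  set.seed(4)
  y <- 0.5 * co$age + 1 * co$group + matrix(rnorm(20 * 200, 0, 0.2),
                                            20, 200)
  X <- cbind(1, co$age, co$group)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_lt(abs(mean(beta[2, ]) - 0.5), 0.02)
  adj3 <- adjust_for_age(y, co)
  shift <- colMeans(adj3[co$group == 1, ]) - colMeans(adj3[co$group == 0, ])
  expect_lt(abs(mean(shift) - 1), 0.05)
})

test_that("rank-deficient designs skip adjustment with a warning", {
  co <- mk_cohort(5, 5)
  co$age <- rep(40, 10)
  vals <- matrix(rnorm(10 * 4), 10, 4)
  expect_warning(out <- adjust_for_age(vals, co), "rank")
  expect_identical(out, vals)
})

test_that("t^2 map matches the textbook pooled formula on a 3-vs-3 sample", {
  x <- c(1.2, 0.7, 1.9, 2.4, 3.1, 2.2)
  labels <- c(0, 0, 0, 1, 1, 1)
  t2 <- t_stat_map(matrix(x, 6, 1), labels)
  m0 <- mean(x[1:3]); m1 <- mean(x[4:6])
  sp2 <- (sum((x[1:3] - m0)^2) + sum((x[4:6] - m1)^2)) / 4
  t_ref <- (m1 - m0) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(t2, t_ref^2, tolerance = 1e-12)
  # identical groups give 0; swapping labels leaves t^2 unchanged
  expect_equal(t_stat_map(matrix(rep(x[1:3], 2), 6, 1), labels), 0)
  expect_equal(t_stat_map(matrix(x, 6, 1), 1 - labels), t2)
})

test_that("zero pooled variance is flagged and set to 0", {
  vals <- matrix(1, 6, 3)
  expect_warning(t2 <- t_stat_map(vals, c(0, 0, 0, 1, 1, 1)), "variance")
  expect_equal(t2, rep(0, 3))
})

test_that("Hotelling's T^2 equals t^2 in dimension 1 and is invariant
           under invertible channel transforms", {
  set.seed(8)
  n <- 14
  labels <- rep(c(0, 1), each = 7)
  vals <- array(rnorm(n * 30), c(n, 30, 1))
  expect_equal(hotelling_map(vals, labels),
               t_stat_map(vals[, , 1], labels),
               tolerance = 1e-10)
  vals3 <- array(rnorm(n * 30 * 3), c(n, 30, 3))
  t2a <- hotelling_map(vals3, labels)
  A <- rbind(c(2, 0.5, -1), c(0, 1.5, 0.3), c(0.2, 0, 0.9))
  vt <- vals3
  for (i in seq_len(n)) vt[i, , ] <- vals3[i, , ] %*% t(A)
  t2b <- hotelling_map(vt, labels)
  expect_equal(t2a, t2b, tolerance = 1e-8)
  # identical group means give 0 (group 1 rows duplicate group 0 rows)
  sym <- array(rnorm(8 * 5 * 3), c(8, 5, 3))
  sym[5:8, , ] <- sym[1:4, , ]
  expect_lt(max(hotelling_map(sym, rep(c(0, 1), each = 4))), 1e-16)
})

test_that("the prepared permutation statistic agrees with the direct
           implementations", {
  set.seed(5)
  labels <- rep(c(0, 1), times = c(9, 8))
  sc <- matrix(rnorm(17 * 40), 17, 40)
  fn1 <- surfmorph:::prepared_stat_fn(sc)
  expect_equal(fn1(sc, labels), t_stat_map(sc, labels), tolerance = 1e-10)
  vec <- array(rnorm(17 * 40 * 4), c(17, 40, 4))
  fn4 <- surfmorph:::prepared_stat_fn(vec)
  expect_equal(fn4(vec, labels), hotelling_map(vec, labels),
               tolerance = 1e-8)
})

test_that("the Freedman-Lane fast path equals explicit residual-permutation
           reconstruction", {
  set.seed(61)
  co <- mk_cohort(10, 9, seed = 62)
  vals <- array(rnorm(19 * 40 * 3), c(19, 40, 3))
  r <- surfmorph:::freedman_lane_perm(vals, co, n_perm = 30, seed = 7)
  Z <- cbind(1, co$age)
  Y <- matrix(vals, 19)
  Fit <- Z %*% solve(crossprod(Z), crossprod(Z, Y))
  Res <- Y - Fit
  perms <- surfmorph:::with_seed(7, t(vapply(1:30, function(b)
    sample.int(19), integer(19))))
  for (b in c(1, 15, 30)) {
    Ystar <- array(Res[perms[b, ], ] + Fit, c(19, 40, 3))
    want <- hotelling_map(adjust_for_age(Ystar, co), co$group)
    expect_equal(r$perm_stats[b, ], want, tolerance = 1e-9)
  }
  expect_equal(r$stat,
               hotelling_map(adjust_for_age(vals, co), co$group),
               tolerance = 1e-10)
})

test_that("permutation p-values match exhaustive enumeration on a 3-vs-3
           toy", {
  set.seed(12)
  vals <- matrix(rnorm(6 * 8), 6, 8)
  labels <- c(0, 0, 0, 1, 1, 1)
  fn <- function(d, l) t_stat_map(d, l, warn = FALSE)
  expect_warning(
    pr <- vertex_permutation(fn, vals, labels, n_perm = 100, seed = 1),
    "distinct")
  p_brute <- brute_force_perm_p(vals, labels, fn)
  expect_equal(pr$p, p_brute, tolerance = 1e-12)
})

test_that("constant data gives p = 1 everywhere", {
  vals <- matrix(5, 8, 6)
  fn <- function(d, l) t_stat_map(d, l, warn = FALSE)
  pr <- vertex_permutation(fn, vals, rep(c(0, 1), each = 4),
                           n_perm = 60, seed = 2)
  expect_true(all(pr$p == 1))
})

test_that("under an exchangeable null the p-values are approximately
           uniform", {
  set.seed(21)
  n <- 16
  vals <- matrix(rnorm(n * 2000), n, 2000)
  labels <- rep(c(0, 1), each = 8)
  fn <- surfmorph:::prepared_stat_fn(vals)
  pr <- vertex_permutation(fn, vals, labels, n_perm = 1000, seed = 3)
  ks <- max(abs(sort(pr$p) - seq_along(pr$p) / length(pr$p)))
  expect_lt(ks, 0.05)
})

test_that("permutation maps are deterministic given the seed", {
  set.seed(33)
  vals <- matrix(rnorm(12 * 50), 12, 50)
  labels <- rep(c(0, 1), each = 6)
  fn <- surfmorph:::prepared_stat_fn(vals)
  p1 <- vertex_permutation(fn, vals, labels, n_perm = 200, seed = 9)
  p2 <- vertex_permutation(fn, vals, labels, n_perm = 200, seed = 9)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$perm_stats, p2$perm_stats)
})

test_that("map-wise correction: threshold 1 gives corrected p = 1, an
           implanted strong effect is significant, null counts calibrate", {
  set.seed(44)
  n <- 20
  labels <- rep(c(0, 1), each = 10)
  vals <- matrix(rnorm(n * 300), n, 300)
  vals[labels == 1, 1:60] <- vals[labels == 1, 1:60] + 1.5
  fn <- surfmorph:::prepared_stat_fn(vals)
  pr <- vertex_permutation(fn, vals, labels, n_perm = 1000, seed = 4)
  mw1 <- mapwise_permutation(pr, threshold = 1.0)
  expect_equal(mw1$corrected_p, 1)
  expect_true(all(mw1$perm_counts == 300))
  mw <- mapwise_permutation(pr, threshold = 0.05)
  expect_lte(mw$corrected_p, 0.01)
  # map-level rejection rate on exchangeable nulls within the binomial band
  rej <- vapply(1:60, function(r) {
    set.seed(1000 + r)
    nv <- matrix(rnorm(12 * 150), 12, 150)
    fnr <- surfmorph:::prepared_stat_fn(nv)
    prr <- vertex_permutation(fnr, nv, rep(c(0, 1), each = 6),
                              n_perm = 150, seed = r)
    mapwise_permutation(prr, 0.05)$corrected_p <= 0.05
  }, NA)
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.15)
})

test_that("the CDF-based FDR critical p matches a reference step-up
           procedure", {
  # all strongly significant: critical p is the largest p-value
  expect_equal(fdr_cdf(rep(1e-6, 100), 0.05)$critical_p, 1e-6)
  # oracle: largest p with BH-adjusted p <= q, via stats::p.adjust
  set.seed(6)
  for (r in 1:20) {
    p <- c(runif(300)^sample(1:3, 1))
    got <- fdr_cdf(p, 0.05)$critical_p
    adj <- stats::p.adjust(p, method = "BH")
    want <- if (any(adj <= 0.05)) max(p[adj <= 0.05]) else NA_real_
    expect_identical(got, want)
  }
  # uniform p-values rarely cross the line
  crossings <- vapply(1:40, function(r) {
    set.seed(500 + r)
    !is.na(fdr_cdf(runif(1000), 0.05)$critical_p)
  }, NA)
  expect_lte(mean(crossings), 0.1)
  expect_error(fdr_cdf(numeric(0)), "empty")
})
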