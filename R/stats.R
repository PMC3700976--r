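# Group inference stack: age-covariate adjustment, pooled t^2 and
# Hotelling's T^2 vertex statistics, dual permutation testing (vertex-wise
# and map-wise suprathreshold count) on a single seeded permutation stream,
# and the CDF-based FDR critical p-value.

#' Cohort table constructor
#'
#' @param id subject identifiers.
#' @param group 0 (term / control) or 1 (preterm / case).
#' @param age age at scan in weeks.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(id, group, age) {
  stopifnot(length(id) == length(group), length(group) == length(age),
            all(group %in% c(0, 1)), all(is.finite(age)))
  if (sum(group == 0) < 2 || sum(group == 1) < 2)
    stop("need at least 2 subjects per group")
  structure(data.frame(id = id, group = as.integer(group), age = age),
            class = c("cohort_table", "data.frame"))
}

#' Adjust per-vertex measures for age at scan
#'
#' At each vertex (and channel), fits value = b0 + b1 age + b2 diagnosis by
#' least squares over subjects, with diagnosis kept in the design so the
#' group signal is not absorbed into the age slope, and removes the age
#' effect: adjusted = value - b1 (age - mean(age)).
#'
#' @param values subjects x vertices matrix, or subjects x vertices x
#'   channels array (channels adjusted separately).
#' @param cohort a [cohort_table()].
#' @return adjusted values, same shape.
#' @export
adjust_for_age <- function(values, cohort) {
  X <- cbind(1, cohort$age, cohort$group)
  if (qr(X)$rank < 3) {
    warning("rank-deficient design (constant ages?); skipping adjustment")
    return(values)
  }
  dm <- dim(values)
  mat <- if (length(dm) == 3) matrix(values, dm[1]) else as.matrix(values)
  beta <- solve(crossprod(X), crossprod(X, mat))
  adj <- mat - outer(cohort$age - mean(cohort$age), beta[2, ])
  if (length(dm) == 3) array(adj, dm) else adj
}

#' Pooled-variance two-sample t-squared statistic per vertex
#'
#' The square of the standard two-sample t statistic (squared so the
#' permutation test is two-sided, matching T^2).  Vertices with zero pooled
#' variance get statistic 0.
#'
#' @param values subjects x vertices matrix.
#' @param labels 0/1 group labels.
#' @param warn warn about zero-variance vertices (default `TRUE`).
#' @return numeric vector of t^2 values.
#' @export
t_stat_map <- function(values, labels, warn = TRUE) {
  g1 <- labels == 1; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- colMeans(values[g1, , drop = FALSE])
  m0 <- colMeans(values[g0, , drop = FALSE])
  ss1 <- colSums(sweep(values[g1, , drop = FALSE], 2, m1)^2)
  ss0 <- colSums(sweep(values[g0, , drop = FALSE], 2, m0)^2)
  sp2 <- (ss1 + ss0) / (n1 + n0 - 2)
  zero <- sp2 <= 0
  if (any(zero) && warn)
    warning(sum(zero), " vertices with zero pooled variance; t set to 0")
  t2 <- (m1 - m0)^2 / (sp2 * (1 / n1 + 1 / n0))
  t2[zero] <- 0
  t2
}

# vectorized SPD solve (Cholesky) for V stacked d x d systems given as a
# list-of-lists of V-vectors; adds a trace-scaled ridge where the pivot
# fails and reports how many vertices needed it
vec_spd_solve <- function(S, rhs, d) {
  V <- length(rhs[[1]])
  tr <- Reduce(`+`, lapply(seq_len(d), function(i) S[[i]][[i]]))
  ridge <- numeric(V)
  repeat {
    L <- rep(list(vector("list", d)), d)
    ok <- rep(TRUE, V)
    for (i in seq_len(d)) {
      s <- S[[i]][[i]] + ridge
      if (i > 1) for (k in seq_len(i - 1)) s <- s - L[[i]][[k]]^2
      ok <- ok & s > 0
      L[[i]][[i]] <- sqrt(pmax(s, .Machine$double.xmin))
      if (i < d) for (j in (i + 1):d) {
        s2 <- S[[j]][[i]]
        if (i > 1) for (k in seq_len(i - 1))
          s2 <- s2 - L[[i]][[k]] * L[[j]][[k]]
        L[[j]][[i]] <- s2 / L[[i]][[i]]
      }
    }
    if (all(ok)) break
    ridge[!ok] <- pmax(ridge[!ok] * 10, 1e-8 * tr[!ok] / d,
                       .Machine$double.xmin)
  }
  # forward then back substitution
  y <- vector("list", d)
  for (i in seq_len(d)) {
    s <- rhs[[i]]
    if (i > 1) for (k in seq_len(i - 1)) s <- s - L[[i]][[k]] * y[[k]]
    y[[i]] <- s / L[[i]][[i]]
  }
  x <- vector("list", d)
  for (i in rev(seq_len(d))) {
    s <- y[[i]]
    if (i < d) for (k in (i + 1):d) s <- s - L[[k]][[i]] * x[[k]]
    x[[i]] <- s / L[[i]][[i]]
  }
  attr(x, "n_ridged") <- sum(ridge > 0)
  x
}

#' Hotelling's T-squared statistic per vertex
#'
#' T^2 = n1 n2 / (n1 + n2) (m1 - m2)' S_pooled^-1 (m1 - m2) with the pooled
#' sample covariance; a trace-scaled ridge is added at vertices where the
#' pooled covariance is numerically singular.
#'
#' @param values subjects x vertices x channels array (channels >= 1).
#' @param labels 0/1 group labels.
#' @return numeric vector of T^2 values.
#' @export
hotelling_map <- function(values, labels) {
  dm <- dim(values)
  if (length(dm) == 2) dm <- c(dm, 1)
  n <- dm[1]; V <- dm[2]; d <- dm[3]
  if (n - 2 <= d) stop("need n1 + n2 - 2 > channel dimension")
  mat <- matrix(values, n)
  g1 <- labels == 1; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- colMeans(mat[g1, , drop = FALSE])
  m0 <- colMeans(mat[g0, , drop = FALSE])
  c1 <- sweep(mat[g1, , drop = FALSE], 2, m1)
  c0 <- sweep(mat[g0, , drop = FALSE], 2, m0)
  ch_idx <- function(k) ((k - 1) * V + 1):(k * V)
  S <- rep(list(vector("list", d)), d)
  for (j in seq_len(d)) for (k in seq_len(j)) {
    s <- (colSums(c1[, ch_idx(j), drop = FALSE] *
                    c1[, ch_idx(k), drop = FALSE]) +
            colSums(c0[, ch_idx(j), drop = FALSE] *
                      c0[, ch_idx(k), drop = FALSE])) / (n1 + n0 - 2)
    S[[j]][[k]] <- s
    S[[k]][[j]] <- s
  }
  delta <- lapply(seq_len(d), function(k) (m1 - m0)[ch_idx(k)])
  x <- vec_spd_solve(S, delta, d)
  t2 <- Reduce(`+`, lapply(seq_len(d), function(k) delta[[k]] * x[[k]]))
  (n1 * n0 / (n1 + n0)) * t2
}

# Precompute label-independent sufficient statistics so the permutation
# loop costs one matrix-vector product per relabeling: the per-vertex
# pooled covariance is T_jk - n1 m1_j m1_k - n0 m0_j m0_k with T the total
# second-moment matrix, which does not depend on the labels.
prepared_stat_fn <- function(values) {
  dm <- dim(values)
  if (length(dm) == 2) dm <- c(dm, 1)
  n <- dm[1]; V <- dm[2]; d <- dm[3]
  mat <- matrix(values, n)
  tot <- colSums(mat)
  ch_idx <- function(k) ((k - 1) * V + 1):(k * V)
  Tm <- rep(list(vector("list", d)), d)
  for (j in seq_len(d)) for (k in seq_len(j)) {
    Tm[[j]][[k]] <- colSums(mat[, ch_idx(j), drop = FALSE] *
                              mat[, ch_idx(k), drop = FALSE])
  }
  function(data, labels) {
    n1 <- sum(labels == 1); n0 <- n - n1
    s1 <- as.numeric(crossprod(labels == 1, mat))
    m1 <- s1 / n1
    m0 <- (tot - s1) / n0
    S <- rep(list(vector("list", d)), d)
    for (j in seq_len(d)) for (k in seq_len(j)) {
      s <- (Tm[[j]][[k]] - n1 * m1[ch_idx(j)] * m1[ch_idx(k)] -
              n0 * m0[ch_idx(j)] * m0[ch_idx(k)]) / (n - 2)
      S[[j]][[k]] <- s; S[[k]][[j]] <- s
    }
    delta <- m1 - m0
    if (d == 1) {
      sp2 <- S[[1]][[1]]
      t2 <- delta^2 / (sp2 * (1 / n1 + 1 / n0))
      t2[sp2 <= 0] <- 0
      return(t2)
    }
    dl <- lapply(seq_len(d), function(k) delta[ch_idx(k)])
    x <- vec_spd_solve(S, dl, d)
    (n1 * n0 / (n1 + n0)) *
      Reduce(`+`, lapply(seq_len(d), function(k) dl[[k]] * x[[k]]))
  }
}

# generate the permutation stream: a B x n matrix of 0/1 label rows with
# the observed group sizes.  Falls back to exhaustive enumeration (minus
# the observed labeling) when there are fewer distinct splits than
# requested permutations.
permutation_stream <- function(labels, n_perm, seed) {
  n <- length(labels)
  n1 <- sum(labels == 1)
  n_all <- choose(n, n1)
  if (n_all - 1 <= n_perm) {
    if (n_all - 1 < n_perm)
      warning("requested ", n_perm, " permutations but only ", n_all - 1,
              " distinct non-observed label splits exist; enumerating all")
    sets <- utils::combn(n, n1)
    perms <- matrix(0L, ncol(sets), n)
    perms[cbind(rep(seq_len(ncol(sets)), each = n1), as.vector(sets))] <- 1L
    obs <- which(apply(perms, 1, function(r) all(r == labels)))
    perms[-obs, , drop = FALSE]
  } else {
    with_seed(seed, {
      t(vapply(seq_len(n_perm), function(b) {
        lab <- integer(n)
        lab[sample.int(n, n1)] <- 1L
        lab
      }, integer(n)))
    })
  }
}

# evaluate a block of code with a fixed RNG state, restoring the caller's
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Vertex-wise permutation test
#'
#' Group labels are randomly reassigned without replacement (preserving the
#' group sizes), the statistic is recomputed per vertex for each relabeling,
#' and p(vertex) = (1 + #\{perm stat >= observed\}) / (1 + n_perm).  With a
#' small cohort all distinct label splits are enumerated instead, which
#' makes the p-values exact.
#'
#' @param stat_fn function(data, labels) returning a per-vertex statistic
#'   (larger = stronger group difference).
#' @param data subjects x vertices matrix or subjects x vertices x channels
#'   array.
#' @param labels observed 0/1 group labels.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed for the permutation stream.
#' @return list of class `perm_result`: `stat` (observed), `p`,
#'   `perm_stats` (B x V), `n_perm` (effective B).
#' @export
vertex_permutation <- function(stat_fn, data, labels, n_perm = 1000,
                               seed = 1) {
  obs <- stat_fn(data, labels)
  perms <- permutation_stream(labels, n_perm, seed)
  B <- nrow(perms)
  perm_stats <- matrix(0, B, length(obs))
  for (b in seq_len(B)) perm_stats[b, ] <- stat_fn(data, perms[b, ])
  exceed <- colSums(perm_stats >= rep(obs, each = B))
  p <- (1 + exceed) / (1 + B)
  structure(list(stat = obs, p = p, perm_stats = perm_stats, n_perm = B),
            class = "perm_result")
}

#' Map-wise permutation correction
#'
#' Reuses the vertex permutation stream: for every relabeling the summary
#' is the number of vertices whose (permutation) p-value falls below
#' `threshold`; the corrected map-level p compares the observed
#' suprathreshold count to this null distribution.
#'
#' @param perm a `perm_result` from [vertex_permutation()].
#' @param threshold vertex-level p threshold (default 0.05).
#' @return list with `corrected_p`, `observed_count`, `perm_counts`.
#' @export
mapwise_permutation <- function(perm, threshold = 0.05) {
  B <- perm$n_perm
  # leave-one-out rank-based p of each permuted map against the same null
  rk <- apply(perm$perm_stats, 2, rank, ties.method = "min")
  p_perm <- (1 + B - rk) / (1 + B)
  perm_counts <- rowSums(p_perm < threshold)
  observed_count <- sum(perm$p < threshold)
  corrected_p <- (1 + sum(perm_counts >= observed_count)) / (1 + B)
  list(corrected_p = corrected_p, observed_count = observed_count,
       perm_counts = perm_counts)
}

#' CDF-based FDR critical p-value
#'
#' Sorts the vertex p-values and returns the largest p(i) <= q i/m — the
#' highest non-origin crossing of the empirical CDF of p-values with the
#' line y = x/q — together with the CDF curve.  Returns `NA` when the CDF
#' never crosses the line (no evidence to reject at FDR q).
#'
#' @param p vector of uncorrected p-values.
#' @param q false discovery rate (default 0.05).
#' @return list with `critical_p` (or `NA`), `cdf` (data.frame with sorted
#'   `p` and empirical `cdf`).
#' @export
fdr_cdf <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value vector")
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= q * seq_len(m) / m)
  critical <- if (length(ok)) ps[max(ok)] else NA_real_
  list(critical_p = critical,
       cdf = data.frame(p = ps, cdf = seq_len(m) / m))
}

# Freedman-Lane permutation of the age-adjusted group statistic: the
# reduced model (intercept + age) is fitted once, its residual rows are
# permuted, the full-model age adjustment is re-estimated on each permuted
# data set, and the statistic is computed with the observed labels.  This
# keeps the permutation distribution valid when the covariate is
# correlated with the group (ages differ between groups), which a naive
# label permutation of once-adjusted data does not.
freedman_lane_perm <- function(values, cohort, n_perm, seed) {
  dm <- dim(values)
  if (length(dm) == 2) dm <- c(dm, 1)
  n <- dm[1]; V <- dm[2]; d <- dm[3]
  labels <- cohort$group
  a <- cohort$age
  Z <- cbind(1, a)
  X <- cbind(1, a, labels)
  A_age <- solve(crossprod(X), t(X))[2, ]   # row extracting the age slope
  cc <- a - mean(a)
  abar <- mean(a)
  g1 <- as.numeric(labels == 1)
  n1 <- sum(g1); n0 <- n - n1
  Ccc1 <- sum(cc * g1)
  Ccc2 <- sum(cc * cc)
  # Per-channel reduced-model (age-only) split Y = F + R and every
  # label-permutation-invariant moment.  With Y* the row-permuted
  # residuals plus the fit, the full-model slope, group sums and total
  # second moments of the adjusted Y* are all linear/bilinear in R, so
  # each permutation costs three 36-vector x residual-matrix products per
  # channel and vector arithmetic - no O(n V) reconstruction.
  G <- vector("list", d)    # 2 x V reduced-model coefficients
  Rch <- vector("list", d)
  colR <- vector("list", d) # invariant: column sums of residuals (= 0)
  t0 <- vector("list", d)   # invariant: total column sums of Y
  sF <- vector("list", d)   # A_age . F
  FS1 <- vector("list", d)  # group-1 column sums of F
  cF <- vector("list", d)   # cc . F
  ZtZ <- crossprod(Z)
  azF <- drop(A_age %*% Z)
  g1Z <- drop(crossprod(g1, Z))
  ccZ <- drop(crossprod(cc, Z))
  for (k in seq_len(d)) {
    Yk <- if (d == 1 && length(dim(values)) == 2) as.matrix(values)
          else values[, , k]
    G[[k]] <- solve(ZtZ, crossprod(Z, Yk))
    Fk <- Z %*% G[[k]]
    Rch[[k]] <- Yk - Fk
    colR[[k]] <- .colSums(Rch[[k]], n, V)
    t0[[k]] <- .colSums(Yk, n, V)
    sF[[k]] <- drop(azF %*% G[[k]])
    FS1[[k]] <- drop(g1Z %*% G[[k]])
    cF[[k]] <- drop(ccZ %*% G[[k]])
  }
  TF <- T0 <- rep(list(vector("list", d)), d)
  for (j in seq_len(d)) for (k in seq_len(j)) {
    T0[[j]][[k]] <- .colSums(Rch[[j]] * Rch[[k]], n, V)
    TF[[j]][[k]] <- ZtZ[1, 1] * G[[j]][1, ] * G[[k]][1, ] +
      ZtZ[1, 2] * (G[[j]][1, ] * G[[k]][2, ] + G[[j]][2, ] * G[[k]][1, ]) +
      ZtZ[2, 2] * G[[j]][2, ] * G[[k]][2, ]
  }
  stat_for <- function(idx) {
    bP <- numeric(n); bP[idx] <- A_age
    wP <- numeric(n); wP[idx] <- g1
    aP <- numeric(n); aP[idx] <- a
    s <- u <- ra <- cY <- m1 <- m0 <- delta <- vector("list", d)
    for (k in seq_len(d)) {
      s[[k]] <- drop(bP %*% Rch[[k]]) + sF[[k]]
      ra[[k]] <- drop(aP %*% Rch[[k]])
      u[[k]] <- drop(wP %*% Rch[[k]]) + FS1[[k]] - Ccc1 * s[[k]]
      m1[[k]] <- u[[k]] / n1
      m0[[k]] <- (t0[[k]] - u[[k]]) / n0
      delta[[k]] <- m1[[k]] - m0[[k]]
      cY[[k]] <- (ra[[k]] - abar * colR[[k]]) + cF[[k]]
    }
    cross <- function(j, k)
      colR[[j]] * G[[k]][1, ] + ra[[j]] * G[[k]][2, ]
    S <- rep(list(vector("list", d)), d)
    for (j in seq_len(d)) for (k in seq_len(j)) {
      Q <- T0[[j]][[k]] + cross(j, k) + cross(k, j) + TF[[j]][[k]] -
        s[[k]] * cY[[j]] - s[[j]] * cY[[k]] + Ccc2 * s[[j]] * s[[k]]
      Sjk <- (Q - n1 * m1[[j]] * m1[[k]] - n0 * m0[[j]] * m0[[k]]) /
        (n - 2)
      S[[j]][[k]] <- Sjk; S[[k]][[j]] <- Sjk
    }
    if (d == 1) {
      sp2 <- S[[1]][[1]]
      t2 <- delta[[1]]^2 / (sp2 * (1 / n1 + 1 / n0))
      t2[sp2 <= 0] <- 0
      return(t2)
    }
    x <- vec_spd_solve(S, delta, d)
    (n1 * n0 / (n1 + n0)) *
      Reduce(`+`, lapply(seq_len(d), function(k) delta[[k]] * x[[k]]))
  }
  obs <- stat_for(seq_len(n))
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
  })
  B <- nrow(perms)
  perm_stats <- matrix(0, B, length(obs))
  for (b in seq_len(B)) perm_stats[b, ] <- stat_for(perms[b, ])
  exceed <- colSums(perm_stats >= rep(obs, each = B))
  structure(list(stat = obs, p = (1 + exceed) / (1 + B),
                 perm_stats = perm_stats, n_perm = B),
            class = "perm_result")
}

#' Full inference for one morphometry statistic
#'
#' Age adjustment, vertex statistic (t^2 for scalar channels, Hotelling's
#' T^2 for vector channels), vertex-wise permutation p-values, map-wise
#' permutation correction and CDF-based FDR.  When the age adjustment is
#' active the permutation follows the Freedman-Lane scheme (reduced-model
#' residual rows are permuted and the adjustment refitted per
#' permutation), which keeps the null distribution valid although age is
#' correlated with group; without adjustment, plain label permutation is
#' used.
#'
#' @param values subjects x vertices matrix or subjects x vertices x
#'   channels array.
#' @param cohort a [cohort_table()].
#' @param name statistic name (for the report).
#' @param n_perm permutations (default 1000).
#' @param seed permutation seed.
#' @param adjust_age adjust for age first (default `TRUE`).
#' @param threshold vertex p threshold of the map-wise count (default 0.05).
#' @param q FDR level (default 0.05).
#' @return object of class `stat_maps`: per-vertex `stat` and `p`, plus
#'   `corrected_p`, `critical_p`, `n_below_threshold`, `cdf`, `name`.
#' @export
stat_maps <- function(values, cohort, name = "stat", n_perm = 1000,
                      seed = 1, adjust_age = TRUE, threshold = 0.05,
                      q = 0.05) {
  adjustable <- adjust_age && qr(cbind(1, cohort$age, cohort$group))$rank == 3
  if (adjust_age && !adjustable)
    warning("rank-deficient design (constant ages?); skipping adjustment")
  if (adjustable) {
    # Freedman-Lane: residuals of the reduced (age-only) model are
    # permuted and the adjustment is refitted per permutation
    perm <- freedman_lane_perm(values, cohort, n_perm = n_perm,
                               seed = seed)
  } else {
    fn <- prepared_stat_fn(values)
    perm <- vertex_permutation(fn, values, cohort$group, n_perm = n_perm,
                               seed = seed)
  }
  mw <- mapwise_permutation(perm, threshold = threshold)
  fdr <- fdr_cdf(perm$p, q = q)
  structure(list(name = name, stat = perm$stat, p = perm$p,
                 corrected_p = mw$corrected_p,
                 n_below_threshold = mw$observed_count,
                 critical_p = fdr$critical_p, cdf = fdr$cdf,
                 n_perm = perm$n_perm, threshold = threshold, q = q),
            class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf(
    "<stat_maps> %s: corrected p = %.4g, %d/%d vertices below %.2g, FDR critical p = %s\n",
    x$name, x$corrected_p, x$n_below_threshold, length(x$p), x$threshold,
    ifelse(is.na(x$critical_p), "none", format(x$critical_p, digits = 3))))
  invisible(x)
}
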