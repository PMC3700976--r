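# Synthetic two-group cohorts of putamen-like surfaces with a known,
# localized shape deficit implanted in group 1, per-subject smooth shape
# noise, and group-specific age distributions, so every downstream stage
# can be validated against ground truth.

#' Putamen-like base shape
#'
#' A bent superellipsoid with aspect ratio about 3 : 1.5 : 1 and a gentle
#' banana bend, triangulated as a closed genus-zero mesh by deforming an
#' icosphere.  Deterministic: the same resolution always yields the same
#' mesh.
#'
#' @param resolution icosphere subdivision level (>= 3).
#' @param semi_axes the three semi-axes in mm (default `c(12.5, 6, 4)`,
#'   a neonatal-putamen-like size).
#' @param bend total bend angle in radians across the long axis
#'   (default 0.4).
#' @param exponent superellipsoid exponent (2 = ellipsoid; default 2.5,
#'   slightly boxy).
#' @return closed `triangle_mesh`, with the unit-sphere source directions
#'   attached as attribute `sphere_dirs`.
#' @export
base_shape <- function(resolution = 3, semi_axes = c(12.5, 6, 4),
                       bend = 0.4, exponent = 2.5) {
  if (resolution < 3) stop("resolution must be >= 3 subdivision levels")
  s <- icosphere(resolution, 1)
  dirs <- s$vertices
  # superellipsoid radial scaling: map each unit direction to the surface
  # |x/a|^e + |y/b|^e + |z/c|^e = 1
  scaled <- sweep(dirs, 2, semi_axes, `*`)
  r <- (rowSums(abs(sweep(scaled, 2, semi_axes, `/`))^exponent))^(-1 / exponent)
  v <- scaled * r
  # banana bend about the y axis, angle proportional to x
  t <- v[, 1] / semi_axes[1] * (bend / 2)
  v2 <- cbind(cos(t) * v[, 1] - sin(t) * v[, 3],
              v[, 2],
              sin(t) * v[, 1] + cos(t) * v[, 3])
  mesh <- triangle_mesh(v2, s$faces)
  attr(mesh, "sphere_dirs") <- dirs
  mesh
}

#' Implant a localized inward deformation
#'
#' Vertices within a geodesic radius of the surface point nearest the given
#' direction are displaced inward along the vertex normal by
#' `delta * (distance to centroid) * taper`, where the taper is a cosine
#' falloff from 1 at the patch center to 0 at its rim.  This emulates local
#' atrophy of known extent; the returned indicator marks the affected patch.
#'
#' @param mesh a closed `triangle_mesh`.
#' @param center_direction unit direction from the centroid picking the
#'   patch center (default anterior/inferior, `c(1, 0, -1)/sqrt(2)`).
#' @param radius geodesic patch radius in mm (default 8).
#' @param delta fractional inward displacement at the patch center
#'   (>= 0; 0 returns the mesh unchanged).
#' @return list with `mesh` (deformed) and `indicator` (0/1 per vertex).
#' @export
implant_effect <- function(mesh, center_direction = c(1, 0, -1) / sqrt(2),
                           radius = 8, delta = 0.1) {
  if (delta < 0) stop("delta must be >= 0")
  n <- nrow(mesh$vertices)
  ctr <- colMeans(mesh$vertices)
  rel <- sweep(mesh$vertices, 2, ctr)
  dirs <- rel / row_norm(rel)
  seed_v <- which.max(dirs %*% (center_direction / sqrt(sum(center_direction^2))))
  g <- mesh_graph(mesh)
  gd <- as.vector(igraph::distances(g, v = seed_v))
  inside <- gd <= radius
  if (!any(inside)) stop("empty effect patch; increase radius")
  indicator <- as.integer(inside)
  if (delta == 0) return(list(mesh = mesh, indicator = indicator))
  taper <- ifelse(inside, 0.5 * (1 + cos(pi * gd / radius)), 0)
  vn <- vertex_normals(mesh)
  scale <- row_norm(rel)
  out <- mesh
  out$vertices <- mesh$vertices - vn * (delta * scale * taper)
  attr(out, "sphere_dirs") <- attr(mesh, "sphere_dirs")
  list(mesh = out, indicator = indicator)
}

# smooth per-subject random displacement field: white noise on the vertices
# low-passed by iterated neighborhood averaging (band-limited random field),
# scaled relative to the local centroid distance, applied along normals
smooth_noise_field <- function(mesh, amplitude, smooth_op, smoothing = 12) {
  n <- nrow(mesh$vertices)
  z <- stats::rnorm(n)
  for (k in seq_len(smoothing)) z <- as.numeric(smooth_op %*% z)
  z <- z / stats::sd(z)
  ctr <- colMeans(mesh$vertices)
  scale <- row_norm(sweep(mesh$vertices, 2, ctr))
  z * amplitude * scale
}

# row-normalized (I + adjacency) averaging operator for noise smoothing
smoothing_operator <- function(mesh) {
  et <- mesh_edge_table(mesh)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(et$edges[, 1], et$edges[, 2], seq_len(n)),
                            j = c(et$edges[, 2], et$edges[, 1], seq_len(n)),
                            x = 1, dims = c(n, n))
  Matrix::Diagonal(n, 1 / Matrix::rowSums(A)) %*% A
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the study conditions: 19 term controls (ages
#' 45.1 +/- 5.1 weeks) versus 17 preterm subjects (41.1 +/- 5.0 weeks),
#' with a localized anterior/inferior deficit of fractional depth `delta`
#' implanted in group 1.
#'
#' @param n_group0,n_group1 group sizes (defaults 19 and 17).
#' @param age_mean0,age_sd0,age_mean1,age_sd1 age distributions (weeks).
#' @param center_direction,radius effect patch placement (see
#'   [implant_effect()]).
#' @param delta effect magnitude (0 = null cohort).
#' @param noise_amplitude per-subject smooth shape noise, as a fraction of
#'   local scale (default 0.02).
#' @param age_slope optional linear age effect on overall scale per week
#'   (default 0).
#' @param resolution base-shape subdivision level (default 3).
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group0 = 19, n_group1 = 17,
                        age_mean0 = 45.1, age_sd0 = 5.1,
                        age_mean1 = 41.1, age_sd1 = 5.0,
                        center_direction = c(1, 0, -1) / sqrt(2),
                        radius = 8, delta = 0.1, noise_amplitude = 0.02,
                        age_slope = 0, resolution = 3, seed = 1) {
  stopifnot(n_group0 >= 2, n_group1 >= 2, delta >= 0, noise_amplitude >= 0)
  structure(list(n_group0 = n_group0, n_group1 = n_group1,
                 age_mean0 = age_mean0, age_sd0 = age_sd0,
                 age_mean1 = age_mean1, age_sd1 = age_sd1,
                 center_direction = center_direction, radius = radius,
                 delta = delta, noise_amplitude = noise_amplitude,
                 age_slope = age_slope, resolution = resolution,
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' Group 0 subjects are the base shape plus per-subject smooth random shape
#' noise (and an optional linear age scaling); group 1 subjects
#' additionally carry the implanted localized deficit.  Fully reproducible
#' from the [cohort_spec()] seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `subjects` (each: `id`,
#'   `group`, `age`, `mesh`), `cohort` (a [cohort_table()]), `indicator`
#'   (ground-truth 0/1 per base-mesh vertex) and `spec`.
#' @export
generate_cohort <- function(spec) {
  base <- base_shape(spec$resolution)
  eff <- implant_effect(base, spec$center_direction, spec$radius,
                        spec$delta)
  smooth_op <- smoothing_operator(base)
  n_total <- spec$n_group0 + spec$n_group1
  groups <- c(rep(0L, spec$n_group0), rep(1L, spec$n_group1))
  subjects <- with_seed(spec$seed, {
    ages <- ifelse(groups == 0,
                   stats::rnorm(n_total, spec$age_mean0, spec$age_sd0),
                   stats::rnorm(n_total, spec$age_mean1, spec$age_sd1))
    lapply(seq_len(n_total), function(i) {
      shape <- if (groups[i] == 1) eff$mesh else base
      noise <- smooth_noise_field(shape, spec$noise_amplitude, smooth_op)
      vn <- vertex_normals(shape)
      v <- shape$vertices + vn * noise
      if (spec$age_slope != 0)
        v <- v * (1 + spec$age_slope * (ages[i] - spec$age_mean0))
      list(id = sprintf("S%03d", i), group = groups[i], age = ages[i],
           mesh = triangle_mesh(v, shape$faces))
    })
  })
  cohort <- cohort_table(vapply(subjects, `[[`, "", "id"),
                         groups,
                         vapply(subjects, `[[`, 0, "age"))
  structure(list(subjects = subjects, cohort = cohort,
                 indicator = eff$indicator, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Per-subject PLY meshes, a manifest CSV (id, group, age) and the
#' ground-truth indicator CSV.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects)
    write_mesh(s$mesh, file.path(dir, paste0(s$id, ".ply")))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(id = cohort$cohort$id,
                              group = cohort$cohort$group,
                              age = cohort$cohort$age,
                              file = paste0(cohort$cohort$id, ".ply")),
                   manifest, row.names = FALSE)
  write_vertex_field_csv(cohort$indicator,
                         file.path(dir, "ground_truth_indicator.csv"))
  invisible(manifest)
}
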