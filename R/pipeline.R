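# End-to-end orchestration: meshes -> cylinder -> conformal grid ->
# registration to a template -> per-vertex morphometry -> permutation
# statistics -> report.  All randomness fans out from one global seed so a
# run is reproducible bit for bit.

#' Pipeline run configuration
#'
#' @param registration `"fluid"` or `"harmonic"`.
#' @param grid feature-grid resolution (n_u, n_v), default `c(32, 32)`.
#' @param reg_params a [registration_params()] list.
#' @param statistics subset of `c("detJ", "logS", "R", "combined")`.
#' @param n_perm permutations for both permutation tests (default 1000).
#' @param threshold vertex-level p threshold of the map-wise count.
#' @param q FDR level.
#' @param cut_k ring depth of the extremity cuts.
#' @param axis_side medial-axis side for the radial distance
#'   (`"subject"` or `"template"`).
#' @param lambda_weight weight the registration force by the template
#'   conformal factor (default `TRUE`).
#' @param template_id subject id to use as template; `NULL` picks one of
#'   the group-0 subjects at random (seeded).
#' @param adjust_age adjust measures for age at scan (default `TRUE`).
#' @param seed global seed.
#' @param output_dir optional directory for result tables and maps.
#' @return list of class `run_config`.
#' @export
run_config <- function(registration = c("fluid", "harmonic"),
                       grid = c(32, 32),
                       reg_params = registration_params(),
                       statistics = c("detJ", "logS", "R", "combined"),
                       n_perm = 1000, threshold = 0.05, q = 0.05,
                       cut_k = 2, axis_side = "subject",
                       lambda_weight = TRUE, template_id = NULL,
                       adjust_age = TRUE, seed = 1, output_dir = NULL) {
  registration <- match.arg(registration)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (!length(statistics)) stop("statistics list must be non-empty")
  structure(list(registration = registration, grid = grid,
                 reg_params = reg_params, statistics = statistics,
                 n_perm = n_perm, threshold = threshold, q = q,
                 cut_k = cut_k, axis_side = axis_side,
                 lambda_weight = lambda_weight, template_id = template_id,
                 adjust_age = adjust_age, seed = seed,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `id`, `group`, `age`, `file` (mesh path
#' relative to the manifest).
#'
#' @param manifest path to the manifest CSV.
#' @return a `synthetic_cohort`-shaped list (without ground truth).
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    list(id = as.character(tab$id[i]), group = tab$group[i],
         age = tab$age[i],
         mesh = read_mesh(file.path(dir, tab$file[i])))
  })
  structure(list(subjects = subjects,
                 cohort = cohort_table(tab$id, tab$group, tab$age),
                 indicator = NULL, spec = NULL),
            class = "synthetic_cohort")
}

# stage 1-2: cut and parameterize every subject
prepare_subjects <- function(cohort, config) {
  lapply(cohort$subjects, function(s) {
    out <- tryCatch({
      cyl <- cut_extremities(s$mesh, k = config$cut_k)
      param <- conformal_parameterize(cyl)
      grid <- sample_feature_grid(param, resolution = config$grid)
      list(param = param, grid = grid)
    }, error = function(e)
      stop("stage parameterize failed for subject ", s$id, ": ",
           conditionMessage(e)))
    c(s[c("id", "group", "age")], out)
  })
}

pick_template <- function(prep, cohort, config) {
  if (!is.null(config$template_id)) {
    k <- match(config$template_id, cohort$cohort$id)
    if (is.na(k)) stop("template id not in cohort: ", config$template_id)
    return(k)
  }
  controls <- which(cohort$cohort$group == 0)
  with_seed(config$seed, controls[sample.int(length(controls), 1)])
}

# stage 3-4: register all subjects to the template and induce
# correspondences; returns per-subject morphometry
correspond_all <- function(prep, template_idx, config) {
  templ <- prep[[template_idx]]
  n_u <- config$grid[1]; n_v <- config$grid[2]
  weight <- NULL
  if (config$lambda_weight && config$registration == "fluid") {
    lam <- sample_grid(templ$param, templ$param$lambda,
                       resolution = config$grid)$values[, , 1]
    weight <- lam / mean(lam)
  }
  lapply(seq_along(prep), function(i) {
    s <- prep[[i]]
    if (i == template_idx) {
      corr <- templ$param$mesh$vertices
      field <- NULL
    } else {
      field <- tryCatch(switch(config$registration,
        fluid = fluid_register(s$grid, templ$grid,
                               params = config$reg_params, weight = weight),
        harmonic = harmonic_register(s$param, templ$param,
                                     resolution = config$grid)),
        error = function(e)
          stop("stage register failed for subject ", s$id, ": ",
               conditionMessage(e)))
      corr <- induce_correspondence(s$param, templ$param, field)
    }
    morph <- vertex_morphometry(templ$param, corr,
                                axis_side = config$axis_side)
    list(id = s$id, corr = corr, morph = morph,
         reg_iterations = if (is.null(field)) 0L else field$iterations,
         reg_ic_rms = if (is.null(field)) 0 else field$ic_rms,
         reg_min_jac = if (is.null(field)) 1 else field$min_jac)
  })
}

# assemble subjects x vertices (x channels) arrays per statistic
morphometry_arrays <- function(corrs, n_vertices) {
  n <- length(corrs)
  detJ <- t(vapply(corrs, function(x) x$morph$detJ, numeric(n_vertices)))
  R <- t(vapply(corrs, function(x) x$morph$R, numeric(n_vertices)))
  logS <- array(0, c(n, n_vertices, 3))
  combined <- array(0, c(n, n_vertices, 4))
  for (i in seq_len(n)) {
    logS[i, , ] <- corrs[[i]]$morph$logS
    combined[i, , ] <- corrs[[i]]$morph$combined
  }
  list(detJ = detJ, logS = logS, R = R, combined = combined)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort (a `synthetic_cohort` from
#' [generate_cohort()] / [read_cohort()]): topology optimization, conformal
#' parameterization, registration to the template, morphometry, and the
#' permutation statistics for each requested measure.
#'
#' @param cohort cohort object or path to a manifest CSV.
#' @param config a [run_config()].
#' @return object of class `run_report`: per-statistic [stat_maps()] under
#'   `stats`, the template index/id, per-subject registration diagnostics,
#'   the template's ground-truth indicator (when the cohort carries one),
#'   and the config.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  prep <- prepare_subjects(cohort, config)
  template_idx <- pick_template(prep, cohort, config)
  corrs <- correspond_all(prep, template_idx, config)
  templ <- prep[[template_idx]]
  nV <- nrow(templ$param$mesh$vertices)
  arrays <- morphometry_arrays(corrs, nV)
  excluded <- unique(unlist(lapply(corrs, function(x) x$morph$excluded)))
  stats_out <- list()
  for (k in seq_along(config$statistics)) {
    nm <- config$statistics[k]
    vals <- arrays[[nm]]
    if (length(excluded)) {
      # drop flagged vertices from inference entirely
      if (length(dim(vals)) == 3) vals <- vals[, -excluded, , drop = FALSE]
      else vals <- vals[, -excluded, drop = FALSE]
    }
    stats_out[[nm]] <- stat_maps(vals, cohort$cohort, name = nm,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 1000 + k,
                                 adjust_age = config$adjust_age,
                                 threshold = config$threshold,
                                 q = config$q)
  }
  indicator_template <- NULL
  if (!is.null(cohort$indicator)) {
    idx <- templ$param$mesh$orig_index
    indicator_template <- cohort$indicator[idx]
    if (length(excluded)) indicator_template <- indicator_template[-excluded]
  }
  report <- structure(list(
    stats = stats_out,
    template_idx = template_idx,
    template_id = cohort$cohort$id[template_idx],
    n_vertices = nV, excluded = excluded,
    indicator_template = indicator_template,
    diagnostics = data.frame(
      id = vapply(corrs, `[[`, "", "id"),
      reg_iterations = vapply(corrs, `[[`, 0L, "reg_iterations"),
      reg_ic_rms = vapply(corrs, `[[`, 0, "reg_ic_rms"),
      reg_min_jac = vapply(corrs, `[[`, 0, "reg_min_jac")),
    config = config), class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, templ, config)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> template %s, %d vertices\n",
              x$template_id, x$n_vertices))
  for (s in x$stats)
    cat(sprintf("  %-9s corrected p = %-8.4g suprathreshold vertices = %d\n",
                s$name, s$corrected_p, s$n_below_threshold))
  invisible(x)
}

write_report <- function(report, templ, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- data.frame(
    statistic = vapply(report$stats, `[[`, "", "name"),
    corrected_p = vapply(report$stats, `[[`, 0, "corrected_p"),
    fdr_critical_p = vapply(report$stats, `[[`, 0, "critical_p"),
    n_below_threshold = vapply(report$stats, `[[`, 0L,
                               "n_below_threshold"))
  utils::write.csv(summ, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  pd <- list(u = templ$param$u, v = templ$param$v,
             lambda = templ$param$lambda, H = templ$param$H)
  keep <- setdiff(seq_len(report$n_vertices), report$excluded)
  for (s in report$stats) {
    p_full <- rep(NA_real_, report$n_vertices)
    p_full[keep] <- s$p
    pd[[paste0("p_", s$name)]] <- p_full
    utils::write.csv(s$cdf,
                     file.path(config$output_dir,
                               paste0("cdf_", s$name, ".csv")),
                     row.names = FALSE)
  }
  write_mesh(templ$param$mesh,
             file.path(config$output_dir, "template_maps.vtk"),
             format = "vtk", point_data = pd)
  invisible(NULL)
}

#' Dice overlap between a detection map and the ground-truth patch
#'
#' @param maps a [stat_maps()] object.
#' @param indicator 0/1 ground truth on the same vertices.
#' @param threshold detection threshold on the uncorrected p (default 0.05).
#' @return Dice coefficient in [0, 1].
#' @export
detection_dice <- function(maps, indicator, threshold = 0.05) {
  det <- maps$p < threshold
  tru <- indicator > 0
  denom <- sum(det) + sum(tru)
  if (denom == 0) return(0)
  2 * sum(det & tru) / denom
}

#' Run both registration methods on the same cohort and template
#'
#' Side-by-side corrected p-values (and detection Dice when the cohort has
#' ground truth) for the fluid and constrained-harmonic registrations,
#' sharing the template and the permutation seeds.
#'
#' @param cohort cohort object or manifest path.
#' @param config a [run_config()] (its `registration` field is ignored).
#' @return list of class `reg_comparison` with `fluid`, `harmonic`
#'   (run reports) and `table` (side-by-side data.frame).
#' @export
compare_registrations <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cf <- config; cf$registration <- "fluid"; cf$output_dir <- NULL
  ch <- config; ch$registration <- "harmonic"; ch$output_dir <- NULL
  rf <- run_pipeline(cohort, cf)
  rh <- run_pipeline(cohort, ch)
  tab <- data.frame(
    statistic = vapply(rf$stats, `[[`, "", "name"),
    corrected_p_fluid = vapply(rf$stats, `[[`, 0, "corrected_p"),
    corrected_p_harmonic = vapply(rh$stats, `[[`, 0, "corrected_p"),
    n_detected_fluid = vapply(rf$stats, `[[`, 0L, "n_below_threshold"),
    n_detected_harmonic = vapply(rh$stats, `[[`, 0L, "n_below_threshold"))
  if (!is.null(rf$indicator_template)) {
    tab$dice_fluid <- vapply(rf$stats, detection_dice,
                             0, indicator = rf$indicator_template)
    tab$dice_harmonic <- vapply(rh$stats, detection_dice,
                                0, indicator = rh$indicator_template)
  }
  structure(list(fluid = rf, harmonic = rh, table = tab),
            class = "reg_comparison")
}
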