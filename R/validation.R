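# Standardized validation studies: type-I-error calibration on null
# cohorts and effect recovery on the default deficit cohort.  Both the
# test suite and the acceptance script run these, so the designs live in
# one place.  Problem sizes (grid, iteration caps, permutations, repeats)
# are chosen so a full calibration fits in minutes on one core while
# keeping the binomial noise of the rejection-rate estimate well inside
# the tolerance band; the methods vignette discusses the choices.

#' Default analysis configuration of the validation studies
#'
#' A lighter setting than [run_config()]'s defaults: 16 x 16 feature grid
#' and a 20-iteration fluid cap, enough for the small deformations of the
#' synthetic cohorts.
#'
#' @param n_perm permutations per test.
#' @param seed global seed.
#' @return a [run_config()].
#' @export
validation_config <- function(n_perm = 250, seed = 1) {
  run_config(grid = c(16, 16), n_perm = n_perm, seed = seed,
             reg_params = registration_params(max_iter = 20, tol = 1e-4))
}

#' Type-I-error calibration on null synthetic cohorts
#'
#' Generates `n_repeats` independent null cohorts (delta = 0, the study's
#' group sizes and age distributions), runs the full pipeline on each, and
#' reports the fraction of repeats whose map-level corrected p is <= alpha
#' for every statistic.  Exchangeable null subjects make this an exact
#' check of the permutation machinery end to end.
#'
#' @param n_repeats number of null cohorts (default 200).
#' @param n_perm permutations per test (default 250).
#' @param alpha rejection level (default 0.05).
#' @param seed base seed; repeat r uses seed + r for the cohort and the
#'   analysis.
#' @param statistics statistics to track.
#' @param progress print a dot per repeat (default `FALSE`).
#' @return list with `rates` (named rejection rates), `rejections`
#'   (repeats x statistics logical matrix), `n_repeats`.
#' @export
calibration_study <- function(n_repeats = 200, n_perm = 250, alpha = 0.05,
                              seed = 1,
                              statistics = c("detJ", "logS", "R",
                                             "combined"),
                              progress = FALSE) {
  rej <- matrix(NA, n_repeats, length(statistics),
                dimnames = list(NULL, statistics))
  for (r in seq_len(n_repeats)) {
    co <- generate_cohort(cohort_spec(delta = 0, seed = seed + 7919L * r))
    cfg <- validation_config(n_perm = n_perm, seed = seed + r)
    cfg$statistics <- statistics
    rep <- run_pipeline(co, cfg)
    rej[r, ] <- vapply(rep$stats[statistics], `[[`, 0,
                       "corrected_p") <= alpha
    if (progress) cat(".", if (r %% 50 == 0) paste0(" ", r, "\n"))
  }
  list(rates = colMeans(rej), rejections = rej, n_repeats = n_repeats)
}

#' Effect recovery on the default deficit cohort
#'
#' Generates the default effect cohort (delta = 0.1, 19 term vs 17
#' preterm), runs the pipeline with `n_perm` permutations, and reports the
#' corrected p-values, suprathreshold vertex counts and the Dice overlap
#' of each detection map with the implanted ground-truth patch.
#'
#' @param n_perm permutations (default 1000).
#' @param seed global seed.
#' @param registration `"fluid"` (default) or `"harmonic"`.
#' @param delta effect size (default 0.1).
#' @return list with `report` (the [run_pipeline()] result), `dice`
#'   (named), `corrected_p` (named), `n_detected` (named).
#' @export
effect_study <- function(n_perm = 1000, seed = 1,
                         registration = "fluid", delta = 0.1) {
  co <- generate_cohort(cohort_spec(delta = delta, seed = seed + 104729L))
  cfg <- validation_config(n_perm = n_perm, seed = seed)
  cfg$registration <- registration
  rep <- run_pipeline(co, cfg)
  dice <- vapply(rep$stats, detection_dice, 0,
                 indicator = rep$indicator_template)
  list(report = rep,
       dice = dice,
       corrected_p = vapply(rep$stats, `[[`, 0, "corrected_p"),
       n_detected = vapply(rep$stats, `[[`, 0L, "n_below_threshold"))
}
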