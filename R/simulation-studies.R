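# Canned simulation studies: behavioral-consistency reproduction, FDR-control
# and planted-effect power replicates. These wrap the generators and fitting
# into the protocols used by the package's validation suite and by
# scripts/acceptance.R.

#' Behavioral consistency of model-based and model-free measures
#'
#' Simulates one cohort under the default study conditions (156 subjects,
#' 120 trials per task, preferences and softmax noise calibrated to the
#' target descriptives), fits the power-utility, hyperbolic-delay and
#' probability-discounting models per subject, applies the exclusion rules,
#' and computes the cross-subject consistency correlations: fitted log10
#' risk tolerance vs. proportion of risky choices, fitted log10 discount
#' rate vs. proportion of immediate choices, and fitted log10(alpha) vs.
#' log10(h) (the latter over subjects whose risk-model fits are estimable
#' and not pinned at a search bound), plus parameter-recovery summaries
#' against the generating truth.
#'
#' @param seed integer seed for the cohort.
#' @param n_subjects,n_trials cohort dimensions.
#' @return List: `r_risky_prop`, `r_delay_prop`, `r_alpha_h`,
#'   `r_recovery_alpha`, `bias_log10_k`, `n_included`, `mean_r2_risk`,
#'   `mean_r2_delay`.
#' @export
simulate_behavioral_consistency <- function(seed, n_subjects = 156,
                                            n_trials = 120) {
  coh <- generate_cohort_choices(cohort_spec(n_subjects = n_subjects,
                                             n_trials_per_task = n_trials,
                                             seed = seed))
  fits <- fit_cohort(coh$datasets, prob_hyperbolic = TRUE)
  inc <- fits$included
  ok_h <- inc & fits$estimable_risk & fits$estimable_h &
    !fits$out_of_bounds_risk & !fits$out_of_bounds_h
  list(
    r_risky_prop = stats::cor(log10(fits$alpha[inc]), fits$prop_risky[inc]),
    r_delay_prop = stats::cor(log10(fits$k[inc]), fits$prop_immediate[inc]),
    r_alpha_h = stats::cor(log10(fits$alpha[ok_h]), log10(fits$h[ok_h])),
    r_recovery_alpha = stats::cor(coh$truth$log10_alpha[inc],
                                  log10(fits$alpha[inc])),
    bias_log10_k = mean(log10(fits$k[inc]) - coh$truth$log10_k[inc]),
    n_included = sum(inc),
    mean_r2_risk = mean(fits$pseudo_r2_risk[inc]),
    mean_r2_delay = mean(fits$pseudo_r2_delay[inc]))
}

#' One null replicate of the TFCE + FDR inference
#'
#' Generates a smooth null metric field (no preference effect) for a cohort
#' with the default covariate structure, runs the full Freedman-Lane TFCE
#' permutation inference for log10(alpha), and reports the realized false
#' discovery proportion at the requested q (under the global null every
#' discovery is false).
#'
#' @param seed integer replicate seed.
#' @param mesh analysis mesh (default 642-vertex icosphere).
#' @param n_subjects cohort size.
#' @param n_permutations permutations per replicate.
#' @param q FDR level.
#' @param behav optional precomputed behavior/covariate table (reused
#'   across replicates for speed).
#' @return List: `fdp` (0 or 1), `n_discoveries`.
#' @export
fdr_null_replicate <- function(seed, mesh = build_icosphere(3, 80),
                               n_subjects = 156, n_permutations = 500,
                               q = 0.05, behav = NULL) {
  if (is.null(behav)) behav <- simulation_behavior(n_subjects, seed)
  eff <- effect_spec(effect_size_alpha = 0, effect_size_k = 0, seed = seed)
  Y <- generate_surface_metrics(mesh, behav, behav, eff)
  des <- design_matrix(behav, "log10_alpha", c("age", "sex", "iq"))
  inf <- permutation_inference(Y, des, mesh,
                               n_permutations = n_permutations,
                               seed = seed + 1L, q = q)
  n_disc <- sum(inf$sig_pos) + sum(inf$sig_neg)
  list(fdp = as.numeric(n_disc > 0), n_discoveries = n_disc)
}

#' One planted-conjunction power replicate
#'
#' Plants the default negative association of both preferences inside a
#' geodesic disc, runs the TFCE permutation inference for each preference,
#' forms the directional conjunction and compares it with the planted disc:
#' Dice overlap, whether the top conjunction cluster peaks inside the disc,
#' and the per-vertex sensitivity.
#'
#' @param seed integer replicate seed.
#' @param mesh analysis mesh.
#' @param n_subjects cohort size.
#' @param n_permutations permutations per analysis.
#' @param effect_size planted slope magnitude (applied negatively to both
#'   preferences), metric units per predictor SD.
#' @param radius_mm planted disc geodesic radius.
#' @param seed_vertex disc center.
#' @param smoothing_fwhm_mm analysis smoothing applied to the maps.
#' @return List: `dice`, `peak_inside`, `sensitivity`, `n_conjunction`.
#' @export
planted_conjunction_replicate <- function(seed,
                                          mesh = build_icosphere(3, 80),
                                          n_subjects = 156,
                                          n_permutations = 1000,
                                          effect_size = 0.55,
                                          radius_mm = 40,
                                          seed_vertex = 1L,
                                          smoothing_fwhm_mm = 20) {
  behav <- simulation_behavior(n_subjects, seed)
  eff <- effect_spec(seed_vertex = seed_vertex,
                     geodesic_radius_mm = radius_mm,
                     effect_size_alpha = -effect_size,
                     effect_size_k = -effect_size, seed = seed + 50L)
  Y <- generate_surface_metrics(mesh, behav, behav, eff)
  Y <- smooth_metric(mesh, Y, smoothing_fwhm_mm)
  des_a <- design_matrix(behav, "log10_alpha", c("age", "sex", "iq"))
  des_k <- design_matrix(behav, "log10_k", c("age", "sex", "iq"))
  inf_a <- permutation_inference(Y, des_a, mesh,
                                 n_permutations = n_permutations,
                                 seed = seed)
  inf_k <- permutation_inference(Y, des_k, mesh,
                                 n_permutations = n_permutations,
                                 seed = seed + 1L)
  conj <- conjunction(inf_a, inf_k, "negative", "negative")
  disc <- geodesic_disc(mesh, seed_vertex, radius_mm)
  cl <- cluster_report(conj, mesh)
  list(dice = 2 * sum(conj$mask & disc) / (sum(conj$mask) + sum(disc)),
       peak_inside = nrow(cl) > 0 && disc[cl$peak_vertex[1]],
       sensitivity = mean(conj$mask[disc]),
       n_conjunction = sum(conj$mask))
}

# True preferences + covariates without choice data: the inputs the surface
# stages consume in the simulation studies.
simulation_behavior <- function(n_subjects, seed) {
  prefs <- draw_preferences(cohort_spec(n_subjects = n_subjects,
                                        seed = seed))
  cov <- generate_covariates(n_subjects, seed = seed + 1L)
  data.frame(prefs, age = cov$age, sex = cov$sex, iq = cov$iq,
             tiv_cm3 = cov$tiv_cm3)
}
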