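# Value functions, softmax likelihood, MLE, exclusions, model-free measures.

test_that("subjective value functions match their closed forms", {
  # power utility
  expect_equal(subjective_value_risky(0.47, 84, 1), 39.48)
  expect_equal(subjective_value_risky(1.0, 20, 1), 20)
  expect_equal(subjective_value_risky(0.5, 100, 0.5), 5)
  # hyperbolic delay discounting
  expect_equal(subjective_value_delayed(40, 31, 1e-12), 40, tolerance = 1e-9)
  expect_equal(subjective_value_delayed(20, 0, 0.05), 20)
  expect_equal(subjective_value_delayed(40, 31, 1 / 31), 20)
  # hyperbolic probability discounting (odds against)
  expect_equal(subjective_value_prob_hyperbolic(1.0, 84, 2), 84)
  expect_equal(subjective_value_prob_hyperbolic(0.5, 40, 1), 20)
  expect_equal(subjective_value_prob_hyperbolic(0.25, 40, 1 / 3), 20)
})

test_that("value functions reject invalid parameters", {
  expect_error(subjective_value_risky(0.5, 50, 0), "positive")
  expect_error(subjective_value_risky(0.5, 50, -1), "positive")
  expect_error(subjective_value_delayed(40, 31, 0), "positive")
  expect_error(subjective_value_prob_hyperbolic(0.5, 40, -2), "positive")
  expect_error(subjective_value_prob_hyperbolic(0, 40, 1), "win_probability")
  expect_error(choice_probability(10, 20, -1), "nonnegative")
})

test_that("softmax choice probabilities behave and sum to one", {
  expect_equal(choice_probability(17.3, 17.3, 5), 0.5)
  expect_equal(choice_probability(123, -4, 0), 0.5)
  expect_equal(choice_probability(30, 20, 10), 1, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:50) {
    sv1 <- runif(1, -20, 20); sv2 <- runif(1, -20, 20)
    b <- runif(1, 0, 0.7)
    p1 <- choice_probability(sv1, sv2, b)
    p2 <- choice_probability(sv2, sv1, b)
    expect_gt(p1, 0); expect_lt(p1, 1)
    expect_equal(p1 + p2, 1, tolerance = 1e-12)
  }
})

test_that("negative log-likelihood equals n log 2 at beta = 0 and matches a direct oracle", {
  ds <- toy_risky_dataset(120, 0.8, 1, seed = 3)
  for (par in c(0.2, 0.8, 2.5))
    expect_equal(choice_nll(ds, par, 0), 120 * log(2))

  # near-deterministic single trial: SV 40 vs 20, accepted
  one <- choice_dataset("risky",
                        data.frame(win_probability = 0.5, win_amount = 80),
                        1)
  expect_lt(choice_nll(one, 1, 50), 1e-4)

  # 3-trial brute-force product oracle over an (alpha, beta) grid
  toy <- choice_dataset("risky",
                        data.frame(win_probability = c(0.3, 0.6, 0.9),
                                   win_amount = c(70, 35, 23)),
                        c(1, 0, 1))
  for (a in c(0.4, 0.9, 1.3)) {
    for (b in c(0.1, 1, 4)) {
      p1 <- 1 / (1 + exp(-b * (toy$trials$win_probability *
                                 toy$trials$win_amount^a - 20^a)))
      p1 <- pmin(pmax(p1, 1e-10), 1 - 1e-10)  # the documented clamping
      manual <- -log(p1[1] * (1 - p1[2]) * p1[3])
      expect_equal(choice_nll(toy, a, b), manual, tolerance = 1e-10)
    }
  }
})

test_that("the optimizer is at least as good as a dense grid search", {
  set.seed(42)
  for (rep in 1:20) {
    ds <- toy_risky_dataset(10, runif(1, 0.4, 1.2), runif(1, 0.2, 2),
                            seed = 1000 + rep)
    if (length(unique(ds$choices)) == 1) next
    est <- fit_preference(ds)
    grid_a <- exp(seq(log(0.01), log(3), length.out = 200))
    grid_b <- exp(seq(log(1e-3), log(100), length.out = 200))
    grid_best <- min(vapply(grid_a, function(a)
      min(vapply(grid_b, function(b) choice_nll(ds, a, b), numeric(1))),
      numeric(1)))
    expect_lte(-est$log_likelihood, grid_best + 1e-6)
  }
})

test_that("maximum likelihood recovers generating parameters at large n", {
  ds <- toy_risky_dataset(5000, 0.8, 0.5, seed = 7)
  est <- fit_preference(ds)
  expect_true(est$converged)
  expect_gt(est$parameter, 0.77)
  expect_lt(est$parameter, 0.83)

  dd <- toy_delay_dataset(5000, 0.02, 2, seed = 8)
  estd <- fit_preference(dd)
  expect_true(estd$converged)
  expect_lt(abs(estd$parameter - 0.02) / 0.02, 0.05)
})

test_that("fitting is scale-consistent: log10 bias small over replicates", {
  set.seed(10)
  biases <- vapply(1:100, function(r) {
    ds <- toy_risky_dataset(5000, 0.8, 0.5, seed = 20000 + r)
    log10(fit_preference(ds)$parameter) - log10(0.8)
  }, numeric(1))
  expect_lt(abs(mean(biases)), 0.02)
})

test_that("one-sided and degenerate datasets are flagged, not fitted", {
  design <- generate_trial_design("risky", 120, seed = 2)
  all_accept <- choice_dataset("risky", design, rep(1, 120))
  est <- fit_preference(all_accept)
  expect_true(est$one_sided)
  expect_true(is.na(est$parameter))

  # all-dominated design: winning less than the certain reference
  dominated <- choice_dataset("risky",
                              data.frame(win_probability = rep(0.5, 6),
                                         win_amount = rep(10, 6)),
                              c(0, 1, 0, 0, 1, 0))
  estd <- fit_preference(dominated)
  expect_false(estd$identifiable)
  expect_true(is.na(estd$parameter))
})

test_that("a chance-level responder is flagged not estimable", {
  design <- generate_trial_design("risky", 120, seed = 5)
  ds <- choice_dataset("risky", design, rep(c(0, 1), 60))
  set.seed(9)
  ds$choices <- rbinom(120, 1, 0.5)
  est <- fit_preference(ds)
  expect_false(est$estimable)
  # and an informative subject is estimable
  expect_true(fit_preference(toy_risky_dataset(120, 0.8, 1, seed = 2))$estimable)
})

test_that("model-free measures count the right option", {
  d <- generate_trial_design("risky", 120, seed = 1)
  expect_equal(model_free_measure(choice_dataset("risky", d,
                                                 rep(c(1, 0), 60))), 0.5)
  dd <- generate_trial_design("intertemporal", 120, seed = 1)
  expect_equal(model_free_measure(choice_dataset("intertemporal", dd,
                                                 rep(0, 120))), 1)
  d5 <- generate_trial_design("risky", 5, seed = 1)
  expect_equal(model_free_measure(choice_dataset("risky", d5,
                                                 c(1, 0, 1, 0, 0))), 0.4)
})

test_that("exclusion rules implement the study's screening bounds", {
  mk <- function(par, one_sided = FALSE)
    structure(list(parameter = par, one_sided = one_sided),
              class = "preference_estimate")
  expect_false(apply_exclusion_rules(mk(0.33), mk(0.01))$included)
  expect_match(paste(apply_exclusion_rules(mk(0.33), mk(0.01))$reasons,
                     collapse = " "), "alpha below")
  expect_true(apply_exclusion_rules(mk(0.80), mk(0.018))$included)
  expect_false(apply_exclusion_rules(mk(1.0), mk(NA, one_sided = TRUE))$included)
  # bounds are inclusive
  expect_true(apply_exclusion_rules(mk(0.34), mk(0.077))$included)
  expect_true(apply_exclusion_rules(mk(1.32), mk(0.0017))$included)
  expect_false(apply_exclusion_rules(mk(1.33), mk(0.018))$included)
  expect_error(apply_exclusion_rules(mk(0.8)), "both task")
})

test_that("choice CSV round-trips through read/write", {
  coh <- generate_cohort_choices(cohort_spec(n_subjects = 2,
                                             n_trials_per_task = 12,
                                             seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_choices(coh$datasets, path)
  back <- read_choices(path)
  expect_named(back, names(coh$datasets))
  for (sid in names(back)) {
    expect_equal(back[[sid]]$risky$choices, coh$datasets[[sid]]$risky$choices)
    expect_equal(back[[sid]]$risky$trials$win_probability,
                 coh$datasets[[sid]]$risky$trials$win_probability)
    expect_equal(back[[sid]]$intertemporal$trials$delay_days,
                 coh$datasets[[sid]]$intertemporal$trials$delay_days)
  }
})
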