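#' Cohort simulation specification
#'
#' Collects the population parameters for a simulated cohort: the bivariate
#' log-normal preference distribution (log10 alpha and log10 k), its
#' truncation to the study's inclusion bounds, trial counts, and the
#' goodness-of-fit targets that set the softmax noise level. Defaults match
#' the study sample this package models: log10(alpha) ~ N(-0.20, 0.17),
#' log10(k) ~ N(-1.74, 0.36), a weak-to-moderate negative correlation
#' between the two preferences, 120 trials per task, and mean McFadden
#' pseudo-R-squared 0.37 (risk) and 0.57 (delay).
#'
#' @param n_subjects number of subjects.
#' @param mean_log10_alpha,sd_log10_alpha log10 risk-tolerance distribution.
#' @param mean_log10_k,sd_log10_k log10 discount-rate distribution.
#' @param preference_correlation correlation between log10(alpha) and
#'   log10(k) in [-1, 1]; negative by default (risk-tolerant subjects tend
#'   to be more patient).
#' @param n_trials_per_task trials per task per subject.
#' @param target_pseudo_r2_risk,target_pseudo_r2_delay cohort-mean McFadden
#'   pseudo-R-squared targets used to calibrate the softmax noise.
#' @param sd_pseudo_r2_risk,sd_pseudo_r2_delay between-subject SD of the
#'   pseudo-R-squared targets (default 0.125, i.e. a standard error of 0.01
#'   at n = 156, the printed spread of fit quality); each subject's beta is
#'   calibrated to a fit-quality target drawn from this distribution.
#' @param alpha_bounds,k_bounds truncation bounds for the preference draws,
#'   mirroring the study's screened sample.
#' @param seed integer seed; every generator derived from the spec is
#'   deterministic given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 156,
                        mean_log10_alpha = -0.20, sd_log10_alpha = 0.17,
                        mean_log10_k = -1.74, sd_log10_k = 0.36,
                        preference_correlation = -0.3,
                        n_trials_per_task = 120,
                        target_pseudo_r2_risk = 0.37,
                        target_pseudo_r2_delay = 0.57,
                        sd_pseudo_r2_risk = 0.125,
                        sd_pseudo_r2_delay = 0.125,
                        alpha_bounds = c(0.34, 1.32),
                        k_bounds = c(0.0017, 0.077),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, sd_log10_alpha > 0, sd_log10_k > 0,
            abs(preference_correlation) <= 1, n_trials_per_task >= 1,
            target_pseudo_r2_risk > 0, target_pseudo_r2_risk < 1,
            target_pseudo_r2_delay > 0, target_pseudo_r2_delay < 1,
            sd_pseudo_r2_risk >= 0, sd_pseudo_r2_delay >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a trial design for one subject
#'
#' Risky task: a full cross of 8 win probabilities log-spaced over
#' [0.10, 0.99] with 15 expected values log-spaced over $10-$80 around the
#' $20 certain reference; the win amount is `A = EV / p`. The grid contains
#' both informative trials (indifference point inside the admissible
#' risk-tolerance range) and trials any subject decides the same way, as a
#' fixed non-adaptive design does. Intertemporal task: each trial pairs a
#' critical discount rate (the `k` at which a deterministic chooser is
#' indifferent; 15 values log-spaced over 5e-4-0.25, bracketing the
#' admissible range 0.0017-0.077) with an integer delay (8 values
#' log-spaced in the window keeping amounts between about $20.5 and $90);
#' the delayed amount is `A = ref * (1 + k* D)`, so subjective values
#' bracket the $20 immediate reference across the k-range. Trial order is
#' shuffled under the seed.
#'
#' @param task `"risky"` or `"intertemporal"`.
#' @param n_trials number of trials (default 120; other sizes rescale the
#'   grid to fit).
#' @param seed integer seed controlling the shuffle (and nothing else: the
#'   grid itself is deterministic).
#' @param reference_amount fixed-option dollars.
#' @return Data frame of trial parameters in shuffled order, suitable as the
#'   `trials` argument of [choice_dataset()].
#' @export
generate_trial_design <- function(task, n_trials = 120, seed = 1L,
                                  reference_amount = 20) {
  task <- match.arg(task, c("risky", "intertemporal"))
  stopifnot(n_trials >= 1)
  n_crit <- max(1L, ceiling(n_trials / 8))
  n_lev <- ceiling(n_trials / n_crit)
  if (task == "risky") {
    p_levels <- exp(seq(log(0.10), log(0.99), length.out = min(8L, n_trials)))
    ev_levels <- reference_amount / 2 *
      exp(seq(0, log(8), length.out = ceiling(n_trials / length(p_levels))))
    g <- expand.grid(p = p_levels, ev = ev_levels)
    rows <- list(data.frame(win_probability = g$p,
                            win_amount = g$ev / g$p))
  } else {
    crit <- exp(seq(log(5e-4), log(0.25), length.out = n_crit))
    rows <- lapply(crit, function(k_star) {
      # A = ref (1 + k* D) in [~20.5, 90] => k* D in [0.025, 3.5]
      d_lo <- max(1, 0.025 / k_star)
      d_hi <- min(180, 3.5 / k_star)
      D <- unique(round(exp(seq(log(d_lo), log(max(d_lo, d_hi)),
                                length.out = n_lev))))
      while (length(D) < n_lev) D <- sort(unique(c(D, max(D) + 1)))
      D <- D[seq_len(n_lev)]
      data.frame(delayed_amount = reference_amount * (1 + k_star * D),
                 delay_days = D)
    })
  }
  design <- do.call(rbind, rows)
  design <- design[seq_len(min(n_trials, nrow(design))), , drop = FALSE]
  ord <- sample_with_seed(seed, nrow(design))
  design <- design[ord, , drop = FALSE]
  rownames(design) <- NULL
  design
}

# Draw a permutation under a local RNG state, leaving the global state alone.
sample_with_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' Calibrate a shared softmax beta to a target mean pseudo-R-squared
#'
#' The expected McFadden pseudo-R-squared of the generating model is
#' `1 - mean(entropy) / log 2`, where the entropy of each trial's softmax
#' accept probability is averaged over trials and subjects. That expectation
#' is monotone increasing in beta, so the beta reproducing a target mean
#' fit quality is found by bisection on log(beta). No data are sampled:
#' calibration uses the closed-form expectation under the true parameters.
#'
#' @param designs list of per-subject trial designs (data frames).
#' @param parameters vector of per-subject true preference parameters
#'   (natural scale), aligned with `designs`.
#' @param task `"risky"` or `"intertemporal"`.
#' @param target target cohort-mean pseudo-R-squared in (0, 1).
#' @param reference_amount fixed-option dollars.
#' @param tol bisection tolerance on the achieved expectation.
#' @return The calibrated scalar beta.
#' @export
calibrate_beta <- function(designs, parameters, task, target,
                           reference_amount = 20, tol = 1e-4) {
  stopifnot(length(designs) == length(parameters), target > 0, target < 1)
  model <- if (task == "risky") "power" else "hyperbolic_delay"
  expected_r2 <- function(beta) {
    ent <- vapply(seq_along(designs), function(i) {
      ds <- choice_dataset(task, designs[[i]],
                           rep(0, nrow(designs[[i]])), reference_amount)
      p1 <- accept_probabilities(ds, parameters[i], beta, model)
      p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
      mean(-p1 * log(p1) - (1 - p1) * log1p(-p1))
    }, numeric(1))
    1 - mean(ent) / log(2)
  }
  lo <- log(1e-6); hi <- log(1e3)
  if (expected_r2(exp(hi)) < target)
    stop("pseudo-R2 target ", target, " is unattainable for this design")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_r2(exp(mid)) < target) lo <- mid else hi <- mid
    if (abs(expected_r2(exp(mid)) - target) < tol) break
  }
  exp((lo + hi) / 2)
}

# Per-subject bisection: the beta at which one subject's expected McFadden
# pseudo-R2 (closed form from the trial entropies) equals `target`.
calibrate_beta_subject <- function(dataset, parameter, model, target) {
  expected_r2 <- function(beta) {
    p1 <- accept_probabilities(dataset, parameter, beta, model)
    p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
    1 - mean(-p1 * log(p1) - (1 - p1) * log1p(-p1)) / log(2)
  }
  lo <- 1e-6; hi <- 1e3
  if (expected_r2(hi) < target) return(hi)
  for (i in 1:50) {
    mid <- sqrt(lo * hi)
    if (expected_r2(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Draw truncated bivariate preference parameters
#'
#' log10(alpha) and log10(k) are drawn jointly normal with the spec's means,
#' SDs and correlation, then draws outside the inclusion bounds are rejected
#' and redrawn (mirroring a screened sample).
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `log10_alpha`, `log10_k`, `alpha`, `k`.
#' @keywords internal
draw_preferences <- function(spec) {
  mu <- c(spec$mean_log10_alpha, spec$mean_log10_k)
  r <- spec$preference_correlation
  Sigma <- matrix(c(spec$sd_log10_alpha^2,
                    r * spec$sd_log10_alpha * spec$sd_log10_k,
                    r * spec$sd_log10_alpha * spec$sd_log10_k,
                    spec$sd_log10_k^2), 2, 2)
  lo <- c(log10(spec$alpha_bounds[1]), log10(spec$k_bounds[1]))
  hi <- c(log10(spec$alpha_bounds[2]), log10(spec$k_bounds[2]))
  out <- matrix(NA_real_, spec$n_subjects, 2)
  filled <- 0L
  while (filled < spec$n_subjects) {
    draw <- MASS::mvrnorm(2L * (spec$n_subjects - filled) + 10L, mu, Sigma)
    ok <- draw[, 1] >= lo[1] & draw[, 1] <= hi[1] &
          draw[, 2] >= lo[2] & draw[, 2] <= hi[2]
    draw <- draw[ok, , drop = FALSE]
    take <- min(nrow(draw), spec$n_subjects - filled)
    if (take > 0) {
      out[filled + seq_len(take), ] <- draw[seq_len(take), , drop = FALSE]
      filled <- filled + take
    }
  }
  data.frame(log10_alpha = out[, 1], log10_k = out[, 2],
             alpha = 10^out[, 1], k = 10^out[, 2])
}

#' Generate a cohort of choice datasets
#'
#' Draws true preferences from the truncated bivariate distribution,
#' generates each subject's shuffled trial designs, draws each subject a
#' fit-quality target from Normal(mean, SD) of the spec's pseudo-R-squared
#' distribution (truncated to [0.02, 0.95]), calibrates that subject's
#' softmax beta by bisection so the expected McFadden pseudo-R-squared of
#' the generating model equals the target (see the closed form in
#' [calibrate_beta()]), and samples binary choices from the softmax model.
#' The calibration reproduces both the mean and the between-subject spread
#' of fit quality. Fully reproducible given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List with `datasets` (named list per subject of `risky` /
#'   `intertemporal` [choice_dataset()]s), `truth` (data frame of true
#'   parameters per subject, including the per-subject `beta_risk` /
#'   `beta_delay` and fit-quality targets), and `spec`.
#' @export
generate_cohort_choices <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_subjects
  truth <- draw_preferences(spec)
  truth$subject_id <- sprintf("sub-%03d", seq_len(n))

  design_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  rtrunc_r2 <- function(n, mean, sd)
    pmin(pmax(stats::rnorm(n, mean, sd), 0.02), 0.95)
  truth$target_r2_risk <- rtrunc_r2(n, spec$target_pseudo_r2_risk,
                                    spec$sd_pseudo_r2_risk)
  truth$target_r2_delay <- rtrunc_r2(n, spec$target_pseudo_r2_delay,
                                     spec$sd_pseudo_r2_delay)
  truth$beta_risk <- NA_real_
  truth$beta_delay <- NA_real_

  datasets <- vector("list", n)
  for (i in seq_len(n)) {
    des_r <- generate_trial_design("risky", spec$n_trials_per_task,
                                   design_seeds[i])
    dr <- choice_dataset("risky", des_r, rep(0, nrow(des_r)))
    br <- calibrate_beta_subject(dr, truth$alpha[i], "power",
                                 truth$target_r2_risk[i])
    p1r <- accept_probabilities(dr, truth$alpha[i], br, "power")
    dr$choices <- as.numeric(stats::runif(length(p1r)) < p1r)

    des_d <- generate_trial_design("intertemporal", spec$n_trials_per_task,
                                   design_seeds[n + i])
    dd <- choice_dataset("intertemporal", des_d, rep(0, nrow(des_d)))
    bd <- calibrate_beta_subject(dd, truth$k[i], "hyperbolic_delay",
                                 truth$target_r2_delay[i])
    p1d <- accept_probabilities(dd, truth$k[i], bd, "hyperbolic_delay")
    dd$choices <- as.numeric(stats::runif(length(p1d)) < p1d)

    truth$beta_risk[i] <- br
    truth$beta_delay[i] <- bd
    datasets[[i]] <- list(risky = dr, intertemporal = dd)
  }
  names(datasets) <- truth$subject_id

  list(datasets = datasets, truth = truth, spec = spec)
}

#' Generate a synthetic covariate table
#'
#' Age ~ Normal(25, 6) truncated at 18 years; IQ ~ Normal(111, 7) truncated
#' at 90 (the study's screening floor); sex ~ Bernoulli(90/156) male; total
#' intracranial volume ~ Normal(1450, 130) cm^3, a plausible adult scale.
#'
#' @param n_subjects number of rows.
#' @param seed integer seed.
#' @return Data frame: `subject_id`, `age`, `sex` (0 female / 1 male),
#'   `iq`, `tiv_cm3`.
#' @export
generate_covariates <- function(n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rtnorm <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n_subjects)),
    age = rtnorm(n_subjects, 25, 6, 18),
    sex = stats::rbinom(n_subjects, 1, 90 / 156),
    iq = rtnorm(n_subjects, 111, 7, 90),
    tiv_cm3 = stats::rnorm(n_subjects, 1450, 130),
    stringsAsFactors = FALSE)
}
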