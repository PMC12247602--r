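#' Subjective value of a risky prospect under power utility
#'
#' `SV = p * A^alpha`, where `p` is the probability of winning amount `A` and
#' `alpha` is the risk tolerance exponent. `alpha = 1` is risk neutrality
#' (expected value); `alpha < 1` is risk aversion.
#'
#' @param win_probability probability of winning, in (0, 1]. Vectorized.
#' @param win_amount amount won, in dollars (> 0). Vectorized.
#' @param alpha risk tolerance exponent (> 0), scalar.
#' @return Numeric vector of subjective values (dollar-utility units).
#' @examples
#' subjective_value_risky(0.47, 84, 1)   # expected value, 39.48
#' @export
subjective_value_risky <- function(win_probability, win_amount, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  win_probability * win_amount^alpha
}

#' Subjective value of a delayed reward under hyperbolic discounting
#'
#' `SV = A / (1 + k * D)`, where `A` is the delayed amount, `D` the delay in
#' days and `k` the discount rate. An immediate reward (`D = 0`) keeps its
#' face value. Higher `k` means steeper devaluation of delayed rewards.
#'
#' @param delayed_amount amount in dollars (> 0). Vectorized.
#' @param delay_days delay in days (>= 0). Vectorized.
#' @param k discount rate per day (> 0), scalar.
#' @return Numeric vector of subjective values.
#' @examples
#' subjective_value_delayed(40, 31, 1 / 31)  # indifferent with $20 now
#' @export
subjective_value_delayed <- function(delayed_amount, delay_days, k) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("k must be a single positive number")
  delayed_amount / (1 + k * delay_days)
}

#' Subjective value of a risky prospect under hyperbolic probability discounting
#'
#' `SV = A / (1 + h * theta)` with odds-against `theta = (1 - p) / p`: the
#' risky analogue of hyperbolic delay discounting, where the odds against
#' winning play the role of the delay. A sure thing (`p = 1`) keeps its face
#' value; higher `h` means stronger devaluation of uncertain rewards (more
#' risk aversion), so `h` moves opposite to the power-utility `alpha`.
#'
#' @inheritParams subjective_value_risky
#' @param h probability discount rate (> 0), scalar.
#' @return Numeric vector of subjective values.
#' @export
subjective_value_prob_hyperbolic <- function(win_probability, win_amount, h) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0)
    stop("h must be a single positive number")
  if (any(win_probability <= 0))
    stop("win_probability must be > 0 (odds against are undefined at p = 0)")
  theta <- (1 - win_probability) / win_probability
  win_amount / (1 + h * theta)
}

#' Softmax (logistic) choice probability
#'
#' `P(accept) = 1 / (1 + exp(-beta * (SV_accept - SV_reference)))`. `beta`
#' scales choice determinism: `beta = 0` is random choice (P = 0.5),
#' `beta -> Inf` approaches deterministic value maximization. Computed via
#' [stats::plogis()] so it saturates smoothly without overflow.
#'
#' @param sv_accept subjective value of the variable (risky/delayed) option.
#' @param sv_reference subjective value of the fixed option.
#' @param beta inverse-temperature scaling factor (>= 0).
#' @return Probability of accepting the variable option, in (0, 1)
#'   (vectorized; exactly 0/1 only in the saturated limit).
#' @export
choice_probability <- function(sv_accept, sv_reference, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0)
    stop("beta must be a single nonnegative number")
  stats::plogis(beta * (sv_accept - sv_reference))
}

# Per-trial accept probabilities for a dataset under a given model.
# model: "power" | "hyperbolic_delay" | "hyperbolic_prob".
accept_probabilities <- function(dataset, parameter, beta, model) {
  ref <- dataset$reference_amount
  tr <- dataset$trials
  if (model == "power") {
    sv1 <- subjective_value_risky(tr$win_probability, tr$win_amount, parameter)
    sv2 <- ref^parameter  # certain option passes through the same utility
  } else if (model == "hyperbolic_delay") {
    sv1 <- subjective_value_delayed(tr$delayed_amount, tr$delay_days, parameter)
    sv2 <- ref  # immediate, D = 0
  } else if (model == "hyperbolic_prob") {
    sv1 <- subjective_value_prob_hyperbolic(tr$win_probability, tr$win_amount,
                                            parameter)
    sv2 <- ref  # certain, odds against = 0
  } else stop("unknown model: ", model)
  choice_probability(sv1, sv2, beta)
}

default_model_for <- function(dataset) {
  if (dataset$task == "risky") "power" else "hyperbolic_delay"
}

#' Negative log-likelihood of a choice dataset under the softmax model
#'
#' Evaluates `-sum_t [c_t log P1_t + (1 - c_t) log(1 - P1_t)]` where `P1_t`
#' is the softmax probability of accepting the variable option on trial `t`.
#' Probabilities are clamped to `[1e-10, 1 - 1e-10]` so the log never hits
#' zero. At `beta = 0` the value is exactly `n * log(2)` (the chance model).
#'
#' @param dataset a [choice_dataset()].
#' @param parameter preference parameter (`alpha`, `k` or `h` depending on
#'   `model`), > 0.
#' @param beta softmax scaling factor, >= 0.
#' @param model one of `"power"`, `"hyperbolic_delay"`, `"hyperbolic_prob"`;
#'   default chosen from the dataset's task (power for risky, hyperbolic for
#'   intertemporal).
#' @return Scalar negative log-likelihood in nats (>= 0).
#' @export
choice_nll <- function(dataset, parameter, beta, model = NULL) {
  if (is.null(model)) model <- default_model_for(dataset)
  if (length(dataset$choices) == 0) stop("dataset has no trials")
  p1 <- accept_probabilities(dataset, parameter, beta, model)
  p1 <- pmin(pmax(p1, 1e-10), 1 - 1e-10)
  c_t <- dataset$choices
  -sum(c_t * log(p1) + (1 - c_t) * log1p(-p1))
}

#' McFadden pseudo-R-squared
#'
#' `1 - NLL_model / (n * log 2)`: the likelihood of the fitted softmax model
#' relative to the coin-flip chance model. 0 means no better than chance,
#' 1 a perfect fit; can be negative for models worse than chance.
#'
#' @param nll model negative log-likelihood in nats.
#' @param n_trials number of binary choices.
#' @return Scalar pseudo-R-squared.
#' @export
mcfadden_r2 <- function(nll, n_trials) 1 - nll / (n_trials * log(2))

# Search bounds per model: parameter, then beta.
model_bounds <- function(model) {
  param <- switch(model,
    power = c(0.01, 3),
    hyperbolic_delay = c(1e-5, 2),
    hyperbolic_prob = c(1e-4, 1e3),
    stop("unknown model: ", model))
  list(parameter = param, beta = c(0, 100))
}

# A design is unidentifiable if, across the whole admissible parameter range,
# no trial ever flips preference: the deterministic chooser behaves
# identically at both parameter bounds and on every trial.
design_identifiable <- function(dataset, model) {
  b <- model_bounds(model)$parameter
  ref <- dataset$reference_amount
  sv_ref <- function(par) if (model == "power") ref^par else ref
  sgn <- function(par) {
    p1 <- accept_probabilities(dataset, par, beta = 1, model = model)
    p1 > 0.5
  }
  prefs <- c(sgn(b[1]), sgn(b[2]))
  !(all(prefs) || all(!prefs))
}

#' Fit a preference parameter by maximum likelihood
#'
#' Maximizes the softmax choice likelihood over (parameter, beta) with
#' bounded L-BFGS-B from multiple starting points (parameter starts
#' log-spaced across its bounds, beta starts spanning 1e-3 to 10; the five
#' most promising start pairs by initial likelihood are polished). Bounds:
#' alpha in [0.01, 3], k in [1e-5, 2], h in [1e-4, 1e3], beta in [0, 100].
#'
#' Degenerate data are flagged rather than fitted: `one_sided = TRUE` when
#' every choice is identical (the parameter is unidentified), and
#' `identifiable = FALSE` when the design itself never flips preference over
#' the admissible parameter range.
#'
#' @param dataset a [choice_dataset()].
#' @param model see [choice_nll()]; defaults by task.
#' @return An object of class `preference_estimate`: list with `model`,
#'   `parameter`, `beta`, `log_likelihood`, `pseudo_r2` (McFadden, vs. the
#'   chance model), `n_trials`, `one_sided`, `identifiable`, `out_of_bounds`
#'   (estimate pinned at a search bound), `estimable` (likelihood-ratio test
#'   of the fitted model against the coin-flip chance model significant at
#'   p < .05 on 2 df; when it is not, the likelihood is essentially flat and
#'   the point estimate carries no information), `converged`.
#' @export
fit_preference <- function(dataset, model = NULL) {
  if (is.null(model)) model <- default_model_for(dataset)
  n <- length(dataset$choices)
  if (n == 0) stop("dataset has no trials")

  est <- list(model = model, parameter = NA_real_, beta = NA_real_,
              log_likelihood = NA_real_, pseudo_r2 = NA_real_,
              n_trials = n, one_sided = FALSE, identifiable = TRUE,
              out_of_bounds = FALSE, estimable = FALSE, converged = FALSE)
  class(est) <- "preference_estimate"

  if (length(unique(dataset$choices)) == 1L) {
    est$one_sided <- TRUE
    return(est)
  }
  if (!design_identifiable(dataset, model)) {
    est$identifiable <- FALSE
    return(est)
  }

  b <- model_bounds(model)
  lower <- c(b$parameter[1], b$beta[1])
  upper <- c(b$parameter[2], b$beta[2])
  par_starts <- exp(seq(log(b$parameter[1] * 1.5), log(b$parameter[2] / 1.5),
                        length.out = 5))
  beta_starts <- c(1e-3, 0.1, 1, 10)
  starts <- expand.grid(parameter = par_starts, beta = beta_starts)

  nll_fun <- function(par) choice_nll(dataset, par[1], par[2], model)

  start_nll <- apply(starts, 1, nll_fun)
  keep <- order(start_nll)[seq_len(min(5L, nrow(starts)))]

  best <- NULL
  for (i in keep) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), nll_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(parscale = c(diff(b$parameter) / 10, 1),
                                  maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(est)

  est$parameter <- best$par[1]
  est$beta <- best$par[2]
  est$log_likelihood <- -best$value
  est$pseudo_r2 <- mcfadden_r2(best$value, n)
  tol <- 1e-6
  est$out_of_bounds <-
    best$par[1] <= lower[1] * (1 + tol) + tol ||
    best$par[1] >= upper[1] * (1 - tol)
  # LR of the fitted model against chance (2 fitted parameters)
  est$estimable <- 2 * (n * log(2) - best$value) >= stats::qchisq(0.95, 2)
  est$converged <- best$convergence == 0
  est
}

#' @method print preference_estimate
#' @export
print.preference_estimate <- function(x, ...) {
  if (x$one_sided) {
    cat("<preference_estimate> one-sided choices; parameter unidentified\n")
  } else if (!x$identifiable) {
    cat("<preference_estimate> non-identifiable design; not fitted\n")
  } else {
    cat(sprintf(
      "<preference_estimate> %s: parameter = %.4g, beta = %.4g, pseudo-R2 = %.3f%s\n",
      x$model, x$parameter, x$beta, x$pseudo_r2,
      if (x$converged) "" else " (NOT converged)"))
  }
  invisible(x)
}

#' Model-free choice measure
#'
#' For the risky task, the proportion of trials on which the risky option was
#' accepted; for the intertemporal task, the proportion of trials on which
#' the immediate (fixed) option was taken, i.e. the delayed option rejected.
#'
#' @param dataset a [choice_dataset()].
#' @return A single proportion in [0, 1].
#' @export
model_free_measure <- function(dataset) {
  if (length(dataset$choices) == 0) stop("dataset has no trials")
  if (dataset$task == "risky") mean(dataset$choices) else
    mean(1 - dataset$choices)
}

#' Apply the study's subject exclusion rules
#'
#' A subject is excluded if either task produced one-sided choices, or the
#' fitted risk tolerance falls outside [0.34, 1.32], or the fitted discount
#' rate falls outside [0.0017, 0.077] (screens against ceiling/floor
#' effects). The bounds are inclusive: exclusion is defined by strict
#' inequalities, so a subject sitting exactly on a bound is retained.
#'
#' @param risk a `preference_estimate` from the risky task (power utility),
#'   or a data frame with columns `alpha`, `k`, `one_sided_risk`,
#'   `one_sided_delay` for the vectorized form.
#' @param delay a `preference_estimate` from the intertemporal task; ignored
#'   in the data-frame form.
#' @param alpha_bounds,k_bounds inclusive inclusion intervals.
#' @return For a pair of estimates, a list with `included` (logical) and
#'   `reasons` (character vector, empty when included). For a data frame,
#'   the same data frame with `included` and `reasons` columns appended.
#' @export
apply_exclusion_rules <- function(risk, delay = NULL,
                                  alpha_bounds = c(0.34, 1.32),
                                  k_bounds = c(0.0017, 0.077)) {
  if (is.data.frame(risk)) {
    df <- risk
    needed <- c("alpha", "k", "one_sided_risk", "one_sided_delay")
    if (!all(needed %in% names(df)))
      stop("data frame must have columns: ", paste(needed, collapse = ", "))
    res <- lapply(seq_len(nrow(df)), function(i) {
      exclusion_reasons(df$alpha[i], df$k[i], df$one_sided_risk[i],
                        df$one_sided_delay[i], alpha_bounds, k_bounds)
    })
    df$included <- !vapply(res, function(r) length(r) > 0, logical(1))
    df$reasons <- vapply(res, paste, character(1), collapse = "; ")
    return(df)
  }
  if (is.null(delay)) stop("both task estimates are required")
  reasons <- exclusion_reasons(risk$parameter, delay$parameter,
                               isTRUE(risk$one_sided), isTRUE(delay$one_sided),
                               alpha_bounds, k_bounds)
  list(included = length(reasons) == 0, reasons = reasons)
}

exclusion_reasons <- function(alpha, k, one_sided_risk, one_sided_delay,
                              alpha_bounds, k_bounds) {
  reasons <- character(0)
  if (isTRUE(one_sided_risk))
    reasons <- c(reasons, "one-sided risky choices")
  if (isTRUE(one_sided_delay))
    reasons <- c(reasons, "one-sided intertemporal choices")
  if (!isTRUE(one_sided_risk)) {
    if (is.na(alpha)) reasons <- c(reasons, "missing alpha estimate")
    else if (alpha < alpha_bounds[1]) reasons <- c(reasons, "alpha below bound")
    else if (alpha > alpha_bounds[2]) reasons <- c(reasons, "alpha above bound")
  }
  if (!isTRUE(one_sided_delay)) {
    if (is.na(k)) reasons <- c(reasons, "missing k estimate")
    else if (k < k_bounds[1]) reasons <- c(reasons, "k below bound")
    else if (k > k_bounds[2]) reasons <- c(reasons, "k above bound")
  }
  reasons
}

#' Fit both tasks for every subject of a cohort
#'
#' Runs [fit_preference()] on each subject's risky and intertemporal
#' datasets and tabulates estimates, fit quality, model-free measures and
#' exclusion flags.
#'
#' @param datasets named list (subject) of named lists with elements
#'   `risky` and `intertemporal`, each a [choice_dataset()] (the shape
#'   returned by [read_choices()] and [generate_cohort_choices()]).
#' @param prob_hyperbolic also fit the hyperbolic probability-discounting
#'   model to the risky data (adds columns `h`, `beta_h`, `pseudo_r2_h`).
#' @return Data frame, one row per subject: `subject_id`, `alpha`,
#'   `beta_risk`, `pseudo_r2_risk`, `prop_risky`, `k`, `beta_delay`,
#'   `pseudo_r2_delay`, `prop_immediate`, one-sided flags, and `included` /
#'   `reasons` from [apply_exclusion_rules()].
#' @export
fit_cohort <- function(datasets, prob_hyperbolic = FALSE) {
  rows <- lapply(names(datasets), function(sid) {
    dr <- datasets[[sid]]$risky
    dd <- datasets[[sid]]$intertemporal
    if (is.null(dr) || is.null(dd))
      stop("subject ", sid, " is missing a task dataset")
    er <- fit_preference(dr)
    ed <- fit_preference(dd)
    row <- data.frame(
      subject_id = sid,
      alpha = er$parameter, beta_risk = er$beta,
      pseudo_r2_risk = er$pseudo_r2,
      prop_risky = model_free_measure(dr),
      one_sided_risk = er$one_sided,
      k = ed$parameter, beta_delay = ed$beta,
      pseudo_r2_delay = ed$pseudo_r2,
      prop_immediate = model_free_measure(dd),
      one_sided_delay = ed$one_sided,
      out_of_bounds_risk = er$out_of_bounds,
      out_of_bounds_delay = ed$out_of_bounds,
      estimable_risk = er$estimable,
      estimable_delay = ed$estimable,
      stringsAsFactors = FALSE)
    if (prob_hyperbolic) {
      eh <- fit_preference(dr, model = "hyperbolic_prob")
      row$h <- eh$parameter
      row$beta_h <- eh$beta
      row$pseudo_r2_h <- eh$pseudo_r2
      row$out_of_bounds_h <- eh$out_of_bounds
      row$estimable_h <- eh$estimable
    }
    row
  })
  df <- do.call(rbind, rows)
  apply_exclusion_rules(df)
}
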