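# Shared fixtures and independent oracles used across the suite.

# Meshes reused by several files (built once per test run).
ico2 <- build_icosphere(2, 80)    # 162 vertices
ico3 <- build_icosphere(3, 80)    # 642 vertices

# Simulate one subject's risky dataset at known (alpha, beta).
toy_risky_dataset <- function(n_trials, alpha, beta, seed) {
  set.seed(seed)
  design <- generate_trial_design("risky", n_trials, seed)
  ds <- choice_dataset("risky", design, rep(0, n_trials))
  p1 <- choice_probability(
    subjective_value_risky(design$win_probability, design$win_amount, alpha),
    20^alpha, beta)
  ds$choices <- as.numeric(stats::runif(n_trials) < p1)
  ds
}

toy_delay_dataset <- function(n_trials, k, beta, seed) {
  set.seed(seed)
  design <- generate_trial_design("intertemporal", n_trials, seed)
  ds <- choice_dataset("intertemporal", design, rep(0, n_trials))
  p1 <- choice_probability(
    subjective_value_delayed(design$delayed_amount, design$delay_days, k),
    20, beta)
  ds$choices <- as.numeric(stats::runif(n_trials) < p1)
  ds
}

# Brute-force TFCE: explicit component relabeling at every threshold step.
# Kept deliberately naive and independent of the compiled implementation.
tfce_oracle <- function(tvals, mesh, E = 0.5, H = 2, n_steps = 100) {
  out <- numeric(length(tvals))
  mx <- max(tvals)
  if (mx <= 0) return(out)
  dh <- mx / n_steps
  for (s in seq_len(floor(mx / dh + 1e-9))) {
    h <- s * dh
    labels <- oracle_components(mesh, tvals >= h)
    for (cl in unique(labels[labels > 0])) {
      idx <- which(labels == cl)
      out[idx] <- out[idx] + length(idx)^E * h^H * dh
    }
  }
  out
}

# Flood-fill component labeling written without igraph.
oracle_components <- function(mesh, mask) {
  nv <- length(mask)
  labels <- integer(nv)
  nxt <- 0L
  for (v in which(mask)) {
    if (labels[v] > 0) next
    nxt <- nxt + 1L
    queue <- v
    labels[v] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- mesh$adjacency[[cur]]
      nb <- nb[mask[nb] & labels[nb] == 0]
      labels[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  labels
}

# O(V^2) Dijkstra, independent of igraph, for fixture-scale meshes.
oracle_dijkstra <- function(mesh, source) {
  nv <- nrow(mesh$vertices)
  wt <- matrix(Inf, nv, nv)
  for (e in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges[e, 1]; b <- mesh$edges[e, 2]
    wt[a, b] <- wt[b, a] <- mesh$edge_lengths[e]
  }
  dist <- rep(Inf, nv)
  dist[source] <- 0
  visited <- rep(FALSE, nv)
  for (i in seq_len(nv)) {
    u <- which.min(ifelse(visited, Inf, dist))
    if (!is.finite(dist[u])) break
    visited[u] <- TRUE
    relax <- dist[u] + wt[u, ]
    dist <- pmin(dist, relax)
  }
  dist
}

# Tiny cohort of covariates + true preferences without choice data, for
# surface-level tests.
toy_behavior <- function(n, seed) {
  cov <- generate_covariates(n, seed = seed)
  prefs <- prefmorph:::draw_preferences(cohort_spec(n_subjects = n,
                                                    seed = seed))
  data.frame(prefs, age = cov$age, sex = cov$sex, iq = cov$iq,
             tiv_cm3 = cov$tiv_cm3)
}
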