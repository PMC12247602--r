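# Vertex-wise GLM, TFCE, permutation inference, conjunction, reporting.

test_that("vertex-wise GLM t-statistics agree with lm() to high precision", {
  set.seed(14)
  n <- 24
  dat <- data.frame(x = rnorm(n), age = rnorm(n, 25, 5),
                    sex = rbinom(n, 1, 0.5), iq = rnorm(n, 111, 7))
  des <- design_matrix(dat, "x", c("age", "sex", "iq"))
  Y <- matrix(rnorm(n * 40), n, 40)
  sm <- vertexwise_glm(Y, des)
  expect_equal(sm$df, n - 5)
  for (v in c(1, 17, 40)) {
    fit <- summary(lm(Y[, v] ~ x + age + sex + iq, dat))
    expect_equal(sm$t[v], fit$coefficients["x", "t value"],
                 tolerance = 1e-8)
  }

  # perfect-fit vertex saturates numerically
  Y[, 3] <- dat$x
  expect_gt(abs(vertexwise_glm(Y, des)$t[3]), 1e6)
})

test_that("null t-maps follow the Student-t distribution", {
  set.seed(15)
  n <- 100
  dat <- data.frame(x = rnorm(n), z = rnorm(n))
  des <- design_matrix(dat, "x", "z")
  Y <- matrix(rnorm(n * 10000), n, 10000)
  sm <- vertexwise_glm(Y, des)
  ks <- ks.test(sm$t, pt, df = sm$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("design matrices must be full rank, with offenders named", {
  dat <- data.frame(x = 1:8, y = 2 * (1:8), z = rnorm(8))
  expect_error(design_matrix(dat, "x", c("y", "z")), "collinear.*y")
  expect_error(design_matrix(dat, "x", "missing_col"), "not found")
})

test_that("TFCE matches the brute-force per-threshold oracle exactly", {
  expect_equal(tfce_transform(numeric(162), ico2)$positive, numeric(162))
  expect_equal(tfce_transform(numeric(162), ico2)$negative, numeric(162))

  # isolated supra-threshold vertex: closed-form step sum
  tv <- numeric(162); tv[40] <- 2.4
  dh <- 2.4 / 100
  manual <- sum((1^0.5) * ((1:100) * dh)^2 * dh)
  out <- tfce_transform(tv, ico2)
  expect_equal(out$positive[40], manual, tolerance = 1e-12)
  expect_equal(out$positive[-40], numeric(161))

  set.seed(16)
  for (r in 1:15) {
    tv <- rnorm(162, sd = runif(1, 0.5, 3))
    got <- tfce_transform(tv, ico2)
    expect_equal(got$positive, tfce_oracle(tv, ico2), tolerance = 1e-12)
    expect_equal(got$negative, tfce_oracle(-tv, ico2), tolerance = 1e-12)
  }
  expect_error(tfce_transform(rnorm(162), ico2, dh = -0.1), "dh")
})

test_that("TFCE is monotone under pointwise increases of the map", {
  set.seed(17)
  for (r in 1:5) {
    tv <- rnorm(162)
    bump <- runif(162, 0, 0.5)
    a <- tfce_transform(tv, ico2, dh = 0.05)$positive
    b <- tfce_transform(tv + bump, ico2, dh = 0.05)$positive
    expect_true(all(b >= a - 1e-12))
  }
})

test_that("permutation inference is reproducible and its q-values are BH within the mask", {
  set.seed(18)
  behav <- toy_behavior(60, seed = 44)
  eff <- effect_spec(seed_vertex = 2, effect_size_alpha = -0.8, seed = 9)
  Y <- generate_surface_metrics(ico2, behav, behav, eff)
  des <- design_matrix(behav, "log10_alpha", c("age", "sex", "iq"))
  inf1 <- permutation_inference(Y, des, ico2, n_permutations = 150, seed = 5)
  inf2 <- permutation_inference(Y, des, ico2, n_permutations = 150, seed = 5)
  expect_identical(inf1$p_pos, inf2$p_pos)
  expect_identical(inf1$p_neg, inf2$p_neg)
  expect_false(identical(
    inf1$p_neg,
    permutation_inference(Y, des, ico2, n_permutations = 150,
                          seed = 6)$p_neg))

  # manual Benjamini-Hochberg step-up on the masked p-values
  mask <- sphere_roi(ico2, c(0, 0, 80), 60)
  infm <- permutation_inference(Y, des, ico2, n_permutations = 150,
                                seed = 5, mask = mask)
  p <- infm$p_neg[mask]
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  stepup[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  stepup <- pmin(stepup, 1)
  expect_equal(infm$q_neg[mask], stepup, tolerance = 1e-12)
  expect_true(all(is.na(infm$q_neg[!mask])))
  expect_false(any(infm$sig_neg[!mask]))

  # p-values bounded away from zero by the +1/+1 estimator
  expect_gte(min(inf1$p_pos), 1 / 151)
})

test_that("null permutation p-values are super-uniform at the tail", {
  behav <- toy_behavior(40, seed = 71)
  des <- design_matrix(behav, "log10_alpha", c("age", "sex", "iq"))
  hits <- 0; total <- 0
  for (r in 1:6) {
    Y <- generate_surface_metrics(
      ico2, behav, behav,
      effect_spec(effect_size_alpha = 0, effect_size_k = 0, seed = 100 + r))
    inf <- permutation_inference(Y, des, ico2, n_permutations = 200,
                                 seed = r)
    hits <- hits + sum(inf$p_pos <= 0.05) + sum(inf$p_neg <= 0.05)
    total <- total + 2 * length(inf$p_pos)
  }
  mc_se <- sqrt(0.05 * 0.95 / total)
  # vertices are spatially correlated, so allow a generous margin over 3 SE
  expect_lt(hits / total, 0.05 + 3 * mc_se + 0.04)
})

test_that("conjunction takes the directional intersection", {
  mk <- function(sig_pos, sig_neg, tf) {
    nv <- 162
    r <- list(t = numeric(nv), mask = rep(TRUE, nv),
              sig_pos = seq_len(nv) %in% sig_pos,
              sig_neg = seq_len(nv) %in% sig_neg,
              tfce_pos = tf, tfce_neg = tf)
    r
  }
  tf <- runif(162)
  a <- mk(c(1, 2, 3), c(10, 11), tf)
  b <- mk(c(2, 3, 4), c(11, 12), tf)
  cj <- conjunction(a, b, "positive", "positive")
  expect_equal(which(cj$mask), c(2L, 3L))
  expect_equal(cj$mean_tfce[2], tf[2])
  expect_equal(which(conjunction(a, b, "negative", "negative")$mask), 11L)
  # disjoint masks give an empty conjunction
  expect_equal(sum(conjunction(mk(1:3, integer(0), tf),
                               mk(7:9, integer(0), tf))$mask), 0)
  # conjunction is contained in both parents
  set.seed(19)
  for (r in 1:10) {
    a <- mk(sample(162, 30), sample(162, 30), tf)
    b <- mk(sample(162, 30), sample(162, 30), tf)
    cj <- conjunction(a, b)
    expect_true(all(cj$mask <= a$sig_pos))
    expect_true(all(cj$mask <= b$sig_pos))
  }
})

test_that("cluster reports find planted components with correct extents", {
  mk_inf <- function(mask, tfce) {
    list(t = tfce, mask = rep(TRUE, 162), sig_pos = mask,
         sig_neg = rep(FALSE, 162), tfce_pos = tfce,
         tfce_neg = numeric(162))
  }
  expect_equal(nrow(cluster_report(mk_inf(rep(FALSE, 162), runif(162)),
                                   ico2)), 0)

  d1 <- geodesic_disc(ico2, 1, 25)
  far <- which.max(geodesic_distances(ico2, 1))
  d2 <- geodesic_disc(ico2, far, 25)
  tfce <- runif(162)
  tfce[far] <- 2  # make the second disc the top cluster
  rep2 <- cluster_report(mk_inf(d1 | d2, tfce), ico2)
  expect_equal(nrow(rep2), 2)
  expect_equal(sort(rep2$extent_k), sort(c(sum(d1), sum(d2))))
  expect_equal(rep2$peak_vertex[1], far)
  expect_equal(rep2$peak_tfce[1], 2)
  expect_true(!is.unsorted(rev(rep2$peak_tfce)))  # sorted descending
  # ROI restriction drops the far cluster
  rep1 <- cluster_report(mk_inf(d1 | d2, tfce), ico2, roi_mask = d1)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$extent_k, sum(d1))
})

test_that("peak-area regression isolates the carrying measure", {
  set.seed(20)
  behav <- toy_behavior(120, seed = 55)
  eff <- effect_spec(seed_vertex = 3, geodesic_radius_mm = 45,
                     effect_size_alpha = -0.8, effect_size_k = -0.4,
                     seed = 31)
  null_eff <- function(s) effect_spec(seed_vertex = 3,
                                      effect_size_alpha = 0,
                                      effect_size_k = 0, seed = s)
  metrics <- list(complexity = generate_surface_metrics(ico2, behav, behav, eff),
                  thickness = generate_surface_metrics(ico2, behav, behav,
                                                       null_eff(32)),
                  gmv = generate_surface_metrics(ico2, behav, behav,
                                                 null_eff(33)))
  disc <- geodesic_disc(ico2, 3, 45)
  conj <- structure(list(mask = disc, mean_tfce = ifelse(disc, 5, 0),
                         mean_tfce_all = ifelse(disc, 5, 0)),
                    class = "conjunction_result")
  tab <- peak_area_regression(metrics, conj, behav, "log10_alpha",
                              c("age", "sex", "iq", "log10_k"),
                              top_n = sum(disc))
  expect_equal(nrow(tab), 7)
  cx <- tab[tab$term == "complexity", ]
  expect_lt(cx$beta_std, 0)
  expect_lt(cx$p, 0.01)
  expect_gt(abs(cx$t), max(abs(tab$t[tab$term %in% c("thickness", "gmv")])))

  # top_n equal to the mask size averages over the whole mask
  avg <- rowMeans(metrics$complexity[, disc])
  fit <- lm(behav$log10_alpha ~ avg + rowMeans(metrics$thickness[, disc]) +
              rowMeans(metrics$gmv[, disc]) + behav$age + behav$sex +
              behav$iq + behav$log10_k)
  expect_equal(cx$t, summary(fit)$coefficients["avg", "t value"],
               tolerance = 1e-8)

  # standardized coefficients are invariant to affine rescaling of a measure
  metrics2 <- metrics
  metrics2$thickness <- metrics2$thickness * 37 + 5
  tab2 <- peak_area_regression(metrics2, conj, behav, "log10_alpha",
                               c("age", "sex", "iq", "log10_k"),
                               top_n = sum(disc))
  expect_equal(tab2$beta_std, tab$beta_std, tolerance = 1e-10)
  expect_error(peak_area_regression(metrics, conj, behav, "log10_alpha",
                                    c("age", "sex", "iq", "log10_k"),
                                    top_n = sum(disc) + 1), "exceeds")
})

test_that("residualization yields standardized residuals matching projection", {
  set.seed(21)
  v <- rnorm(30)
  cov <- matrix(rnorm(60), 30, 2)
  r <- residualize_for_plot(v, cov)
  expect_equal(mean(r), 0, tolerance = 1e-10)
  expect_equal(sd(r), 1, tolerance = 1e-10)

  # hand-computed projection on a 5-point example
  v5 <- c(1, 3, 2, 5, 4)
  c5 <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  X <- cbind(1, c5)
  manual <- v5 - X %*% solve(crossprod(X), crossprod(X, v5))
  expect_equal(residualize_for_plot(v5, c5), as.vector(manual / sd(manual)),
               tolerance = 1e-12)

  # covariates orthogonal to the values leave them unchanged (standardized)
  v_orth <- c(1, -1, 1, -1)
  c_orth <- matrix(c(1, 1, -1, -1), ncol = 1)
  expect_equal(residualize_for_plot(v_orth, c_orth),
               as.vector(scale(v_orth)), tolerance = 1e-12)
  expect_error(residualize_for_plot(v5, cbind(c5, 2 * c5)), "rank")
})

test_that("whole-map correlations report r, df and nulls correctly", {
  a <- rnorm(500)
  expect_equal(whole_map_correlation(a, a)$r, 1)
  expect_equal(whole_map_correlation(a, -a)$r, -1)
  expect_equal(whole_map_correlation(a, a)$df, 498)
  set.seed(22)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(whole_map_correlation(x, y)$r), 0.05)
  expect_error(whole_map_correlation(a, rep(1, 500)), "variance")
  expect_error(whole_map_correlation(a, a[-1]), "equal length")
})
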