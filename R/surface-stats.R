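#' Build a design matrix for vertex-wise regression
#'
#' Assembles intercept + predictor of interest + nuisance covariates into a
#' full-rank design. Rank deficiency is reported with the names of the
#' offending columns.
#'
#' @param data data frame holding predictor and covariate columns.
#' @param interest name of the predictor of interest.
#' @param covariates character vector of nuisance covariate names.
#' @return List of class `design_matrix`: `X` (with intercept), `interest`
#'   (column name), `interest_index`.
#' @export
design_matrix <- function(data, interest, covariates = character(0)) {
  cols <- c(interest, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("design columns not found: ", paste(missing_cols, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, cols, drop = FALSE]))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, interest = interest,
                 interest_index = match(interest, colnames(X))),
            class = "design_matrix")
}

#' Mass-univariate vertex-wise linear regression
#'
#' Fits an ordinary least-squares regression of each vertex's metric on the
#' design and returns the t-statistic for the predictor of interest at every
#' vertex. Implemented by partialling the nuisance columns out of the
#' predictor of interest, which gives the identical t to a full-model fit.
#'
#' @param metrics subjects x vertices numeric matrix.
#' @param design a [design_matrix()] (rows aligned with `metrics`).
#' @return Object of class `stat_map`: list with `t` (per-vertex), `beta`,
#'   `df` (n - p), `predictor`.
#' @export
vertexwise_glm <- function(metrics, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (nrow(metrics) != nrow(X))
    stop("metrics rows must align with design rows")
  j <- design$interest_index
  Z <- X[, -j, drop = FALSE]
  Qz <- qr.Q(qr(Z))
  x <- X[, j]
  x_res <- x - Qz %*% crossprod(Qz, x)
  xtx <- sum(x_res^2)
  if (xtx < 1e-12)
    stop("predictor of interest is collinear with the nuisance columns")
  Yz <- metrics - Qz %*% crossprod(Qz, metrics)  # subjects x vertices
  num <- as.vector(crossprod(x_res, Yz))
  beta <- num / xtx
  rss <- pmax(colSums(Yz^2) - num^2 / xtx, 0)
  df <- nrow(X) - ncol(X)
  sigma2 <- rss / df
  t <- beta / sqrt(pmax(sigma2 / xtx, .Machine$double.xmin))
  structure(list(t = t, beta = beta, df = df, predictor = design$interest),
            class = "stat_map")
}

#' @method print stat_map
#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s: %d vertices, df = %d, |t| max = %.2f\n",
              x$predictor, length(x$t), x$df, max(abs(x$t))))
  invisible(x)
}

#' Threshold-free cluster enhancement of a statistic map on a mesh
#'
#' For each vertex, integrates `extent^E * height^H` of the supra-threshold
#' connected component containing it over equally spaced thresholds from
#' `dh` up to the map maximum: TFCE boosts spatially extended signals
#' without committing to a single cluster-forming threshold. The positive
#' and negative tails are enhanced separately (the negative tail on the
#' negated map).
#'
#' @param stat_map a `stat_map` or plain numeric per-vertex vector.
#' @param mesh a [surface_mesh()].
#' @param E extent exponent (default 0.5, the canonical surface default).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` (default) uses `max|t| / n_steps`
#'   per tail, the usual adaptive step.
#' @param n_steps number of threshold steps when `dh` is `NULL`.
#' @return Object of class `tfce_map`: list with `positive` and `negative`
#'   per-vertex TFCE values (both nonnegative) and the parameters used.
#' @export
tfce_transform <- function(stat_map, mesh, E = 0.5, H = 2, dh = NULL,
                           n_steps = 100L) {
  t_vals <- if (inherits(stat_map, "stat_map")) stat_map$t else
    as.numeric(stat_map)
  if (length(t_vals) != n_vertices(mesh))
    stop("stat map length must equal vertex count")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (E <= 0 || H <= 0) stop("E and H must be positive")
  dh_arg <- if (is.null(dh)) -1 else dh
  pos <- .tfce_positive(t_vals, mesh$edges, E, H, dh_arg, as.integer(n_steps))
  neg <- .tfce_positive(-t_vals, mesh$edges, E, H, dh_arg, as.integer(n_steps))
  structure(list(positive = pos, negative = neg, E = E, H = H, dh = dh,
                 n_steps = n_steps), class = "tfce_map")
}

#' Permutation inference with TFCE and FDR correction
#'
#' Tests the predictor of interest at every vertex using Freedman-Lane
#' permutation: the nuisance-only (reduced) model is fitted once, its
#' residuals are permuted and added back to the nuisance fit, the full model
#' is refitted to each permuted dataset, and the resulting t-map is
#' TFCE-enhanced. Per-vertex permutation p-values use the +1/+1 estimator
#' `p = (1 + #(perm >= observed)) / (1 + n_perm)` separately for the
#' positive and negative tails, and Benjamini-Hochberg FDR is applied
#' within the analysis mask per tail.
#'
#' @param metrics subjects x vertices matrix.
#' @param design a [design_matrix()].
#' @param mesh a [surface_mesh()].
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param q FDR level (default 0.05).
#' @param mask optional logical analysis mask (default: all vertices).
#' @param E,H,dh,n_steps TFCE parameters, see [tfce_transform()].
#' @return Object of class `tfce_inference`: per-vertex `t`, `tfce_pos`,
#'   `tfce_neg`, `p_pos`, `p_neg`, `q_pos`, `q_neg` (NA outside the mask),
#'   logical `sig_pos`, `sig_neg` (q <= level within the mask), plus `df`,
#'   `mask`, `n_permutations`, `seed`, `q`, `predictor`.
#' @export
permutation_inference <- function(metrics, design, mesh,
                                  n_permutations = 1000L, seed = 1L,
                                  q = 0.05, mask = NULL,
                                  E = 0.5, H = 2, dh = NULL,
                                  n_steps = 100L) {
  stopifnot(inherits(design, "design_matrix"))
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  nv <- n_vertices(mesh)
  if (ncol(metrics) != nv) stop("metrics columns must equal vertex count")
  n <- nrow(metrics)
  X <- design$X
  if (nrow(X) != n) stop("design rows must align with metrics rows")
  if (is.null(mask)) mask <- rep(TRUE, nv)
  if (length(mask) != nv) stop("mask length must equal vertex count")

  j <- design$interest_index
  Z <- X[, -j, drop = FALSE]
  Qz <- qr.Q(qr(Z))
  x_res <- X[, j] - Qz %*% crossprod(Qz, X[, j])
  xtx <- sum(x_res^2)
  if (xtx < 1e-12)
    stop("design degenerate: interest predictor collinear with nuisance")
  df <- n - ncol(X)

  Yz <- metrics - Qz %*% crossprod(Qz, metrics)
  t_from_partial <- function(Yp) {
    # Yp: residualized (nuisance-orthogonal) response, subjects x vertices
    num <- as.vector(crossprod(x_res, Yp))
    rss <- pmax(colSums(Yp^2) - num^2 / xtx, 0)
    (num / xtx) / sqrt(pmax(rss / df / xtx, .Machine$double.xmin))
  }

  t_obs <- t_from_partial(Yz)
  tf_obs <- tfce_transform(t_obs, mesh, E = E, H = H, dh = dh,
                           n_steps = n_steps)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  cnt_pos <- numeric(nv)
  cnt_neg <- numeric(nv)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    PY <- Yz[perm, , drop = FALSE]
    # residualize the permuted response against the nuisance again
    PYz <- PY - Qz %*% crossprod(Qz, PY)
    t_perm <- t_from_partial(PYz)
    tf_perm <- tfce_transform(t_perm, mesh, E = E, H = H, dh = dh,
                              n_steps = n_steps)
    cnt_pos <- cnt_pos + (tf_perm$positive >= tf_obs$positive)
    cnt_neg <- cnt_neg + (tf_perm$negative >= tf_obs$negative)
  }
  p_pos <- (1 + cnt_pos) / (1 + n_permutations)
  p_neg <- (1 + cnt_neg) / (1 + n_permutations)

  q_pos <- q_neg <- rep(NA_real_, nv)
  q_pos[mask] <- stats::p.adjust(p_pos[mask], method = "BH")
  q_neg[mask] <- stats::p.adjust(p_neg[mask], method = "BH")
  sig_pos <- !is.na(q_pos) & q_pos <= q
  sig_neg <- !is.na(q_neg) & q_neg <= q

  structure(list(t = t_obs, df = df,
                 tfce_pos = tf_obs$positive, tfce_neg = tf_obs$negative,
                 p_pos = p_pos, p_neg = p_neg,
                 q_pos = q_pos, q_neg = q_neg,
                 sig_pos = sig_pos, sig_neg = sig_neg,
                 mask = mask, n_permutations = n_permutations,
                 seed = seed, q = q, predictor = design$interest),
            class = "tfce_inference")
}

#' @method print tfce_inference
#' @export
print.tfce_inference <- function(x, ...) {
  cat(sprintf(
    "<tfce_inference> %s: %d vertices in mask, %d permutations, q = %.2f\n  significant: %d positive, %d negative\n",
    x$predictor, sum(x$mask), x$n_permutations, x$q,
    sum(x$sig_pos), sum(x$sig_neg)))
  invisible(x)
}

sig_mask_for <- function(result, sign) {
  sign <- match.arg(sign, c("positive", "negative"))
  if (sign == "positive") result$sig_pos else result$sig_neg
}

tfce_map_for <- function(result, sign) {
  sign <- match.arg(sign, c("positive", "negative"))
  if (sign == "positive") result$tfce_pos else result$tfce_neg
}

#' Directional conjunction of two TFCE inference results
#'
#' A vertex qualifies only if it is independently significant in both
#' component analyses at the requested effect signs. The accompanying map is
#' the elementwise mean of the two TFCE maps, zeroed outside the conjunction
#' mask.
#'
#' @param result_a,result_b `tfce_inference` objects on the same mesh/mask.
#' @param sign_a,sign_b `"positive"` or `"negative"` effect direction for
#'   each analysis.
#' @return List of class `conjunction_result`: logical `mask`, numeric
#'   `mean_tfce` (zero outside the mask), and a full-length `mean_tfce_all`
#'   (unmasked mean TFCE, used for peak-area vertex ranking).
#' @export
conjunction <- function(result_a, result_b, sign_a = "positive",
                        sign_b = "positive") {
  if (length(result_a$t) != length(result_b$t) ||
      !identical(result_a$mask, result_b$mask))
    stop("conjunction inputs must share the same mesh and analysis mask")
  mask <- sig_mask_for(result_a, sign_a) & sig_mask_for(result_b, sign_b)
  mean_all <- (tfce_map_for(result_a, sign_a) +
               tfce_map_for(result_b, sign_b)) / 2
  mean_masked <- ifelse(mask, mean_all, 0)
  structure(list(mask = mask, mean_tfce = mean_masked,
                 mean_tfce_all = mean_all,
                 sign_a = sign_a, sign_b = sign_b),
            class = "conjunction_result")
}

#' Cluster table for a significance mask
#'
#' Labels the connected components of the significance mask (optionally
#' restricted to an ROI) and reports, per cluster: the peak vertex (highest
#' TFCE; ties broken by lowest vertex index), its mm coordinates, the peak
#' TFCE value and the cluster extent `k` in vertices. Sorted by peak TFCE
#' descending.
#'
#' @param result a `tfce_inference` or `conjunction_result`.
#' @param mesh the [surface_mesh()] the result was computed on.
#' @param roi_mask optional logical ROI restriction.
#' @param sign which tail of a `tfce_inference` to report (ignored for
#'   conjunctions, which carry their own mask).
#' @return Data frame: `cluster`, `peak_vertex`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_tfce`, `extent_k`, `sign`; zero rows when nothing is
#'   significant.
#' @export
cluster_report <- function(result, mesh, roi_mask = NULL,
                           sign = "positive") {
  if (inherits(result, "conjunction_result")) {
    mask <- result$mask
    tfce <- result$mean_tfce_all
    sign_label <- "conjunction"
  } else {
    mask <- sig_mask_for(result, sign)
    tfce <- tfce_map_for(result, sign)
    sign_label <- sign
  }
  if (!is.null(roi_mask)) mask <- mask & roi_mask
  labels <- connected_components(mesh, mask)
  empty <- data.frame(cluster = integer(0), peak_vertex = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_tfce = numeric(0),
                      extent_k = integer(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  comps <- sort(unique(labels[labels > 0]))
  rows <- lapply(comps, function(cl) {
    members <- which(labels == cl)
    peak <- members[which.max(tfce[members])]  # which.max: lowest index tie
    data.frame(cluster = cl, peak_vertex = peak,
               peak_x = mesh$vertices[peak, 1],
               peak_y = mesh$vertices[peak, 2],
               peak_z = mesh$vertices[peak, 3],
               peak_tfce = tfce[peak], extent_k = length(members),
               sign = sign_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_tfce, out$peak_vertex), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Peak-area multi-measure regression
#'
#' Averages each morphometric measure over the `top_n` conjunction vertices
#' with the highest mean TFCE (ties broken by ascending vertex index), then
#' regresses a preference on all measure averages plus age, sex, IQ and the
#' other preference. Coefficients are standardized (all variables z-scored),
#' with t and two-sided p from the unstandardized fit (identical under
#' rescaling).
#'
#' @param metric_matrices named list of subjects x vertices matrices, one
#'   per measure.
#' @param conj a `conjunction_result` (its `mean_tfce` ranks vertices).
#' @param data data frame with the outcome preference, the other
#'   preference, and covariates, rows aligned with the metric matrices.
#' @param outcome column name of the preference to predict.
#' @param other_terms column names entered alongside the measure averages
#'   (default `age`, `sex`, `iq` and the other preference must be included
#'   by the caller).
#' @param top_n number of peak vertices to average over (must not exceed
#'   the conjunction mask size).
#' @return Data frame: `term`, `beta_std`, `t`, `p`, `df`.
#' @export
peak_area_regression <- function(metric_matrices, conj, data, outcome,
                                 other_terms, top_n = 500) {
  stopifnot(inherits(conj, "conjunction_result"))
  masked <- which(conj$mask)
  if (length(masked) == 0) stop("conjunction mask is empty")
  if (top_n > length(masked))
    stop("top_n (", top_n, ") exceeds conjunction mask size (",
         length(masked), ")")
  ord <- masked[order(-conj$mean_tfce[masked], masked)]
  top <- ord[seq_len(top_n)]
  averages <- lapply(metric_matrices, function(m)
    rowMeans(m[, top, drop = FALSE]))
  reg <- data.frame(averages, data[, c(outcome, other_terms), drop = FALSE])
  X <- as.matrix(reg[, setdiff(names(reg), outcome), drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("collinear measure averages or covariates in peak-area regression")
  y <- reg[[outcome]]
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)$coefficients
  terms <- colnames(X)
  rows <- sm[-1, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  data.frame(term = terms,
             beta_std = rows[, "Estimate"] * sds / stats::sd(y),
             t = rows[, "t value"],
             p = rows[, "Pr(>|t|)"],
             df = fit$df.residual,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Standardized residuals after regressing out covariates
#'
#' OLS residuals of `values` on an intercept plus the covariates, divided by
#' their standard deviation: mean 0, SD 1, the quantity typically plotted in
#' adjusted scatter plots.
#'
#' @param values numeric outcome vector.
#' @param covariates data frame or matrix of covariates (no intercept).
#' @return Numeric vector of standardized residuals.
#' @export
residualize_for_plot <- function(values, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient")
  r <- stats::lm.fit(X, values)$residuals
  r / stats::sd(r)
}

#' Correlation between two whole-surface maps
#'
#' Pearson correlation across vertices of two (typically group-mean) maps,
#' with degrees of freedom reported as `n_vertices - 2`.
#'
#' @param map_a,map_b numeric per-vertex vectors of equal length.
#' @return List: `r`, `df`, `p` (two-sided, treating vertices as
#'   independent observations — an approximation on smooth maps).
#' @export
whole_map_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stop("maps must have equal length")
  if (stats::sd(map_a) == 0 || stats::sd(map_b) == 0)
    stop("map has zero variance")
  r <- stats::cor(map_a, map_b)
  df <- length(map_a) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tstat), df))
}
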