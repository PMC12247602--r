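#' Planted-effect specification for synthetic surface metrics
#'
#' Describes one planted brain-behavior association: a geodesic disc on the
#' mesh inside which the metric depends linearly on the (standardized)
#' preferences, tapering smoothly to zero at the disc boundary, on top of a
#' smooth Gaussian random field plus covariate contributions.
#'
#' @param seed_vertex 1-based index of the disc center.
#' @param geodesic_radius_mm disc radius along the surface (> 0).
#' @param effect_size_alpha,effect_size_k slopes in metric units per SD of
#'   log10(alpha) / log10(k) at the disc center (0 = no planted effect).
#' @param noise_sd per-vertex SD of the smooth noise field (> 0).
#' @param smoothing_fwhm_mm FWHM of the noise field's spatial smoothness.
#' @param age_slope,sex_effect,iq_slope uniform covariate contributions in
#'   metric units (per year, male-female difference, per IQ point).
#' @param seed integer seed for the noise field.
#' @return List of class `effect_spec`.
#' @export
effect_spec <- function(seed_vertex = 1L, geodesic_radius_mm = 40,
                        effect_size_alpha = 0, effect_size_k = 0,
                        noise_sd = 1, smoothing_fwhm_mm = 15,
                        age_slope = -0.02, sex_effect = 0.1,
                        iq_slope = 0.005, seed = 1L) {
  stopifnot(geodesic_radius_mm > 0, noise_sd > 0, smoothing_fwhm_mm >= 0)
  structure(as.list(environment()), class = "effect_spec")
}

#' Generate synthetic per-vertex morphometric maps for a cohort
#'
#' Each subject's map is the sum of (i) a smooth Gaussian random field —
#' white vertex noise smoothed to `smoothing_fwhm_mm` and rescaled so its
#' per-vertex SD equals `noise_sd`; (ii) spatially uniform, mean-centered
#' covariate contributions (age, sex, IQ); and (iii) a planted linear
#' effect of the standardized preferences inside the geodesic disc around
#' `seed_vertex`, weighted by a plateau-cosine taper (full strength inside
#' 60% of the radius, smoothly reaching zero at the boundary).
#' Deterministic given `effect$seed`.
#'
#' @param mesh a [surface_mesh()].
#' @param preferences data frame with columns `log10_alpha` and `log10_k`
#'   (one row per subject).
#' @param covariates data frame with columns `age`, `sex`, `iq`, rows
#'   aligned with `preferences`.
#' @param effect an [effect_spec()].
#' @return Subjects x vertices numeric matrix.
#' @export
generate_surface_metrics <- function(mesh, preferences, covariates, effect) {
  stopifnot(inherits(effect, "effect_spec"))
  nv <- n_vertices(mesh)
  if (effect$seed_vertex < 1 || effect$seed_vertex > nv)
    stop("seed_vertex outside mesh")
  n <- nrow(preferences)
  if (nrow(covariates) != n)
    stop("covariates and preferences must have the same number of rows")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(effect$seed)

  noise <- matrix(stats::rnorm(n * nv), n, nv)
  if (effect$smoothing_fwhm_mm > 0)
    noise <- smooth_metric(mesh, noise, effect$smoothing_fwhm_mm)
  noise <- noise / stats::sd(as.vector(noise)) * effect$noise_sd

  zc <- function(x) x - mean(x)
  covar_part <- effect$age_slope * zc(covariates$age) +
    effect$sex_effect * zc(covariates$sex) +
    effect$iq_slope * zc(covariates$iq)

  d <- geodesic_distances(mesh, effect$seed_vertex)
  r <- effect$geodesic_radius_mm
  taper <- numeric(nv)
  inside <- d <= r
  plateau <- d <= 0.6 * r
  ramp <- inside & !plateau
  taper[plateau] <- 1
  taper[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - 0.6 * r) / (0.4 * r)))

  zs <- function(x) as.vector(scale(x))
  slope_per_subject <- effect$effect_size_alpha * zs(preferences$log10_alpha) +
    effect$effect_size_k * zs(preferences$log10_k)

  noise + covar_part + outer(slope_per_subject, taper)
}
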