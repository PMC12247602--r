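#' Pipeline run configuration
#'
#' Central knobs for an end-to-end run. In simulation mode (the default)
#' every input is generated by the synthetic modules; in ingest mode,
#' `choices_path` / `covariates_path` / `metric_paths` / `mesh_path` point
#' at files in the package's documented formats.
#'
#' The five morphometric measures mirror a surface-based morphometry study:
#' complexity and gyrification are analysis-smoothed at 20 mm FWHM, sulcal
#' depth and thickness at 12 mm, and a GMV surrogate (8 mm) additionally
#' controls total intracranial volume.
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_subjects simulated cohort size.
#' @param n_trials_per_task choice trials per task.
#' @param mesh_subdivisions,mesh_radius_mm icosphere fixture surface.
#' @param measures character vector of measure names.
#' @param smoothing_fwhm_mm named numeric vector, analysis smoothing per
#'   measure.
#' @param effect_measures measures carrying the planted conjunction effect.
#' @param effect_size_alpha,effect_size_k planted slopes (negative by
#'   default: higher risk tolerance and steeper discounting both reduce the
#'   metric, the direction reported for medial prefrontal complexity).
#' @param effect_radius_mm,effect_seed_vertex planted disc geometry
#'   (`effect_seed_vertex = NULL` uses vertex 1).
#' @param n_permutations,q,tfce_e,tfce_h inference parameters.
#' @param top_n peak-area vertex count (capped at the conjunction size at
#'   run time).
#' @param sign_alpha,sign_k tested effect directions for the conjunction.
#' @param choices_path,covariates_path,metric_paths,mesh_path ingest-mode
#'   inputs (`NULL` = simulate).
#' @param output_dir optional directory; when set, maps, tables and the
#'   JSON report are written there.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_subjects = 156L,
                       n_trials_per_task = 120L,
                       mesh_subdivisions = 3L,
                       mesh_radius_mm = 80,
                       measures = c("complexity", "gyrification",
                                    "sulcal_depth", "thickness", "gmv"),
                       smoothing_fwhm_mm = c(complexity = 20,
                                             gyrification = 20,
                                             sulcal_depth = 12,
                                             thickness = 12, gmv = 8),
                       effect_measures = "complexity",
                       effect_size_alpha = -0.55,
                       effect_size_k = -0.55,
                       effect_radius_mm = 40,
                       effect_seed_vertex = NULL,
                       n_permutations = 1000L,
                       q = 0.05,
                       tfce_e = 0.5, tfce_h = 2,
                       top_n = 500L,
                       sign_alpha = "negative", sign_k = "negative",
                       choices_path = NULL, covariates_path = NULL,
                       metric_paths = NULL, mesh_path = NULL,
                       output_dir = NULL) {
  stopifnot(q > 0, q < 1, n_permutations >= 100)
  if (!all(measures %in% names(smoothing_fwhm_mm)))
    stop("smoothing_fwhm_mm must name every measure")
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; unknown keys are an
#' error so typos fail loudly.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$smoothing_fwhm_mm))
    vals$smoothing_fwhm_mm <- unlist(vals$smoothing_fwhm_mm)
  do.call(run_config, vals)
}

load_or_simulate_inputs <- function(config) {
  ingest <- !is.null(config$choices_path)
  if (ingest) {
    for (p in c(config$choices_path, config$covariates_path,
                unlist(config$metric_paths), unlist(config$mesh_path))) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    mesh <- if (grepl("\\.gii$", config$mesh_path[[1]])) {
      read_gifti_surface(config$mesh_path[[1]])
    } else read_mesh_arrays(config$mesh_path[[1]], config$mesh_path[[2]])
    datasets <- read_choices(config$choices_path)
    covariates <- utils::read.csv(config$covariates_path)
    metrics <- lapply(config$metric_paths, function(p) {
      if (grepl("\\.gii$", p)) read_gifti_metric(p) else read_metric_tsv(p)
    })
    names(metrics) <- config$measures
    return(list(datasets = datasets, covariates = covariates,
                metrics = metrics, mesh = mesh, truth = NULL))
  }
  mesh <- build_icosphere(config$mesh_subdivisions, config$mesh_radius_mm)
  spec <- cohort_spec(n_subjects = config$n_subjects,
                      n_trials_per_task = config$n_trials_per_task,
                      seed = config$seed)
  cohort <- generate_cohort_choices(spec)
  covariates <- generate_covariates(config$n_subjects,
                                    seed = config$seed + 1L)
  seed_vertex <- if (is.null(config$effect_seed_vertex)) 1L else
    config$effect_seed_vertex
  metrics <- lapply(seq_along(config$measures), function(i) {
    meas <- config$measures[i]
    planted <- meas %in% config$effect_measures
    eff <- effect_spec(
      seed_vertex = seed_vertex,
      geodesic_radius_mm = config$effect_radius_mm,
      effect_size_alpha = if (planted) config$effect_size_alpha else 0,
      effect_size_k = if (planted) config$effect_size_k else 0,
      seed = config$seed + 100L + i)
    generate_surface_metrics(mesh, cohort$truth, covariates, eff)
  })
  names(metrics) <- config$measures
  list(datasets = cohort$datasets, covariates = covariates,
       metrics = metrics, mesh = mesh, truth = cohort$truth,
       planted_vertex = seed_vertex)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, fits both choice tasks per subject,
#' applies the exclusion rules, smooths each morphometric measure at its
#' per-measure FWHM, runs the vertex-wise GLM + TFCE permutation inference
#' for each preference and measure, forms the directional conjunction per
#' measure, tabulates clusters, and — when the conjunction is nonempty —
#' runs the peak-area multi-measure regression for both preferences.
#'
#' @param config a [run_config()].
#' @return List of class `pipeline_report`: `estimates` (per-subject
#'   behavioral table), `inference` (per measure: the two `tfce_inference`
#'   objects and the `conjunction_result`), `clusters` (data frame),
#'   `peak_area` (list of regression tables or `NULL`), `mesh`, `config`,
#'   `provenance`. When `config$output_dir` is set, maps (GIFTI), tables
#'   (CSV) and a JSON report are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  inputs <- load_or_simulate_inputs(config)
  mesh <- inputs$mesh

  message("fitting choice preferences for ", length(inputs$datasets),
          " subjects")
  estimates <- fit_cohort(inputs$datasets)
  included <- which(estimates$included)
  if (length(included) < 10)
    stop("pipeline stage fit+exclude: fewer than 10 included subjects")
  est_inc <- estimates[included, , drop = FALSE]
  covar_inc <- inputs$covariates[included, , drop = FALSE]

  behav <- data.frame(log10_alpha = log10(est_inc$alpha),
                      log10_k = log10(est_inc$k),
                      age = covar_inc$age, sex = covar_inc$sex,
                      iq = covar_inc$iq, tiv_cm3 = covar_inc$tiv_cm3)

  message("vertex-wise inference on ", length(config$measures),
          " measures, ", config$n_permutations, " permutations")
  inference <- list()
  clusters <- list()
  for (meas in config$measures) {
    Y <- inputs$metrics[[meas]][included, , drop = FALSE]
    Y <- smooth_metric(mesh, Y, config$smoothing_fwhm_mm[[meas]])
    nuisance <- c("age", "sex", "iq", if (meas == "gmv") "tiv_cm3")
    des_a <- design_matrix(behav, "log10_alpha", nuisance)
    des_k <- design_matrix(behav, "log10_k", nuisance)
    inf_a <- permutation_inference(Y, des_a, mesh,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed + 200L,
                                   q = config$q, E = config$tfce_e,
                                   H = config$tfce_h)
    inf_k <- permutation_inference(Y, des_k, mesh,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed + 201L,
                                   q = config$q, E = config$tfce_e,
                                   H = config$tfce_h)
    conj <- conjunction(inf_a, inf_k, config$sign_alpha, config$sign_k)
    inference[[meas]] <- list(alpha = inf_a, k = inf_k, conjunction = conj,
                              smoothed = Y)
    cl <- cluster_report(conj, mesh)
    if (nrow(cl)) cl$measure <- meas
    clusters[[meas]] <- cl
  }
  clusters <- do.call(rbind, clusters[vapply(clusters, nrow, 1L) > 0])
  if (is.null(clusters)) clusters <- cluster_report(
    inference[[1]]$conjunction, mesh)  # canonical empty frame

  peak_area <- NULL
  primary <- config$effect_measures[1]
  conj_primary <- inference[[primary]]$conjunction
  if (any(conj_primary$mask)) {
    smoothed_all <- lapply(inference, `[[`, "smoothed")
    top_n <- min(config$top_n, sum(conj_primary$mask))
    peak_area <- list(
      log10_alpha = peak_area_regression(
        smoothed_all, conj_primary, behav, "log10_alpha",
        c("age", "sex", "iq", "log10_k"), top_n = top_n),
      log10_k = peak_area_regression(
        smoothed_all, conj_primary, behav, "log10_k",
        c("age", "sex", "iq", "log10_alpha"), top_n = top_n))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("prefmorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_included = length(included),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(
    list(estimates = estimates, behav = behav, inference = inference,
         clusters = clusters, peak_area = peak_area, mesh = mesh,
         truth = inputs$truth, planted_vertex = inputs$planted_vertex,
         config = config, provenance = provenance),
    class = "pipeline_report")

  if (!is.null(config$output_dir)) write_pipeline_outputs(report)
  report
}

#' @method print pipeline_report
#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects included of %d fitted\n",
              x$provenance$n_included, nrow(x$estimates)))
  for (meas in names(x$inference)) {
    conj <- x$inference[[meas]]$conjunction
    cat(sprintf("  %-12s conjunction vertices: %d\n", meas,
                sum(conj$mask)))
  }
  if (nrow(x$clusters))
    cat(sprintf("  %d conjunction cluster(s); top peak TFCE %.1f (k = %d)\n",
                nrow(x$clusters), x$clusters$peak_tfce[1],
                x$clusters$extent_k[1]))
  invisible(x)
}

# Serialize a report bundle: GIFTI maps, CSV tables, JSON summary.
write_pipeline_outputs <- function(report) {
  dir.create(report$config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(report$config$output_dir, ...)
  utils::write.csv(report$estimates, out("behavioral_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$clusters, out("conjunction_clusters.csv"),
                   row.names = FALSE)
  write_gifti_surface(report$mesh, out("mesh.surf.gii"))
  for (meas in names(report$inference)) {
    inf <- report$inference[[meas]]
    for (pref in c("alpha", "k")) {
      r <- inf[[pref]]
      write_gifti_metric(rbind(r$t, r$tfce_pos, r$tfce_neg, r$p_pos,
                               r$p_neg, as.numeric(r$sig_pos),
                               as.numeric(r$sig_neg)),
                         out(sprintf("%s_%s_maps.func.gii", meas, pref)))
    }
    write_gifti_metric(rbind(as.numeric(inf$conjunction$mask),
                             inf$conjunction$mean_tfce),
                       out(sprintf("%s_conjunction.func.gii", meas)))
  }
  summary_list <- list(
    provenance = report$provenance,
    config = report$config[!vapply(report$config, is.null, logical(1))],
    n_conjunction_vertices = lapply(report$inference, function(i)
      sum(i$conjunction$mask)),
    clusters = report$clusters,
    peak_area = report$peak_area)
  jsonlite::write_json(summary_list, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(report$config$output_dir)
}
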