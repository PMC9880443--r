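#' Run the full synthetic-cohort analysis pipeline
#'
#' Drives the end-to-end study on a synthetic cohort: simulate patients,
#' compute per-fraction effectiveness and deformation features, accumulate
#' dose per patient (optionally with a gamma-index check of one pulled-back
#' fraction against the plan), and evaluate the leave-one-patient-out
#' prediction models. Every output is written with the seed and a config
#' checksum for provenance; stages can be toggled.
#'
#' @param config either a [cohort_config()], a list with elements `cohort`
#'   (arguments to [cohort_config()]) and optional `stages`/`model`, or a
#'   path to a YAML file with that structure.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of `c("features", "accumulate", "gamma",
#'   "predict")`; simulation always runs.
#' @param write_volumes also write per-patient NIfTI volumes (plan dose, CTV
#'   mask, accumulated dose); off by default to keep outputs small.
#' @param model `"rf"`, `"mlp"` or both, used in the predict stage.
#' @param fsets feature-set names evaluated in the predict stage.
#' @param seed overrides the seed in the config when not `NULL`.
#' @return invisibly, a list with `cohort`, `features`, `accumulation`,
#'   `gamma`, `models` and `metrics` (also written to
#'   `file.path(out_dir, "metrics.json")`).
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = tempfile("eudgate_"),
                         stages = c("features", "accumulate", "predict"),
                         write_volumes = FALSE, model = c("rf", "mlp"),
                         fsets = c("A", "F"), seed = NULL) {
  t0 <- proc.time()["elapsed"]
  if (is.character(config) && length(config) == 1) {
    spec <- yaml::read_yaml(config)
    cfg <- do.call(cohort_config, modifyList(
      spec$cohort %||% list(),
      if (!is.null(spec$cohort$grid)) list(grid = do.call(grid_spec, spec$cohort$grid)) else list()))
    if (!is.null(spec$stages)) stages <- spec$stages
    if (!is.null(spec$model)) model <- spec$model
  } else if (inherits(config, "cohort_config")) {
    cfg <- config
  } else {
    cfg <- do.call(cohort_config, config)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  stages <- match.arg(stages, c("features", "accumulate", "gamma", "predict"),
                      several.ok = TRUE)
  model <- match.arg(model, c("rf", "mlp"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  checksum <- config_checksum(unclass(cfg)[setdiff(names(cfg), "grid")])
  log_stage <- function(name, start)
    message(sprintf("[eudgate] %-10s %6.1f s", name,
                    proc.time()["elapsed"] - start))

  ts <- proc.time()["elapsed"]
  cohort <- generate_cohort(cfg)
  log_stage("simulate", ts)
  metrics <- list(seed = cfg$seed, config_checksum = checksum,
                  n_patients = length(cohort),
                  n_fractions = sum(vapply(cohort, function(s) length(s$fractions), numeric(1))))

  features <- NULL
  if ("features" %in% stages || "predict" %in% stages) {
    ts <- proc.time()["elapsed"]
    features <- extract_cohort_features(cohort)
    write_features_csv(features, file.path(out_dir, "features.csv"))
    kw <- kruskal_wallis_groups(features$geud, features$patient_id)
    sp <- spearman_rank(features$geud, features$eud_sf)
    metrics$features <- list(
      n_low_geud = sum(features$geud < 0.93),
      geud_range = range(features$geud),
      kruskal_wallis = kw,
      spearman_geud_eudsf = sp)
    log_stage("features", ts)
  }

  accumulation <- NULL
  if ("accumulate" %in% stages) {
    ts <- proc.time()["elapsed"]
    accumulation <- lapply(cohort, function(s) {
      acc <- accumulate_dose(s)
      if (write_volumes)
        write_grid(acc$dose, file.path(out_dir, sprintf("%s_accumulated.nii.gz", s$patient_id)))
      list(patient_id = s$patient_id, geud_acc_norm = acc$geud_acc_norm,
           d_min_acc_norm = acc$d_min_acc_norm, n_fractions = acc$n_fractions)
    })
    metrics$accumulation <- accumulation
    log_stage("accumulate", ts)
  }

  gamma_report <- NULL
  if ("gamma" %in% stages) {
    ts <- proc.time()["elapsed"]
    s <- cohort[[1]]
    fr <- s$fractions[[1]]
    pb <- suppressWarnings(pullback_dose(s$plan_dose, fr$field))
    roi <- dilate_mask(s$ctv_plan, 15)
    gm <- gamma_pass_rate(s$plan_dose, pb, roi, dta_mm = 3, dd = 0.03,
                          norm_dose = s$prescription)
    gamma_report <- list(patient_id = s$patient_id, fraction = 1,
                         pass_rate = gm$pass_rate, n_evaluated = gm$n_evaluated,
                         criteria = gm$criteria)
    metrics$gamma <- gamma_report
    write_metrics_json(gamma_report, file.path(out_dir, "gamma.json"))
    log_stage("gamma", ts)
  }

  models <- NULL
  if ("predict" %in% stages) {
    ts <- proc.time()["elapsed"]
    w <- make_weights(features$geud)
    models <- list()
    for (fs in fsets) {
      feats <- feature_set(fs)
      if ("rf" %in% model)
        models[[paste0("rf_", fs)]] <-
          lopo_random_forest(features, feats, weights = w, seed = cfg$seed)
      if ("mlp" %in% model)
        models[[paste0("mlp_", fs)]] <-
          nested_lopo_mlp(features, feats, weights = w, seed = cfg$seed)
    }
    for (nm in names(models)) {
      write.csv(models[[nm]]$predictions,
                file.path(out_dir, sprintf("predictions_%s.csv", nm)),
                row.names = FALSE)
      if (!is.null(models[[nm]]$importance))
        write.csv(data.frame(feature = names(models[[nm]]$importance),
                             importance = as.numeric(models[[nm]]$importance)),
                  file.path(out_dir, sprintf("importance_%s.csv", nm)),
                  row.names = FALSE)
    }
    metrics$models <- lapply(models, function(m)
      list(pearson_r = m$pearson_r, fisher_ci = as.list(m$fisher_ci),
           ve_cv = m$ve_cv))
    log_stage("predict", ts)
  }

  if (write_volumes) {
    for (s in cohort) {
      write_grid(s$plan_dose, file.path(out_dir, sprintf("%s_plan_dose.nii.gz", s$patient_id)))
      write_grid(s$ctv_plan, file.path(out_dir, sprintf("%s_ctv_plan.nii.gz", s$patient_id)))
    }
  }
  metrics$elapsed_s <- unname(proc.time()["elapsed"] - t0)
  write_metrics_json(metrics, file.path(out_dir, "metrics.json"))
  invisible(list(cohort = cohort, features = features,
                 accumulation = accumulation, gamma = gamma_report,
                 models = models, metrics = metrics, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
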