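# End-to-end orchestration: generate (or read) a cohort, engineer features,
# fit both stages, cluster trajectories, screen discriminants, and persist
# every intermediate artifact plus a JSON + Markdown report.

#' Pipeline configuration
#'
#' @param n_encounters Cohort size when generating synthetically.
#' @param out_dir Directory for all artifacts.
#' @param input_dir Optional directory with an existing cohort (from
#'   [write_cohort()]); when `NULL` a synthetic cohort is generated.
#' @param seed_generate,seed_cv,seed_kmeans Seeds for the generator, the
#'   cross-validation folds, and K-means restarts.
#' @param missing_threshold Missingness filter threshold (default 0.30).
#' @param alpha_remove Backward-elimination threshold (default 0.05).
#' @param alpha_kw Kruskal-Wallis screening threshold (default 0.001).
#' @param drop_threshold Centroid drop defining a decreasing cluster
#'   (default 0.15).
#' @param k Number of trajectory clusters (default 4).
#' @param folds Cross-validation folds (default 5).
#' @param n_restarts K-means restarts (default 50).
#' @param stage2_features `"selected"` (stage-1 selected set, default) or
#'   `"all"` (full retained pool).
#' @param generator Optional [generator_config()] overriding the default
#'   generator settings (its seed and size win over `seed_generate` /
#'   `n_encounters`).
#' @return Validated list of class `hf_pipeline_config`.
#' @export
pipeline_config <- function(n_encounters = 534,
                            out_dir = tempfile("hftraj_run_"),
                            input_dir = NULL,
                            seed_generate = 20130901L,
                            seed_cv = 11L,
                            seed_kmeans = 7L,
                            missing_threshold = 0.30,
                            alpha_remove = 0.05,
                            alpha_kw = 0.001,
                            drop_threshold = 0.15,
                            k = 4L,
                            folds = 5L,
                            n_restarts = 50L,
                            stage2_features = c("selected", "all"),
                            generator = NULL) {
  check_prob(missing_threshold, "missing_threshold")
  check_prob(alpha_remove, "alpha_remove")
  check_prob(alpha_kw, "alpha_kw")
  if (k < 1 || folds < 2 || n_restarts < 1) {
    stop_hf("k, folds and n_restarts out of range",
            class = "hftraj_validation_error")
  }
  structure(list(
    n_encounters = as.integer(n_encounters), out_dir = out_dir,
    input_dir = input_dir, seed_generate = as.integer(seed_generate),
    seed_cv = as.integer(seed_cv), seed_kmeans = as.integer(seed_kmeans),
    missing_threshold = missing_threshold, alpha_remove = alpha_remove,
    alpha_kw = alpha_kw, drop_threshold = drop_threshold,
    k = as.integer(k), folds = as.integer(folds),
    n_restarts = as.integer(n_restarts),
    stage2_features = match.arg(stage2_features),
    generator = generator
  ), class = "hf_pipeline_config")
}

#' Run the full dynamic readmission-risk pipeline
#'
#' Executes generate/read -> features -> stage-1 logistic (with 5-fold CV
#' AUC) -> counterfactual daily risks + KS beta check -> stage-2 beta
#' regression (with CV pseudo R-squared) -> trajectory K-means ->
#' Kruskal-Wallis discriminants, writing every intermediate table under
#' `config$out_dir` together with `report.json` and `report.md`. Idempotent
#' under fixed seeds.
#'
#' @param config An [pipeline_config()] object.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all fitted objects and the report.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (!inherits(config, "hf_pipeline_config")) {
    stop_hf("'config' must come from pipeline_config()",
            class = "hftraj_validation_error")
  }
  say <- function(...) if (!quiet) message("[hftraj] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage: cohort")
  truth <- NULL
  if (is.null(config$input_dir)) {
    gcfg <- config$generator
    if (is.null(gcfg)) {
      gcfg <- generator_config(config$n_encounters,
                               seed = config$seed_generate)
    }
    gen <- generate_cohort(gcfg)
    cohort <- gen$cohort
    truth <- gen$truth
    write_cohort(cohort, file.path(config$out_dir, "cohort"), truth)
  } else {
    cohort <- read_cohort(config$input_dir)
  }
  y <- cohort$outcomes$readmitted_30d[
    match(cohort$static$encounter_id, cohort$outcomes$encounter_id)]
  patient_days <- sum(ceiling(as.numeric(difftime(
    cohort$static$discharge_time, cohort$static$admission_time,
    units = "days"))))

  say("stage: features")
  discharge_rows <- build_feature_table(cohort, "discharge")
  fm <- assemble_matrix(discharge_rows, config$missing_threshold)
  utils::write.csv(fm$data, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(feature_names = fm$pipeline$feature_names,
         dropped_families = fm$pipeline$dropped_families,
         imputation_means = as.list(fm$pipeline$imputation_means),
         missing_threshold = fm$pipeline$missing_threshold),
    file.path(config$out_dir, "feature_pipeline.json"),
    auto_unbox = TRUE, digits = 10)

  say("stage: stage-1 logistic (", config$folds, "-fold CV)")
  cv <- cross_validate(discharge_rows, y, k = config$folds,
                       seed = config$seed_cv,
                       alpha_remove = config$alpha_remove,
                       missing_threshold = config$missing_threshold)
  fit1 <- backward_eliminate(design_matrix(fm$data), y,
                             alpha_remove = config$alpha_remove)
  jsonlite::write_json(
    list(selected = fit1$selected,
         coefficients = as.list(fit1$coefficients),
         se = as.list(fit1$se),
         odds_ratios = as.list(coefficient_to_odds_ratio(
           fit1$coefficients, digits = 2)),
         elimination_steps = nrow(fit1$trace),
         fold_auc = cv$fold_auc, auc_mean = cv$auc_mean,
         auc_sd = cv$auc_sd, seed = cv$seed),
    file.path(config$out_dir, "fit1.json"), auto_unbox = TRUE, digits = 10)

  say("stage: counterfactual daily risks (out-of-fold)")
  daily_rows <- build_feature_table(cohort, "milestones")
  daily_data <- apply_feature_pipeline(daily_rows, fm$pipeline)
  # Counterfactual targets come from the fold model that held each
  # encounter out, so both stages are developed under the same
  # cross-validation and the stage-2 regression is not handed its own
  # deterministic image of the stage-1 map.
  enc_fold <- stats::setNames(cv$fold_assignment,
                              cohort$static$encounter_id)
  day_fold <- unname(enc_fold[daily_rows$encounter_id])
  cf_risk <- numeric(nrow(daily_rows))
  for (j in seq_len(config$folds)) {
    in_j <- day_fold == j
    if (!any(in_j)) next
    dj <- apply_feature_pipeline(daily_rows[in_j, , drop = FALSE],
                                 cv$fold_pipelines[[j]])
    cf_risk[in_j] <- predict_encounter_risk(cv$fold_fits[[j]], dj)
  }
  cf <- data.frame(encounter_id = daily_rows$encounter_id,
                   milestone = daily_rows$milestone,
                   cutoff_hours = daily_rows$cutoff_hours,
                   counterfactual_risk = cf_risk,
                   stringsAsFactors = FALSE)
  # KS beta check on the held-out encounter-level first-stage risks
  ks <- ks_beta_check(cv$oof_scores)

  say("stage: stage-2 beta regression")
  s2_feats <- if (config$stage2_features == "selected" &&
                  length(fit1$selected) > 0) {
    fit1$selected
  } else fm$pipeline$feature_names
  X2 <- design_matrix(daily_data, s2_feats)
  target <- cf$counterfactual_risk
  fit2 <- fit_beta_regression(X2, target)

  # out-of-sample pseudo R-squared over the stage-1 encounter folds
  r2_folds <- vapply(seq_len(config$folds), function(j) {
    tr <- day_fold != j
    f2 <- fit_beta_regression(X2[tr, , drop = FALSE], target[tr])
    pseudo_r_squared(target[!tr],
                     predict_daily_risk(f2, X2[!tr, , drop = FALSE]))
  }, 0)

  daily_risk <- cf
  daily_risk$predicted_risk <- predict_daily_risk(fit2, X2)
  utils::write.csv(daily_risk,
                   file.path(config$out_dir, "daily_risk.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(coefficients = as.list(fit2$coefficients),
         phi = fit2$phi, pseudo_r2_insample = fit2$pseudo_r2,
         pseudo_r2_folds = r2_folds,
         pseudo_r2_cv_mean = mean(r2_folds),
         ks = ks, features = s2_feats),
    file.path(config$out_dir, "fit2.json"), auto_unbox = TRUE, digits = 10)

  say("stage: trajectory clustering (k = ", config$k, ")")
  traj <- build_trajectories(daily_risk)
  # inertia profile over k so the cluster-count choice is inspectable
  elbow <- vapply(2:6, function(kk) {
    kmeans_cluster(traj, k = kk, n_restarts = 10,
                   seed = config$seed_kmeans)$inertia
  }, 0)
  names(elbow) <- paste0("k", 2:6)
  clusters <- kmeans_cluster(traj, k = config$k,
                             n_restarts = config$n_restarts,
                             seed = config$seed_kmeans)
  clusters <- label_clusters(clusters, config$drop_threshold)
  cluster_label <- clusters$labels[as.character(clusters$assignments)]
  utils::write.csv(
    data.frame(encounter_id = names(clusters$assignments),
               cluster = unname(clusters$assignments),
               label = unname(cluster_label), stringsAsFactors = FALSE),
    file.path(config$out_dir, "clusters.csv"), row.names = FALSE)
  cen <- data.frame(cluster = seq_len(config$k),
                    label = unname(clusters$labels), clusters$centroids,
                    stringsAsFactors = FALSE)
  utils::write.csv(cen, file.path(config$out_dir, "centroids.csv"),
                   row.names = FALSE)

  say("stage: discriminant screening")
  named_assign <- stats::setNames(unname(cluster_label),
                                  names(clusters$assignments))
  kw <- screen_discriminants(fm$data, named_assign, alpha = config$alpha_kw)
  utils::write.csv(kw, file.path(config$out_dir, "kw.csv"),
                   row.names = FALSE)
  profiles <- temporal_profiles(daily_data, named_assign)
  utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
                   row.names = FALSE)

  sizes <- table(factor(unname(cluster_label),
                        levels = unname(clusters$labels)))
  report <- list(
    cohort = list(
      n_encounters = nrow(cohort$static),
      n_readmitted = sum(y),
      readmitted = format_fraction(sum(y), length(y)),
      patient_days = patient_days),
    features = list(
      n_features = length(fm$pipeline$feature_names),
      dropped_families = fm$pipeline$dropped_families,
      n_imputed = fm$n_imputed),
    stage1 = list(
      n_selected = length(fit1$selected),
      fold_auc = round(cv$fold_auc, 6),
      auc_mean = round(cv$auc_mean, 6), auc_sd = round(cv$auc_sd, 6)),
    stage2 = list(
      pseudo_r2_insample = round(fit2$pseudo_r2, 6),
      pseudo_r2_cv_mean = round(mean(r2_folds), 6),
      phi = round(fit2$phi, 4),
      ks = lapply(ks, function(v) round(v, 6))),
    clusters = list(
      k = config$k,
      inertia_by_k = round(elbow, 6),
      labels = unname(clusters$labels),
      sizes = as.integer(sizes),
      proportions = vapply(as.integer(sizes), function(s)
        format_fraction(s, length(y)), ""),
      centroids = round(clusters$centroids, 4)),
    discriminants = list(
      n_selected = sum(kw$selected),
      top = utils::head(kw$feature, 10)),
    seeds = list(generate = config$seed_generate, cv = config$seed_cv,
                 kmeans = config$seed_kmeans),
    thresholds = list(missing = config$missing_threshold,
                      alpha_remove = config$alpha_remove,
                      alpha_kw = config$alpha_kw,
                      drop = config$drop_threshold)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10)
  writeLines(render_report_md(report),
             file.path(config$out_dir, "report.md"))
  say("done: ", config$out_dir)

  invisible(list(config = config, cohort = cohort, truth = truth,
                 feature_matrix = fm, cv = cv, fit1 = fit1,
                 daily_risk = daily_risk, ks = ks, fit2 = fit2,
                 r2_folds = r2_folds, trajectories = traj,
                 clusters = clusters, kw = kw, profiles = profiles,
                 report = report))
}

render_report_md <- function(r) {
  c("# Dynamic readmission-risk pipeline report",
    "",
    "## Cohort",
    sprintf("- encounters: %d (%s readmitted), %d patient days",
            r$cohort$n_encounters, r$cohort$readmitted,
            r$cohort$patient_days),
    "",
    "## Stage 1 (encounter-level logistic)",
    sprintf("- selected predictors: %d", r$stage1$n_selected),
    sprintf("- out-of-sample AUC: %.3f (SD %.3f)", r$stage1$auc_mean,
            r$stage1$auc_sd),
    "",
    "## Stage 2 (daily beta regression)",
    sprintf("- pseudo R-squared: %.3f in-sample, %.3f CV",
            r$stage2$pseudo_r2_insample, r$stage2$pseudo_r2_cv_mean),
    sprintf("- precision phi: %.2f; KS vs fitted Beta(%.2f, %.2f): D = %.4f, p = %.3f",
            r$stage2$phi, r$stage2$ks$alpha, r$stage2$ks$beta,
            r$stage2$ks$statistic, r$stage2$ks$p_value),
    "",
    "## Trajectory clusters",
    sprintf("- %s: %s", r$clusters$labels, r$clusters$proportions),
    "",
    "## Discriminant predictors",
    sprintf("- %d features at the screening threshold; top: %s",
            r$discriminants$n_selected,
            paste(utils::head(r$discriminants$top, 5), collapse = ", ")))
}
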