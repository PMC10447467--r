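# End-to-end orchestration: simulate -> preprocess -> train -> predict ->
# evaluate -> chemo-benefit -> immuno-response, with a reproducibility
# manifest (config hash, per-stage output hashes, timestamps). A stage failure
# is recorded and downstream stages are skipped.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed (generator and training seeds derive from it).
#' @param n_subjects Cohort size.
#' @param backbone Network backbone (`"tiny"` for CPU-scale runs).
#' @param epochs Training epochs.
#' @param train_fraction Fraction of subjects in the training split.
#' @param horizon Evaluation horizon in months.
#' @param pec_B Bootstrap resamples for the .632+ prediction-error curves.
#' @param augment Apply the default augmentation policy during training.
#' @return A nested configuration list.
#' @export
default_run_config <- function(out_dir, seed = 20230823L, n_subjects = 100L,
                               backbone = "tiny", epochs = 30L,
                               train_fraction = 0.7, horizon = 36,
                               pec_B = 50L, augment = FALSE) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    generator = list(n_subjects = as.integer(n_subjects)),
    network = list(backbone = backbone, epochs = as.integer(epochs)),
    train_fraction = train_fraction,
    evaluation = list(horizon = horizon, pec_B = as.integer(pec_B)),
    augment = augment,
    psm_covariates = c("age", "sex", "differentiation", "cea", "ca19_9",
                       "location", "t_stage", "n_stage", "size_cm", "lauren")
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing fields fall back to [default_run_config()]
#'   defaults (`out_dir` must be present in the file or supplied).
#' @param out_dir Optional override of the output directory.
#' @return Configuration list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  usr <- yaml::read_yaml(path)
  if (is.null(out_dir)) out_dir <- usr$out_dir
  if (is.null(out_dir)) stop("out_dir must be given in the config or as argument")
  cfg <- default_run_config(out_dir)
  modify <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  modify(cfg, usr)
}

hash_file <- function(path) unname(tools::md5sum(path))

hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  hash_file(tmp)
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order and writes a
#' reproducibility manifest (`run_manifest.json`) with the config hash and
#' per-stage output hashes. On a stage failure the manifest marks the failure
#' point and downstream stages are skipped.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param stages `"all"` or a subset of `c("simulate", "preprocess", "train",
#'   "predict", "evaluate", "chemo_benefit", "immuno_response")`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  all_stages <- c("simulate", "preprocess", "train", "predict",
                  "evaluate", "chemo_benefit", "immuno_response")
  if (identical(stages, "all")) stages <- all_stages
  stages <- all_stages[all_stages %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(config_hash = hash_config(config),
                   package_version = as.character(utils::packageVersion("tmesurv")),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  failed <- FALSE
  for (st in stages) {
    if (failed) {
      manifest$stages[[st]] <- list(status = "skipped")
      next
    }
    res <- tryCatch({
      files <- do.call(paste0("stage_", st), list(config))
      list(status = "ok",
           outputs = as.list(stats::setNames(vapply(files, hash_file, character(1)),
                                             basename(files))))
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    manifest$stages[[st]] <- res
    if (!identical(res$status, "ok")) failed <- TRUE
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(config) {
  gen <- do.call(generator_config,
                 c(config$generator, list(seed = config$seed)))
  cdir <- file.path(config$out_dir, "cohort")
  generate_cohort(gen, out_dir = cdir)
  file.path(cdir, "manifest.csv")
}

stage_preprocess <- function(config) {
  cdir <- file.path(config$out_dir, "cohort")
  cohort <- utils::read.csv(file.path(cdir, "manifest.csv"))
  n <- nrow(cohort)
  stacks <- array(0, c(n, 5L, 160L, 160L))
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    v <- read_volume_nifti(cohort$volume_path[i])
    m <- read_volume_nifti(cohort$mask_path[i])
    st <- preprocess_subject(v, m)
    stacks[i, , , ] <- st$planes
    meta[[i]] <- list(subject_id = cohort$subject_id[i],
                      source_slice_indices = st$source_slice_indices,
                      crop_center = unname(st$crop_center))
  }
  p1 <- file.path(config$out_dir, "stacks.rds")
  p2 <- file.path(config$out_dir, "stacks_meta.json")
  saveRDS(stacks, p1)
  jsonlite::write_json(meta, p2, auto_unbox = TRUE, digits = NA)
  c(p1, p2)
}

pipeline_splits <- function(config, cohort) {
  n_train <- max(2L, ceiling(config$train_fraction * nrow(cohort)))
  list(train = seq_len(n_train),
       valid = if (n_train < nrow(cohort)) (n_train + 1L):nrow(cohort) else integer(0))
}

stage_train <- function(config) {
  out <- config$out_dir
  cohort <- utils::read.csv(file.path(out, "cohort", "manifest.csv"))
  stacks <- readRDS(file.path(out, "stacks.rds"))
  sp <- pipeline_splits(config, cohort)

  # IHC ground truth: thresholds fitted on the training split only
  thr <- fit_tme_thresholds(cohort$is_gc[sp$train], cohort$postn_score[sp$train],
                            cohort_id = "train")
  labels <- assign_tme_class(cohort$is_gc, cohort$postn_score, thr)
  write_tme_thresholds(thr, file.path(out, "tme_thresholds.json"))
  utils::write.csv(data.frame(subject_id = cohort$subject_id, tme_class = labels),
                   file.path(out, "tme_labels.csv"), row.names = FALSE)

  ncfg <- do.call(network_config,
                  c(config$network, list(seed = config$seed)))
  pol <- if (isTRUE(config$augment)) augment_policy() else NULL
  set.seed(config$seed)
  net <- train_network(ncfg, stacks[sp$train, , , , drop = FALSE],
                       labels[sp$train], cohort$time[sp$train],
                       cohort$event[sp$train], augment = pol)
  ck <- file.path(out, "checkpoint.rds")
  save_checkpoint(net, ck)
  utils::write.csv(net$history, file.path(out, "training_history.csv"),
                   row.names = FALSE)
  c(ck, file.path(out, "training_history.csv"),
    file.path(out, "tme_thresholds.json"), file.path(out, "tme_labels.csv"))
}

stage_predict <- function(config) {
  out <- config$out_dir
  cohort <- utils::read.csv(file.path(out, "cohort", "manifest.csv"))
  stacks <- readRDS(file.path(out, "stacks.rds"))
  net <- load_checkpoint(file.path(out, "checkpoint.rds"))
  pred <- predict_network(net, stacks, subject_id = cohort$subject_id)
  p <- file.path(out, "predictions.csv")
  utils::write.csv(pred, p, row.names = FALSE)
  p
}

stage_evaluate <- function(config) {
  out <- config$out_dir
  cohort <- utils::read.csv(file.path(out, "cohort", "manifest.csv"))
  labels <- utils::read.csv(file.path(out, "tme_labels.csv"))$tme_class
  pred <- utils::read.csv(file.path(out, "predictions.csv"))
  sp <- pipeline_splits(config, cohort)
  va <- if (length(sp$valid) >= 10L) sp$valid else seq_len(nrow(cohort))
  horizon <- min(config$evaluation$horizon, max(cohort$time[va]) * 0.9,
                 max(cohort$time[sp$train]) * 0.9)

  # classification accuracy on the held-out split
  rep_cls <- classification_report(labels[va], pred$predicted_class[va],
                                   as.matrix(pred[va, paste0("p_class", 1:4)]))

  # prognosis: frozen training-median DLS cutoff, KM/log-rank, Cox, tdROC, C
  cutoff <- risk_cutoff(pred$dls[sp$train], "train")
  grp <- apply_risk_groups(pred$dls[va], cutoff)
  lr <- tryCatch(log_rank_test(cohort$time[va], cohort$event[va], grp),
                 error = function(e) list(statistic = NA, p = NA))
  cx <- tryCatch(cox_fit(cohort$time[va], cohort$event[va],
                         data.frame(dls = pred$dls[va])),
                 error = function(e) NULL)
  roc <- tryCatch(time_dependent_roc(pred$dls[va], cohort$time[va],
                                     cohort$event[va], horizon),
                  error = function(e) NULL)
  cidx <- tryCatch(concordance_index(pred$dls[va], cohort$time[va], cohort$event[va]),
                   error = function(e) NA_real_)

  # calibration: training-fitted Cox on DLS -> predicted survival at horizon
  train_df <- data.frame(time = cohort$time[sp$train], event = cohort$event[sp$train],
                         dls = pred$dls[sp$train])
  cal <- tryCatch({
    cfit <- survival::coxph(survival::Surv(time, event) ~ dls, data = train_df,
                            ties = "breslow")
    sv <- cox_surv_matrix(cfit, data.frame(dls = pred$dls[va]), horizon)
    calibration_curve(sv[, 1], cohort$time[va], cohort$event[va], horizon)
  }, error = function(e) NULL)

  # prediction-error curves for nested models on the full cohort
  pec_df <- data.frame(time = cohort$time, event = cohort$event,
                       dls = pred$dls, t_stage = cohort$t_stage,
                       n_stage = cohort$n_stage, m_stage = cohort$m_stage,
                       cea = cohort$cea, location = cohort$location,
                       differentiation = cohort$differentiation)
  grid <- seq(6, floor(horizon), by = 6)
  pec <- tryCatch(prediction_error_632plus(
    list(stage_only = ~ t_stage + n_stage + m_stage,
         clinical = ~ t_stage + n_stage + m_stage + cea + location + differentiation,
         dls = ~ dls,
         integrated = ~ dls + t_stage + n_stage + m_stage + cea + location + differentiation),
    pec_df, grid, B = config$evaluation$pec_B), error = function(e) NULL)

  imodel <- tryCatch(integrated_model(pec_df), error = function(e) NULL)
  imp <- if (!is.null(imodel)) tryCatch(chi2_importance(imodel$fit),
                                        error = function(e) NULL) else NULL

  metrics <- list(
    horizon = horizon,
    classification = list(accuracy = rep_cls$accuracy,
                          accuracy_ci = rep_cls$accuracy_ci,
                          per_class = rep_cls$per_class),
    prognosis = list(
      dls_cutoff = cutoff$cutoff,
      logrank = lr[c("statistic", "p")],
      cox_dls = if (!is.null(cx)) cx$coefficients else NULL,
      auc_t = if (!is.null(roc)) roc$auc else NA,
      c_index = cidx),
    ibs = if (!is.null(pec)) lapply(pec, `[[`, "ibs") else NULL,
    chi2_importance = imp)
  p1 <- file.path(out, "metrics.json")
  jsonlite::write_json(metrics, p1, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- p1
  if (!is.null(roc)) {
    p <- file.path(out, "roc_curve.csv")
    utils::write.csv(roc$curve, p, row.names = FALSE); files <- c(files, p)
  }
  if (!is.null(cal)) {
    p <- file.path(out, "calibration.csv")
    utils::write.csv(cal, p, row.names = FALSE); files <- c(files, p)
  }
  if (!is.null(pec)) {
    p <- file.path(out, "prediction_error.csv")
    pcurves <- do.call(rbind, lapply(names(pec), function(nm)
      cbind(model = nm, pec[[nm]]$curve)))
    utils::write.csv(pcurves, p, row.names = FALSE); files <- c(files, p)
  }
  files
}

stage_chemo_benefit <- function(config) {
  out <- config$out_dir
  cohort <- utils::read.csv(file.path(out, "cohort", "manifest.csv"),
                            stringsAsFactors = TRUE)
  pred <- utils::read.csv(file.path(out, "predictions.csv"))
  set.seed(config$seed + 1L)
  ps <- fit_propensity(cohort[, config$psm_covariates], cohort$chemo)
  mt <- match_1to1_nearest(ps, cohort$chemo,
                           covariates = cohort[, config$psm_covariates])
  mi <- mt$matched
  effects <- lapply(1:4, function(k) {
    sel <- mi[pred$predicted_class[mi] == k]
    tryCatch({
      e <- stratum_treatment_effect(cohort$time[sel], cohort$event[sel],
                                    cohort$chemo[sel])
      list(class = k, n = e$n, hr = e$hr, lower = e$ci[1], upper = e$ci[2],
           p = e$p, logrank_p = e$logrank_p)
    }, error = function(err) list(class = k, n = length(sel),
                                  error = conditionMessage(err)))
  })
  it <- tryCatch({
    z <- interaction_test(cohort$time[mi], cohort$event[mi],
                          as.numeric(pred$predicted_class[mi] %in% c(3, 4)),
                          cohort$chemo[mi])
    z[c("coef", "se", "p")]
  }, error = function(e) list(error = conditionMessage(e)))

  p1 <- file.path(out, "chemo_benefit.json")
  jsonlite::write_json(list(n_matched_pairs = nrow(mt$pairs),
                            per_class = effects, interaction = it),
                       p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p2 <- file.path(out, "matched_pairs.csv")
  utils::write.csv(mt$pairs, p2, row.names = FALSE)
  p3 <- file.path(out, "balance_table.csv")
  utils::write.csv(mt$balance, p3, row.names = FALSE)
  c(p1, p2, p3)
}

stage_immuno_response <- function(config) {
  out <- config$out_dir
  cohort <- utils::read.csv(file.path(out, "cohort", "manifest.csv"))
  pred <- utils::read.csv(file.path(out, "predictions.csv"))
  df <- data.frame(predicted_class = pred$predicted_class,
                   cps = cohort$cps, response = cohort$response)
  rep <- response_report(df)
  p1 <- file.path(out, "immuno_response.json")
  jsonlite::write_json(list(orr_overall = rep$orr_overall,
                            orr_by_class = as.list(rep$orr_by_class),
                            orr_by_cps = as.list(rep$orr_by_cps),
                            auc = as.list(rep$auc),
                            delong_composite_vs_cps =
                              rep$delong_composite_vs_cps[c("delta_auc", "p")],
                            leaf_table = rep$tree$leaf_table),
                       p1, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p2 <- file.path(out, "response_tree.txt")
  if (!is.null(rep$tree$fit)) {
    utils::capture.output(print(rep$tree$fit), file = p2)
  } else writeLines("trivial stump (single-class outcome)", p2)
  c(p1, p2)
}
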