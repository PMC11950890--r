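# Pipeline commands tying the modules into one workflow:
# simulate -> compute markers -> statistical reports -> CNN train/eval.
# Each command writes a JSON run manifest alongside its outputs.

#' Read a YAML pipeline configuration
#'
#' Recognized fields (all optional; defaults shown by
#' [default_pipeline_config()]): `seed`, `shape`, `n_controls`, `delta`,
#' `group_sizes`, `modalities`, `cutoffs` (named per modality),
#' `directions` (named per modality), `amyloid_threshold`, and a `cnn`
#' block (epochs, channels, lr, batch_size, val_fraction). Unknown fields
#' pass through untouched.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- c()
    for (nm in names(user)) {
      if (nm == "cnn" && is.list(user[[nm]]))
        cfg$cnn[names(user$cnn)] <- user$cnn
      else cfg[[nm]] <- user[[nm]]
    }
    for (nm in c("seed", "n_controls", "delta"))
      if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1)
        bad <- c(bad, nm)
    at <- cfg$amyloid_threshold
    if (!(identical(at, "auto") || (is.numeric(at) && length(at) == 1)))
      bad <- c(bad, "amyloid_threshold")
    if (length(bad) > 0)
      stop("usage error: invalid config field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  list(seed = 1L, shape = c(32L, 32L, 32L), n_controls = 40L, delta = 5,
       group_sizes = c(CN = 30L, SCD = 30L, MCI = 30L, dementia = 30L),
       modalities = c("amyloid", "tau", "neurodegeneration"),
       cutoffs = c(amyloid = 1.65, tau = 1.65, neurodegeneration = -1.65),
       directions = c(amyloid = "greater", tau = "greater",
                      neurodegeneration = "less"),
       amyloid_threshold = "auto",
       cnn = list(epochs = 30L, channels = c(8L, 16L, 32L), lr = 3e-3,
                  batch_size = 16L, val_fraction = 0.3))
}

pipeline_phantom_config <- function(cfg) {
  phantom_config(shape = cfg$shape, n_controls = cfg$n_controls,
                 delta = cfg$delta, seed = cfg$seed)
}

write_manifest <- function(out_dir, command, cfg, inputs = list()) {
  hashes <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  manifest <- list(command = command, config = cfg, input_md5 = hashes,
                   version = as.character(utils::packageVersion("fillstate")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a synthetic phantom cohort to disk
#'
#' @param out_dir Output directory (created if needed): per-subject NIfTI
#'   volumes, masks, `cohort.csv`, `manifest.json`.
#' @param config Pipeline configuration list (see
#'   [read_pipeline_config()]).
#' @return The cohort data frame, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = default_pipeline_config()) {
  pc <- pipeline_phantom_config(config)
  res <- generate_cohort(pc, group_sizes = unlist(config$group_sizes),
                         modalities = config$modalities, dir = out_dir,
                         amyloid_threshold = config$amyloid_threshold)
  write_manifest(out_dir, "simulate", config)
  invisible(res$cohort)
}

#' Compute fill-state markers for a cohort directory
#'
#' Fits one control model per modality from the amyloid-negative CN
#' subjects, then computes the marker set (fill state, SUVR,
#' abnormal-voxel intensity) for every non-control subject and modality.
#'
#' @param cohort_dir Directory produced by [cmd_simulate()] (or laid out
#'   the same way: `<subject>_<modality>.nii.gz`, `mask_roi.nii.gz`,
#'   `cohort.csv`).
#' @param out_csv Output marker CSV path.
#' @param config Pipeline configuration list.
#' @return The marker data frame, invisibly.
#' @export
cmd_compute <- function(cohort_dir, out_csv, config = default_pipeline_config()) {
  cohort <- utils::read.csv(file.path(cohort_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  is_control <- cohort$group == "CN" & cohort$amyloid_status == "negative"
  if (!any(is_control))
    stop("no amyloid-negative CN controls in cohort", call. = FALSE)
  roi <- read_mask(file.path(cohort_dir, "mask_roi.nii.gz"), "meta-ROI")
  patients <- cohort$subject_id[!is_control]
  vol_path <- function(id, m) {
    p <- file.path(cohort_dir, sprintf("%s_%s.nii.gz", id, m))
    if (!file.exists(p))
      stop("missing volume file for subject ", id, " (", m, "): ", p,
           call. = FALSE)
    p
  }
  all_rows <- list()
  for (m in config$modalities) {
    ctl_vols <- lapply(cohort$subject_id[is_control],
                       function(id) read_volume(vol_path(id, m), modality = m))
    model <- fit_control_model(ctl_vols, modality = m)
    markers <- lapply(patients, function(id) {
      subj <- read_volume(vol_path(id, m), modality = m)
      compute_markers(subj, model, roi,
                      cutoff = config$cutoffs[[m]],
                      direction = config$directions[[m]])
    })
    names(markers) <- patients
    if (length(markers) > 0) all_rows[[m]] <- marker_table(markers)
  }
  out <- if (length(all_rows) > 0) do.call(rbind, all_rows) else
    data.frame(subject_id = character(0), modality = character(0),
               roi_label = character(0), cutoff = numeric(0),
               direction = character(0), fill_state_pct = numeric(0),
               suvr = numeric(0), abnormal_intensity = numeric(0),
               n_roi_voxels = integer(0), n_abnormal_voxels = integer(0))
  rownames(out) <- NULL
  utils::write.csv(out, out_csv, row.names = FALSE)
  write_manifest(dirname(out_csv), "compute", config,
                 inputs = list(cohort = file.path(cohort_dir, "cohort.csv")))
  invisible(out)
}

#' Run the full marker-comparison report bundle
#'
#' Joins the marker table with the cohort table and emits, per modality:
#' the staging table (Kruskal-Wallis across SCD/MCI/dementia with post hoc
#' pairwise Mann-Whitney tests), the paired ROC/DeLong comparison of fill
#' state vs SUVR for impairment (MCI + dementia vs SCD), the partial
#' Spearman correlations of each marker with each cognitive score adjusted
#' for age, sex, and education, and regression models 1-3 (per-modality:
#' score block ~ fill state + SUVR + age + sex + education) plus model 4
#' (score block ~ all fill states + age + sex + education). Significance is
#' flagged at the three conventional tiers (alpha = .05,
#' Bonferroni-corrected alpha, alpha = .001).
#'
#' @param markers_csv Marker CSV from [cmd_compute()].
#' @param cohort_csv Cohort CSV.
#' @param out_dir Report output directory.
#' @param config Pipeline configuration list.
#' @param scores Cognitive score columns to analyze.
#' @return List of report data frames, invisibly (also written as CSV/JSON
#'   under `out_dir`).
#' @export
cmd_stats <- function(markers_csv, cohort_csv, out_dir,
                      config = default_pipeline_config(),
                      scores = c("score_global", "score_memory",
                                 "score_executive")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  markers <- utils::read.csv(markers_csv, stringsAsFactors = FALSE)
  cohort <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  joined <- merge(markers, cohort, by = "subject_id")
  joined <- joined[joined$group %in% c("SCD", "MCI", "dementia"), ]
  modalities <- intersect(config$modalities, unique(joined$modality))
  alpha_bonf <- bonferroni(0.05, 3)$alpha_display
  tiers <- function(p) ifelse(p < 0.001, "p<.001",
                       ifelse(p < alpha_bonf, "bonferroni",
                       ifelse(p < 0.05, "p<.05", "ns")))
  skipped <- character(0)

  staging <- list(); rocs <- list(); cors <- list()
  for (m in modalities) {
    dm <- joined[joined$modality == m, ]
    for (marker in c("fill_state_pct", "suvr")) {
      grp_n <- table(dm$group)
      if (length(grp_n) < 2) {
        skipped <- c(skipped, paste("staging", m, marker))
        next
      }
      kw <- kruskal_wallis(dm[[marker]], dm$group)
      staging[[paste(m, marker, "omnibus")]] <- data.frame(
        modality = m, marker = marker, test = "kruskal-wallis",
        comparison = "SCD|MCI|dementia", statistic = kw$H,
        p_value = kw$p_value, n = kw$n, tier = tiers(kw$p_value))
      pairs <- utils::combn(intersect(c("SCD", "MCI", "dementia"),
                                      names(grp_n)), 2, simplify = FALSE)
      for (pr in pairs) {
        mw <- mann_whitney(dm[[marker]][dm$group == pr[1]],
                           dm[[marker]][dm$group == pr[2]],
                           exact_max_n = 0L)
        staging[[paste(m, marker, pr[1], pr[2])]] <- data.frame(
          modality = m, marker = marker, test = "mann-whitney",
          comparison = paste(pr, collapse = " vs "), statistic = mw$U,
          p_value = mw$p_value, n = mw$n1 + mw$n2, tier = tiers(mw$p_value))
      }
    }
    # impairment (MCI + dementia) vs no impairment (SCD)
    impaired <- dm$group %in% c("MCI", "dementia")
    fs <- dm$fill_state_pct  # higher fill state = more pathology, both directions
    sv <- if (config$directions[[m]] == "less") -dm$suvr else dm$suvr
    if (any(impaired) && any(!impaired)) {
      dl <- delong_test(fs, sv, impaired)
      rocs[[m]] <- data.frame(
        modality = m, auc_fill_state = dl$auc_a, auc_suvr = dl$auc_b,
        delong_z = dl$delong_z, p_value = dl$p_value,
        n_impaired = dl$n_pos, n_unimpaired = dl$n_neg,
        tier = tiers(dl$p_value))
    } else skipped <- c(skipped, paste("roc", m))
    covs <- dm[, c("age", "sex", "education")]
    for (marker in c("fill_state_pct", "suvr")) for (sc in scores) {
      ps <- partial_spearman(dm[[marker]], dm[[sc]], covs)
      cors[[paste(m, marker, sc)]] <- data.frame(
        modality = m, marker = marker, score = sc, rho = ps$rho,
        p_value = ps$p_value, n = ps$n, tier = tiers(ps$p_value))
    }
  }

  # regression models 1-3 (one per modality) and model 4 (all fill states)
  wide <- stats::reshape(
    joined[, c("subject_id", "modality", "fill_state_pct", "suvr")],
    direction = "wide", idvar = "subject_id", timevar = "modality")
  wide <- merge(wide, cohort, by = "subject_id")
  regression <- list()
  for (i in seq_along(modalities)) {
    m <- modalities[i]
    terms <- c(paste0("fill_state_pct.", m), paste0("suvr.", m),
               "age", "sex", "education")
    ok <- all(terms %in% names(wide))
    if (!ok) { skipped <- c(skipped, paste("model", i)); next }
    fit <- tryCatch(fit_regression(wide, scores, terms),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, paste("model", i)); next }
    mv <- fit$multivariate
    mv$model <- paste0("model", i)
    mv$tier <- tiers(mv$p_value)
    regression[[paste0("model", i)]] <- mv
  }
  fs_terms <- paste0("fill_state_pct.", modalities)
  if (all(fs_terms %in% names(wide))) {
    fit4 <- tryCatch(
      fit_regression(wide, scores, c(fs_terms, "age", "sex", "education")),
      error = function(e) NULL)
    if (!is.null(fit4)) {
      mv <- fit4$multivariate
      mv$model <- "model4"
      mv$tier <- tiers(mv$p_value)
      regression[["model4"]] <- mv
    } else skipped <- c(skipped, "model 4")
  }

  reports <- list(staging = do.call(rbind, c(staging, list(make.row.names = FALSE))),
                  roc_delong = do.call(rbind, c(rocs, list(make.row.names = FALSE))),
                  partial_correlations = do.call(rbind, c(cors, list(make.row.names = FALSE))),
                  regression = do.call(rbind, c(regression, list(make.row.names = FALSE))))
  for (nm in names(reports))
    if (!is.null(reports[[nm]]))
      utils::write.csv(reports[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  jsonlite::write_json(
    list(alpha_tiers = list(alpha = 0.05, bonferroni = alpha_bonf,
                            strict = 0.001),
         skipped_analyses = skipped),
    file.path(out_dir, "report_meta.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_manifest(out_dir, "stats", config,
                 inputs = list(markers = markers_csv, cohort = cohort_csv))
  if (length(skipped) > 0)
    message("skipped analyses: ", paste(skipped, collapse = "; "))
  invisible(reports)
}

#' Train the CNN estimator from a simulated cohort directory
#'
#' Uses ground-truth fill states computed against the phantom's true
#' (population) control model as training labels, then trains the CNN for
#' the requested modality.
#'
#' @param cohort_dir Directory from [cmd_simulate()].
#' @param out_checkpoint Checkpoint path (`.rds`).
#' @param config Pipeline configuration list.
#' @param modality Modality to train on.
#' @return The trained `fill_estimator`, invisibly.
#' @export
cmd_cnn_train <- function(cohort_dir, out_checkpoint,
                          config = default_pipeline_config(),
                          modality = "tau") {
  cohort <- utils::read.csv(file.path(cohort_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  roi <- read_mask(file.path(cohort_dir, "mask_roi.nii.gz"), "meta-ROI")
  pc <- pipeline_phantom_config(config)
  model <- true_control_model(pc, modality = modality)
  volumes <- list(); labels <- numeric(0)
  for (id in cohort$subject_id) {
    vol <- read_volume(file.path(cohort_dir,
                                 sprintf("%s_%s.nii.gz", id, modality)),
                       modality = modality)
    mk <- compute_markers(vol, model, roi,
                          cutoff = config$cutoffs[[modality]],
                          direction = config$directions[[modality]])
    volumes[[id]] <- vol
    labels <- c(labels, mk$fill_state)
  }
  cc <- cnn_config(input_shape = config$shape,
                   channels = config$cnn$channels, lr = config$cnn$lr,
                   batch_size = config$cnn$batch_size,
                   epochs = config$cnn$epochs,
                   val_fraction = config$cnn$val_fraction,
                   seed = config$seed)
  est <- train_estimator(volumes, labels, cc)
  save_estimator(est, out_checkpoint)
  invisible(est)
}

#' Evaluate a trained CNN estimator on a cohort directory
#'
#' @param checkpoint Checkpoint from [cmd_cnn_train()].
#' @param cohort_dir Cohort directory with volumes and `cohort.csv`.
#' @param out_prefix Output prefix: writes `<prefix>_pairs.csv` and
#'   `<prefix>_report.json`.
#' @param config Pipeline configuration list.
#' @param modality Modality to evaluate.
#' @return The evaluation report list, invisibly.
#' @export
cmd_cnn_eval <- function(checkpoint, cohort_dir, out_prefix,
                         config = default_pipeline_config(),
                         modality = "tau") {
  est <- load_estimator(checkpoint)
  cohort <- utils::read.csv(file.path(cohort_dir, "cohort.csv"),
                            stringsAsFactors = FALSE)
  roi <- read_mask(file.path(cohort_dir, "mask_roi.nii.gz"), "meta-ROI")
  pc <- pipeline_phantom_config(config)
  model <- true_control_model(pc, modality = modality)
  volumes <- list(); truth <- numeric(0)
  for (id in cohort$subject_id) {
    vol <- read_volume(file.path(cohort_dir,
                                 sprintf("%s_%s.nii.gz", id, modality)),
                       modality = modality)
    mk <- compute_markers(vol, model, roi,
                          cutoff = config$cutoffs[[modality]],
                          direction = config$directions[[modality]])
    volumes[[id]] <- vol
    truth <- c(truth, mk$fill_state)
  }
  rep <- evaluate_estimator(est, volumes, truth)
  pairs <- cbind(subject_id = cohort$subject_id, rep$pairs)
  utils::write.csv(pairs, paste0(out_prefix, "_pairs.csv"), row.names = FALSE)
  jsonlite::write_json(list(mae = rep$mae, r2 = rep$r2, n = nrow(pairs),
                            modality = modality),
                       paste0(out_prefix, "_report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(rep)
}
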