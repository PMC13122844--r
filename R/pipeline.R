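#' Pipeline configuration
#'
#' Bundles the settings of a full run: the synthetic cohort (or paths to
#' NIfTI volumes plus a clinical CSV), the filter band, localizer top-k,
#' rSRM and classifier settings, and PLSR settings.
#'
#' @param cohort a [cohort_config()] for a simulated run, or `NULL` when
#'   reading data from disk.
#' @param bold_paths named character vector of 4-D NIfTI paths per
#'   subject (ignored when `cohort` is given).
#' @param groups named `"ALS"`/`"CTL"` vector (disk runs only).
#' @param clinical_path clinical CSV path (disk runs only).
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param top_k localizer mask size per condition (voxels).
#' @param srm_k,srm_gamma,srm_max_iter rSRM settings.
#' @param svm_c SVM cost.
#' @param plsr_L PLSR components.
#' @param seed master seed for model initializations.
#' @param out_dir output directory for CSV/JSON summaries (`NULL` for
#'   none).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), bold_paths = NULL,
                            groups = NULL, clinical_path = NULL,
                            low_hz = 0.01, high_hz = 0.1,
                            top_k = 27L, srm_k = 5L, srm_gamma = NULL,
                            srm_max_iter = 100L, svm_c = 1, plsr_L = 2L,
                            seed = 1L, out_dir = NULL) {
  if (is.null(cohort) &&
      (is.null(bold_paths) || is.null(groups) || is.null(clinical_path)))
    fp_stop("funcphen_bad_config",
            "need either a cohort config or bold_paths + groups + clinical_path")
  if (top_k < 1L || srm_k < 1L || plsr_L < 1L || svm_c <= 0)
    fp_stop("funcphen_bad_config", "numeric settings out of range")
  structure(list(cohort = cohort, bold_paths = bold_paths, groups = groups,
                 clinical_path = clinical_path, low_hz = low_hz,
                 high_hz = high_hz, top_k = as.integer(top_k),
                 srm_k = as.integer(srm_k), srm_gamma = srm_gamma,
                 srm_max_iter = as.integer(srm_max_iter), svm_c = svm_c,
                 plsr_L = as.integer(plsr_L), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fp_stop("funcphen_stage_failure", "stage '%s' failed [%s]: %s",
            name, paste(setdiff(class(e), c("error", "condition")),
                        collapse = ","),
            conditionMessage(e))
  })
}

# deterministic string hash for the manifest
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Sequences simulate (or read) -> band-pass -> synchronize -> localize
#' (GLM t-maps, top-k masks, group intersection masks, combined mask) ->
#' connectivity (ECM, seed maps, stage contrasts) -> rSRM dual-space LOSO
#' classification with the first-affected contrast -> PLSR (ECM vs
#' ALSFRS-R and masked time series vs PUMNS). When `config$out_dir` is
#' set, CSV summaries and a JSON manifest (package version, seed, config
#' hash) are written there; a rerun with the same config is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return a report list with elements `masks`, `ecm_maps`,
#'   `stage_contrasts`, `folds`, `accuracy`, `affected`, `plsr_alsfrs`,
#'   `plsr_pumns`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  sim <- .stage("simulate", {
    if (!is.null(config$cohort)) {
      cohort <- generate_cohort(config$cohort)
      list(bold = cohort$bold, groups = cohort$groups,
           records = cohort$clinical, schedules = cohort$truth$schedules)
    } else {
      bold <- lapply(names(config$bold_paths), function(id)
        read_bold(config$bold_paths[[id]], subject_id = id))
      names(bold) <- names(config$bold_paths)
      records <- read_clinical_table(config$clinical_path)
      sched <- lapply(bold, function(s)
        generate_design(cohort_config(seed = config$seed)))
      list(bold = bold, groups = config$groups, records = records,
           schedules = sched)
    }
  })

  filt <- .stage("preprocess", lapply(sim$bold, bandpass,
                                      low_hz = config$low_hz,
                                      high_hz = config$high_hz))
  synced <- .stage("preprocess", {
    out <- Map(synchronize_blocks, filt, sim$schedules[names(filt)])
    names(out) <- names(filt)
    out
  })

  loc <- .stage("localize", {
    glms <- Map(fit_glm, filt, sim$schedules[names(filt)])
    grid <- sim$bold[[1]]$grid
    cond_masks <- lapply(stats::setNames(CONDITIONS, CONDITIONS),
                         function(cond) {
      subj <- lapply(glms, function(g)
        top_k_mask(g$tmaps[[cond]], config$top_k, grid))
      group_mask(subj)
    })
    comb <- combined_mask(cond_masks)
    # seed centre per condition: the peak mean-t voxel of its group mask
    seeds <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cond) {
      m <- cond_masks[[cond]]
      key <- function(v) paste(v[, 1], v[, 2], v[, 3])
      mean_t <- Reduce(`+`, lapply(glms, function(g) {
        pos <- match(key(m$voxel_index), key(g$voxel_index))
        g$tmaps[[cond]]$values[pos]
      })) / length(glms)
      m$voxel_index[which.max(mean_t), ]
    })
    list(glms = glms, cond_masks = cond_masks, combined = comb,
         seeds = seeds)
  })

  conn <- .stage("connectivity", {
    ecm_maps <- lapply(filt, ecm, mask = loc$combined)
    seed_maps <- lapply(filt, function(s)
      lapply(loc$seeds, function(ctr)
        seed_connectivity(s, ctr, radius = 5, mask = loc$combined)))
    pat_ids <- names(sim$groups)[sim$groups == "ALS"]
    ctl_ids <- names(sim$groups)[sim$groups == "CTL"]
    contrasts <- stage_contrast(seed_maps[pat_ids], seed_maps[ctl_ids],
                                sim$records)
    list(ecm_maps = ecm_maps, seed_maps = seed_maps, contrasts = contrasts)
  })

  cls <- .stage("classify", {
    t_run1 <- n_timepoints(synced[[1]]) %/% 2L
    usable <- Filter(function(m)
      mask_size(m) >= config$srm_k && t_run1 >= config$srm_k,
      loc$cond_masks)
    if (length(usable) < length(loc$cond_masks))
      fp_warn("funcphen_small_roi",
              "%d ROI mask(s) smaller than srm_k skipped in classification",
              length(loc$cond_masks) - length(usable))
    if (length(usable) == 0L)
      fp_stop("funcphen_empty_mask",
              "no ROI mask large enough for srm_k = %d", config$srm_k)
    folds <- loso_classify(synced, sim$groups, usable,
                           k = config$srm_k, gamma = config$srm_gamma,
                           seed = config$seed, C = config$svm_c,
                           max_iter = config$srm_max_iter)
    list(folds = folds,
         accuracy = mean(folds$correct),
         affected = affected_contrast(folds, sim$records))
  })

  pls <- .stage("plsr", {
    pat_ids <- sim$records$patient_id
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    union_mask <- function(labels, name) {
      ms <- loc$cond_masks[labels]
      combined_mask(ms, label = name)
    }
    rois <- list(hand = union_mask(c("LH", "RH"), "hand"),
                 foot = union_mask(c("LF", "RF"), "foot"),
                 tongue = union_mask("TONGUE", "tongue"))
    alsfrs <- run_plsr_analysis(filt[pat_ids], sim$records,
                                predictor = "ecm", response = "alsfrs",
                                mask = loc$combined, rois = rois,
                                L = config$plsr_L)
    pumns <- run_plsr_analysis(synced[pat_ids], sim$records,
                               predictor = "timeseries", response = "pumns",
                               mask = loc$combined, rois = rois,
                               L = config$plsr_L)
    list(alsfrs = alsfrs, pumns = pumns)
  })

  manifest <- list(package = "funcphen",
                   version = as.character(utils::packageVersion("funcphen")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config_hash = .config_hash(unclass(config)))

  report <- list(masks = loc$cond_masks, combined_mask = loc$combined,
                 ecm_maps = conn$ecm_maps,
                 stage_contrasts = conn$contrasts,
                 folds = cls$folds, accuracy = cls$accuracy,
                 affected = cls$affected,
                 plsr_alsfrs = pls$alsfrs, plsr_pumns = pls$pumns,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cls$folds,
                     file.path(config$out_dir, "classification_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(conn$contrasts,
                     file.path(config$out_dir, "stage_contrasts.csv"),
                     row.names = FALSE)
    utils::write.csv(pls$alsfrs$folds[, c("fold", "patient_id", "mse",
                                          "lv1", "lv2", "kings_stage",
                                          "onset_type")],
                     file.path(config$out_dir, "plsr_alsfrs_folds.csv"),
                     row.names = FALSE)
    utils::write.csv(pls$pumns$folds[, c("fold", "patient_id", "mse",
                                         "lv1", "lv2", "kings_stage",
                                         "onset_type")],
                     file.path(config$out_dir, "plsr_pumns_folds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
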