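#' Leave-one-subject-out dual-space group classification
#'
#' For each held-out subject and each ROI: the remaining patients' run-1
#' data fit a patient rSRM and the remaining controls' run-1 data fit a
#' control rSRM; every subject's dual-space features (run 2 projected
#' through both frozen shared spaces, bases learned from run 1; see
#' [dual_space_features()]) are computed against those two models; a
#' linear SVM (C = 1), trained on training-mean-centered features with
#' the training set balanced by majority-class subsampling, predicts the
#' held-out subject's group. The held-out subject's data never enters
#' rSRM fitting or classifier training. Chance level for this binary
#' task is 0.5, and with the centering and balancing above the permuted
#' label null is empirically calibrated at it (see
#' [loso_permutation_test()] and the methods vignette).
#'
#' @param bold list of synchronized [bold_series()], named by subject id.
#' @param groups named character vector (`"ALS"` / `"CTL"`) per subject.
#' @param roi_masks list of [roi_mask()] (one entry is fine: whole-mask
#'   classification).
#' @param k shared dimension (default 10).
#' @param gamma rSRM sparsity penalty; `NULL` for the data-driven default.
#' @param seed integer seed for rSRM initializations.
#' @param C SVM cost.
#' @param max_iter rSRM sweep cap (exposed so large studies can bound
#'   runtime).
#' @return `data.frame` of fold records: `held_out_subject`, `roi_label`,
#'   `predicted`, `truth`, `correct`.
#' @export
loso_classify <- function(bold, groups, roi_masks, k = 10L, gamma = NULL,
                          seed = 1L, C = 1, max_iter = 100L) {
  prep <- .loso_prepare(bold, groups, roi_masks, k, gamma, seed, max_iter)
  folds <- NULL
  for (fold in prep) {
    pred <- .classify_fold(fold$feats, fold$train, fold$held,
                           fold$groups, C,
                           split_seed(seed, paste0("balance/",
                                                   fold$roi_label, "/",
                                                   fold$held)))
    folds <- rbind(folds, data.frame(held_out_subject = fold$held,
                                     roi_label = fold$roi_label,
                                     predicted = pred,
                                     truth = unname(fold$groups[fold$held]),
                                     correct = as.integer(pred == fold$groups[fold$held]),
                                     stringsAsFactors = FALSE))
  }
  rownames(folds) <- NULL
  folds
}

# classification stage of one LOSO fold: the training set is balanced by
# dropping random majority-class subjects (a leave-one-out fold is
# necessarily imbalanced against the held-out label, which would bias a
# maximum-margin classifier toward the majority class and de-calibrate
# the permutation null), features are centered by the training column
# means (dual-space features share a large common component that would
# otherwise dominate every inner product), and a linear SVM predicts the
# held-out subject.
.classify_fold <- function(feats, train, held, labels, C, bal_seed) {
  y <- labels[train]
  tab <- table(y)
  if (length(tab) == 2L && tab[1] != tab[2]) {
    maj <- names(tab)[which.max(tab)]
    n_drop <- max(tab) - min(tab)
    drop <- with_seed(bal_seed, sample(train[y == maj], n_drop))
    train <- setdiff(train, drop)
  }
  x <- feats[train, , drop = FALSE]
  mu <- colMeans(x)
  svm <- linear_svm(sweep(x, 2L, mu), labels[train], C = C,
                    class_weight = "none")
  predict(svm, sweep(feats[held, , drop = FALSE], 2L, mu))
}

# fit per-fold dual rSRM models and dual-space features for all subjects;
# returns one entry per (mask, held-out subject)
.loso_prepare <- function(bold, groups, roi_masks, k, gamma, seed,
                          max_iter) {
  ids <- names(bold)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  groups <- groups[ids]
  if (sum(groups == "ALS") < 2L || sum(groups == "CTL") < 2L)
    fp_stop("funcphen_too_few_subjects", "need at least 2 subjects per group")
  if (inherits(roi_masks, "roi_mask")) roi_masks <- list(roi_masks)
  out <- list()
  for (m in roi_masks) {
    runs <- lapply(bold, function(s) split_runs(mask_bold(s, m)))
    run1 <- lapply(runs, `[[`, "run1")
    run2 <- lapply(runs, `[[`, "run2")
    n_feat <- 2L * k * n_timepoints(run2[[ids[1]]])
    for (held in ids) {
      train <- setdiff(ids, held)
      tr_als <- train[groups[train] == "ALS"]
      tr_ctl <- train[groups[train] == "CTL"]
      if (length(tr_als) < 2L || length(tr_ctl) < 2L)
        fp_stop("funcphen_too_few_subjects",
                "fewer than 2 training subjects in a group after holdout")
      fit_seed <- split_seed(seed, paste0("loso/", m$label, "/", held))
      model_als <- fit_rsrm(run1[tr_als], k = k, gamma = gamma,
                            seed = fit_seed, group_label = "ALS",
                            max_iter = max_iter)
      model_ctl <- fit_rsrm(run1[tr_ctl], k = k, gamma = gamma,
                            seed = fit_seed, group_label = "CTL",
                            max_iter = max_iter)
      feats <- t(vapply(ids, function(id)
        dual_space_features(model_als, model_ctl, run1[[id]], run2[[id]]),
        numeric(n_feat)))
      rownames(feats) <- ids
      out[[length(out) + 1L]] <- list(roi_label = m$label, held = held,
                                      train = train, feats = feats,
                                      groups = groups)
    }
  }
  out
}

#' Permutation calibration of the LOSO dual-space classifier
#'
#' Runs the classification stage of [loso_classify()] under random
#' permutations of the group labels: the dual-space features of every
#' fold are computed once (models fit per fold without the held-out
#' subject, exactly as in [loso_classify()]); for each permutation the
#' class labels are shuffled across subjects and the per-fold SVMs are
#' retrained on the permuted labels. Under this null the labels carry no
#' information about the features, so the mean fold accuracy is
#' calibrated at the binary chance level of 0.5 (the class-weighted SVM
#' keeps the 5-versus-6 training imbalance of a leave-one-out fold from
#' biasing predictions toward the majority class).
#'
#' @inheritParams loso_classify
#' @param n_perm number of label permutations.
#' @return a list: `perm_acc` (mean fold accuracy per permutation),
#'   `mean` (grand mean), `se` (standard error of the permutation mean),
#'   `observed` (fold accuracy under the true labels).
#' @export
loso_permutation_test <- function(bold, groups, roi_masks, n_perm = 200L,
                                  k = 10L, gamma = NULL, seed = 1L, C = 1,
                                  max_iter = 100L) {
  prep <- .loso_prepare(bold, groups, roi_masks, k, gamma, seed, max_iter)
  ids <- names(bold)
  run_once <- function(g, tag) {
    acc <- vapply(seq_along(prep), function(f) {
      fold <- prep[[f]]
      pred <- .classify_fold(fold$feats, fold$train, fold$held, g, C,
                             split_seed(seed, paste0("balance/", tag,
                                                     "/", f)))
      as.numeric(pred == g[fold$held])
    }, numeric(1))
    mean(acc)
  }
  observed <- run_once(groups[ids], "observed")
  perms <- with_seed(split_seed(seed, "permutation"), {
    lapply(seq_len(n_perm), function(p)
      stats::setNames(sample(unname(groups[ids])), ids))
  })
  perm_acc <- vapply(seq_len(n_perm), function(p)
    run_once(perms[[p]], paste0("perm", p)), numeric(1))
  list(perm_acc = perm_acc, mean = mean(perm_acc),
       se = stats::sd(perm_acc) / sqrt(n_perm), observed = observed)
}

#' First-affected versus non-first-affected accuracy contrast
#'
#' Pools patient fold accuracies (0/1 per subject x ROI) into two groups
#' — folds whose ROI is among the patient's first-affected body-part
#' fields versus the rest — and compares them with a pooled-variance
#' two-sample t-test (dof = n1 + n2 - 2). Control folds carry no
#' first-affected label and are excluded.
#'
#' @param folds fold `data.frame` from [loso_classify()].
#' @param records clinical `data.frame` with `patient_id` and
#'   `first_affected_rois`.
#' @return a list: `mean_first`, `mean_nonfirst`, `t`, `dof`, `p`,
#'   `degenerate` (TRUE when both groups have zero variance; then p is 1
#'   for equal means and 0 otherwise by convention).
#' @export
affected_contrast <- function(folds, records) {
  pf <- folds[folds$truth == "ALS" &
                folds$held_out_subject %in% records$patient_id, ]
  if (nrow(pf) == 0L)
    fp_stop("funcphen_empty_group", "no patient folds")
  first <- mapply(function(subj, roi) {
    roi %in% records$first_affected_rois[[match(subj, records$patient_id)]]
  }, pf$held_out_subject, pf$roi_label)
  a <- pf$correct[first]
  b <- pf$correct[!first]
  if (length(a) == 0L || length(b) == 0L)
    fp_stop("funcphen_empty_group",
            "one accuracy group is empty (first: %d, non-first: %d)",
            length(a), length(b))
  n1 <- length(a); n2 <- length(b)
  dof <- n1 + n2 - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dof
  if (sp2 == 0) {
    equal <- mean(a) == mean(b)
    return(list(mean_first = mean(a), mean_nonfirst = mean(b),
                t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                dof = dof, p = if (equal) 1 else 0, degenerate = TRUE))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(mean_first = mean(a), mean_nonfirst = mean(b), t = tstat, dof = dof,
       p = 2 * stats::pt(-abs(tstat), dof), degenerate = FALSE)
}
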