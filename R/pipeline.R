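# Two-stage CDTL orchestration.
#
# Stage 1 (base task, e.g. AD vs CN): select the 20 highest-entropy
# slices per subject -> fine-tune the extractor -> extract features ->
# PCA + scaling -> per-class k-means decomposition -> relabel -> train
# the subclass classifier.
#
# Stage 2 (target task, e.g. sMCI vs pMCI): select the 30 middle slices
# per subject, freeze the base classifier's body, replace the head with a
# binary one and retrain only the head.
#
# Evaluation uses subject-grouped, label-stratified cross-validation so
# no subject's slices ever straddle a train/test boundary.

#' Pipeline configuration
#'
#' @param glcm a [glcm_config()] for entropy-based selection.
#' @param base_slice_rule list `(rule, n)`; default top-20 by entropy.
#' @param target_slice_rule list `(rule, n)`; default the 30 middle
#'   slices.
#' @param k_per_class subclasses per parent class (default 2).
#' @param reduction PCA component count or variance fraction (default
#'   0.95).
#' @param backbone a [backbone_spec()].
#' @param train a [train_config()].
#' @param reassembly_mode `"argmax_map"` or `"prob_sum"`.
#' @param folds CV folds (default 10).
#' @param holdout_fraction subject fraction held out by
#'   [holdout_split()] (default 0.10).
#' @param oversample balance training classes by duplicating whole
#'   minority-class subjects.
#' @param oversample_by_stratum balance within each stratum separately.
#' @param decompose_target also decompose the target task's classes
#'   (default `FALSE`: the target head is plain binary).
#' @param aggregation slice-to-subject rule, `"slice_majority"` or
#'   `"mean_score"`.
#' @param positive positive-class label for reports; defaults to the
#'   lexicographically last label in the evaluated data.
#' @param seed master seed; per-fold and per-stage seeds derive from it.
#' @return An object of class `cdtl_config`.
#' @export
cdtl_config <- function(glcm = glcm_config(),
                        base_slice_rule = list(rule = "top_entropy", n = 20L),
                        target_slice_rule = list(rule = "middle", n = 30L),
                        k_per_class = 2L,
                        reduction = 0.95,
                        backbone = backbone_spec(),
                        train = train_config(),
                        reassembly_mode = c("argmax_map", "prob_sum"),
                        folds = 10L,
                        holdout_fraction = 0.10,
                        oversample = FALSE,
                        oversample_by_stratum = FALSE,
                        decompose_target = FALSE,
                        aggregation = c("slice_majority", "mean_score"),
                        positive = NULL,
                        seed = 1L) {
  reassembly_mode <- match.arg(reassembly_mode)
  aggregation <- match.arg(aggregation)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  structure(list(glcm = glcm, base_slice_rule = base_slice_rule,
                 target_slice_rule = target_slice_rule,
                 k_per_class = k_per_class, reduction = reduction,
                 backbone = backbone, train = train,
                 reassembly_mode = reassembly_mode, folds = folds,
                 holdout_fraction = holdout_fraction,
                 oversample = isTRUE(oversample),
                 oversample_by_stratum = isTRUE(oversample_by_stratum),
                 decompose_target = isTRUE(decompose_target),
                 aggregation = aggregation, positive = positive,
                 seed = as.integer(seed)),
            class = "cdtl_config")
}

apply_slice_rule <- function(slices, rule, glcm) {
  switch(rule$rule,
         top_entropy = select_top_entropy(slices, rule$n, glcm),
         middle = select_middle(slices, rule$n),
         all = slices,
         stop("unknown slice rule ", rule$rule))
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Train the decomposed base classifier (stage 1)
#'
#' @param base_data a [slice_set()] with two parent classes and
#'   consistent per-subject labels.
#' @param cfg a [cdtl_config()].
#' @return An object of class `cdtl_base_model` bundling the extractor,
#'   reduction model, decomposition map, subclass classifier, per-class
#'   silhouettes, and the training-subject record.
#' @export
train_base <- function(base_data, cfg = cdtl_config()) {
  stopifnot(inherits(base_data, "slice_set"), inherits(cfg, "cdtl_config"))
  classes <- sort(unique(base_data$meta$label[!is.na(base_data$meta$label)]))
  if (length(classes) != 2L)
    stop("base task must have exactly 2 parent classes, got ",
         length(classes), call. = FALSE)
  train_subjects <- sort(unique(base_data$meta$subject_id))
  sel <- stage_wrap("slice_selection",
                    apply_slice_rule(base_data, cfg$base_slice_rule, cfg$glcm))
  ext <- stage_wrap("fit_extractor",
                    fit_extractor(cfg$backbone, sel, cfg$train))
  fm <- stage_wrap("transform", transform_features(ext, sel))
  red <- stage_wrap("fit_reduction", fit_reduction(fm, cfg$reduction))
  fmr <- stage_wrap("transform", transform_reduction(red, fm))
  dm <- stage_wrap("decompose",
                   decompose(fmr, cfg$k_per_class, seed = cfg$seed))
  sil <- silhouette_by_class(fmr, dm)
  sel2 <- stage_wrap("relabel", relabel(sel, dm))
  clf_spec <- cfg$backbone
  clf_spec$head_classes <- length(dm$subclass_of)
  clf <- stage_wrap("fit_classifier",
                    fit_classifier(clf_spec, sel2, cfg$train))
  structure(list(extractor = ext, reduction = red, decomposition = dm,
                 classifier = clf, silhouettes = sil, cfg = cfg,
                 classes = classes,
                 fitted_subjects = train_subjects),
            class = "cdtl_base_model")
}

#' @export
print.cdtl_base_model <- function(x, ...) {
  cat(sprintf("<cdtl_base_model> classes=[%s] -> %d subclasses; silhouettes: %s\n",
              paste(x$classes, collapse = ", "),
              length(x$decomposition$subclass_of),
              paste(names(x$silhouettes),
                    sprintf("%.2f", x$silhouettes), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Transfer the base model to the target task (stage 2)
#'
#' Applies the target slice rule (middle slices), freezes the base
#' classifier's body, replaces the head (binary by default; subclass-wide
#' when `cfg$decompose_target`), retrains the head only, and verifies the
#' body digest did not move.
#'
#' @param base a `cdtl_base_model`.
#' @param target_data a [slice_set()] with binary labels.
#' @param cfg a [cdtl_config()].
#' @return An object of class `cdtl_target_model`.
#' @export
transfer_to_target <- function(base, target_data, cfg = base$cfg) {
  stopifnot(inherits(base, "cdtl_base_model"),
            inherits(target_data, "slice_set"))
  classes <- sort(unique(target_data$meta$label))
  if (any(is.na(classes)) || length(classes) != 2L)
    stop("target task must have exactly 2 labeled classes", call. = FALSE)
  train_subjects <- sort(unique(target_data$meta$subject_id))
  sel <- stage_wrap("slice_selection",
                    apply_slice_rule(target_data, cfg$target_slice_rule,
                                     cfg$glcm))
  dm_t <- NULL
  if (cfg$decompose_target) {
    fm <- stage_wrap("transform", transform_features(base$extractor, sel))
    red_t <- stage_wrap("fit_reduction", fit_reduction(fm, cfg$reduction))
    fmr <- transform_reduction(red_t, fm)
    dm_t <- stage_wrap("decompose",
                       decompose(fmr, cfg$k_per_class, seed = cfg$seed + 13L))
    sel <- stage_wrap("relabel", relabel(sel, dm_t))
  }
  n_head <- if (is.null(dm_t)) 2L else length(dm_t$subclass_of)
  base_digest <- body_digest(base$classifier)
  frozen <- stage_wrap("freeze_and_replace_head",
                       freeze_and_replace_head(base$classifier, n_head,
                                               seed = cfg$seed))
  trained <- stage_wrap("retrain_head", retrain_head(frozen, sel, cfg$train))
  if (!identical(body_digest(trained), base_digest))
    stop("internal consistency error: transferred body digest differs ",
         "from the base model's", call. = FALSE)
  structure(list(classifier = trained, classes = classes,
                 decomposition = dm_t, body_digest = base_digest,
                 cfg = cfg, base_classes = base$classes,
                 fitted_subjects = train_subjects),
            class = "cdtl_target_model")
}

#' @export
print.cdtl_target_model <- function(x, ...) {
  cat(sprintf("<cdtl_target_model> classes=[%s], frozen body %s\n",
              paste(x$classes, collapse = ", "),
              substr(x$body_digest, 1, 8)))
  invisible(x)
}

#' Predict parent labels and scores for slices
#'
#' For a base model, subclass scores are reassembled to parent classes
#' under the configured mode; for a target model, the binary head's
#' scores are used directly (or reassembled when the target was
#' decomposed).
#'
#' @param model a `cdtl_base_model` or `cdtl_target_model`.
#' @param slices a [slice_set()] (already slice-selected).
#' @return List with `labels` (character) and `scores` (matrix of parent
#'   probabilities, rows summing to 1).
#' @export
predict_parent <- function(model, slices) UseMethod("predict_parent")

#' @export
predict_parent.cdtl_base_model <- function(model, slices) {
  S <- predict_scores(model$classifier, slices)
  re <- reassemble(S, model$decomposition, model$cfg$reassembly_mode)
  list(labels = re$labels, scores = re$scores)
}

#' @export
predict_parent.cdtl_target_model <- function(model, slices) {
  S <- predict_scores(model$classifier, slices)
  if (!is.null(model$decomposition)) {
    re <- reassemble(S, model$decomposition, model$cfg$reassembly_mode)
    return(list(labels = re$labels, scores = re$scores))
  }
  list(labels = colnames(S)[max.col(S, ties.method = "first")], scores = S)
}

#' Aggregate one subject's slice predictions to a subject call
#'
#' `"slice_majority"`: the modal slice-level label, ties broken in favor
#' of the label with the higher mean score. `"mean_score"`: average the
#' slice score vectors and take the argmax.
#'
#' @param model a fitted base or target model.
#' @param slices a [slice_set()] containing one subject's slices.
#' @param aggregation aggregation rule.
#' @return List with `label` and `score` (the mean parent-score vector).
#' @export
predict_subject <- function(model, slices,
                            aggregation = c("slice_majority", "mean_score")) {
  aggregation <- match.arg(aggregation)
  if (n_slices(slices) < 1L) stop("need >= 1 slice", call. = FALSE)
  pr <- predict_parent(model, slices)
  mean_scores <- colMeans(pr$scores)
  label <- if (aggregation == "mean_score") {
    names(mean_scores)[which.max(mean_scores)]
  } else {
    votes <- table(pr$labels)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else top[which.max(mean_scores[top])]
  }
  list(label = label, score = mean_scores)
}

# ---- cross-validation -------------------------------------------------

#' Subject-grouped, label-stratified fold assignment
#'
#' Subjects of each class are shuffled (seeded) and dealt round-robin
#' into folds, so every subject is held out exactly once and per-class
#' fold sizes differ by at most one subject.
#'
#' @param subject_ids character vector of subject IDs (unique).
#' @param labels subject-level labels aligned with `subject_ids`.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Named integer vector: fold (1..folds) per subject.
#' @export
make_subject_folds <- function(subject_ids, labels, folds, seed = 1L) {
  stopifnot(!anyDuplicated(subject_ids))
  folds <- as.integer(folds)
  assignment <- stats::setNames(integer(length(subject_ids)), subject_ids)
  set.seed(seed)
  for (cls in sort(unique(labels))) {
    subs <- sort(subject_ids[labels == cls])
    if (length(subs) < folds)
      stop("class ", cls, " has ", length(subs),
           " subjects; need >= folds (", folds, ")", call. = FALSE)
    subs <- sample(subs)
    assignment[subs] <- rep(seq_len(folds), length.out = length(subs))
  }
  assignment
}

#' Split subjects into a train/holdout pair
#'
#' Label-stratified subject-level split holding out approximately
#' `holdout_fraction` of each class (at least one subject per class).
#'
#' @param data a [slice_set()].
#' @param holdout_fraction fraction of subjects per class to hold out.
#' @param seed integer seed.
#' @return List with `train` and `holdout` slice sets.
#' @export
holdout_split <- function(data, holdout_fraction = 0.10, seed = 1L) {
  st <- subject_table(data$meta)
  set.seed(seed)
  hold <- character(0)
  for (cls in sort(unique(st$label))) {
    subs <- sort(st$subject_id[st$label == cls])
    nh <- max(1L, round(length(subs) * holdout_fraction))
    hold <- c(hold, sample(subs, nh))
  }
  is_hold <- data$meta$subject_id %in% hold
  list(train = subset_slices(data, which(!is_hold)),
       holdout = subset_slices(data, which(is_hold)))
}

# strip oversampling suffixes to recover origin subjects
origin_subject <- function(ids) sub("\\.dup[0-9]+$", "", ids)

#' Subject-grouped cross-validation of the base or target stage
#'
#' For each fold: train on the remaining subjects' slices (optionally
#' oversampled), evaluate on the held-out subjects' slices at both slice
#' and subject level. Every fitted component records the subjects it was
#' trained on; `run_cv` verifies each such set is contained in the fold's
#' training subjects (leakage guard). Fully reproducible under
#' `cfg$seed`.
#'
#' @param data a labeled [slice_set()] (slice selection is applied per
#'   fold according to the stage's rule).
#' @param cfg a [cdtl_config()].
#' @param stage `"base"` (train a decomposed base model per fold) or
#'   `"target"` (transfer `base_model` to each fold's training data).
#' @param base_model a `cdtl_base_model`, required when
#'   `stage = "target"`.
#' @return An object of class `cdtl_cv`: lists `slice_reports` and
#'   `subject_reports` (one `evaluation_report` per fold),
#'   `stratum_reports` (subject-level, per stratum and fold, when strata
#'   exist), `fold_assignment`, and `leakage` (per-fold fitted-subject
#'   records).
#' @export
run_cv <- function(data, cfg = cdtl_config(), stage = c("base", "target"),
                   base_model = NULL) {
  stage <- match.arg(stage)
  if (stage == "target" && is.null(base_model))
    stop("stage = \"target\" requires base_model", call. = FALSE)
  st <- subject_table(data$meta)
  fold_of <- make_subject_folds(st$subject_id, st$label, cfg$folds,
                                seed = cfg$seed)
  rule <- if (stage == "base") cfg$base_slice_rule else cfg$target_slice_rule
  slice_reports <- subject_reports <- vector("list", cfg$folds)
  stratum_reports <- list()
  leakage <- vector("list", cfg$folds)
  for (f in seq_len(cfg$folds)) {
    test_subjects <- names(fold_of)[fold_of == f]
    train_rows <- which(!(data$meta$subject_id %in% test_subjects))
    test_rows <- which(data$meta$subject_id %in% test_subjects)
    train_set <- subset_slices(data, train_rows)
    if (cfg$oversample)
      train_set <- oversample(train_set,
                              by_stratum = cfg$oversample_by_stratum,
                              seed = cfg$seed * 1000L + f)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + 31L * f
    cfg_f$train$seed <- cfg$train$seed + 31L * f
    model <- if (stage == "base") train_base(train_set, cfg_f)
             else transfer_to_target(base_model, train_set, cfg_f)
    fitted <- fitted_subject_record(model)
    train_subject_ids <- unique(origin_subject(train_set$meta$subject_id))
    for (comp in names(fitted)) {
      extra <- setdiff(origin_subject(fitted[[comp]]), train_subject_ids)
      if (length(extra))
        stop("leakage: component ", comp, " saw non-training subject(s) ",
             paste(extra, collapse = ", "), call. = FALSE)
    }
    leakage[[f]] <- fitted
    test_sel <- apply_slice_rule(subset_slices(data, test_rows), rule,
                                 cfg$glcm)
    pr <- predict_parent(model, test_sel)
    truth <- test_sel$meta$label
    positive <- cfg$positive %||% rev(sort(unique(data$meta$label)))[1]
    pos_scores <- pr$scores[, positive]
    slice_reports[[f]] <- evaluation_report(
      truth, pr$labels, pos_scores, positive, fold = f,
      seed = cfg$seed + f)
    sub_truth <- sub_pred <- character(0)
    sub_score <- numeric(0)
    sub_stratum <- character(0)
    for (s in unique(test_sel$meta$subject_id)) {
      rows <- which(test_sel$meta$subject_id == s)
      ps <- predict_subject(model, subset_slices(test_sel, rows),
                            cfg$aggregation)
      sub_truth <- c(sub_truth, test_sel$meta$label[rows[1]])
      sub_stratum <- c(sub_stratum, test_sel$meta$stratum[rows[1]])
      sub_pred <- c(sub_pred, ps$label)
      sub_score <- c(sub_score, ps$score[positive])
    }
    subject_reports[[f]] <- evaluation_report(
      sub_truth, sub_pred, sub_score, positive, fold = f,
      seed = cfg$seed + f)
    for (strat in sort(unique(sub_stratum[!is.na(sub_stratum)]))) {
      i <- which(sub_stratum == strat)
      stratum_reports[[length(stratum_reports) + 1L]] <-
        evaluation_report(sub_truth[i], sub_pred[i], sub_score[i],
                          positive, stratum = strat, fold = f,
                          seed = cfg$seed + f)
    }
  }
  structure(list(slice_reports = slice_reports,
                 subject_reports = subject_reports,
                 stratum_reports = stratum_reports,
                 fold_assignment = fold_of, leakage = leakage,
                 stage = stage, cfg = cfg),
            class = "cdtl_cv")
}

#' @export
print.cdtl_cv <- function(x, ...) {
  acc <- vapply(x$subject_reports, function(r) r$accuracy, numeric(1))
  cat(sprintf(
    "<cdtl_cv> stage=%s folds=%d subject-level accuracy %.3f +/- %.3f\n",
    x$stage, length(x$subject_reports), mean(acc, na.rm = TRUE),
    stats::sd(acc, na.rm = TRUE)))
  invisible(x)
}

# per-component record of the subjects each fitted part was trained on
fitted_subject_record <- function(model) {
  if (inherits(model, "cdtl_base_model")) {
    list(extractor = model$extractor$fitted_subjects,
         classifier = model$classifier$fitted_subjects,
         pipeline = model$fitted_subjects)
  } else {
    list(classifier = model$classifier$fitted_subjects,
         pipeline = model$fitted_subjects)
  }
}
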