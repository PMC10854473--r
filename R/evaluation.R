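# Evaluation: confusion matrices, scalar metrics, rank-based AUC with
# bootstrap confidence intervals, minority-class oversampling, and
# stratified summaries.
#
# Convention: a metric whose denominator is 0 (e.g. sensitivity when the
# test set contains no positives) is *undefined* and reported as NA —
# never silently 0 or 1. This matters for small single-sex test strata
# where accuracy can be perfect while F1 is meaningless.

#' Confusion matrix for binary predictions
#'
#' @param y_true,y_pred character/factor vectors of equal length drawn
#'   from two known classes.
#' @param positive the positive-class label (the progressive/disease
#'   class by convention).
#' @return A `confusion_matrix`: 2x2 integer matrix with the positive
#'   class first, rows = truth, columns = prediction.
#' @export
confusion <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  classes <- sort(unique(y_true))
  if (!positive %in% classes) classes <- sort(unique(c(classes, positive)))
  if (length(classes) > 2L)
    stop("confusion() is binary; got classes ",
         paste(classes, collapse = ", "), call. = FALSE)
  negative <- setdiff(classes, positive)
  if (length(negative) == 0L) negative <- "<other>"
  bad <- setdiff(unique(y_pred), c(positive, negative))
  if (length(bad))
    stop("predictions contain unseen label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred == negative)
  fp <- sum(y_true == negative & y_pred == positive)
  tn <- sum(y_true == negative & y_pred == negative)
  m <- matrix(as.integer(c(tp, fn, fp, tn)), 2, 2, byrow = TRUE,
              dimnames = list(truth = c(positive, negative),
                              prediction = c(positive, negative)))
  structure(m, class = c("confusion_matrix", "matrix"),
            positive = positive, negative = negative)
}

#' Scalar metrics from a confusion matrix
#'
#' accuracy = (TP+TN)/N, sensitivity (= recall) = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), F1 = harmonic mean of
#' precision and sensitivity. Zero denominators yield `NA` (undefined).
#'
#' @param conf a `confusion_matrix` from [confusion()].
#' @return Named list of metrics plus `n`.
#' @export
metrics <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  tp <- conf[1, 1]; fn <- conf[1, 2]; fp <- conf[2, 1]; tn <- conf[2, 2]
  n <- tp + fn + fp + tn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(accuracy = safe(tp + tn, n), sensitivity = sens, recall = sens,
       specificity = spec, precision = prec, f1 = f1, n = as.integer(n))
}

#' AUC with a bootstrap confidence interval
#'
#' AUC by the rank (Mann-Whitney) formulation — the probability that a
#' random positive outranks a random negative, ties counted 0.5. The CI is
#' a seeded stratified percentile bootstrap: positives and negatives are
#' resampled separately, preserving class counts.
#'
#' @param y_true labels; both classes must be present for a defined AUC.
#' @param scores numeric positive-class scores.
#' @param positive the positive-class label.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param alpha CI level is `1 - alpha` (default 0.05 for 95%).
#' @return List with `auc`, `ci_low`, `ci_high` (all `NA` when only one
#'   class is present).
#' @export
auc_with_ci <- function(y_true, scores, positive, n_boot = 1000L,
                        seed = 1L, alpha = 0.05) {
  y_true <- as.character(y_true)
  pos <- y_true == positive
  if (!any(pos) || all(pos))
    return(list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  auc_rank <- function(s_pos, s_neg) {
    r <- rank(c(s_pos, s_neg))
    np <- length(s_pos)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(s_neg))
  }
  sp <- scores[pos]; sn <- scores[!pos]
  a <- auc_rank(sp, sn)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    auc_rank(sample(sp, replace = TRUE), sample(sn, replace = TRUE)),
    numeric(1))
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  list(auc = a, ci_low = ci[1], ci_high = ci[2])
}

#' Build an evaluation report
#'
#' Bundles the confusion matrix, scalar metrics, and (when scores are
#' supplied) AUC with its bootstrap CI into one record, optionally tagged
#' with a stratum and a fold number.
#'
#' @param y_true,y_pred label vectors.
#' @param scores optional positive-class scores for AUC.
#' @param positive positive-class label.
#' @param stratum,fold optional tags.
#' @param n_boot,seed,alpha bootstrap settings, see [auc_with_ci()].
#' @return An object of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, scores = NULL, positive,
                              stratum = NA_character_, fold = NA_integer_,
                              n_boot = 1000L, seed = 1L, alpha = 0.05) {
  conf <- confusion(y_true, y_pred, positive)
  met <- metrics(conf)
  auc <- list(auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  if (!is.null(scores))
    auc <- auc_with_ci(y_true, scores, positive, n_boot, seed, alpha)
  structure(c(list(confusion = conf, positive = positive,
                   stratum = stratum, fold = fold),
              met, auc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf(
    "<evaluation_report>%s n=%d acc=%s sens=%s spec=%s f1=%s auc=%s\n",
    if (!is.na(x$fold)) sprintf(" fold=%d", x$fold) else "",
    x$n, fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
    fmt(x$f1), fmt(x$auc)))
  invisible(x)
}

# ---- oversampling -----------------------------------------------------

#' Oversample the minority class
#'
#' Duplicates minority-class members uniformly at random with replacement
#' until class counts are equal, keeping every original sample. For slice
#' sets, duplication operates on *whole subjects* (all their slices), so
#' subject-grouped evaluation guarantees survive; duplicated subjects get
#' a `.dupK` suffix to keep `(subject, slice)` keys unique. With
#' `by_stratum = TRUE` each stratum (e.g. each sex) is balanced
#' independently; a stratum containing a single class is left unchanged
#' with a warning. Intended for training data only — the pipeline never
#' applies it to evaluation folds.
#'
#' @param data a [slice_set()] or [feature_matrix()] with binary labels.
#' @param by_stratum balance within each stratum separately.
#' @param seed integer seed.
#' @return Same container type, enlarged.
#' @export
oversample <- function(data, by_stratum = FALSE, seed = 1L) {
  UseMethod("oversample")
}

# subject-level table: one row per subject with its (consistent) label
# and stratum
subject_table <- function(meta) {
  agg <- unique(meta[, c("subject_id", "label", "stratum")])
  if (anyDuplicated(agg$subject_id))
    stop("subject(s) with inconsistent labels/strata across slices",
         call. = FALSE)
  agg
}

# which subjects to duplicate (with multiplicity) to balance classes
oversample_draws <- function(subjects, labels, seed) {
  tab <- table(labels)
  if (length(tab) < 2L) return(NULL)
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  if (deficit == 0L) return(character(0))
  pool <- sort(subjects[labels == minority])
  set.seed(seed)
  sample(pool, deficit, replace = TRUE)
}

#' @export
oversample.slice_set <- function(data, by_stratum = FALSE, seed = 1L) {
  st <- subject_table(data$meta)
  groups <- if (by_stratum) split(st, st$stratum) else list(all = st)
  draws <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[[order(names(groups))[gi]]]
    d <- oversample_draws(g$subject_id, g$label, seed + gi)
    if (is.null(d)) {
      warning("stratum '", names(groups)[order(names(groups))[gi]],
              "' contains a single class; left unchanged")
      next
    }
    draws <- c(draws, d)
  }
  if (length(draws) == 0L) return(data)
  images <- data$images
  meta <- data$meta
  counter <- stats::setNames(integer(length(unique(draws))), unique(draws))
  for (s in draws) {
    counter[s] <- counter[s] + 1L
    idx <- which(data$meta$subject_id == s)
    newm <- data$meta[idx, , drop = FALSE]
    newm$subject_id <- paste0(s, ".dup", counter[s])
    images <- c(images, data$images[idx])
    meta <- rbind(meta, newm)
  }
  slice_set(images, meta,
            c(data$provenance, list(oversampled = TRUE, seed = seed)))
}

#' @export
oversample.feature_matrix <- function(data, by_stratum = FALSE, seed = 1L) {
  if (by_stratum)
    stop("stratum-aware oversampling needs a slice_set (strata live there)",
         call. = FALSE)
  st <- unique(data.frame(subject_id = data$subject_ids,
                          label = data$labels, stringsAsFactors = FALSE))
  if (anyDuplicated(st$subject_id))
    stop("subject(s) with inconsistent labels", call. = FALSE)
  d <- oversample_draws(st$subject_id, st$label, seed + 1L)
  if (is.null(d)) {
    warning("single class present; left unchanged")
    return(data)
  }
  if (length(d) == 0L) return(data)
  X <- data$X; ids <- data$sample_ids; labs <- data$labels
  subs <- data$subject_ids
  counter <- stats::setNames(integer(length(unique(d))), unique(d))
  for (s in d) {
    counter[s] <- counter[s] + 1L
    idx <- which(data$subject_ids == s)
    X <- rbind(X, data$X[idx, , drop = FALSE])
    ids <- c(ids, paste0(data$sample_ids[idx], ".dup", counter[s]))
    labs <- c(labs, data$labels[idx])
    subs <- c(subs, paste0(s, ".dup", counter[s]))
  }
  feature_matrix(X, ids, labs, subs)
}

# ---- summaries --------------------------------------------------------

report_metric_names <- c("accuracy", "sensitivity", "specificity",
                         "precision", "f1", "auc")

#' Summarize evaluation reports by group
#'
#' Mean and SD of each metric across reports, per group (e.g. per
#' stratum), with a combined all-groups row. Undefined (`NA`) metrics are
#' dropped from their mean/SD with `n_defined` recording how many reports
#' contributed.
#'
#' @param reports list of `evaluation_report` objects.
#' @param group_by field to group on: `"stratum"`, `"fold"`, or `NULL`
#'   for a single combined row.
#' @return data.frame with one row per group plus `"<combined>"`,
#'   columns `<metric>_mean`, `<metric>_sd`, `n_reports`.
#' @export
stratified_summary <- function(reports, group_by = "stratum") {
  stopifnot(length(reports) >= 1L)
  keys <- if (is.null(group_by)) rep("<combined>", length(reports))
          else vapply(reports, function(r)
            as.character(r[[group_by]] %||% NA), character(1))
  keys[is.na(keys)] <- "<unspecified>"
  groups <- c(split(reports, keys))
  if (length(groups) > 1L || !identical(names(groups), "<combined>"))
    groups[["<combined>"]] <- reports
  rows <- lapply(names(groups), function(g) {
    rs <- groups[[g]]
    out <- list(group = g, n_reports = length(rs))
    for (mn in report_metric_names) {
      vals <- vapply(rs, function(r) r[[mn]] %||% NA_real_, numeric(1))
      vals <- vals[!is.na(vals)]
      out[[paste0(mn, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
      out[[paste0(mn, "_sd")]] <- if (length(vals) > 1) stats::sd(vals)
                                  else if (length(vals) == 1) 0 else NA_real_
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
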