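# Class decomposition: reduce features, cluster each parent class into k
# subclasses, relabel samples with subclass labels, and map subclass
# predictions back to parent classes.
#
# Decomposing irregular classes into tighter subclasses makes class
# boundaries easier to learn; after prediction the subclasses are
# reassembled so the user-facing output is always in parent labels.

#' Fit a dimensionality-reduction model
#'
#' PCA fitted on training rows only (no leakage), followed by
#' standardization of the retained component scores — features are scaled
#' after the reduction. `n_components` may be an integer count or a
#' fraction in (0, 1), in which case the smallest number of components
#' whose cumulative explained-variance share reaches that fraction is kept.
#'
#' @param train a [feature_matrix()] with >= 2 rows.
#' @param n_components integer count or variance fraction in (0, 1);
#'   default keeps 95% of variance.
#' @return An object of class `reduction_model`.
#' @export
fit_reduction <- function(train, n_components = 0.95) {
  stopifnot(inherits(train, "feature_matrix"))
  n <- nrow(train$X)
  if (n < 2L) stop("need at least 2 samples to fit a reduction", call. = FALSE)
  pc <- stats::prcomp(train$X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- ev / sum(ev)
  max_k <- sum(pc$sdev > 1e-12)
  if (max_k < 1L) max_k <- 1L
  if (n_components < 1) {
    k <- which(cumsum(share) >= n_components - 1e-12)[1]
    if (is.na(k)) k <- max_k
  } else {
    k <- as.integer(n_components)
    if (k > min(n, ncol(train$X)))
      stop("requested ", k, " components but only ", min(n, ncol(train$X)),
           " available", call. = FALSE)
  }
  k <- min(k, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(scores)
  sdv <- apply(scores, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k,
                 explained_share = share[seq_len(k)],
                 score_center = mu, score_scale = sdv),
            class = "reduction_model")
}

#' Project a feature matrix through a fitted reduction
#'
#' @param model a `reduction_model` from [fit_reduction()].
#' @param fm a [feature_matrix()] with the same feature columns as the
#'   training data.
#' @param scale standardize the component scores with the training
#'   mean/SD (default `TRUE`).
#' @return A [feature_matrix()] with `n_components` columns.
#' @export
transform_reduction <- function(model, fm, scale = TRUE) {
  stopifnot(inherits(model, "reduction_model"), inherits(fm, "feature_matrix"))
  S <- sweep(fm$X, 2, model$center) %*% model$rotation
  if (scale) S <- sweep(sweep(S, 2, model$score_center), 2,
                        model$score_scale, "/")
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  feature_matrix(S, fm$sample_ids, fm$labels, fm$subject_ids)
}

#' Invert a reduction (reconstruction)
#'
#' Maps reduced (optionally standardized) scores back to the original
#' feature space. Exact for training data when all components are kept.
#'
#' @inheritParams transform_reduction
#' @param fm_reduced a [feature_matrix()] of component scores.
#' @return A [feature_matrix()] in the original feature space.
#' @export
inverse_reduction <- function(model, fm_reduced, scale = TRUE) {
  S <- fm_reduced$X
  if (scale) S <- sweep(sweep(S, 2, model$score_scale, "*"), 2,
                        model$score_center, "+")
  X <- sweep(S %*% t(model$rotation), 2, model$center, "+")
  feature_matrix(X, fm_reduced$sample_ids, fm_reduced$labels,
                 fm_reduced$subject_ids)
}

subclass_label <- function(parent, idx0) paste0(parent, "#", idx0)

#' Decompose classes into k-means subclasses
#'
#' Runs k-means independently within each parent class (seeded, 10
#' restarts) and relabels each cluster's members with a new subclass label
#' `"<parent>#<cluster>"` (0-based cluster index). With two parent classes
#' and k = 2 each, this yields the four subclasses the decomposed
#' classifier is trained on. Cluster indices are ordered by the first
#' centroid coordinate so the labeling is reproducible.
#'
#' A class whose sample count is below `k * min_cluster_size` falls back to
#' k = 1 with a warning when `fallback = TRUE`, otherwise errors.
#'
#' @param train a [feature_matrix()] with parent labels (typically the
#'   reduced, scaled space from [transform_reduction()]).
#' @param k_per_class single integer applied to every class (default 2) or
#'   a named integer vector, one entry per parent label.
#' @param seed integer seed controlling the k-means restarts.
#' @param fallback fall back to k = 1 for infeasible classes (default
#'   `TRUE`).
#' @param min_cluster_size feasibility floor: a class needs at least
#'   `k * min_cluster_size` samples (default 1).
#' @return An object of class `decomposition_map` with fields
#'   `k_per_class`, `subclass_of` (subclass -> parent), `assignments`
#'   (sample_id -> subclass), `centroids`, `seed`.
#' @export
decompose <- function(train, k_per_class = 2L, seed = 1L,
                      fallback = TRUE, min_cluster_size = 1L) {
  stopifnot(inherits(train, "feature_matrix"))
  if (any(is.na(train$labels)))
    stop("all samples must carry a parent label", call. = FALSE)
  parents <- sort(unique(train$labels))
  if (length(k_per_class) == 1L && is.null(names(k_per_class)))
    k_per_class <- stats::setNames(rep(as.integer(k_per_class),
                                       length(parents)), parents)
  k_per_class <- k_per_class[parents]
  if (any(is.na(k_per_class)))
    stop("k_per_class must cover every parent label", call. = FALSE)
  assignments <- stats::setNames(rep(NA_character_, nrow(train$X)),
                                 train$sample_ids)
  subclass_of <- character(0)
  centroids <- NULL
  k_used <- k_per_class
  for (ci in seq_along(parents)) {
    cls <- parents[ci]
    rows <- which(train$labels == cls)
    Xc <- train$X[rows, , drop = FALSE]
    k <- as.integer(k_per_class[[cls]])
    if (k < 1L) stop("k must be >= 1", call. = FALSE)
    if (nrow(Xc) < k * max(1L, as.integer(min_cluster_size)) ||
        nrow(unique(Xc)) < k) {
      if (!fallback)
        stop("class ", cls, " has too few samples for k = ", k, call. = FALSE)
      warning("class ", cls, " cannot support k = ", k,
              "; falling back to k = 1")
      k <- 1L
    }
    if (k == 1L) {
      cl <- rep(1L, nrow(Xc))
      cen <- matrix(colMeans(Xc), 1)
    } else {
      set.seed(seed + ci)
      km <- tryCatch(
        stats::kmeans(Xc, centers = k, nstart = 10, iter.max = 300),
        error = function(e) NULL)
      if (is.null(km)) {
        if (!fallback)
          stop("k-means failed for class ", cls, call. = FALSE)
        warning("k-means failed for class ", cls, "; falling back to k = 1")
        k <- 1L
        cl <- rep(1L, nrow(Xc))
        cen <- matrix(colMeans(Xc), 1)
      } else {
        # reorder clusters by first centroid coordinate for determinism
        ord <- order(km$centers[, 1],
                     if (ncol(km$centers) > 1) km$centers[, 2] else
                       seq_len(nrow(km$centers)))
        remap <- match(seq_len(k), ord)
        cl <- remap[km$cluster]
        cen <- km$centers[ord, , drop = FALSE]
      }
    }
    k_used[[cls]] <- k
    labs <- subclass_label(cls, seq_len(k) - 1L)
    subclass_of[labs] <- cls
    rownames(cen) <- labs
    centroids <- rbind(centroids, cen)
    assignments[rows] <- labs[cl]
  }
  structure(list(k_per_class = k_used, subclass_of = subclass_of,
                 assignments = assignments, centroids = centroids,
                 seed = as.integer(seed)),
            class = "decomposition_map")
}

#' @export
print.decomposition_map <- function(x, ...) {
  cat(sprintf("<decomposition_map> %d parents -> %d subclasses, %d samples\n",
              length(x$k_per_class), length(x$subclass_of),
              length(x$assignments)))
  invisible(x)
}

#' Map subclass labels back to their parents
#'
#' @param labels character vector of subclass labels.
#' @param map a `decomposition_map`.
#' @return Character vector of parent labels.
#' @export
parent_labels <- function(labels, map) {
  out <- unname(map$subclass_of[labels])
  if (any(is.na(out)))
    stop("unknown subclass label(s): ",
         paste(unique(labels[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Relabel a dataset with subclass labels
#'
#' Replaces parent labels by the per-sample subclass assignments recorded
#' in a `decomposition_map`. Sample count is unchanged; mapping the new
#' labels back through `subclass_of` recovers the original labels exactly.
#'
#' @param x a [slice_set()] or [feature_matrix()].
#' @param map a `decomposition_map` covering every sample in `x`.
#' @return Same container type with subclass labels.
#' @export
relabel <- function(x, map) UseMethod("relabel")

#' @export
relabel.feature_matrix <- function(x, map) {
  new <- map$assignments[x$sample_ids]
  if (any(is.na(new)))
    stop("sample(s) not present in decomposition map: ",
         paste(utils::head(x$sample_ids[is.na(new)], 5), collapse = ", "),
         call. = FALSE)
  feature_matrix(x$X, x$sample_ids, unname(new), x$subject_ids)
}

#' @export
relabel.slice_set <- function(x, map) {
  ids <- slice_ids(x)
  new <- map$assignments[ids]
  if (any(is.na(new)))
    stop("slice(s) not present in decomposition map: ",
         paste(utils::head(ids[is.na(new)], 5), collapse = ", "),
         call. = FALSE)
  out <- x
  out$meta$label <- unname(new)
  out
}

#' Reassemble subclass predictions into parent predictions
#'
#' Two modes: `"argmax_map"` picks the highest-scoring subclass and
#' reports its parent (the default); `"prob_sum"` sums subclass scores
#' within each parent and reports the argmax parent. The two can disagree
#' when one parent's mass is split across its subclasses. With hard
#' subclass labels (a character vector) the mapping is direct.
#'
#' @param pred character vector of subclass labels, or a numeric matrix of
#'   per-sample subclass scores with subclass labels as column names (rows
#'   summing to 1).
#' @param map a `decomposition_map`.
#' @param mode `"argmax_map"` or `"prob_sum"`.
#' @return A list with `labels` (parent predictions) and, when scores were
#'   given, `scores`: a matrix of parent scores (summed subclass mass,
#'   rows summing to 1).
#' @export
reassemble <- function(pred, map, mode = c("argmax_map", "prob_sum")) {
  mode <- match.arg(mode)
  if (is.character(pred)) {
    return(list(labels = parent_labels(pred, map), scores = NULL))
  }
  pred <- as.matrix(pred)
  if (is.null(colnames(pred)))
    stop("score matrix must have subclass labels as column names",
         call. = FALSE)
  pars <- parent_labels(colnames(pred), map)
  if (mode == "prob_sum") {
    rs <- rowSums(pred)
    if (any(pred < -1e-9) || any(abs(rs - 1) > 1e-6))
      stop("prob_sum requires nonnegative scores summing to 1 per sample",
           call. = FALSE)
  }
  uniq <- sort(unique(pars))
  parent_scores <- sapply(uniq, function(pp)
    rowSums(pred[, pars == pp, drop = FALSE]))
  if (!is.matrix(parent_scores))
    parent_scores <- matrix(parent_scores, nrow = nrow(pred),
                            dimnames = list(NULL, uniq))
  labels <- if (mode == "argmax_map") {
    pars[max.col(pred, ties.method = "first")]
  } else {
    uniq[max.col(parent_scores, ties.method = "first")]
  }
  list(labels = labels, scores = parent_scores)
}

#' Per-class mean silhouette of the subclass clustering
#'
#' Diagnostic for how well separated the discovered subclasses are,
#' computed within each parent class over that class's own samples, in the
#' same (reduced, scaled) feature space the clustering saw. Parents with a
#' single nonempty subclass are undefined and reported as `NA`.
#'
#' @param features a [feature_matrix()] in the clustering space.
#' @param map a `decomposition_map` covering the samples.
#' @return Named numeric vector, one mean silhouette in `[-1, 1]` (or
#'   `NA`) per parent label.
#' @export
silhouette_by_class <- function(features, map) {
  stopifnot(inherits(features, "feature_matrix"))
  assig <- map$assignments[features$sample_ids]
  if (any(is.na(assig)))
    stop("sample(s) missing from decomposition map", call. = FALSE)
  parents <- sort(unique(unname(map$subclass_of)))
  out <- stats::setNames(rep(NA_real_, length(parents)), parents)
  for (cls in parents) {
    rows <- which(parent_labels(unname(assig), map) == cls)
    sub <- assig[rows]
    if (length(unique(sub)) < 2L) next
    sil <- cluster::silhouette(as.integer(factor(sub)),
                               stats::dist(features$X[rows, , drop = FALSE]))
    out[cls] <- mean(sil[, "sil_width"])
  }
  out
}
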