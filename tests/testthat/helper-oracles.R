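# Independent brute-force oracles and small fixture builders shared by
# the test files. The oracles deliberately use naive enumeration, not the
# package's vectorized code paths.

# GLCM by explicit double-loop pair enumeration.
oracle_glcm <- function(image, distance, angle, levels, symmetric = TRUE) {
  off <- switch(as.character(angle),
                "0" = c(0L, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0L), "135" = c(-distance, -distance))
  M <- matrix(0, levels, levels)
  nr <- nrow(image); nc <- ncol(image)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      i <- image[r, c] + 1L; j <- image[r2, c2] + 1L
      M[i, j] <- M[i, j] + 1
      if (symmetric) M[j, i] <- M[j, i] + 1
    }
  }
  M / sum(M)
}

oracle_entropy <- function(p, base = exp(1)) {
  s <- 0
  for (v in as.numeric(p)) if (v > 0) s <- s - v * log(v, base = base)
  s
}

# Silhouette by explicit pairwise distances.
oracle_silhouette_mean <- function(X, cl) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0L) { widths[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k)
      mean(D[i, cl == k]), numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  mean(widths)
}

# AUC as the all-pairs probability of correct ranking, ties = 0.5.
oracle_auc <- function(y, s, positive) {
  pos <- which(y == positive); neg <- which(y != positive)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

# Top-level eigendecomposition oracle for explained-variance shares.
oracle_ev_shares <- function(X) {
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  ev / sum(ev)
}

# ---- fixtures ---------------------------------------------------------

# Small slice set built by hand: n subjects x k slices of given size.
toy_slices <- function(n_subjects = 2L, n_slices = 3L, dim = c(6L, 6L),
                       labels = NULL, seed = 1L) {
  set.seed(seed)
  images <- list(); rows <- list()
  for (s in seq_len(n_subjects)) for (k in seq_len(n_slices) - 1L) {
    images[[length(images) + 1L]] <- matrix(stats::runif(prod(dim)), dim[1])
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sprintf("sub%02d", s), slice_index = k,
      label = if (is.null(labels)) NA_character_ else labels[s],
      stringsAsFactors = FALSE)
  }
  slice_set(images, do.call(rbind, rows))
}

# Fast desk-scale config for pipeline tests.
fast_cfg <- function(seed = 1L, k = 2L, folds = 3L, backbone = NULL,
                     epochs = 40L, lr = 0.1) {
  cdtl_config(
    backbone = backbone %||% backbone_spec("deterministic_texture"),
    train = train_config(epochs = epochs, batch_size = 32L,
                         learning_rate = lr, seed = seed),
    base_slice_rule = list(rule = "all"),
    target_slice_rule = list(rule = "all"),
    k_per_class = k, folds = folds, seed = seed)
}

small_task_spec <- function(seed = 1L, n = 10L, slices = 4L, ...) {
  task_spec(n_subjects_per_class = c(A = n, B = n),
            slices_per_subject = slices, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# slice-level ids aligned with a task's meta, for looking up assignments
task_ids <- function(task) paste(task$meta$subject_id, task$meta$slice_index,
                                 sep = ":")
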