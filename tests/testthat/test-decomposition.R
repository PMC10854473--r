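make_blob_fm <- function(n_per = 20, centers, sd = 0.3, seed = 1,
                         labels = NULL) {
  set.seed(seed)
  X <- NULL; labs <- character(0)
  for (i in seq_len(nrow(centers))) {
    X <- rbind(X, sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
                               n_per), 2, centers[i, ], "+"))
    labs <- c(labs, rep(if (is.null(labels)) letters[i] else labels[i],
                        n_per))
  }
  feature_matrix(X, sprintf("s%03d", seq_len(nrow(X))), labs)
}

test_that("PCA reduction picks components by explained variance", {
  # rank-2 data embedded in 10D
  set.seed(3)
  B <- matrix(stats::rnorm(20), 10, 2)
  Z <- matrix(stats::rnorm(60 * 2), 60, 2)
  fm <- feature_matrix(Z %*% t(B), sprintf("s%d", 1:60))
  red <- fit_reduction(fm, 0.99)
  expect_equal(red$n_components, 2L)
  # keeping all components makes transform/inverse-transform exact
  fm2 <- make_blob_fm(centers = rbind(c(0, 0, 0), c(3, 1, -1)), seed = 5)
  red2 <- fit_reduction(fm2, 3L)
  rec <- inverse_reduction(red2, transform_reduction(red2, fm2))
  expect_equal(rec$X, fm2$X, tolerance = 1e-9, ignore_attr = TRUE)
  # explained shares match an eigendecomposition oracle
  shares <- oracle_ev_shares(fm2$X)
  expect_equal(red2$explained_share, shares[1:3], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(fit_reduction(fm2, 50L), "components")
})

test_that("per-class k-means recovers well-separated planted subclusters", {
  # two classes x two subclusters, separation >> within-cluster sd
  centers <- rbind(c(0, 0), c(8, 0), c(0, 20), c(8, 20))
  fm <- make_blob_fm(centers = centers, sd = 0.5, seed = 11,
                     labels = c("cn", "cn", "ad", "ad"))
  dm <- decompose(fm, 2L, seed = 7)
  expect_length(dm$subclass_of, 4L)
  expect_setequal(unname(dm$subclass_of), c("cn", "cn", "ad", "ad"))
  truth <- rep(c("cn1", "cn2", "ad1", "ad2"), each = 20)
  expect_gte(mclust::adjustedRandIndex(unname(dm$assignments), truth), 0.99)
  # deterministic given (data, k, seed)
  dm2 <- decompose(fm, 2L, seed = 7)
  expect_identical(dm$assignments, dm2$assignments)
  expect_identical(dm$centroids, dm2$centroids)
})

test_that("k = 1 decomposition is the identity up to the #0 suffix", {
  fm <- make_blob_fm(centers = rbind(c(0, 0), c(5, 5)), seed = 2,
                     labels = c("x", "y"))
  dm <- decompose(fm, 1L, seed = 1)
  expect_equal(unname(dm$assignments), paste0(fm$labels, "#0"))
  expect_equal(unname(dm$subclass_of[c("x#0", "y#0")]), c("x", "y"))
})

test_that("infeasible k falls back to k = 1 with a warning, or errors", {
  fm <- make_blob_fm(n_per = 3, centers = rbind(c(0, 0), c(9, 9)),
                     labels = c("big", "tiny"), seed = 4)
  expect_warning(dm <- decompose(fm, c(big = 2L, tiny = 5L), seed = 1),
                 "falling back")
  expect_equal(unname(dm$k_per_class[c("big", "tiny")]), c(2L, 1L))
  expect_error(decompose(fm, c(big = 2L, tiny = 5L), seed = 1,
                         fallback = FALSE), "too few")
})

test_that("relabel swaps in subclass labels and is exactly invertible", {
  fm <- make_blob_fm(centers = rbind(c(0, 0), c(0, 9), c(9, 0), c(9, 9)),
                     labels = c("a", "a", "b", "b"), seed = 6)
  dm <- decompose(fm, 2L, seed = 3)
  rl <- relabel(fm, dm)
  expect_equal(nrow(rl$X), nrow(fm$X))
  expect_equal(parent_labels(rl$labels, dm), fm$labels)
  expect_equal(rl$labels, unname(dm$assignments[fm$sample_ids]))
  bad <- feature_matrix(fm$X[1:2, ], c("ghost1", "ghost2"))
  expect_error(relabel(bad, dm), "not present")
})

test_that("reassembly reproduces the hand-computed score cases", {
  dm <- list(subclass_of = c("A#0" = "A", "A#1" = "A",
                             "B#0" = "B", "B#1" = "B"))
  class(dm) <- "decomposition_map"
  s1 <- matrix(c(0.3, 0.4, 0.2, 0.1), 1,
               dimnames = list(NULL, names(dm$subclass_of)))
  r_arg <- reassemble(s1, dm, "argmax_map")
  r_sum <- reassemble(s1, dm, "prob_sum")
  expect_equal(r_arg$labels, "A")
  expect_equal(r_sum$labels, "A")
  expect_equal(unname(r_sum$scores[1, "A"]), 0.7, tolerance = 1e-12)
  # the modes can disagree; both answers are forced by arithmetic
  s2 <- matrix(c(0.35, 0.05, 0.30, 0.30), 1,
               dimnames = list(NULL, names(dm$subclass_of)))
  expect_equal(reassemble(s2, dm, "argmax_map")$labels, "A")
  r2 <- reassemble(s2, dm, "prob_sum")
  expect_equal(r2$labels, "B")
  expect_equal(unname(r2$scores[1, "B"]), 0.60, tolerance = 1e-12)
  # parent scores always sum to 1
  set.seed(12)
  S <- matrix(stats::rexp(40), 10)
  S <- S / rowSums(S)
  colnames(S) <- names(dm$subclass_of)
  expect_equal(rowSums(reassemble(S, dm, "prob_sum")$scores),
               rep(1, 10), tolerance = 1e-9)
  # hard subclass labels map straight through; perfect subclass
  # predictions reassemble to perfect parent predictions
  hard <- c("A#1", "B#0", "A#0", "B#1")
  expect_equal(reassemble(hard, dm)$labels, c("A", "B", "A", "B"))
  expect_error(reassemble(c("C#0"), dm), "unknown subclass")
})

test_that("per-class silhouettes match the brute-force oracle", {
  fm <- make_blob_fm(centers = rbind(c(0, 0), c(6, 0), c(0, 30), c(40, 30)),
                     sd = 0.4, seed = 9, labels = c("p", "p", "q", "q"))
  dm <- decompose(fm, 2L, seed = 2)
  sil <- silhouette_by_class(fm, dm)
  for (cls in c("p", "q")) {
    rows <- which(fm$labels == cls)
    cl <- as.integer(factor(dm$assignments[fm$sample_ids[rows]]))
    expect_equal(unname(sil[cls]),
                 oracle_silhouette_mean(fm$X[rows, ], cl),
                 tolerance = 1e-9)
  }
  # strongly separated point masses approach silhouette 1
  expect_gt(sil[["q"]], 0.95)
  # a parent with a single subclass is undefined, not a number
  dm1 <- decompose(fm, c(p = 1L, q = 2L), seed = 2)
  expect_true(is.na(silhouette_by_class(fm, dm1)[["p"]]))
})

test_that("subcluster recovery degrades gracefully as separation shrinks", {
  seps <- c(8, 3, 0.5)
  mean_ari <- vapply(seps, function(sep) {
    aris <- vapply(1:3, function(sd_) {
      spec <- small_task_spec(seed = sd_, n = 8L, slices = 3L,
                              subcluster_separation = sep)
      task <- make_classification_task(spec)
      ext <- fit_extractor(backbone_spec("deterministic_texture"), task)
      fm <- transform_features(ext, task)
      fmr <- transform_reduction(fit_reduction(fm, 0.95), fm)
      dm <- decompose(fmr, 2L, seed = sd_)
      mclust::adjustedRandIndex(unname(dm$assignments[task_ids(task)]),
                                task$meta$subcluster)
    }, numeric(1))
    mean(aris)
  }, numeric(1))
  expect_true(all(diff(mean_ari) <= 1e-9))
  expect_gte(mean_ari[1], 0.99)
})
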