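test_that("confusion tallies match a direct oracle", {
  y <- rep(c("p", "n"), 5)
  conf <- confusion(y, y, positive = "p")
  expect_equal(conf[1, 1] + conf[2, 2], 10L)
  flipped <- ifelse(y == "p", "n", "p")
  cf <- confusion(y, flipped, positive = "p")
  expect_equal(cf[1, 1] + cf[2, 2], 0L)
  expect_equal(cf[1, 2] + cf[2, 1], 10L)
  set.seed(14)
  yt <- sample(c("p", "n"), 50, replace = TRUE)
  yp <- sample(c("p", "n"), 50, replace = TRUE)
  cc <- confusion(yt, yp, "p")
  expect_equal(cc[1, 1], sum(yt == "p" & yp == "p"))
  expect_equal(cc[1, 2], sum(yt == "p" & yp == "n"))
  expect_equal(cc[2, 1], sum(yt == "n" & yp == "p"))
  expect_equal(cc[2, 2], sum(yt == "n" & yp == "n"))
  expect_error(confusion(yt, replace(yp, 1, "zz"), "p"), "unseen")
})

test_that("metric formulas match hand computation on the toy matrix", {
  yt <- c(rep("pos", 10), rep("neg", 10))
  yp <- c(rep("pos", 9), "neg", rep("pos", 2), rep("neg", 8))
  m <- metrics(confusion(yt, yp, "pos"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  expect_identical(m$recall, m$sensitivity)
})

test_that("zero-denominator metrics are undefined (NA), never 0 or 1", {
  # truth all negative: sensitivity and precision have no denominator
  yt <- rep("neg", 6)
  yp <- rep("neg", 6)
  m <- metrics(confusion(yt, yp, "pos"))
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$specificity, 1)
})

test_that("AUC equals the all-pairs ranking oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    y <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    s <- round(stats::rnorm(n), 1)  # rounding forces ties
    got <- auc_with_ci(y, s, positive = "b", n_boot = 10, seed = 1)$auc
    expect_equal(got, oracle_auc(y, s, "b"), tolerance = 1e-12)
  }
  # perfect separation and all-ties extremes
  y <- c(rep("d", 5), rep("h", 5))
  r <- auc_with_ci(y, c(6:10, 1:5), positive = "d", n_boot = 50, seed = 2)
  expect_equal(r$auc, 1.0)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(auc_with_ci(y, rep(3, 10), positive = "d")$auc, 0.5)
  # single class -> undefined
  expect_true(is.na(auc_with_ci(rep("d", 4), 1:4, positive = "d")$auc))
  # CI reproducible under a fixed seed
  s <- stats::rnorm(10)
  c1 <- auc_with_ci(y, s, "d", n_boot = 200, seed = 9)
  c2 <- auc_with_ci(y, s, "d", n_boot = 200, seed = 9)
  expect_identical(c1, c2)
  expect_true(c1$ci_low <= c1$auc && c1$auc <= c1$ci_high)
})

make_flat_set <- function(counts, strata = NULL) {
  # one slice per subject; counts is a named vector label -> n
  ids <- labs <- strs <- character(0)
  for (lab in names(counts)) {
    n <- counts[[lab]]
    ids <- c(ids, sprintf("%s%04d", lab, seq_len(n)))
    labs <- c(labs, rep(lab, n))
    strs <- c(strs, if (is.null(strata)) rep(NA_character_, n)
              else rep(names(strata), times = round(n * strata)))
  }
  slice_set(replicate(length(ids), matrix(0, 2, 2), simplify = FALSE),
            data.frame(subject_id = ids, slice_index = 0L, label = labs,
                       stratum = strs, stringsAsFactors = FALSE))
}

test_that("oversampling equalizes a 321:146 cohort and keeps originals", {
  d <- make_flat_set(c(sMCI = 321L, pMCI = 146L))
  o <- oversample(d, seed = 42)
  tab <- table(o$meta$label)
  expect_equal(unname(tab[["pMCI"]]), 321L)
  expect_equal(unname(tab[["sMCI"]]), 321L)
  # every original sample is still present
  expect_true(all(d$meta$subject_id %in% o$meta$subject_id))
  # duplicates come only from the minority class
  dups <- grepl("\\.dup", o$meta$subject_id)
  expect_true(all(o$meta$label[dups] == "pMCI"))
  # already balanced data is returned unchanged
  b <- make_flat_set(c(x = 10L, y = 10L))
  expect_identical(oversample(b, seed = 1)$meta, b$meta)
})

test_that("stratum-aware oversampling balances each stratum independently", {
  # stratum F: 36 s vs 4 p (9:1); stratum M: 24 s vs 16 p (6:4)
  d <- make_flat_set(c(s = 60L, p = 20L))
  d$meta$stratum[d$meta$label == "s"] <- rep(c("F", "M"), c(36, 24))
  d$meta$stratum[d$meta$label == "p"] <- rep(c("F", "M"), c(4, 16))
  o <- oversample(d, by_stratum = TRUE, seed = 3)
  counts <- table(o$meta$stratum, o$meta$label)
  expect_equal(unname(counts["F", "p"]), unname(counts["F", "s"]))
  expect_equal(unname(counts["M", "p"]), unname(counts["M", "s"]))
  expect_equal(unname(counts["F", "s"]), 36L)
  expect_equal(unname(counts["M", "s"]), 24L)
  # a single-class stratum is warned about and left unchanged; the
  # healthy stratum is still balanced
  solo <- make_flat_set(c(u = 4L, v = 4L))
  solo$meta$stratum <- c("F", "F", "M", "M", "M", "M", "M", "M")
  expect_warning(o2 <- oversample(solo, by_stratum = TRUE, seed = 1),
                 "single class")
  cnt <- table(o2$meta$stratum, o2$meta$label)
  expect_equal(as.integer(cnt["F", c("u", "v")]), c(2L, 0L))
  expect_equal(cnt[["M", "u"]], cnt[["M", "v"]])
})

test_that("oversampling duplicates whole subjects, not loose slices", {
  imgs <- replicate(9, matrix(0, 2, 2), simplify = FALSE)
  meta <- data.frame(
    subject_id = c(rep("m1", 3), rep("m2", 3), rep("j1", 3)),
    slice_index = rep(0:2, 3),
    label = c(rep("maj", 6), rep("min", 3)))
  d <- slice_set(imgs, meta)
  o <- oversample(d, seed = 5)
  expect_equal(sum(o$meta$label == "min"), 6L)
  dup_subjects <- unique(grep("\\.dup", o$meta$subject_id, value = TRUE))
  for (s in dup_subjects)
    expect_equal(sort(o$meta$slice_index[o$meta$subject_id == s]), 0:2)
  # determinism under seed
  o2 <- oversample(d, seed = 5)
  expect_identical(o$meta, o2$meta)
})

test_that("stratified summaries aggregate fold reports correctly", {
  r1 <- evaluation_report(c("p", "p", "n", "n"), c("p", "n", "n", "n"),
                          positive = "p", fold = 1L, stratum = "F")
  expect_equal(r1$accuracy, 0.75)
  s1 <- stratified_summary(list(r1), group_by = "stratum")
  expect_equal(s1$accuracy_mean[s1$group == "F"], r1$accuracy)
  expect_equal(s1$accuracy_sd[s1$group == "F"], 0)
  # two identical reports -> SD 0
  s2 <- stratified_summary(list(r1, r1), group_by = "stratum")
  expect_equal(s2$accuracy_sd[s2$group == "F"], 0)
  # mixed strata: means match direct computation, combined row present
  r2 <- evaluation_report(c("p", "n"), c("p", "p"), positive = "p",
                          fold = 2L, stratum = "M")
  s3 <- stratified_summary(list(r1, r2), group_by = "stratum")
  expect_setequal(s3$group, c("F", "M", "<combined>"))
  expect_equal(s3$accuracy_mean[s3$group == "<combined>"],
               mean(c(r1$accuracy, r2$accuracy)))
  expect_equal(s3$accuracy_sd[s3$group == "<combined>"],
               stats::sd(c(r1$accuracy, r2$accuracy)))
})

test_that("report metric identities hold against the stored confusion", {
  set.seed(50)
  yt <- sample(c("p", "n"), 40, replace = TRUE)
  yp <- sample(c("p", "n"), 40, replace = TRUE)
  sc <- stats::runif(40)
  r <- evaluation_report(yt, yp, sc, positive = "p", n_boot = 50, seed = 1)
  m <- metrics(r$confusion)
  for (k in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    expect_identical(r[[k]], m[[k]])
  expect_equal(r$auc, oracle_auc(yt, sc, "p"), tolerance = 1e-12)
})
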