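test_that("the texture extractor is stateless and repeatable", {
  task <- make_classification_task(small_task_spec(seed = 1, n = 4L,
                                                   slices = 2L))
  bb <- backbone_spec("deterministic_texture")
  e1 <- fit_extractor(bb, task)
  e2 <- fit_extractor(bb, task)
  f1 <- transform_features(e1, task)
  f2 <- transform_features(e2, task)
  expect_identical(f1$X, f2$X)
  expect_equal(ncol(f1$X), 40L)
  expect_equal(f1$sample_ids, task_ids(task))
})

test_that("reference_cnn fine-tuning reduces training loss, deterministically", {
  task <- make_classification_task(small_task_spec(seed = 2, n = 6L,
                                                   slices = 3L))
  bb <- backbone_spec("reference_cnn", n_filters = 4L, hidden = 8L)
  cfg <- train_config(epochs = 8L, batch_size = 16L, learning_rate = 0.01,
                      seed = 5L)
  e1 <- fit_extractor(bb, task, cfg)
  expect_lt(e1$loss_history[length(e1$loss_history)], e1$loss_history[1])
  e2 <- fit_extractor(bb, task, cfg)
  expect_identical(transform_features(e1, task)$X,
                   transform_features(e2, task)$X)
})

test_that("extractor refuses single-class data", {
  task <- make_classification_task(small_task_spec(seed = 3, n = 4L,
                                                   slices = 2L))
  one <- subset_slices(task, which(task$meta$label == "A"))
  expect_error(fit_extractor(backbone_spec(), one), "2 classes")
})

test_that("classifier heads match labels and emit proper probabilities", {
  task <- make_classification_task(small_task_spec(seed = 4, n = 6L,
                                                   slices = 3L))
  # four subclass labels -> four-column score vectors
  ext <- fit_extractor(backbone_spec("deterministic_texture"), task)
  fm <- transform_features(ext, task)
  fmr <- transform_reduction(fit_reduction(fm, 0.95), fm)
  dm <- decompose(fmr, 2L, seed = 4)
  rl <- relabel(task, dm)
  bb4 <- backbone_spec("deterministic_texture", head_classes = 4L)
  clf <- fit_classifier(bb4, rl, train_config(epochs = 30L,
                                              batch_size = 32L,
                                              learning_rate = 0.1, seed = 4))
  S <- predict_scores(clf, task)
  expect_equal(ncol(S), 4L)
  expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-6)
  expect_true(all(S >= 0))
  # head/label mismatch is a validation error
  expect_error(fit_classifier(backbone_spec(head_classes = 3L), rl),
               "classes")
})

test_that("a separable task is learned to training accuracy 1", {
  spec <- small_task_spec(seed = 6, n = 8L, slices = 3L, class_overlap = 0)
  task <- make_classification_task(spec)
  clf <- fit_classifier(backbone_spec("deterministic_texture"), task,
                        train_config(epochs = 80L, batch_size = 32L,
                                     learning_rate = 0.1, seed = 6))
  S <- predict_scores(clf, task)
  pred <- colnames(S)[max.col(S, ties.method = "first")]
  expect_equal(mean(pred == task$meta$label), 1.0)
})

test_that("freeze-and-replace keeps the body bit-identical through retraining", {
  pair <- make_transfer_pair(small_task_spec(seed = 7, n = 6L, slices = 3L),
                             target_shift = 0.4, seed = 7)
  bb <- backbone_spec("reference_cnn", n_filters = 4L, hidden = 8L,
                      head_classes = 2L)
  cfg <- train_config(epochs = 10L, batch_size = 32L, learning_rate = 0.01,
                      seed = 7)
  clf <- fit_classifier(bb, pair$base, cfg)
  d0 <- body_digest(clf)
  frz <- freeze_and_replace_head(clf, 2L, seed = 7)
  expect_true(frz$frozen)
  expect_identical(frz$frozen_body_digest, d0)
  trained <- retrain_head(frz, pair$target, cfg)
  expect_identical(body_digest(trained), d0)
  S <- predict_scores(trained, pair$target)
  expect_equal(ncol(S), 2L)
  expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-6)
  # replacing the head twice keeps only the latest head, body stable
  frz2 <- freeze_and_replace_head(freeze_and_replace_head(clf, 3L), 2L)
  expect_identical(body_digest(frz2), d0)
  expect_equal(ncol(frz2$layers[[length(frz2$layers)]]$W), 2L)
  expect_error(freeze_and_replace_head(clf, 1L), ">= 2")
})

test_that("identical seeds give identical model states", {
  task <- make_classification_task(small_task_spec(seed = 8, n = 5L,
                                                   slices = 2L))
  bb <- backbone_spec("reference_cnn", n_filters = 4L, hidden = 8L)
  cfg <- train_config(epochs = 5L, batch_size = 16L, learning_rate = 0.01,
                      seed = 9)
  m1 <- fit_classifier(bb, task, cfg)
  m2 <- fit_classifier(bb, task, cfg)
  expect_identical(body_digest(m1), body_digest(m2))
  expect_identical(m1$layers, m2$layers)
})
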