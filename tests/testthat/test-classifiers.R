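test_that("majority subsampling hits the scaled target and is seeded", {
  docs <- c(lapply(1:50, function(i) make_doc(i, "pos", 1L)),
            lapply(51:550, function(i) make_doc(i, "neg", 0L)))
  cfg <- imbalance_config(sampling_ratio = c(3411, 589), seed = 5)
  out <- subsample_majority(docs, cfg)
  labs <- sapply(out, `[[`, "source_label")
  expect_equal(sum(labs == 1), 50)                      # all minority kept
  expect_equal(sum(labs == 0), round(50 * 3411 / 589))  # scaled target
  out2 <- subsample_majority(docs, cfg)
  expect_identical(sapply(out, `[[`, "record_id"),
                   sapply(out2, `[[`, "record_id"))     # determinism
  # infeasible target: keep everything (message, no error)
  cfg2 <- imbalance_config(sampling_ratio = c(50000, 589), seed = 5)
  expect_message(out3 <- subsample_majority(docs, cfg2), "keeping all")
  expect_length(out3, 550)
})

test_that("balanced class weights reproduce the published pair", {
  w <- balanced_class_weights(3411, 589)
  expect_equal(signif(unname(w), 2), c(0.59, 3.4))
  expect_equal(unname(balanced_class_weights(500, 500)), c(1, 1))
  expect_equal(unname(balanced_class_weights(900, 100)),
               c(1000 / 1800, 5.0), tolerance = 1e-12)
  expect_error(balanced_class_weights(0, 10), "positive")
})

test_that("a separable corpus is learned nearly perfectly by the CNN", {
  docs <- separable_docs(n = 400, seed = 2)
  labels <- sapply(docs, `[[`, "source_label")
  emb <- train_embeddings(docs, embedding_config("wholeword", dim = 16,
                                                 epochs = 2, min_count = 1,
                                                 seed = 3))
  cfg <- cnn_config("wholeword", max_length = 30, n_filters = 64,
                    n_epochs = 3, batch_size = 16,
                    embedding = embedding_config("wholeword", dim = 16,
                                                 epochs = 2, seed = 3),
                    seed = 4)
  m <- train_cnn(docs, emb, cfg)
  p <- predict(m, docs)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(roc_auc(p, labels), 0.99)
  # max-norm constraint holds for every convolution filter
  expect_true(all(m$fit$filter_norms <= cfg$maxnorm_constraint + 1e-6))
})

test_that("CNN training requires both classes and matching dimensions", {
  docs <- separable_docs(40)
  one_class <- docs[sapply(docs, `[[`, "source_label") == 1]
  emb <- train_embeddings(docs, embedding_config("wholeword", dim = 8,
                                                 epochs = 1, min_count = 1))
  expect_error(train_cnn(one_class, emb,
                         cnn_config("wholeword",
                                    embedding = embedding_config(dim = 8))),
               "single class")
  bad_cfg <- cnn_config("wholeword",
                        embedding = embedding_config(dim = 99))
  expect_error(train_cnn(docs, emb, bad_cfg), "does not match")
})

test_that("the SVM separates well-separated clouds and is calibrated symmetrically", {
  # two disjoint vocabularies: genuinely separated clouds in TF-IDF space
  set.seed(9)
  pos_vocab <- paste0("p", letters[1:10])
  neg_vocab <- paste0("n", letters[1:10])
  docs <- lapply(1:120, function(i) {
    lab <- as.integer(i <= 60)
    make_doc(i, sample(if (lab) pos_vocab else neg_vocab, 8,
                       replace = TRUE), lab)
  })
  labels <- sapply(docs, `[[`, "source_label")
  train_idx <- seq(1, 120, by = 2)
  m <- train_svm(docs[train_idx], cfg = svm_config(seed = 1))
  p <- predict(m, docs[-train_idx])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(as.integer(p >= 0.5), labels[-train_idx])  # 100% held-out
  # label inversion flips probabilities (calibration symmetry)
  flipped <- lapply(docs[train_idx], function(d) {
    d$source_label <- 1L - d$source_label; d
  })
  m2 <- train_svm(flipped, cfg = svm_config(seed = 1))
  p2 <- predict(m2, docs[-train_idx])
  expect_lt(max(abs(p2 - (1 - p))), 0.05)
})

test_that("prediction is deterministic, order-preserving and batch-consistent", {
  docs <- separable_docs(n = 80, seed = 5)
  emb <- train_embeddings(docs, embedding_config("wholeword", dim = 8,
                                                 epochs = 1, min_count = 1,
                                                 seed = 1))
  m <- train_cnn(docs, emb,
                 cnn_config("wholeword", max_length = 20, n_filters = 8,
                            n_epochs = 1,
                            embedding = embedding_config(dim = 8), seed = 1))
  p_batch <- predict(m, docs[1:10])
  p_single <- vapply(docs[1:10], function(d) predict(m, d), numeric(1))
  expect_equal(p_batch, p_single, tolerance = 1e-6)
  expect_identical(predict(m, docs[[3]]), predict(m, docs[[3]]))
  # empty document: valid probability plus a warning
  expect_warning(pe <- predict(m, make_doc("e", character())),
                 "no usable text")
  expect_true(pe >= 0 && pe <= 1)
})

test_that("end-to-end training is reproducible and leak-free under permutation", {
  docs <- separable_docs(n = 200, seed = 12)
  emb_cfg <- embedding_config("wholeword", dim = 8, epochs = 1,
                              min_count = 1, seed = 6)
  emb <- train_embeddings(docs, emb_cfg)
  cfg <- cnn_config("wholeword", max_length = 20, n_filters = 8,
                    n_epochs = 2, embedding = emb_cfg, seed = 6)
  p1 <- predict(train_cnn(docs, emb, cfg), docs[1:20])
  p2 <- predict(train_cnn(docs, emb, cfg), docs[1:20])
  expect_equal(p1, p2, tolerance = 1e-6)

  # label permutation: validation AUC must hover at chance (checked over
  # several seeds at scale in the acceptance suite; one spot check here)
  set.seed(31)
  perm <- lapply(docs, function(d) {
    d$source_label <- NA_integer_; d
  })
  labs <- sample(sapply(docs, `[[`, "source_label"))
  for (i in seq_along(perm)) perm[[i]]$source_label <- labs[i]
  m <- train_svm(perm[1:100], cfg = svm_config(seed = 2))
  au <- roc_auc(predict(m, perm[101:200]),
                sapply(perm[101:200], `[[`, "source_label"))
  expect_gt(au, 0.3)
  expect_lt(au, 0.7)
})
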