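test_that("label prevalence is exact and generation is byte-identical", {
  cfg <- generator_config(1000, prevalence = 0.12, seed = 3)
  corp <- generate_corpus(cfg)
  expect_equal(sum(sapply(corp, `[[`, "label")), 120)
  corp2 <- generate_corpus(cfg)
  expect_identical(corp, corp2)
  # a different seed changes the corpus
  corp3 <- generate_corpus(generator_config(1000, prevalence = 0.12,
                                            seed = 4))
  expect_false(identical(corp, corp3))
})

test_that("signal-phrase document frequency matches its configured rate", {
  corp <- generate_corpus(generator_config(2000, seed = 7))
  labs <- sapply(corp, `[[`, "label")
  has_phrase <- sapply(corp, function(c)
    grepl("cluster randomized trial", paste(c$title, c$abstract,
                                            paste(c$keywords,
                                                  collapse = " ")),
          fixed = TRUE))
  expect_lt(abs(mean(has_phrase[labs == 1]) - 0.67), 0.05)
  expect_lt(abs(mean(has_phrase[labs == 0]) - 0.017), 0.01)
})

test_that("structured abstracts carry droppable conclusion sections", {
  corp <- generate_corpus(generator_config(400, seed = 9))
  structured <- grepl("CONCLUSIONS:", sapply(corp, `[[`, "abstract"),
                      fixed = TRUE)
  expect_gt(mean(structured), 0.35); expect_lt(mean(structured), 0.55)
  # preprocessing removes the conclusions text
  one <- corp[[which(structured)[1]]]
  stripped <- strip_structured_sections(one$abstract)
  expect_false(grepl("CONCLUSIONS:", stripped, fixed = TRUE))
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(1), "n_records")
  expect_error(generator_config(3, prevalence = 0.01), "infeasible")
  expect_error(generator_config(100, prevalence = 1.2), "prevalence")
  expect_error(generator_config(100, topic_shift = 1.5), "probabilities")
})

test_that("label noise flips the expected fraction of labels", {
  base <- generate_corpus(generator_config(1500, seed = 5, label_noise = 0))
  noisy <- generate_corpus(generator_config(1500, seed = 5,
                                            label_noise = 0.1))
  flips <- mean(sapply(base, `[[`, "label") != sapply(noisy, `[[`, "label"))
  expect_gt(flips, 0.06); expect_lt(flips, 0.14)
})

test_that("the screening file round-trips through the CSV reader", {
  cfg <- generator_config(40, prevalence = 0.25, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  corp <- generate_screening_file(cfg, path)
  back <- read_citations_csv(path)
  expect_length(back, 40)
  for (i in c(1, 17, 40)) {
    expect_equal(back[[i]]$record_id, corp[[i]]$record_id)
    expect_equal(back[[i]]$title, corp[[i]]$title)
    expect_equal(back[[i]]$abstract, corp[[i]]$abstract)
    expect_equal(back[[i]]$keywords, corp[[i]]$keywords)
    expect_equal(back[[i]]$subject_headings, corp[[i]]$subject_headings)
    expect_equal(back[[i]]$label, corp[[i]]$label)
  }
  # unlabeled variant has no label column
  path2 <- withr::local_tempfile(fileext = ".csv")
  generate_screening_file(cfg, path2, labeled = FALSE)
  expect_false("label" %in% names(read.csv(path2)))
  back2 <- read_citations_csv(path2)
  expect_true(all(is.na(sapply(back2, `[[`, "label"))))
})

test_that("the separability dial moves held-out AUC from perfect to chance", {
  # maximum separability: the signal phrase in every positive and no negative
  phrases_on <- default_signal_phrases()
  phrases_on$p_positive <- c(1, 0, 0, 0)
  phrases_on$p_negative <- 0
  cfg_on <- generator_config(2000, prevalence = 0.3, seed = 13,
                             signal_phrases = phrases_on, topic_shift = 0,
                             confuser_phrases =
                               default_confuser_phrases()[0, ])
  # no class difference at all
  phrases_off <- phrases_on
  phrases_off$p_positive <- phrases_off$p_negative <- 0.2
  cfg_off <- generator_config(2000, prevalence = 0.3, seed = 13,
                              signal_phrases = phrases_off, topic_shift = 0,
                              confuser_phrases =
                                default_confuser_phrases()[0, ])
  for (case in list(list(cfg = cfg_on, lo = 0.99, hi = 1.0),
                    list(cfg = cfg_off, lo = 0.4, hi = 0.6))) {
    docs <- lapply(generate_corpus(case$cfg), preprocess_citation)
    labs <- sapply(docs, `[[`, "source_label")
    set.seed(1)
    val <- sort(unlist(lapply(split(seq_along(labs), labs),
                              function(i) sample(i, round(0.3 * length(i))))))
    fit_docs <- docs[-val]
    members <- list(
      cnn_wholeword = train_cnn(
        fit_docs,
        train_embeddings(fit_docs, tiny_embedding("wholeword", seed = 2)),
        tiny_cnn("wholeword", seed = 2, max_length = 150L)),
      cnn_subword = train_cnn(
        fit_docs,
        train_embeddings(fit_docs, tiny_embedding("subword", seed = 2)),
        tiny_cnn("subword", seed = 2, max_length = 150L)),
      svm = train_svm(fit_docs, cfg = tiny_svm(seed = 2)))
    res <- ensemble_predict(members, docs[val], policy = 0.5)
    au <- roc_auc(res$probability, labs[val])
    expect_gte(au, case$lo)
    expect_lte(au, case$hi)
  }
})
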