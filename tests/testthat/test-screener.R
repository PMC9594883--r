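test_that("the fitted screener exposes its structure and methods", {
  fit <- fixture_screener()
  expect_s3_class(fit, "crt_screener")
  expect_named(fit$members, c("cnn_wholeword", "cnn_subword", "svm"))
  expect_s3_class(fit$policy, "threshold_policy")
  expect_s3_class(fit$validation, "screen_eval")
  expect_output(print(fit), "Ensemble CRT citation screener")
  expect_output(summary(fit), "Number needed to screen")
  # the policy achieved its target on validation (attainable here)
  expect_gte(fit$policy$achieved_sensitivity, 0.95)
})

test_that("predict returns consistent results across input forms", {
  fit <- fixture_screener()
  corp <- fixture_corpus()[1:20]
  res <- predict(fit, corp)
  expect_s3_class(res, "screening_results")
  expect_equal(nrow(res), 20)
  expect_true(all(res$probability >= 0 & res$probability <= 1))
  expect_equal(res$probability,
               rowMeans(res[, c("cnn_wholeword", "cnn_subword", "svm")]),
               tolerance = 1e-12)
  expect_equal(res$predicted_label,
               as.integer(res$probability >= fit$policy$threshold))
  expect_equal(predict(fit, corp, type = "response"), res$probability)
  expect_equal(predict(fit, corp, type = "class"), res$predicted_label)
})

test_that("training fails clearly without labels or with one class", {
  corp <- fixture_corpus()[1:30]
  unl <- lapply(corp, function(c) { c$label <- NA_integer_; c })
  expect_error(crt_screener(unl), "label")
  neg_only <- lapply(corp, function(c) { c$label <- 0L; c })
  expect_error(crt_screener(neg_only), "no positive records")
})

test_that("refitting with the same seed reproduces every reported number", {
  corp <- generate_corpus(generator_config(300, prevalence = 0.2,
                                           seed = 55))
  args <- list(corp, cnn_wholeword = tiny_cnn("wholeword"),
               cnn_subword = tiny_cnn("subword"), svm = tiny_svm(),
               validation_fraction = 0.2, bootstrap = NULL, seed = 77L)
  f1 <- do.call(crt_screener, args)
  f2 <- do.call(crt_screener, args)
  expect_equal(f1$policy$threshold, f2$policy$threshold, tolerance = 1e-6)
  expect_equal(f1$validation$auc, f2$validation$auc, tolerance = 1e-6)
  expect_equal(f1$validation_scores$probability,
               f2$validation_scores$probability, tolerance = 1e-6)
})

test_that("a bundle saves, checksums and restores to identical predictions", {
  fit <- fixture_screener()
  corp <- fixture_corpus()[31:45]
  dir <- withr::local_tempdir()
  save_screener(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(manifest$format, "crtscreen_bundle")
  back <- load_screener(dir)
  expect_equal(predict(back, corp, type = "response"),
               predict(fit, corp, type = "response"), tolerance = 1e-12)
  # tampering is detected
  payload <- file.path(dir, "members.rds")
  writeBin(as.raw(c(1, 2, 3)), payload)
  expect_error(load_screener(dir), "checksum")
})

test_that("file screening writes sorted results and reports the reduction", {
  fit <- fixture_screener()
  input <- withr::local_tempfile(fileext = ".csv")
  generate_screening_file(generator_config(60, prevalence = 0.25, seed = 6),
                          input, labeled = FALSE)
  output <- withr::local_tempfile(fileext = ".csv")
  res <- suppressMessages(screen_file(fit, input, output))
  expect_equal(res$n, 60)
  expect_equal(res$reduction_ratio, res$n_positive / 60)
  out <- read.csv(output)
  expect_equal(nrow(out), 60)
  expect_true(all(diff(out$probability) <= 0))
  # records carrying the signal phrase rank above those without, on average
  back <- read_citations_csv(input)
  has_sig <- sapply(back, function(c)
    grepl("cluster", paste(c$title, c$abstract), fixed = TRUE))
  ranks <- rank(-out$probability)[match(sapply(back, `[[`, "record_id"),
                                        out$record_id)]
  expect_lt(mean(ranks[has_sig]), mean(ranks[!has_sig]))
})

test_that("screening an empty file yields a header-only output and warning", {
  fit <- fixture_screener()
  input <- withr::local_tempfile(fileext = ".csv")
  writeLines("record_id,title,abstract", input)
  output <- withr::local_tempfile(fileext = ".csv")
  expect_warning(res <- screen_file(fit, input, output), "no records")
  expect_equal(res$n, 0L)
  expect_equal(nrow(read.csv(output)), 0)
})

test_that("external evaluation reproduces the validation report on its own split", {
  fit <- fixture_screener()
  corp <- fixture_corpus()
  ids <- fit$validation_scores$record_id
  val_cits <- corp[match(ids, sapply(corp, `[[`, "record_id"))]
  rep <- suppressWarnings(
    evaluate_screener(fit, val_cits, bootstrap = NULL))
  expect_equal(rep$auc, fit$validation$auc, tolerance = 1e-12)
  expect_equal(rep$sensitivity, fit$validation$sensitivity)
  expect_equal(unclass(rep$counts), unclass(fit$validation$counts))
})

test_that("small external samples and inverted signal raise warnings", {
  fit <- fixture_screener()
  small <- fixture_corpus()[1:40]
  expect_warning(evaluate_screener(fit, small, bootstrap = NULL),
                 "fewer than 100")
  # adversarial corpus: the signal phrase pattern appears in NEGATIVES
  inverted <- default_signal_phrases()
  tmp <- inverted$p_positive
  inverted$p_positive <- inverted$p_negative
  inverted$p_negative <- tmp
  adv <- generate_corpus(generator_config(300, prevalence = 0.3, seed = 23,
                                          signal_phrases = inverted,
                                          topic_shift = 0))
  w <- capture_warnings(rep <- evaluate_screener(fit, adv, bootstrap = NULL))
  expect_true(any(grepl("below chance", w)))
  expect_lt(rep$auc, 0.5)
})
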