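# brute-force pairwise-concordance oracle for the AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

test_that("AUC matches the worked examples and the concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(11)
  for (i in 1:300) {
    n <- sample(4:20, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:2, 1))
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    labels <- rbinom(80, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- runif(80) + 0.5 * labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(5)
  labels <- rbinom(2000, 1, 0.3)
  scores <- runif(2000)
  au <- roc_auc(scores, labels)
  expect_gt(au, 0.45); expect_lt(au, 0.55)
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and integrates to the AUC", {
  set.seed(8)
  scores <- round(runif(200), 2)
  labels <- rbinom(200, 1, 0.25)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("confusion counts respect the >= decision rule and boundaries", {
  scores <- c(0.9, 0.8, 0.3, 0.1); labels <- c(1, 1, 0, 0)
  cc <- confusion_at_threshold(scores, labels, 0.5)
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  cc0 <- confusion_at_threshold(scores, labels, 0)
  expect_equal(cc0$TN + cc0$FN, 0L)
  cc1 <- confusion_at_threshold(scores, labels, 0.91)
  expect_equal(cc1$TP + cc1$FP, 0L)
  # ties: a score exactly at the threshold counts positive
  cct <- confusion_at_threshold(c(0.5, 0.5), c(1, 0), 0.5)
  expect_equal(cct$TP, 1L); expect_equal(cct$FP, 1L)
})

test_that("screening workload metrics follow their defining formulas", {
  perfect <- confusion_at_threshold(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(number_needed_to_screen(perfect), 1.0)
  expect_equal(nns_from_rates(0.5, 0.5, 0.5, 1000), 2.0)
  expect_warning(und <- number_needed_to_screen(
    confusion_at_threshold(c(0.1), c(1), 0.5)), "undefined")
  expect_true(is.na(und))
  expect_equal(number_needed_to_read(10, 10), 1.0)
  expect_equal(number_needed_to_read(1, 10), 10.0)
  # NNS equals 1/precision to machine precision on random counts
  set.seed(3)
  for (i in 1:50) {
    cc <- confusion_at_threshold(runif(50), rbinom(50, 1, 0.4), 0.4)
    if (cc$TP == 0) next
    expect_equal(number_needed_to_screen(cc),
                 1 / (cc$TP / (cc$TP + cc$FP)), tolerance = 1e-15)
  }
})

test_that("bootstrap CIs are seeded, degenerate-safe and cover the truth", {
  # perfectly separated scores: every replicate is perfect
  ci <- bootstrap_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), "auc",
                     bootstrap_config(n_replicates = 50, seed = 4))
  expect_equal(ci, c(1, 1))
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  cfg <- bootstrap_config(n_replicates = 100, seed = 9)
  expect_identical(bootstrap_ci(scores, labels, "auc", cfg),
                   bootstrap_ci(scores, labels, "auc", cfg))
  # nominal coverage under a binormal score model with known AUC
  mu <- 1.2
  true_auc <- pnorm(mu / sqrt(2))
  set.seed(77)
  covered <- 0
  n_sim <- 200
  for (s in 1:n_sim) {
    lab <- c(rep(1, 40), rep(0, 60))
    sc <- c(rnorm(40, mu), rnorm(60))
    ci <- bootstrap_ci(sc, lab, "auc",
                       bootstrap_config(n_replicates = 400, seed = s))
    covered <- covered + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gte(covered / n_sim, 0.90)
})

test_that("per-class term fractions match construction", {
  docs <- list(make_doc(1, c("cluster", "trial"), 1L),
               make_doc(2, c("cluster", "cluster", "drug"), 1L),
               make_doc(3, c("drug", "trial"), 0L),
               make_doc(4, c("placebo"), 0L))
  assoc <- term_class_association(docs)
  row <- assoc[assoc$term == "cluster", ]
  expect_equal(row$frac_positive, 1.0)   # within-doc repeats count once
  expect_equal(row$frac_negative, 0.0)
  expect_equal(assoc$term[1], "cluster") # sorted by difference
  expect_false("absent" %in% assoc$term)
  expect_equal(assoc[assoc$term == "trial", ]$frac_positive, 0.5)
})

test_that("generated signal-phrase frequency round-trips through association scores", {
  corp <- generate_corpus(generator_config(2000, seed = 17))
  docs <- lapply(corp, preprocess_citation)
  assoc <- term_class_association(docs)
  row <- assoc[assoc$term == "cluster", ]
  expect_lt(abs(row$frac_positive - 0.67), 0.05)
  expect_lt(abs(row$frac_negative - 0.017), 0.02)
})

test_that("the evaluation report is internally consistent and serializes", {
  set.seed(12)
  scores <- c(runif(40, 0.4, 1), runif(160, 0, 0.6))
  labels <- c(rep(1, 40), rep(0, 160))
  rep <- eval_report(scores, labels, 0.5,
                     bootstrap_config(n_replicates = 200, seed = 2))
  expect_equal(rep$sensitivity, rep$counts$TP / 40)
  expect_equal(rep$fpr, 1 - rep$specificity)
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_gte(rep$nns, 1)
  expect_equal(rep$nnr, 200 / 40)
  js <- jsonlite::fromJSON(eval_report_json(rep))
  expect_equal(js$auc, rep$auc, tolerance = 1e-12)
  expect_output(print(rep), "Number needed to screen")
})
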