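as_citation_list <- function(x, column_map = NULL, label_values = NULL) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(read_citations_csv(x, column_map, label_values))
  if (is.data.frame(x)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp))
    write.csv(x, tmp, row.names = FALSE)
    return(read_citations_csv(tmp, column_map, label_values))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "citation_record")))
    return(x)
  stop2("x must be a CSV path, a data frame, or a list of citation records")
}

#' Fit the ensemble citation screener
#'
#' The package's central fitting function.  From a labeled citation corpus it
#' runs the full training pipeline: stratified train/validation split,
#' deterministic preprocessing, corpus-trained whole-word and subword
#' skip-gram embeddings, sequence and TF-IDF encoders, class-imbalance
#' handling, the three member models (two convolutional classifiers and the
#' RBF support-vector classifier), probability-averaging ensembling, and
#' selection of the sensitivity-targeted decision threshold on the
#' validation split.  Every stage is seeded; identical inputs, configuration
#' and seed reproduce identical results.
#'
#' @param x Labeled citations: a CSV path, a data frame, or a list of
#'   [citation_record()] records.
#' @param preprocess A [preprocess_config()].
#' @param cnn_wholeword,cnn_subword [cnn_config()]s for the two
#'   convolutional members (defaults: the published presets).
#' @param svm An [svm_config()].
#' @param imbalance An [imbalance_config()] applied to the training split.
#' @param target_sensitivity Required validation sensitivity for the
#'   decision threshold (default 0.95).
#' @param validation_fraction Stratified holdout fraction (default 0.12,
#'   i.e. 600 of 5000).
#' @param bootstrap A [bootstrap_config()] for the validation report CIs,
#'   or `NULL` to skip intervals.
#' @param embedding_corpus Optional additional unlabeled citations on which
#'   the embeddings (only) are trained together with the training split —
#'   mirrors training embeddings on the full retrieved corpus rather than
#'   the labeled subset.
#' @param column_map,label_values Passed to [read_citations_csv()] when `x`
#'   is a file or data frame.
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return An object of class `"crt_screener"` with `members` (the three
#'   fitted models), `policy` (the threshold), `validation` (a
#'   [eval_report()] on the holdout), the configurations, and provenance
#'   (seeds, package version, input checksum).
#' @seealso [predict.crt_screener()], [screen_file()],
#'   [evaluate_screener()], [save_screener()]
#' @export
crt_screener <- function(x, preprocess = preprocess_config(),
                         cnn_wholeword = cnn_config("wholeword"),
                         cnn_subword = cnn_config("subword"),
                         svm = svm_config(),
                         imbalance = imbalance_config(),
                         target_sensitivity = 0.95,
                         validation_fraction = 0.12,
                         bootstrap = bootstrap_config(),
                         embedding_corpus = NULL,
                         column_map = NULL, label_values = NULL, seed = 1L) {
  cl <- match.call()
  citations <- as_citation_list(x, column_map, label_values)
  labels <- citation_labels(citations)
  if (anyNA(labels))
    stop2("all records must carry a 0/1 value in the label column")
  if (sum(labels == 1) == 0)
    stop2("no positive records in the label column; both classes required")
  if (sum(labels == 0) == 0)
    stop2("no negative records in the label column; both classes required")

  docs <- preprocess_corpus(citations, preprocess)
  val_idx <- stratified_split(labels, validation_fraction,
                              derive_seed(seed, "split"))
  train_docs <- docs[-val_idx]
  val_docs <- docs[val_idx]
  val_labels <- labels[val_idx]

  emb_docs <- train_docs
  if (!is.null(embedding_corpus)) {
    extra <- preprocess_corpus(as_citation_list(embedding_corpus),
                               preprocess)
    emb_docs <- c(emb_docs, extra)
  }
  cnn_wholeword$embedding$seed <- derive_seed(seed, "embed_wholeword")
  cnn_subword$embedding$seed <- derive_seed(seed, "embed_subword")
  cnn_wholeword$seed <- derive_seed(seed, "cnn_wholeword")
  cnn_subword$seed <- derive_seed(seed, "cnn_subword")
  svm$seed <- derive_seed(seed, "svm")
  imbalance$seed <- derive_seed(seed, "subsample")

  emb_ww <- train_embeddings(emb_docs, cnn_wholeword$embedding)
  emb_sw <- train_embeddings(emb_docs, cnn_subword$embedding)
  encoder <- build_sequence_encoder(train_docs, cnn_wholeword$vocab_cap,
                                    cnn_wholeword$max_length)

  members <- list(
    cnn_wholeword = train_cnn(train_docs, emb_ww, cnn_wholeword, imbalance,
                              encoder = encoder),
    cnn_subword = train_cnn(train_docs, emb_sw, cnn_subword, imbalance,
                            encoder = encoder),
    svm = train_svm(train_docs, cfg = svm, imbalance = imbalance))

  val_probs <- vapply(members, function(m) predict(m, val_docs),
                      numeric(length(val_docs)))
  ens <- rowMeans(val_probs)
  policy <- select_threshold(ens, val_labels, target_sensitivity)
  validation <- eval_report(ens, val_labels, policy$threshold, bootstrap)

  structure(list(
    members = members, policy = policy, validation = validation,
    preprocess = preprocess,
    configs = list(cnn_wholeword = cnn_wholeword, cnn_subword = cnn_subword,
                   svm = svm, imbalance = imbalance),
    embeddings = list(wholeword = emb_ww, subword = emb_sw),
    encoder = encoder,
    n_train = length(train_docs), n_validation = length(val_docs),
    validation_scores = data.frame(record_id = vapply(val_docs, `[[`,
                                                      character(1),
                                                      "record_id"),
                                   probability = ens, label = val_labels,
                                   stringsAsFactors = FALSE),
    seed = as.integer(seed), version = as.character(utils::packageVersion("crtscreen")),
    call = cl),
    class = "crt_screener")
}

#' @export
print.crt_screener <- function(x, ...) {
  cat("Ensemble CRT citation screener\n")
  cat("  members: ", paste(names(x$members), collapse = ", "), "\n", sep = "")
  cat("  trained on ", x$n_train, " records, validated on ",
      x$n_validation, "\n", sep = "")
  cat(sprintf("  threshold %.4f (target sensitivity %.0f%%)\n",
              x$policy$threshold, 100 * x$policy$target_sensitivity))
  cat(sprintf("  validation AUC %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$validation$auc, 100 * x$validation$sensitivity,
              100 * x$validation$specificity))
  invisible(x)
}

#' @export
summary.crt_screener <- function(object, ...) {
  print(object)
  cat("\nValidation report:\n")
  print(object$validation)
  invisible(object)
}

#' Plot the validation ROC curve
#'
#' @param x A fitted [crt_screener()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crt_screener <- function(x, ...) {
  roc <- x$validation$roc
  graphics::plot(roc$fpr, roc$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Validation ROC (AUC %.1f%%)",
                                100 * x$validation$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Screen citations with a fitted ensemble
#'
#' @param object A fitted [crt_screener()].
#' @param newdata Citations to screen: CSV path, data frame, list of
#'   [citation_record()] records, or a list of preprocessed `token_document`s.
#' @param type `"results"` (default): the full `screening_results` data
#'   frame; `"response"`: ensemble probabilities; `"class"`: binary labels.
#' @param ... Unused.
#' @return Per `type`.
#' @export
predict.crt_screener <- function(object, newdata,
                                 type = c("results", "response", "class"),
                                 ...) {
  type <- match.arg(type)
  docs <- if (is.list(newdata) && length(newdata) &&
              all(vapply(newdata, inherits, logical(1), "token_document"))) {
    newdata
  } else {
    preprocess_corpus(as_citation_list(newdata), object$preprocess)
  }
  res <- ensemble_predict(object$members, docs, object$policy)
  switch(type, results = res, response = res$probability,
         class = res$predicted_label)
}

#' Screen an input file and write sorted results
#'
#' Reads unlabeled citations, scores them with the fitted ensemble, writes
#' the probability-sorted results CSV, and reports the number classified
#' positive together with the screening-reduction ratio
#' (positives / total records).
#'
#' @param object A fitted [crt_screener()].
#' @param input Input citations (CSV path or anything
#'   [predict.crt_screener()] accepts).
#' @param output Output CSV path.
#' @param column_map Optional column mapping for the input file.
#' @return Invisibly, a list with `n`, `n_positive`, `reduction_ratio` and
#'   the sorted results.
#' @export
screen_file <- function(object, input, output, column_map = NULL) {
  citations <- as_citation_list(input, column_map)
  if (!length(citations)) {
    empty <- data.frame(record_id = character(), probability = numeric(),
                        predicted_label = integer())
    for (k in names(object$members)) empty[[k]] <- numeric()
    write_results_csv(empty, output)
    warning("input file contains no records; header-only output written",
            call. = FALSE)
    return(invisible(list(n = 0L, n_positive = 0L,
                          reduction_ratio = NA_real_, results = empty)))
  }
  res <- predict(object, citations)
  sorted <- write_results_csv(res, output)
  n_pos <- sum(res$predicted_label == 1)
  message(sprintf(
    "screened %d records: %d classified positive (screening-reduction ratio %.3f)",
    nrow(res), n_pos, n_pos / nrow(res)))
  invisible(list(n = nrow(res), n_positive = n_pos,
                 reduction_ratio = n_pos / nrow(res), results = sorted))
}

#' Evaluate a fitted screener on a labeled set
#'
#' External-validation mode: scores the provided labeled citations and
#' produces the full evaluation report at the screener's stored threshold.
#' Warns when fewer than 100 labeled records are supplied (small external
#' samples give unstable estimates) and when AUC falls below 0.5 (the
#' ensemble ranks records worse than chance on this set).
#'
#' @param object A fitted [crt_screener()].
#' @param newdata Labeled citations (CSV path, data frame or citation list).
#' @param bootstrap A [bootstrap_config()] or `NULL`.
#' @param column_map,label_values Passed to the reader for file input.
#' @return A [eval_report()] object.
#' @export
evaluate_screener <- function(object, newdata, bootstrap = bootstrap_config(),
                              column_map = NULL, label_values = NULL) {
  citations <- as_citation_list(newdata, column_map, label_values)
  labels <- citation_labels(citations)
  if (anyNA(labels)) stop2("all records must be labeled for evaluation")
  if (length(unique(labels)) < 2)
    stop2("both classes must be present in the evaluation set")
  if (length(citations) < 100)
    warning("fewer than 100 labeled records; external validation on at ",
            "least 100 randomly screened records is recommended",
            call. = FALSE)
  docs <- preprocess_corpus(citations, object$preprocess)
  scores <- predict(object, docs, type = "response")
  rep <- eval_report(scores, labels, object$policy$threshold, bootstrap)
  if (rep$auc < 0.5)
    warning(sprintf("AUC %.3f is below chance on this set; the screener ",
                    rep$auc), "does not transfer to this corpus",
            call. = FALSE)
  rep
}

# ---- bundle persistence -----------------------------------------------------

#' Save a fitted screener as a model bundle directory
#'
#' Writes a directory containing a JSON manifest (package version, all
#' configurations, the threshold policy, seeds, and per-file MD5 checksums)
#' plus the model payload.  [load_screener()] verifies the checksums.
#'
#' @param object A fitted [crt_screener()].
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_screener <- function(object, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- file.path(dir, "members.rds")
  saveRDS(object[setdiff(names(object), "call")], payload, version = 2)
  manifest <- list(
    format = "crtscreen_bundle", format_version = 1L,
    package_version = object$version,
    threshold = object$policy$threshold,
    target_sensitivity = object$policy$target_sensitivity,
    seed = object$seed,
    n_train = object$n_train, n_validation = object$n_validation,
    checksums = as.list(tools::md5sum(payload)))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load a saved screener bundle
#'
#' @param dir Directory written by [save_screener()].
#' @return The restored `crt_screener` object.
#' @export
load_screener <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop2("not a screener bundle: ", dir)
  manifest <- jsonlite::fromJSON(manifest_path)
  if (!identical(manifest$format, "crtscreen_bundle"))
    stop2("unrecognized bundle format in ", dir)
  payload <- file.path(dir, "members.rds")
  sum_now <- unname(tools::md5sum(payload))
  if (!identical(sum_now, unname(unlist(manifest$checksums["members.rds"]))))
    stop2("bundle checksum mismatch for members.rds")
  obj <- readRDS(payload)
  class(obj) <- "crt_screener"
  obj
}
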