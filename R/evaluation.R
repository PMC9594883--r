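#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney concordance probability:
#' `(concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg)`, evaluated via
#' mid-ranks, which agrees exactly with trapezoidal integration of the ROC
#' curve.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop2("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' One `(fpr, tpr)` point per unique score threshold (ties pooled), from
#' `(0, 0)` to `(1, 1)`, monotone non-decreasing in both coordinates.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  uniq <- !duplicated(s, fromLast = TRUE)   # last index of each tie block
  tp <- cumsum(y)[uniq]; fp <- cumsum(1 - y)[uniq]
  data.frame(threshold = c(Inf, s[uniq]),
             fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Confusion counts at a decision threshold
#'
#' Positive iff `score >= t`.
#'
#' @inheritParams roc_auc
#' @param t Decision threshold.
#' @return Object of class `"confusion_counts"`: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  labels <- as.integer(labels)
  pred <- scores >= t
  structure(list(TP = sum(pred & labels == 1), FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0), FN = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' Number needed to screen
#'
#' The average number of algorithm-positive records a reviewer must read to
#' find one true CRT report: `(TP + FP) / TP`, i.e. the reciprocal of the
#' positive predictive value.  Undefined (NA, with a warning) when `TP = 0`.
#'
#' @param counts A [confusion_at_threshold()] result.
#' @return Numeric scalar (full precision; report rounded to 1 decimal).
#' @export
number_needed_to_screen <- function(counts) {
  if (counts$TP == 0) {
    warning("TP = 0: number needed to screen is undefined", call. = FALSE)
    return(NA_real_)
  }
  (counts$TP + counts$FP) / counts$TP
}

#' Number needed to screen from published rates
#'
#' Builds the implied confusion counts from a sensitivity, false-positive
#' rate, prevalence and sample size, then applies
#' [number_needed_to_screen()].  This reconstructs the screening-workload
#' column of a performance table from its printed rates.
#'
#' @param sensitivity True-positive rate in \[0, 1\].
#' @param fpr False-positive rate (1 - specificity) in \[0, 1\].
#' @param prevalence Fraction of records that are true positives.
#' @param n Total number of records.
#' @return Numeric scalar.
#' @export
nns_from_rates <- function(sensitivity, fpr, prevalence, n) {
  n_pos <- prevalence * n
  n_neg <- n - n_pos
  counts <- structure(list(TP = sensitivity * n_pos, FP = fpr * n_neg,
                           TN = (1 - fpr) * n_neg,
                           FN = (1 - sensitivity) * n_pos),
                      class = "confusion_counts")
  number_needed_to_screen(counts)
}

#' Number needed to read
#'
#' Without any classifier, the average number of records read per relevant
#' record: `n_total / n_relevant` (the reciprocal of prevalence).
#'
#' @param n_relevant Number of relevant (positive) records; must be > 0.
#' @param n_total Total records.
#' @return Numeric scalar.
#' @export
number_needed_to_read <- function(n_relevant, n_total) {
  if (n_relevant <= 0) {
    warning("no relevant records: number needed to read is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  n_total / n_relevant
}

#' Bootstrap configuration for confidence intervals
#'
#' Class-stratified percentile bootstrap, 2000 replicates at the 95% level
#' by default — matching the conventional defaults of ROC bootstrap
#' procedures.
#'
#' @param n_replicates Number of bootstrap replicates (default 2000).
#' @param stratified Resample within each class (default `TRUE`).
#' @param ci_level Interval coverage (default 0.95).
#' @param seed Integer seed.
#' @return An object of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(n_replicates = 2000L, stratified = TRUE,
                             ci_level = 0.95, seed = 1L) {
  stopifnot(n_replicates >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 stratified = isTRUE(stratified), ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap confidence interval for a screening metric
#'
#' Class-stratified resampling with replacement; the percentile interval of
#' the metric over replicates.  Degenerate replicates (metric undefined) are
#' redrawn, up to a cap.
#'
#' @inheritParams roc_auc
#' @param metric `"auc"`, `"sensitivity"` or `"specificity"` (the latter two
#'   at threshold `t`).
#' @param cfg A [bootstrap_config()].
#' @param t Decision threshold for the thresholded metrics.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = c("auc", "sensitivity",
                                                    "specificity"),
                         cfg = bootstrap_config(), t = 0.5) {
  metric <- match.arg(metric)
  labels <- as.integer(labels)
  i_pos <- which(labels == 1); i_neg <- which(labels == 0)
  if (!length(i_pos) || !length(i_neg))
    stop2("both classes must be present")
  metric_fun <- switch(metric,
    auc = function(s, l) roc_auc(s, l),
    sensitivity = function(s, l) sum(s >= t & l == 1) / sum(l == 1),
    specificity = function(s, l) sum(s < t & l == 0) / sum(l == 0))
  set.seed(cfg$seed)
  vals <- numeric(cfg$n_replicates)
  redraws <- 0L
  for (b in seq_len(cfg$n_replicates)) {
    repeat {
      idx <- if (cfg$stratified) {
        c(sample(i_pos, length(i_pos), replace = TRUE),
          sample(i_neg, length(i_neg), replace = TRUE))
      } else sample(seq_along(labels), length(labels), replace = TRUE)
      v <- tryCatch(metric_fun(scores[idx], labels[idx]), error = function(e) NA_real_)
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > 100L) {
        warning("too many degenerate bootstrap replicates", call. = FALSE)
        v <- NA_real_
        break
      }
    }
    vals[b] <- v
  }
  alpha <- (1 - cfg$ci_level) / 2
  unname(quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Per-class term document frequencies
#'
#' For every token in the labeled corpus, the fraction of positive (CRT) and
#' of negative documents containing it — the quantities behind per-class
#' term-association scatter plots (e.g. "cluster" appearing in 67% of CRT
#' vs 1.7% of non-CRT citations).
#'
#' @param corpus Labeled `token_document`s.
#' @param sort_by `"difference"` (positive minus negative fraction,
#'   descending) or `"none"` (alphabetical).
#' @return Data frame with columns `term`, `frac_positive`, `frac_negative`,
#'   `difference`.
#' @export
term_class_association <- function(corpus, sort_by = c("difference", "none")) {
  sort_by <- match.arg(sort_by)
  labels <- check_labeled(corpus)
  pos_docs <- corpus[labels == 1]
  neg_docs <- corpus[labels == 0]
  df_of <- function(docs)
    table(unlist(lapply(docs, function(d) unique(d$tokens)),
                 use.names = FALSE))
  t_pos <- df_of(pos_docs); t_neg <- df_of(neg_docs)
  terms <- sort(union(names(t_pos), names(t_neg)))
  fp <- as.numeric(t_pos[terms]); fp[is.na(fp)] <- 0
  fn <- as.numeric(t_neg[terms]); fn[is.na(fn)] <- 0
  out <- data.frame(term = terms,
                    frac_positive = fp / length(pos_docs),
                    frac_negative = fn / length(neg_docs),
                    stringsAsFactors = FALSE)
  out$difference <- out$frac_positive - out$frac_negative
  if (sort_by == "difference") out <- out[order(-out$difference, out$term), ]
  rownames(out) <- NULL
  out
}

#' Full screening evaluation report
#'
#' Everything a performance table needs for one model on one labeled set:
#' AUC with bootstrap CI, sensitivity and specificity at the decision
#' threshold with bootstrap CIs, confusion counts, number needed to screen
#' (with CI derived from the sensitivity/specificity replicates), number
#' needed to read, and the ROC curve.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold.
#' @param bootstrap A [bootstrap_config()], or `NULL` to skip intervals.
#' @return An object of class `"screen_eval"`.
#' @export
eval_report <- function(scores, labels, threshold,
                        bootstrap = bootstrap_config()) {
  labels <- as.integer(labels)
  counts <- confusion_at_threshold(scores, labels, threshold)
  n_pos <- counts$TP + counts$FN; n_neg <- counts$TN + counts$FP
  sens <- counts$TP / n_pos
  spec <- counts$TN / n_neg
  nns <- number_needed_to_screen(counts)
  cis <- list(auc = c(NA, NA), sensitivity = c(NA, NA),
              specificity = c(NA, NA), nns = c(NA, NA))
  if (!is.null(bootstrap)) {
    cis$auc <- bootstrap_ci(scores, labels, "auc", bootstrap)
    cis$sensitivity <- bootstrap_ci(scores, labels, "sensitivity", bootstrap,
                                    t = threshold)
    cis$specificity <- bootstrap_ci(scores, labels, "specificity", bootstrap,
                                    t = threshold)
    # NNS interval from the implied rate intervals (worst/best case pairing)
    prev <- n_pos / (n_pos + n_neg)
    n <- n_pos + n_neg
    lo <- nns_from_rates(cis$sensitivity[2], 1 - cis$specificity[1], prev, n)
    hi <- nns_from_rates(cis$sensitivity[1], 1 - cis$specificity[2], prev, n)
    cis$nns <- c(lo, hi)
  }
  structure(list(auc = roc_auc(scores, labels), auc_ci = cis$auc,
                 sensitivity = sens, sensitivity_ci = cis$sensitivity,
                 specificity = spec, specificity_ci = cis$specificity,
                 fpr = 1 - spec, threshold = threshold, counts = counts,
                 nns = nns, nns_ci = cis$nns,
                 nnr = number_needed_to_read(n_pos, n_pos + n_neg),
                 n = n_pos + n_neg, n_pos = n_pos,
                 roc = roc_curve(scores, labels)),
            class = "screen_eval")
}

#' @export
print.screen_eval <- function(x, digits = 1, ...) {
  pct <- function(v) sprintf(paste0("%.", digits, "f"), 100 * v)
  ci <- function(v) if (anyNA(v)) "" else
    sprintf(" (%s, %s)", pct(v[1]), pct(v[2]))
  cat("Screening evaluation on ", x$n, " records (", x$n_pos,
      " positives)\n", sep = "")
  cat("  AUC, %:                 ", pct(x$auc), ci(x$auc_ci), "\n", sep = "")
  cat("  Sensitivity, %:         ", pct(x$sensitivity),
      ci(x$sensitivity_ci), "\n", sep = "")
  cat("  False positive rate, %: ", pct(x$fpr),
      if (anyNA(x$specificity_ci)) "" else
        sprintf(" (%s, %s)", pct(1 - x$specificity_ci[2]),
                pct(1 - x$specificity_ci[1])), "\n", sep = "")
  cat("  Number needed to screen:", sprintf(" %.1f", x$nns),
      if (anyNA(x$nns_ci)) "" else sprintf(" (%.1f, %.1f)", x$nns_ci[1],
                                           x$nns_ci[2]), "\n", sep = "")
  cat("  Number needed to read:  ", sprintf(" %.1f", x$nnr), "\n", sep = "")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param x A [eval_report()] result.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
eval_report_json <- function(x, path = NULL) {
  obj <- list(auc = x$auc, auc_ci = x$auc_ci, sensitivity = x$sensitivity,
              sensitivity_ci = x$sensitivity_ci, specificity = x$specificity,
              specificity_ci = x$specificity_ci, threshold = x$threshold,
              counts = unclass(x$counts), nns = x$nns, nnr = x$nnr, n = x$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
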