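#' Select the sensitivity-targeted decision threshold
#'
#' Candidate thresholds are the unique observed probabilities.  The returned
#' threshold is the LARGEST candidate `t` whose sensitivity (positive iff
#' `score >= t`) meets the target — which, because specificity is
#' non-decreasing in `t`, simultaneously maximizes specificity subject to
#' the sensitivity constraint.  If no candidate qualifies, the minimum
#' observed score is returned with a warning.
#'
#' @param scores Numeric validation probabilities.
#' @param labels 0/1 labels aligned with `scores`; positives must be present.
#' @param target_sensitivity Required sensitivity in (0, 1\]; default 0.95.
#' @return An object of class `"threshold_policy"`: `threshold`,
#'   `target_sensitivity`, `achieved_sensitivity`, `achieved_specificity`.
#' @export
select_threshold <- function(scores, labels, target_sensitivity = 0.95) {
  stopifnot(length(scores) == length(labels),
            target_sensitivity > 0, target_sensitivity <= 1)
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop2("validation set contains no positives")
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1) / n_pos,
                 numeric(1))
  ok <- which(sens >= target_sensitivity)
  if (length(ok)) {
    threshold <- cand[max(ok)]
  } else {
    threshold <- min(scores)
    warning("no threshold achieves sensitivity >= ", target_sensitivity,
            "; falling back to the minimum observed score", call. = FALSE)
  }
  n_neg <- sum(labels == 0)
  structure(list(
    threshold = threshold,
    target_sensitivity = target_sensitivity,
    achieved_sensitivity = sum(scores >= threshold & labels == 1) / n_pos,
    achieved_specificity = if (n_neg > 0)
      sum(scores < threshold & labels == 0) / n_neg else NA_real_),
    class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf(
    "<threshold_policy> threshold=%.6f (target sens %.0f%%; achieved sens %.1f%%, spec %.1f%%)\n",
    x$threshold, 100 * x$target_sensitivity, 100 * x$achieved_sensitivity,
    100 * x$achieved_specificity))
  invisible(x)
}

#' Combine member probabilities into screening results
#'
#' The ensemble score of a record is the unweighted arithmetic mean of the
#' member probabilities; the binary class applies the policy rule
#' (positive iff mean probability >= threshold).
#'
#' @param members Named list of `crt_member` models; the default
#'   configuration requires exactly the three kinds `cnn_wholeword`,
#'   `cnn_subword`, `svm` (override with `allow_any_members = TRUE`).
#' @param docs `token_document`s to score.
#' @param policy A [select_threshold()] policy (or a bare threshold).
#' @param allow_any_members Permit a member set other than the default three.
#' @return A `screening_results` data frame: `record_id`, `probability`,
#'   `predicted_label`, and one probability column per member.
#' @export
ensemble_predict <- function(members, docs, policy,
                             allow_any_members = FALSE) {
  kinds <- vapply(members, `[[`, character(1), "kind")
  if (!allow_any_members &&
      !setequal(kinds, c("cnn_wholeword", "cnn_subword", "svm")))
    stop2("expected exactly the member kinds cnn_wholeword, cnn_subword, ",
          "svm; got: ", paste(kinds, collapse = ", "),
          " (set allow_any_members = TRUE to override)")
  if (inherits(docs, "token_document")) docs <- list(docs)
  threshold <- if (inherits(policy, "threshold_policy")) policy$threshold
               else as.numeric(policy)
  probs <- lapply(members, function(m) predict(m, docs))
  mat <- do.call(cbind, probs)
  colnames(mat) <- kinds
  avg <- rowMeans(mat)
  out <- data.frame(
    record_id = vapply(docs, `[[`, character(1), "record_id"),
    probability = avg,
    predicted_label = as.integer(avg >= threshold),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat))
  class(out) <- c("screening_results", "data.frame")
  out
}
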